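#' Continuous two-reference differentiation index (B-Index)
#'
#' Fits the B-Index: for each sample, the beta profile at the top `n_cpgs`
#' most differentially methylated CpGs between two reference cell types is
#' projected (non-negative least squares) onto the two-column reference, and
#' the index is
#' \deqn{B = \max(0,\hat p_{mem}) / (\max(0,\hat p_{mem}) + \max(0,\hat p_{nv}))}
#' so that 0 means fully naive-like and 1 fully memory-like. The clamp at 0
#' is kept explicitly even though the solver already enforces non-negativity,
#' for robustness to alternative solvers.
#'
#' A sample whose two raw coefficients are both zero has an undefined index
#' and is returned as `NA` with a warning.
#'
#' @param b Beta matrix (CpGs x samples).
#' @param ref Reference library containing both named cell types.
#' @param mem_type,nv_type Reference column names for the memory-like and
#'   naive-like endpoints (defaults `"B-memory"`, `"B-naive"`).
#' @param n_cpgs Number of top-ranked informative CpGs to project on
#'   (default 400, the point where the index stabilizes as CpGs are added in
#'   decreasing order of reference difference).
#' @param curve_grid Optional ascending integer vector; if given, a
#'   stabilization curve over these CpG-set sizes is computed and stored
#'   (see [stabilization_curve()]).
#' @return Object of class `"bindex"`: list with `b_index` (named vector),
#'   `raw` (samples x 2 matrix of raw coefficients), `cpg_list`,
#'   `n_cpgs_used`, and optionally `curve`.
#' @seealso [stabilization_curve()], [classify_by_cutoff()]
#' @examples
#' ref <- cbind(`B-memory` = c(.9, .9, .1, .5), `B-naive` = c(.1, .1, .9, .5))
#' rownames(ref) <- paste0("cg", 1:4)
#' b <- cbind(s1 = ref[, 1], s2 = 0.5 * ref[, 1] + 0.5 * ref[, 2])
#' fit <- bindex(b, ref, n_cpgs = 3)
#' coef(fit)  # s1 = 1 (pure memory), s2 = 0.5
#' @export
bindex <- function(b, ref, mem_type = "B-memory", nv_type = "B-naive",
                   n_cpgs = 400, curve_grid = NULL) {
  stopifnot(n_cpgs >= 2)
  al <- align_cpgs(b, ref[, c(mem_type, nv_type), drop = FALSE])
  if (n_cpgs > al$n_common)
    stop("n_cpgs (", n_cpgs, ") exceeds the ", al$n_common,
         " CpGs shared by data and reference")
  cpgs <- rank_informative_cpgs(al$b, mem_type, nv_type, n_cpgs)
  raw <- project_two_ref(al$a[cpgs, , drop = FALSE],
                         al$b[cpgs, , drop = FALSE])
  bi <- bindex_from_raw(raw[, 1], raw[, 2])
  if (anyNA(bi))
    warning("undefined B-Index (zero raw coefficients) for sample(s): ",
            paste(names(bi)[is.na(bi)], collapse = ", "))
  out <- structure(list(b_index = bi, raw = raw, cpg_list = cpgs,
                        n_cpgs_used = n_cpgs,
                        mem_type = mem_type, nv_type = nv_type,
                        call = match.call()),
                   class = "bindex")
  if (!is.null(curve_grid))
    out$curve <- stabilization_curve(b, ref, mem_type, nv_type,
                                     grid = curve_grid)
  out
}

# project every sample (columns of betas) onto a two-column reference
project_two_ref <- function(betas, ref2) {
  raw <- t(apply(betas, 2, function(y) nnls_fit(ref2, y)))
  dimnames(raw) <- list(colnames(betas), colnames(ref2))
  raw
}

bindex_from_raw <- function(p_mem, p_nv) {
  num <- pmax(p_mem, 0)   # argument order keeps the sample names
  den <- num + pmax(p_nv, 0)
  ifelse(den == 0, NA_real_, num / den)
}

#' B-Index stabilization curve over CpG-set sizes
#'
#' Recomputes the B-Index at each size in `grid`, always using nested
#' prefixes of one fixed ranking (CpGs added in decreasing order of
#' reference difference). The per-sample stability score is the maximum
#' absolute change over the tail of the grid (from the second-largest size
#' on).
#'
#' @inheritParams bindex
#' @param grid Ascending vector of CpG counts, minimum at least 2.
#' @return Object of class `"bindex_curve"`: list with `curve`
#'   (samples x grid matrix of indices), `grid`, and `stability`
#'   (per-sample max |change| over the last two grid sizes).
#' @export
stabilization_curve <- function(b, ref, mem_type = "B-memory",
                                nv_type = "B-naive", grid) {
  grid <- as.integer(grid)
  stopifnot(length(grid) >= 1, min(grid) >= 2, !is.unsorted(grid, strictly = TRUE))
  al <- align_cpgs(b, ref[, c(mem_type, nv_type), drop = FALSE])
  if (max(grid) > al$n_common)
    stop("largest grid value exceeds the available CpGs")
  ranking <- rank_informative_cpgs(al$b, mem_type, nv_type, max(grid))
  curve <- sapply(grid, function(n) {
    cpgs <- ranking[seq_len(n)]
    raw <- project_two_ref(al$a[cpgs, , drop = FALSE],
                           al$b[cpgs, , drop = FALSE])
    bindex_from_raw(raw[, 1], raw[, 2])
  })
  if (is.null(dim(curve))) curve <- matrix(curve, nrow = 1,
                                           dimnames = list(colnames(b), NULL))
  colnames(curve) <- as.character(grid)
  k <- length(grid)
  stability <- if (k >= 2) abs(curve[, k] - curve[, k - 1]) else rep(NA_real_, nrow(curve))
  structure(list(curve = curve, grid = grid, stability = stability),
            class = "bindex_curve")
}

#' Dichotomize an index at a cutoff
#'
#' Labels `"high"` where the value is strictly greater than the cutoff,
#' `"low"` otherwise (ties go to `"low"`); `NA` values stay unlabeled.
#'
#' @param b_index Numeric vector (e.g. `coef()` of a [bindex()] fit).
#' @param cutoff Threshold in (0, 1); 0.60 is the Youden-optimal value
#'   reported for separating memory-like from naive-like tumors, kept here
#'   as a configurable default rather than a recommendation.
#' @return Factor with levels `low`, `high`.
#' @export
classify_by_cutoff <- function(b_index, cutoff = 0.60) {
  stopifnot(cutoff >= 0, cutoff < 1)
  factor(ifelse(b_index > cutoff, "high", "low"), levels = c("low", "high"))
}

#' @export
print.bindex <- function(x, ...) {
  cat("B-Index fit (", x$mem_type, " vs ", x$nv_type, ")\n", sep = "")
  cat(sprintf("  %d samples, %d informative CpGs\n",
              length(x$b_index), x$n_cpgs_used))
  print(summary(unname(x$b_index)))
  invisible(x)
}

#' @export
coef.bindex <- function(object, ...) object$b_index

#' @export
summary.bindex <- function(object, cutoff = 0.60, ...) {
  cls <- classify_by_cutoff(object$b_index, cutoff)
  structure(list(n = length(object$b_index),
                 n_cpgs_used = object$n_cpgs_used,
                 mean = mean(object$b_index, na.rm = TRUE),
                 sd = stats::sd(object$b_index, na.rm = TRUE),
                 range = range(object$b_index, na.rm = TRUE),
                 cutoff = cutoff, counts = table(cls),
                 n_undefined = sum(is.na(object$b_index))),
            class = "summary.bindex")
}

#' @export
print.summary.bindex <- function(x, ...) {
  cat(sprintf("B-Index over %d samples (%d informative CpGs)\n",
              x$n, x$n_cpgs_used))
  cat(sprintf("  mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              x$mean, x$sd, x$range[1], x$range[2]))
  cat(sprintf("  at cutoff %.2f: %d low, %d high", x$cutoff,
              x$counts[["low"]], x$counts[["high"]]))
  if (x$n_undefined > 0) cat(sprintf(", %d undefined", x$n_undefined))
  cat("\n")
  invisible(x)
}

#' @export
predict.bindex <- function(object, cutoff = 0.60, ...) {
  classify_by_cutoff(object$b_index, cutoff)
}

#' @export
plot.bindex <- function(x, ...) {
  if (!is.null(x$curve)) return(plot(x$curve, ...))
  graphics::stripchart(x$b_index, method = "jitter", pch = 16,
                       xlab = "B-Index", xlim = c(0, 1), ...)
  invisible(x)
}

#' @export
plot.bindex_curve <- function(x, ...) {
  graphics::matplot(x$grid, t(x$curve), type = "l", lty = 1,
                    col = grDevices::grey(0.3, alpha = 0.5),
                    xlab = "CpGs included", ylab = "B-Index",
                    ylim = c(0, 1), ...)
  invisible(x)
}
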