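#' Rank CpGs by reference differential methylation between two cell types
#'
#' CpGs are ordered by decreasing absolute difference between the two
#' reference mean-beta columns; ties are broken by CpG identifier
#' (lexicographic, ascending).
#'
#' @param ref Reference library matrix (CpGs x cell types).
#' @param type_a,type_b Cell-type column names.
#' @param n Number of top CpGs to return; defaults to all.
#' @return Character vector of CpG identifiers, most differential first.
#' @export
rank_informative_cpgs <- function(ref, type_a, type_b, n = nrow(ref)) {
  for (ty in c(type_a, type_b))
    if (!ty %in% colnames(ref)) stop("unknown cell type: ", ty)
  if (n > nrow(ref)) stop("n exceeds the number of CpGs in the library")
  d <- abs(ref[, type_a] - ref[, type_b])
  ord <- order(-d, rownames(ref), method = "radix")
  rownames(ref)[ord][seq_len(n)]
}

#' Project one sample onto a reference library (raw coefficients)
#'
#' Non-negative least-squares fit of a sample's beta profile onto the
#' reference columns; coefficients are the raw (unnormalized) cell-type
#' loadings.
#'
#' @param sample_betas Numeric vector of betas, aligned to the rows of `ref`.
#' @param ref Reference matrix, CpGs x cell types; must have full column rank
#'   and at least as many CpGs as cell types.
#' @return Named non-negative coefficient vector.
#' @export
project_proportions <- function(sample_betas, ref) {
  ref <- as.matrix(ref)
  if (length(sample_betas) != nrow(ref))
    stop("sample and reference are not CpG-aligned")
  if (nrow(ref) < ncol(ref))
    stop("fewer CpGs than cell types after alignment")
  if (qr(ref)$rank < ncol(ref))
    stop("reference matrix is rank-deficient after CpG alignment")
  nnls_fit(ref, sample_betas)
}

#' Reference-based cell-type deconvolution of a beta matrix
#'
#' Each sample is projected onto the reference library by non-negative
#' constrained projection on the common CpG set; raw coefficients are then
#' normalized to sum to one per sample. Samples whose raw coefficients are
#' all zero get `NA` proportions (flagged, never silently 0).
#'
#' @param b Beta matrix (CpGs x samples).
#' @param ref Reference library (CpGs x cell types).
#' @param cell_types Optional subset of reference columns to use.
#' @return An object of class `"cell_proportions"`: a list with matrices
#'   `raw` and `proportions` (samples x cell types), and `n_cpgs_used`.
#' @export
deconvolve <- function(b, ref, cell_types = NULL) {
  if (!is.null(cell_types)) {
    missing_ty <- setdiff(cell_types, colnames(ref))
    if (length(missing_ty) > 0)
      stop("cell types not in reference: ", paste(missing_ty, collapse = ", "))
    ref <- ref[, cell_types, drop = FALSE]
  }
  al <- align_cpgs(b, ref)
  raw <- t(apply(al$a, 2, project_proportions, ref = al$b))
  dimnames(raw) <- list(colnames(b), colnames(ref))
  rs <- rowSums(raw)
  prop <- raw / rs
  prop[rs == 0, ] <- NA_real_
  if (any(rs == 0))
    warning("all-zero raw coefficients for sample(s): ",
            paste(rownames(raw)[rs == 0], collapse = ", "),
            "; proportions set to NA")
  structure(list(raw = raw, proportions = prop, n_cpgs_used = al$n_common),
            class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat("Cell-type deconvolution by constrained projection\n")
  cat(sprintf("  %d samples, %d cell types, %d CpGs used\n",
              nrow(x$proportions), ncol(x$proportions), x$n_cpgs_used))
  cat("Mean proportions:\n")
  print(round(colMeans(x$proportions, na.rm = TRUE), 4))
  invisible(x)
}

#' @export
coef.cell_proportions <- function(object, normalized = TRUE, ...) {
  if (normalized) object$proportions else object$raw
}

#' @export
summary.cell_proportions <- function(object, ...) {
  s <- cbind(mean = colMeans(object$proportions, na.rm = TRUE),
             sd   = apply(object$proportions, 2, stats::sd, na.rm = TRUE),
             min  = apply(object$proportions, 2, min, na.rm = TRUE),
             max  = apply(object$proportions, 2, max, na.rm = TRUE))
  structure(list(table = s, n = nrow(object$proportions),
                 n_cpgs_used = object$n_cpgs_used),
            class = "summary.cell_proportions")
}

#' @export
print.summary.cell_proportions <- function(x, ...) {
  cat(sprintf("Deconvolution of %d samples on %d CpGs\n", x$n, x$n_cpgs_used))
  print(round(x$table, 4))
  invisible(x)
}
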