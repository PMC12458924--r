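#' Select the most-mixed tertile of samples
#'
#' Samples are ranked ascending by their deconvolved proportion of
#' `key_type`; the lowest `ceiling(n/3)` are returned (a cohort of 89 gives
#' 30). Ties at the boundary are broken by sample identifier.
#'
#' @param p A `"cell_proportions"` object from [deconvolve()], or a
#'   samples x cell-types proportion matrix.
#' @param key_type Cell-type column to rank by (e.g. `"B-memory"`).
#' @return List with `samples` (identifiers of the lowest tertile, in rank
#'   order) and `threshold` (the largest `key_type` proportion within the
#'   selected tertile).
#' @export
select_most_mixed_tertile <- function(p, key_type) {
  prop <- if (inherits(p, "cell_proportions")) p$proportions else as.matrix(p)
  if (!key_type %in% colnames(prop)) stop("unknown cell type: ", key_type)
  if (nrow(prop) < 3) stop("need at least 3 samples to form tertiles")
  v <- prop[, key_type]
  ord <- order(v, rownames(prop), method = "radix")
  k <- ceiling(nrow(prop) / 3)
  sel <- rownames(prop)[ord][seq_len(k)]
  list(samples = sel, threshold = v[sel[k]])
}

#' Expected betas of a sample under the mixture hypothesis
#'
#' If a sample truly were a physical blend of the reference cell types with
#' its deconvolved proportions, its beta at CpG i would be the weighted
#' average of the reference betas:
#' \eqn{\tilde\beta_i = \sum_k p_k \beta^{ref}_{i,k}}.
#'
#' @param sample_proportions Non-negative weights over the reference cell
#'   types (named or in reference column order), summing to 1.
#' @param ref Reference library matrix.
#' @param cpgs CpG identifiers at which to evaluate; must be present in `ref`.
#' @return Named numeric vector of expected betas.
#' @export
build_custom_mixture <- function(sample_proportions, ref, cpgs) {
  missing_cg <- setdiff(cpgs, rownames(ref))
  if (length(missing_cg) > 0)
    stop("CpG(s) absent from reference: ", paste(missing_cg, collapse = ", "))
  p <- as.numeric(sample_proportions)
  if (!is.null(names(sample_proportions)))
    ref <- ref[, names(sample_proportions), drop = FALSE]
  stopifnot(length(p) == ncol(ref), all(p >= -1e-12),
            abs(sum(p) - 1) < 1e-6)
  drop(ref[cpgs, , drop = FALSE] %*% p)
}

#' In-silico weighted-average mixture of reference profiles
#'
#' @param ref Reference library matrix.
#' @param weights Non-negative weights over the columns of `ref`, summing
#'   to 1 (named, or in column order).
#' @return Beta vector over the reference CpGs.
#' @export
in_silico_mixture <- function(ref, weights) {
  w <- as.numeric(weights)
  if (!is.null(names(weights))) ref <- ref[, names(weights), drop = FALSE]
  if (length(w) != ncol(ref)) stop("weights length does not match cell types")
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9)
  drop(ref %*% w)
}

#' Tally each CpG to its nearest hypothesis profile
#'
#' Per CpG the observed beta is compared by absolute difference to (i) the
#' sample's custom mixture profile, (ii) the pure memory reference and
#' (iii) the pure naive reference; the CpG is tallied to the closest. Exact
#' ties are assigned with precedence mixture > pure memory > pure naive
#' (i.e. conservatively in favor of the mixture hypothesis); this precedence
#' is configurable via `tie_order`.
#'
#' @param sample_betas Observed betas.
#' @param mixture Expected betas under the mixture hypothesis
#'   ([build_custom_mixture()] output or any aligned vector).
#' @param pure_mem,pure_nv Pure reference beta vectors, aligned to
#'   `sample_betas`.
#' @param tie_order Character permutation of
#'   `c("mixture", "pure_mem", "pure_nv")`, first = highest precedence.
#' @return List of class `"mixture_tally"` with counts `tally_mixture`,
#'   `tally_pure_mem`, `tally_pure_nv`, `n_cpgs_tested`, and
#'   `pure_fraction` = (pure_mem + pure_nv) / n.
#' @export
tally_nearest <- function(sample_betas, mixture, pure_mem, pure_nv,
                          tie_order = c("mixture", "pure_mem", "pure_nv")) {
  n <- length(sample_betas)
  stopifnot(length(mixture) == n, length(pure_mem) == n, length(pure_nv) == n)
  stopifnot(setequal(tie_order, c("mixture", "pure_mem", "pure_nv")))
  d <- cbind(mixture  = abs(sample_betas - mixture),
             pure_mem = abs(sample_betas - pure_mem),
             pure_nv  = abs(sample_betas - pure_nv))
  d <- d[, tie_order, drop = FALSE]  # max.col ties resolved by precedence
  win <- tie_order[max.col(-d, ties.method = "first")]
  structure(list(n_cpgs_tested = n,
                 tally_mixture  = sum(win == "mixture"),
                 tally_pure_mem = sum(win == "pure_mem"),
                 tally_pure_nv  = sum(win == "pure_nv"),
                 pure_fraction  = sum(win != "mixture") / n),
            class = "mixture_tally")
}

#' Mixture-vs-intermediate-state diagnostic
#'
#' Decides whether deconvolved samples look like physical mixtures of two
#' cell populations or like a single population with per-CpG intermediate
#' states. The most-mixed tertile (lowest `mem_type` proportion) is
#' selected; at the top `n_top` CpGs separating the two references, each
#' sample's betas are compared to its own expected-mixture profile (built
#' from the sample's full proportion vector over all reference cell types)
#' and to the two pure references, and tallied to the nearest. A high pure
#' fraction indicates intermediate states, a low one indicates true
#' mixtures.
#'
#' @param b Beta matrix.
#' @param ref Reference library (all cell types used for the expected
#'   mixture).
#' @param p `"cell_proportions"` from [deconvolve()] on the same samples.
#' @param mem_type,nv_type The two endpoint cell types.
#' @param n_top Number of top differential CpGs to test (default 100).
#' @param tie_order Passed to [tally_nearest()].
#' @return Data frame of class `"mixture_diagnostic"`, one row per selected
#'   sample: tallies, `pure_fraction`, plus attributes `samples` and
#'   `threshold` from the tertile selection.
#' @export
run_mixture_diagnostic <- function(b, ref, p, mem_type = "B-memory",
                                   nv_type = "B-naive", n_top = 100,
                                   tie_order = c("mixture", "pure_mem", "pure_nv")) {
  al <- align_cpgs(b, ref)
  sel <- select_most_mixed_tertile(p, mem_type)
  cpgs <- rank_informative_cpgs(al$b, mem_type, nv_type,
                                min(n_top, al$n_common))
  prop <- if (inherits(p, "cell_proportions")) p$proportions else as.matrix(p)
  rows <- lapply(sel$samples, function(s) {
    mix <- build_custom_mixture(prop[s, ], al$b, cpgs)
    tl <- tally_nearest(al$a[cpgs, s], mix,
                        al$b[cpgs, mem_type], al$b[cpgs, nv_type],
                        tie_order = tie_order)
    data.frame(sample_id = s, n_cpgs_tested = tl$n_cpgs_tested,
               tally_mixture = tl$tally_mixture,
               tally_pure_mem = tl$tally_pure_mem,
               tally_pure_nv = tl$tally_pure_nv,
               pure_fraction = tl$pure_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- sel$threshold
  class(out) <- c("mixture_diagnostic", "data.frame")
  out
}

#' @export
print.mixture_diagnostic <- function(x, ...) {
  cat(sprintf("Mixture diagnostic on %d most-mixed samples (%d CpGs each)\n",
              nrow(x), x$n_cpgs_tested[1]))
  cat(sprintf("  mean pure fraction %.3f (sd %.3f)\n",
              mean(x$pure_fraction), stats::sd(x$pure_fraction)))
  NextMethod()
}
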