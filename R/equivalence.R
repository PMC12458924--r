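#' Two one-sided tests (TOST) of equivalence between two samples
#'
#' Welch (unequal-variance) construction by default: with
#' `diff = mean(x) - mean(y)` and Welch-Satterthwaite SE and df,
#' `t_lower = (diff + epsilon)/SE` is tested against `H0: diff <= -epsilon`
#' (upper-tail p) and `t_upper = (diff - epsilon)/SE` against
#' `H0: diff >= epsilon` (lower-tail p); the TOST p-value is the larger of
#' the two. Equivalence within `+/- epsilon` is concluded when both
#' one-sided tests reject.
#'
#' When both groups have zero variance and the difference lies strictly
#' inside `(-epsilon, epsilon)`, the limiting p-value 0 is returned with a
#' `degenerate` flag.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param epsilon Equivalence margin (> 0); 0.1 is the conventional
#'   tolerance of +/- 0.1 on the beta scale.
#' @param var_equal Use the pooled-variance construction instead of Welch.
#' @return List: `mean_diff`, `p_lower`, `p_upper`,
#'   `p_tost = max(p_lower, p_upper)`, `df`, `degenerate`.
#' @export
tost_two_sample <- function(x, y, epsilon, var_equal = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, epsilon >= 0)
  r <- tost_stats(mean(x), stats::var(x), length(x),
                  mean(y), stats::var(y), length(y),
                  epsilon, var_equal)
  lapply(r, unname)
}

# vectorized TOST core on summary statistics
tost_stats <- function(m1, v1, n1, m2, v2, n2, epsilon, var_equal = FALSE) {
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep_len(n1 + n2 - 2, length(diff))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  degenerate <- se == 0
  df[degenerate] <- 1  # t is +/-Inf or 0 there; df value immaterial
  one_sided <- function(t_num) {
    t <- ifelse(degenerate, sign(t_num) * Inf, t_num / se)
    t[degenerate & t_num == 0] <- 0
    list(t = t)
  }
  t_lower <- one_sided(diff + epsilon)$t
  t_upper <- one_sided(diff - epsilon)$t
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  list(mean_diff = diff, p_lower = p_lower, p_upper = p_upper,
       p_tost = pmax(p_lower, p_upper), df = df,
       degenerate = degenerate & abs(diff) < epsilon)
}

#' Per-CpG TOST equivalence screen of a case group against reference groups
#'
#' For each CpG in `cpgs` the case group is TOST-tested (margin `epsilon`
#' on the beta scale) against each reference donor group; BH-FDR is applied
#' separately per reference over all CpGs entering the screen, and the
#' equivalent set per reference is `{fdr < alpha}`.
#'
#' @param cases Beta matrix of the case group (CpGs x samples).
#' @param ref_groups Named list of two beta matrices, one per reference
#'   donor group.
#' @param cpgs CpG identifiers to screen (e.g. the differentially
#'   methylated CpGs between the two references); must be present in all
#'   matrices.
#' @param epsilon Equivalence margin (default 0.1).
#' @param alpha FDR threshold (default 0.05).
#' @param var_equal Passed to the TOST construction.
#' @return Object of class `"tost_screen"`: list with `table` (long data
#'   frame: `cpg_id`, `reference`, `mean_diff`, `p_lower`, `p_upper`,
#'   `p_tost`, `fdr_p`) and `sets` (named list of equivalent CpG vectors).
#' @export
run_tost_screen <- function(cases, ref_groups, cpgs, epsilon = 0.1,
                            alpha = 0.05, var_equal = FALSE) {
  stopifnot(is.list(ref_groups), length(ref_groups) >= 1,
            !is.null(names(ref_groups)))
  for (nm in names(ref_groups)) {
    miss <- setdiff(cpgs, rownames(ref_groups[[nm]]))
    if (length(miss) > 0)
      stop("CpG(s) missing from reference group '", nm, "': ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  miss <- setdiff(cpgs, rownames(cases))
  if (length(miss) > 0)
    stop("CpG(s) missing from case matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))

  cx <- cases[cpgs, , drop = FALSE]
  m1 <- rowMeans(cx)
  v1 <- apply(cx, 1, stats::var)
  n1 <- ncol(cx)
  pieces <- lapply(names(ref_groups), function(nm) {
    rx <- ref_groups[[nm]][cpgs, , drop = FALSE]
    st <- tost_stats(m1, v1, n1, rowMeans(rx), apply(rx, 1, stats::var),
                     ncol(rx), epsilon, var_equal)
    data.frame(cpg_id = cpgs, reference = nm, mean_diff = st$mean_diff,
               p_lower = st$p_lower, p_upper = st$p_upper,
               p_tost = st$p_tost, fdr_p = bh_fdr(st$p_tost),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, pieces)
  sets <- lapply(split(tab, tab$reference),
                 function(d) d$cpg_id[d$fdr_p < alpha])
  structure(list(table = tab, sets = sets[names(ref_groups)],
                 epsilon = epsilon, alpha = alpha),
            class = "tost_screen")
}

#' @export
print.tost_screen <- function(x, ...) {
  n_cpg <- length(unique(x$table$cpg_id))
  cat(sprintf("TOST equivalence screen (epsilon = %g) over %d CpGs\n",
              x$epsilon, n_cpg))
  for (nm in names(x$sets))
    cat(sprintf("  equivalent to %s at FDR < %g: %d CpGs\n",
                nm, x$alpha, length(x$sets[[nm]])))
  invisible(x)
}

#' Whole-profile Manhattan-distance similarity to reference means
#'
#' L1 distance (sum of absolute per-CpG beta differences) from each sample
#' to each reference mean profile; the nearest reference is reported, with
#' exact ties flagged.
#'
#' @param samples Beta matrix (CpGs x samples).
#' @param ref_means Matrix of reference mean betas (CpGs x references) or a
#'   named list of vectors; row-aligned with `samples` via the common CpGs.
#' @return Data frame: `sample_id`, one distance column per reference,
#'   `nearest`, `tie`.
#' @export
manhattan_similarity <- function(samples, ref_means) {
  if (is.list(ref_means) && !is.matrix(ref_means))
    ref_means <- do.call(cbind, ref_means)
  al <- align_cpgs(samples, ref_means)
  d <- sapply(seq_len(ncol(al$b)),
              function(j) colSums(abs(al$a - al$b[, j])))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  colnames(d) <- colnames(al$b)
  mins <- apply(d, 1, min)
  tie <- rowSums(d == mins) > 1
  data.frame(sample_id = colnames(samples), d,
             nearest = colnames(d)[apply(d, 1, which.min)],
             tie = tie, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Methylation-state contingency summary of TOST-equivalent CpGs
#'
#' Cross-tabulates which reference each equivalent CpG matches against its
#' methylation state in the cases: a CpG is called hypomethylated when the
#' case-group mean beta is below the midpoint of the two reference means at
#' that CpG, hypermethylated otherwise. CpGs equivalent to both references
#' are excluded from the table and counted separately. Association is
#' tested by Pearson chi-square without continuity correction.
#'
#' @param tost_sets Named list of two CpG id vectors (one per reference),
#'   e.g. `sets` from [run_tost_screen()].
#' @param case_means Named vector of case-group mean betas per CpG.
#' @param ref_means CpGs x 2 matrix of the two reference mean betas (or
#'   named list of two vectors), rownames covering the tested CpGs.
#' @return List of class `"state_contingency"`: `table` (2 x 2 counts,
#'   rows = reference, cols = hypo/hyper), `chisq`, `p`, `n_both_excluded`.
#' @export
state_contingency <- function(tost_sets, case_means, ref_means) {
  stopifnot(length(tost_sets) == 2)
  if (is.list(ref_means) && !is.matrix(ref_means))
    ref_means <- do.call(cbind, ref_means)
  both <- intersect(tost_sets[[1]], tost_sets[[2]])
  sets <- lapply(tost_sets, setdiff, y = both)
  if (sum(lengths(sets)) == 0) stop("no CpGs left for the contingency table")
  mid <- rowMeans(ref_means[, 1:2, drop = FALSE])
  tab <- t(sapply(sets, function(cg) {
    state <- ifelse(case_means[cg] < mid[cg], "hypo", "hyper")
    c(hypo = sum(state == "hypo"), hyper = sum(state == "hyper"))
  }))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, chisq = unname(chi$statistic),
                 p = chi$p.value, n_both_excluded = length(both)),
            class = "state_contingency")
}

#' @export
print.state_contingency <- function(x, ...) {
  cat("Methylation state of equivalent CpGs by matched reference\n")
  print(x$table)
  cat(sprintf("  chi-square = %.4g, p = %.3g (%d CpGs equivalent to both excluded)\n",
              x$chisq, x$p, x$n_both_excluded))
  invisible(x)
}
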