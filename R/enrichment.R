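#' Fisher's exact test on a 2x2 table with a plain odds ratio
#'
#' The p-value follows the exact hypergeometric conventions of
#' [stats::fisher.test()]: `greater` is the upper tail `P(X >= a)`, and
#' `two.sided` sums the probabilities of all outcomes no more likely than
#' the observed one. The reported odds ratio is the sample cross-product
#' `(a*d)/(b*c)`, with the Haldane-Anscombe 0.5 added to every cell iff any
#' cell is zero; the 95% CI is Woolf (normal on the log odds ratio). The
#' exact p is unaffected by the correction.
#'
#' @param a,b,c_,d Cell counts: `a` = foreground with feature, `b` =
#'   foreground without, `c_` = background-only with feature, `d` =
#'   background-only without.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return List: `odds_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
fisher_exact <- function(a, b, c_, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c_, d)
  if (any(counts < 0)) stop("negative cell count")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p = p))  # zero margin: OR undefined
  if (any(counts == 0)) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  list(odds_ratio = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       p = p)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Chi-square statistic `(sum_k (a_k - E[a_k]))^2 / sum_k Var(a_k)` with
#' hypergeometric expectation and variance per stratum and no continuity
#' correction; p-value from chi-square with 1 df. The common odds ratio is
#' the Mantel-Haenszel estimate `sum(a_k d_k/n_k) / sum(b_k c_k/n_k)` with
#' a 95% CI from the Robins-Breslow-Greenland variance of its log.
#'
#' Degenerate strata (zero margin) contribute nothing; if all strata are
#' degenerate the result is flagged undefined.
#'
#' @param strata List of 2x2 count matrices (or of `c(a, b, c, d)` vectors,
#'   row-wise).
#' @param correct Apply a 0.5 continuity correction to the statistic
#'   (default `FALSE`).
#' @return List: `statistic`, `p`, `odds_ratio` (MH), `ci_low`, `ci_high`,
#'   `defined`.
#' @export
cmh_test <- function(strata, correct = FALSE) {
  tabs <- lapply(strata, function(s) {
    if (is.matrix(s)) s else matrix(s, 2, 2, byrow = TRUE)
  })
  a <- vapply(tabs, function(t) t[1, 1], numeric(1))
  b <- vapply(tabs, function(t) t[1, 2], numeric(1))
  cc <- vapply(tabs, function(t) t[2, 1], numeric(1))
  d <- vapply(tabs, function(t) t[2, 2], numeric(1))
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  ok <- n > 1 & r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  if (!any(ok))
    return(list(statistic = NA_real_, p = NA_real_, odds_ratio = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, defined = FALSE))
  ex <- r1 * c1 / n
  vr <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  dev <- abs(sum(a[ok] - ex[ok]))
  if (correct) dev <- max(0, dev - 0.5)
  stat <- dev^2 / sum(vr[ok])
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  R <- a * d / n; S <- b * cc / n
  or_mh <- sum(R) / sum(S)
  P <- (a + d) / n; Q <- (b + cc) / n
  v_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v_log)
  list(statistic = stat, p = p, odds_ratio = or_mh,
       ci_low = exp(log(or_mh) - 1.96 * se),
       ci_high = exp(log(or_mh) + 1.96 * se),
       defined = TRUE)
}

#' Collapse multiple genomic-context annotations to one per CpG
#'
#' Applies the precedence Promoter > 5'UTR > 3'UTR > Exon > Intron; a CpG
#' mapping to no range is labeled Intergenic.
#'
#' @param mappings Named list: CpG id -> character vector of context labels
#'   (possibly empty).
#' @return Named character vector of single context labels.
#' @export
collapse_genomic_context <- function(mappings) {
  precedence <- c("Promoter", "5'UTR", "3'UTR", "Exon", "Intron")
  vapply(mappings, function(ctx) {
    if (length(ctx) == 0) return("Intergenic")
    bad <- setdiff(ctx, precedence)
    if (length(bad) > 0) stop("unknown context label: ",
                              paste(bad, collapse = ", "))
    precedence[min(match(ctx, precedence))]
  }, character(1))
}

#' Flag probes falling in promoter windows of stranded genes
#'
#' The promoter window spans up to 1,500 bases upstream and 200 bases
#' downstream of the TSS (the 5' end per strand): `[TSS-1500, TSS+200]` on
#' `+`, `[TSS-200, TSS+1500]` on `-`; 1-based inclusive coordinates.
#'
#' @param gene_ranges Data frame with columns `chromosome`, `tss`
#'   (transcription start position), `strand` (`"+"` or `"-"`).
#' @param probe_positions Data frame with columns `cpg_id`, `chromosome`,
#'   `position`.
#' @param upstream,downstream Window sizes in bases (defaults 1500, 200).
#' @return Logical vector per probe: falls in at least one promoter window.
#' @export
annotate_promoters <- function(gene_ranges, probe_positions,
                               upstream = 1500, downstream = 200) {
  if (!all(gene_ranges$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  start <- ifelse(gene_ranges$strand == "+",
                  gene_ranges$tss - upstream, gene_ranges$tss - downstream)
  end <- ifelse(gene_ranges$strand == "+",
                gene_ranges$tss + downstream, gene_ranges$tss + upstream)
  hit <- logical(nrow(probe_positions))
  for (chr in unique(probe_positions$chromosome)) {
    gi <- gene_ranges$chromosome == chr
    if (!any(gi)) next
    pi <- which(probe_positions$chromosome == chr)
    pos <- probe_positions$position[pi]
    hit[pi] <- vapply(pos, function(x)
      any(x >= start[gi] & x <= end[gi]), logical(1))
  }
  names(hit) <- probe_positions$cpg_id
  hit
}

#' Feature enrichment of a CpG set against a background
#'
#' Tests each feature on the chosen axis for over/under-representation in
#' the foreground versus the rest of the background:
#' \describe{
#'   \item{chromosome}{two-sided Fisher's exact test per chromosome}
#'   \item{island}{CMH test per island-context level, stratified by
#'     Illumina probe type}
#'   \item{context}{CMH test per genomic-context level, stratified by
#'     island context}
#'   \item{tfbs}{one-sided (`greater`) Fisher's exact test per TFBS
#'     feature set}
#' }
#' BH-FDR is applied across the features within the axis. Odds ratios with
#' 95% CIs are reported, plus log2-scale columns for forest plots.
#'
#' @param foreground CpG id vector, a subset of `background`.
#' @param background CpG id vector (the full tested universe; the 2x2
#'   tables use background excluding foreground as the comparison margin).
#' @param ann Annotation data frame (see [read_annotation()]) covering the
#'   background CpGs; for `axis = "tfbs"` supply `tfbs_sets`.
#' @param axis One of `"chromosome"`, `"island"`, `"context"`, `"tfbs"`.
#' @param tfbs_sets Named list of CpG id vectors (required for
#'   `axis = "tfbs"`).
#' @return Data frame of class `"enrichment_result"`: `feature`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `fdr_p`, `test`, `log2_or`,
#'   `log2_ci_low`, `log2_ci_high`.
#' @export
run_enrichment <- function(foreground, background, ann,
                           axis = c("chromosome", "island", "context", "tfbs"),
                           tfbs_sets = NULL) {
  axis <- match.arg(axis)
  extra <- setdiff(foreground, background)
  if (length(extra) > 0)
    stop("foreground is not a subset of background (",
         length(extra), " CpGs outside)")
  bg_only <- setdiff(background, foreground)

  if (axis == "tfbs") {
    if (is.null(tfbs_sets)) stop("axis 'tfbs' requires tfbs_sets")
    rows <- lapply(names(tfbs_sets), function(f) {
      memb <- tfbs_sets[[f]]
      a <- sum(foreground %in% memb); b <- length(foreground) - a
      cc <- sum(bg_only %in% memb);   d <- length(bg_only) - cc
      if (a + cc == 0) return(NULL)  # feature absent from background
      fe <- fisher_exact(a, b, cc, d, alternative = "greater")
      data.frame(feature = f, odds_ratio = fe$odds_ratio,
                 ci_low = fe$ci_low, ci_high = fe$ci_high, p = fe$p,
                 test = "fisher.greater", stringsAsFactors = FALSE)
    })
  } else {
    ann <- ann[match(background, ann$cpg_id), ]
    if (anyNA(ann$cpg_id)) stop("annotation does not cover the background")
    fg <- ann$cpg_id %in% foreground
    spec <- switch(axis,
      chromosome = list(feat = "chromosome", strat = NULL,
                        test = "fisher.two.sided"),
      island = list(feat = "island_context", strat = "probe_type",
                    test = "cmh"),
      context = list(feat = "genomic_context", strat = "island_context",
                     test = "cmh"))
    fvals <- ann[[spec$feat]]
    svals <- if (is.null(spec$strat)) rep("all", nrow(ann)) else ann[[spec$strat]]
    feats <- sort(unique(fvals))
    rows <- lapply(feats, function(f) {
      has <- fvals == f
      if (spec$test == "fisher.two.sided") {
        a <- sum(fg & has); b <- sum(fg & !has)
        cc <- sum(!fg & has); d <- sum(!fg & !has)
        if (a + cc == 0) return(NULL)
        fe <- fisher_exact(a, b, cc, d, alternative = "two.sided")
        data.frame(feature = f, odds_ratio = fe$odds_ratio,
                   ci_low = fe$ci_low, ci_high = fe$ci_high, p = fe$p,
                   test = spec$test, stringsAsFactors = FALSE)
      } else {
        strata <- lapply(unique(svals), function(s) {
          in_s <- svals == s
          matrix(c(sum(fg & has & in_s), sum(fg & !has & in_s),
                   sum(!fg & has & in_s), sum(!fg & !has & in_s)),
                 2, 2, byrow = TRUE)
        })
        cm <- cmh_test(strata)
        if (!cm$defined) return(NULL)
        data.frame(feature = f, odds_ratio = cm$odds_ratio,
                   ci_low = cm$ci_low, ci_high = cm$ci_high, p = cm$p,
                   test = "cmh", stringsAsFactors = FALSE)
      }
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no testable features on this axis")
  out$fdr_p <- bh_fdr(out$p)
  out$log2_or <- log2(out$odds_ratio)
  out$log2_ci_low <- log2(out$ci_low)
  out$log2_ci_high <- log2(out$ci_high)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment (%s): %d features, %d at FDR < 0.05\n",
              x$test[1], nrow(x), sum(x$fdr_p < 0.05)))
  NextMethod()
}
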