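test_that("Fisher exact tests match their worked and enumerated values", {
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)

  gr <- fisher_exact(3, 1, 1, 3, alternative = "greater")
  expect_equal(gr$p, 17 / 70, tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:40) {
    tot <- sample(4:30, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    cells <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], tot - cuts[3])
    for (alt in c("two.sided", "greater")) {
      got <- fisher_exact(cells[1], cells[2], cells[3], cells[4], alt)$p
      expect_equal(got, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                           cells[4], alt), tolerance = 1e-8)
    }
  }
  expect_error(fisher_exact(-1, 2, 3, 4), "negative")
})

test_that("zero cells get the Haldane-Anscombe odds ratio with a Woolf CI", {
  fe <- fisher_exact(10, 0, 5, 5, alternative = "greater")
  expect_equal(fe$odds_ratio, (10.5 * 5.5) / (0.5 * 5.5))
  expect_true(fe$ci_low <= fe$odds_ratio && fe$odds_ratio <= fe$ci_high)
  # exact p unaffected by the correction
  expect_equal(fe$p, fisher_enum_oracle(10, 0, 5, 5, "greater"),
               tolerance = 1e-10)
})

test_that("CMH with one stratum reduces to the uncorrected chi-square", {
  set.seed(11)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    cm <- cmh_test(list(tab))
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    # the single-stratum CMH uses the hypergeometric (n-1) variance
    n <- sum(tab)
    expect_equal(cm$statistic, unname(chi$statistic) * (n - 1) / n,
                 tolerance = 1e-10)
    expect_equal(cm$odds_ratio, tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-12)
  }
})

test_that("CMH agrees with the stats reference and handles identical strata", {
  set.seed(12)
  t1 <- matrix(c(12, 5, 7, 14), 2)
  cm1 <- cmh_test(list(t1, t1))
  expect_equal(cm1$odds_ratio, cmh_test(list(t1))$odds_ratio, tolerance = 1e-12)

  arr <- array(c(t1, matrix(c(3, 9, 8, 4), 2)), dim = c(2, 2, 2))
  cm <- cmh_test(list(arr[, , 1], arr[, , 2]))
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(cm$statistic, unname(mh$statistic), tolerance = 1e-10)
  expect_equal(cm$p, mh$p.value, tolerance = 1e-10)
  expect_equal(cm$odds_ratio, unname(mh$estimate), tolerance = 1e-8)
})

test_that("stratification undoes a constructed Simpson reversal", {
  # per-stratum OR > 1 in both strata, pooled OR < 1
  s1 <- matrix(c(81, 6, 234, 36), 2, byrow = TRUE)     # OR 2.08
  s2 <- matrix(c(192, 71, 55, 25), 2, byrow = TRUE)    # OR 1.23
  pooled <- s1 + s2
  or_pooled <- pooled[1, 1] * pooled[2, 2] / (pooled[1, 2] * pooled[2, 1])
  expect_lt(or_pooled, 1)
  cm <- cmh_test(list(s1, s2))
  expect_gt(cm$odds_ratio, 1)
  # direct MH formula oracle
  n1 <- sum(s1); n2 <- sum(s2)
  or_mh <- (s1[1, 1] * s1[2, 2] / n1 + s2[1, 1] * s2[2, 2] / n2) /
    (s1[1, 2] * s1[2, 1] / n1 + s2[1, 2] * s2[2, 1] / n2)
  expect_equal(cm$odds_ratio, or_mh, tolerance = 1e-12)
})

test_that("genomic context collapses by precedence with intergenic fallback", {
  m <- list(cg1 = c("Exon", "Promoter"), cg2 = character(0), cg3 = "Intron",
            cg4 = c("Intron", "3'UTR", "5'UTR"))
  out <- collapse_genomic_context(m)
  expect_identical(unname(out), c("Promoter", "Intergenic", "Intron", "5'UTR"))
  expect_error(collapse_genomic_context(list(cg = "Enhancer")), "unknown")
})

test_that("promoter windows are strand-reflected around the TSS", {
  genes <- data.frame(chromosome = c("chr1", "chr1"), tss = c(10000, 10000),
                      strand = c("+", "-"))
  probes <- data.frame(cpg_id = c("a", "b", "c", "d"),
                       chromosome = "chr1",
                       position = c(9000, 10300, 8400, 11600))
  plus <- annotate_promoters(genes[1, ], probes)
  expect_identical(unname(plus), c(TRUE, FALSE, FALSE, FALSE))
  minus <- annotate_promoters(genes[2, ], probes)
  expect_identical(unname(minus), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(annotate_promoters(data.frame(chromosome = "chr1", tss = 1,
                                             strand = "x"), probes), "strand")
})

test_that("planted TFBS enrichment is recovered and nulls stay calibrated", {
  ids <- sprintf("cg%05d", 1:8000)
  set.seed(13)
  fgr <- sample(ids, 800)
  an <- make_annotation(ids, foreground = fgr, fold = 3, base_rate = 0.05,
                        n_null_features = 10, seed = 14)
  er <- run_enrichment(fgr, ids, an$ann, axis = "tfbs",
                       tfbs_sets = an$tfbs_sets)
  hit <- er[er$feature == "TF_planted", ]
  expect_gt(hit$odds_ratio, 2)
  expect_lt(hit$odds_ratio, 4.5)
  expect_lt(hit$fdr_p, 0.05)
  expect_lte(sum(er$fdr_p[er$feature != "TF_planted"] < 0.05), 1)
})

test_that("a foreground equal to or random within the background shows nothing", {
  ids <- sprintf("cg%05d", 1:4000)
  an <- make_annotation(ids, seed = 15)
  er <- run_enrichment(ids, ids, an$ann, axis = "chromosome")
  # degenerate background-only margin: OR flagged undefined, nothing significant
  expect_true(all(is.na(er$odds_ratio)))
  expect_true(all(er$p == 1))
  expect_true(all(er$fdr_p > 0.05))

  set.seed(16)
  fgr <- sample(ids, 400)
  for (ax in c("chromosome", "island", "context")) {
    er <- run_enrichment(fgr, ids, an$ann, axis = ax)
    expect_true(all(er$ci_low <= er$odds_ratio & er$odds_ratio <= er$ci_high))
    expect_equal(er$log2_or, log2(er$odds_ratio))
  }
  expect_error(run_enrichment(c(fgr, "cgNOPE"), ids, an$ann,
                              axis = "chromosome"), "subset")
})

test_that("axis results are invariant to CpG input order", {
  ids <- sprintf("cg%05d", 1:2000)
  set.seed(17)
  fgr <- sample(ids, 300)
  an <- make_annotation(ids, foreground = fgr, fold = 2, seed = 18)
  a <- run_enrichment(fgr, ids, an$ann, axis = "island")
  b <- run_enrichment(sample(fgr), sample(ids), an$ann, axis = "island")
  expect_equal(a, b)
})
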