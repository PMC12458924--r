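test_that("TOST boundary and degenerate behaviors follow the construction", {
  set.seed(1)
  # diff exactly +epsilon: the upper test statistic is 0, so p_upper = 0.5
  x <- rnorm(12, 0.5, 0.02)
  y <- rnorm(10, 0.5, 0.02)
  eps <- mean(x) - mean(y)
  if (eps <= 0) { tmp <- x; x <- y; y <- tmp; eps <- -eps }
  r <- tost_two_sample(x, y, epsilon = eps)
  expect_equal(r$p_upper, 0.5, tolerance = 1e-12)
  expect_gte(r$p_tost, 0.5)

  # epsilon -> 0: equivalence can never be concluded
  r0 <- tost_two_sample(x, y, epsilon = 0)
  expect_gte(r0$p_tost, 0.5)

  # both groups constant, difference inside the margin: limiting p = 0, flagged
  rz <- tost_two_sample(rep(0.5, 5), rep(0.52, 5), epsilon = 0.1)
  expect_equal(rz$p_tost, 0)
  expect_true(rz$degenerate)
  # constant groups far apart: no equivalence
  rf <- tost_two_sample(rep(0.1, 5), rep(0.9, 5), epsilon = 0.1)
  expect_equal(rf$p_tost, 1)
  expect_false(rf$degenerate)
})

test_that("TOST p-values match direct Welch t-CDF evaluation", {
  set.seed(2)
  for (rep in 1:20) {
    x <- rnorm(24, 0.5, 0.02)
    y <- rnorm(6, 0.5, 0.02)
    r <- tost_two_sample(x, y, epsilon = 0.1)
    expect_equal(r$p_tost, tost_oracle(x, y, 0.1), tolerance = 1e-12)
    expect_equal(r$p_tost, max(r$p_lower, r$p_upper))
  }
})

test_that("TOST is swap-invariant and monotone in the margin", {
  set.seed(3)
  x <- rnorm(10, 0.55, 0.05); y <- rnorm(7, 0.5, 0.04)
  for (eps in c(0.02, 0.1, 0.3)) {
    a <- tost_two_sample(x, y, eps)
    b <- tost_two_sample(y, x, eps)
    expect_equal(a$p_tost, b$p_tost, tolerance = 1e-12)
    expect_equal(a$p_lower, b$p_upper, tolerance = 1e-12)
  }
  ps <- sapply(seq(0.01, 0.4, by = 0.01),
               function(e) tost_two_sample(x, y, e)$p_tost)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the screen declares equivalence to the matched reference only", {
  cfg <- synth_config(n_cpgs = 500, n_informative = 400, noise_sd = 0.03)
  rates <- sapply(1:5, function(s) {
    ref <- make_reference_pair(cfg, seed = 100 + s)
    dg <- make_donor_groups(cfg, ref, seed = 200 + s, equiv_frac = 1,
                            within_sd = 0.03)
    cpgs <- attr(ref, "informative")
    scr <- run_tost_screen(dg$cases, list(mem = dg$mem_donors,
                                          nv = dg$nv_donors), cpgs)
    c(mem = length(scr$sets$mem) / length(cpgs),
      nv = length(scr$sets$nv) / length(cpgs))
  })
  expect_gt(mean(rates["mem", ]), 0.9)
  expect_lt(mean(rates["nv", ]), 0.05)
})

test_that("zero margin and midway cases yield no equivalence", {
  cfg <- synth_config(n_cpgs = 200, n_informative = 200, reference_gap = 0.6,
                      noise_sd = 0.02)
  ref <- make_reference_pair(cfg, seed = 61)
  dg <- make_donor_groups(cfg, ref, seed = 62, equiv_frac = 0)  # all midway
  cpgs <- attr(ref, "informative")
  refs <- list(mem = dg$mem_donors, nv = dg$nv_donors)
  scr0 <- run_tost_screen(dg$cases, refs, cpgs, epsilon = 0)
  expect_length(scr0$sets$mem, 0)
  expect_length(scr0$sets$nv, 0)
  scr <- run_tost_screen(dg$cases, refs, cpgs, epsilon = 0.1)
  expect_lt(length(scr$sets$mem) / length(cpgs), 0.02)
  expect_lt(length(scr$sets$nv) / length(cpgs), 0.02)
})

test_that("Manhattan distances and nearest references behave as an L1 metric", {
  refm <- cbind(A = c(cg1 = 0.0, cg2 = 1.0), B = c(0.5, 0.5))
  s <- matrix(c(0.5, 0.5, 0.0, 1.0), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("mid", "pureA")))
  d <- manhattan_similarity(s, refm)
  expect_equal(d$A, c(1.0, 0))
  expect_equal(d$nearest, c("B", "A"))

  # triangle inequality across sample and the two references
  set.seed(5)
  for (rep in 1:20) {
    x <- runif(30); a <- runif(30); b <- runif(30)
    d_ab <- sum(abs(a - b))
    d_xa <- sum(abs(x - a)); d_xb <- sum(abs(x - b))
    expect_lte(d_ab, d_xa + d_xb + 1e-12)
  }

  cfg <- synth_config(n_cpgs = 300, n_informative = 200, noise_sd = 0.02,
                      n_samples = 10, w = 1)
  ref <- make_reference_pair(cfg, seed = 71)
  coh <- make_intermediate_cohort(cfg, ref, seed = 72)  # memory-like cohort
  dd <- manhattan_similarity(coh$betas, ref[, 1:2])
  expect_true(all(dd$nearest == "B-memory"))
})

test_that("the state contingency summary matches the chi-square oracle", {
  mk_ref <- function(n) {
    out <- cbind(mem = rep(0.1, n), nv = rep(0.9, n))
    rownames(out) <- paste0("cg", seq_len(n))
    out
  }
  rm20 <- mk_ref(20)
  # 10 memory-equivalent CpGs all hypo, 10 naive-equivalent all hyper
  case_means <- c(rep(0.1, 10), rep(0.9, 10))
  names(case_means) <- paste0("cg", 1:20)
  sets <- list(mem = paste0("cg", 1:10), nv = paste0("cg", 11:20))
  sc <- state_contingency(sets, case_means, rm20)
  expect_equal(unname(sc$table), matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(sc$chisq, 20)
  expect_lt(sc$p, 1e-4)

  # balanced table: no association
  case_means2 <- rep(c(0.1, 0.9), 10)
  names(case_means2) <- paste0("cg", 1:20)
  sc2 <- state_contingency(sets, case_means2, rm20)
  expect_equal(sc2$chisq, 0)
  expect_equal(sc2$p, 1)

  # random tables against the direct O/E formula
  set.seed(6)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi_oracle <- sum((tab - ex)^2 / ex)
    chi_pkg <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    expect_equal(unname(chi_pkg), chi_oracle, tolerance = 1e-10)
  }

  # CpGs equivalent to both references are excluded and counted
  sets_overlap <- list(mem = paste0("cg", 1:12), nv = paste0("cg", 11:20))
  sc3 <- state_contingency(sets_overlap, case_means, rm20)
  expect_equal(sc3$n_both_excluded, 2)
  expect_equal(sum(sc3$table), 18)
})
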