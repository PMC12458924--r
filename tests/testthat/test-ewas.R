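make_meta <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", 1:n),
             v = rnorm(n), age = round(rnorm(n, 70, 8)),
             sex = sample(c("F", "M"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("design matrices center age and code sex against the first level", {
  meta <- data.frame(sample_id = paste0("s", 1:4), v = c(1, 2, 3, 4),
                     age = c(60, 70, 70, 80), sex = c("M", "F", "F", "M"))
  X <- build_design(meta, "v")
  expect_identical(colnames(X), c("(Intercept)", "v", "age", "sex"))
  expect_equal(unname(X[, "age"]), c(-10, 0, 0, 10))
  expect_equal(unname(X[, "sex"]), c(1, 0, 0, 1))
  expect_identical(attr(X, "sex_reference"), "F")

  const <- meta; const$v <- 1
  expect_error(build_design(const, "v"), "collinear")

  allf <- meta; allf$sex <- "F"
  expect_warning(X2 <- build_design(allf, "v"), "zero variance")
  expect_false("sex" %in% colnames(X2))
})

test_that("per-CpG OLS matches the normal-equations oracle", {
  meta <- make_meta(20, seed = 2)
  X <- build_design(meta, "v")
  set.seed(3)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("cg%02d", 1:50), meta$sample_id))
  f <- fit_linear_models(m, X)
  oracle_b <- t(solve(crossprod(X)) %*% t(X) %*% t(m))
  expect_equal(unname(f$coefficients), unname(oracle_b), tolerance = 1e-8)
  expect_equal(f$df_resid, 20 - 4)

  # exact linear responses give the planted slope and zero residual variance
  m_exact <- matrix(rep(2 * X[, "v"] + 1, each = 2), 2, 20, byrow = FALSE,
                    dimnames = list(c("a", "b"), meta$sample_id))
  fe <- fit_linear_models(m_exact, X)
  expect_equal(unname(fe$coefficients[, "v"]), c(2, 2), tolerance = 1e-10)
  expect_equal(unname(fe$s2), c(0, 0), tolerance = 1e-20)
})

test_that("variance moderation branches behave as specified", {
  d <- 16
  # equal variances: infinite prior df, all posteriors equal
  mod <- ebayes_moderate(rep(0.3, 100), d)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(mod$s0_sq, 100))
  # d0 = 0: no moderation at all
  s2 <- rgamma(50, 3, 10)
  mod0 <- ebayes_moderate(s2, d, d0 = 0)
  expect_identical(mod0$s2_post, s2)
  expect_equal(mod0$df_total, d)
  # shrinkage: posterior variance always between s2 and s0_sq
  set.seed(8)
  s2 <- 4 * 0.05 / rchisq(500, 4)
  mod4 <- ebayes_moderate(s2, d)
  lo <- pmin(s2, mod4$s0_sq); hi <- pmax(s2, mod4$s0_sq)
  expect_true(all(mod4$s2_post >= lo - 1e-12 & mod4$s2_post <= hi + 1e-12))
  # zero-variance rows are flagged, not dropped
  modz <- ebayes_moderate(c(0, s2), d)
  expect_true(modz$zero_variance[1])
  expect_false(any(modz$zero_variance[-1]))
})

test_that("moderation hyperparameters are recovered from simulated variances", {
  set.seed(12)
  d0_true <- 4; s0_true <- 0.05; d <- 16
  est <- replicate(10, {
    s2 <- d0_true * s0_true / rchisq(5000, d0_true) *
      rchisq(5000, d) / d  # observed s2 ~ s0^2 * F(d, d0) scaled
    mod <- ebayes_moderate(s2, d)
    c(mod$d0, mod$s0_sq)
  })
  expect_lt(abs(mean(est[1, ]) - d0_true) / d0_true, 0.3)
  expect_lt(abs(mean(est[2, ]) - s0_true) / s0_true, 0.1)
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  ec <- make_ewas_cohort(n_cpgs = 400, n_samples = 24, seed = 33)
  X <- build_design(ec$meta, "v")
  fits <- fit_linear_models(ec$m, X)
  mod <- ebayes_moderate(fits$s2, fits$df_resid)
  lf <- limma::eBayes(limma::lmFit(ec$m, X))
  expect_equal(mod$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$s2_post), unname(lf$s2.post), tolerance = 1e-8)
  t_mod <- fits$coefficients[, "v"] / (fits$se_unscaled["v"] * sqrt(mod$s2_post))
  expect_equal(unname(t_mod), unname(lf$t[, "v"]), tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), bh_oracle(p))
  o <- sample(200)
  expect_equal(bh_fdr(p[o]), bh_fdr(p)[o])  # order invariance
  expect_true(all(bh_fdr(p) >= p))
})

test_that("M-scale effects convert to beta-scale effects by the logistic rule", {
  expect_equal(delta_m_to_delta_beta(2, 0), 0.3)
  expect_equal(delta_m_to_delta_beta(0, c(-3, 0, 5)), c(0, 0, 0))
  expect_equal(delta_m_to_delta_beta(4, -2), 0.6)
  dm <- seq(-6, 6, by = 0.25)
  db <- delta_m_to_delta_beta(dm, beta0 = 0.7)
  expect_true(all(diff(db) > 0))
  expect_true(all(db > -1 & db < 1))
})

test_that("with d0 = 0 the pipeline reproduces ordinary OLS t-tests", {
  ec <- make_ewas_cohort(n_cpgs = 30, n_samples = 15, seed = 44)
  fit <- run_ewas(ec$m, ec$meta, "v", d0 = 0)
  for (i in c(1, 7, 30)) {
    lm_fit <- lm(ec$m[i, ] ~ v + I(age - mean(age)) + factor(sex),
                 data = ec$meta)
    sm <- summary(lm_fit)$coefficients
    expect_equal(fit$table$delta_m[i], sm["v", "Estimate"], tolerance = 1e-9)
    expect_equal(fit$table$p[i], sm["v", "Pr(>|t|)"], tolerance = 1e-9)
  }
})

test_that("global-null cohorts keep false discoveries controlled", {
  hits <- sapply(1:10, function(s) {
    ec <- make_ewas_cohort(n_cpgs = 500, n_samples = 30, prop_effect = 0,
                           seed = 5000 + s)
    fit <- run_ewas(ec$m, ec$meta, "v")
    length(fit$hyper) + length(fit$hypo)
  })
  expect_lte(mean(hits), 0.05 * 500)
})

test_that("a delta-beta threshold above every true effect empties the sets", {
  ec <- make_ewas_cohort(n_cpgs = 300, n_samples = 30, seed = 66)
  fit <- run_ewas(ec$m, ec$meta, "v")
  big <- max(abs(fit$table$delta_beta)) + 0.01
  fit2 <- run_ewas(ec$m, ec$meta, "v", dm_threshold = big)
  expect_length(fit2$hyper, 0)
  expect_length(fit2$hypo, 0)
})
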