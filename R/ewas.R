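#' Build a design matrix for per-CpG linear modeling
#'
#' Columns: intercept first, then the variable of interest, then adjusters.
#' Age is centered at its mean; sex is coded 0/1 with the reference level
#' recorded (first level in sort order, i.e. `F` when both are present).
#' Character/factor columns with two levels are coded 0/1; zero-variance
#' adjusters are dropped with a warning; any remaining collinearity is an
#' error naming the offending columns.
#'
#' @param meta Data frame of per-sample metadata with a `sample_id` column.
#' @param variable Name of the column of interest.
#' @param adjust Character vector of adjuster column names (default
#'   `c("age", "sex")`).
#' @return Numeric design matrix (samples x columns) with attribute
#'   `sex_reference` when sex was coded.
#' @export
build_design <- function(meta, variable, adjust = c("age", "sex")) {
  stopifnot("sample_id" %in% names(meta))
  used <- c(variable, adjust)
  missing_col <- setdiff(used, names(meta))
  if (length(missing_col) > 0)
    stop("metadata lacks column(s): ", paste(missing_col, collapse = ", "))
  if (anyNA(meta[used]))
    stop("missing values in model columns: ",
         paste(used[vapply(meta[used], anyNA, logical(1))], collapse = ", "))

  n <- nrow(meta)
  X <- matrix(1, n, 1, dimnames = list(meta$sample_id, "(Intercept)"))
  sex_ref <- NULL
  add_col <- function(X, v, nm) {
    X <- cbind(X, v); colnames(X)[ncol(X)] <- nm; X
  }
  encode <- function(col, nm) {
    v <- meta[[col]]
    if (is.numeric(v)) {
      if (identical(col, "age")) v <- v - mean(v)
      return(v)
    }
    lev <- sort(unique(as.character(v)))
    if (length(lev) == 1) return(rep(0, n))     # constant; caught below
    if (length(lev) != 2)
      stop("column '", col, "' must be numeric or two-level")
    if (identical(col, "sex")) sex_ref <<- lev[1]
    as.numeric(as.character(v) == lev[2])
  }
  X <- add_col(X, encode(variable, variable), variable)
  for (a in adjust) {
    v <- encode(a, a)
    if (stats::var(v) == 0) {
      warning("adjuster '", a, "' has zero variance across samples; dropped")
      next
    }
    X <- add_col(X, v, a)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design columns: ", paste(dep, collapse = ", "))
  }
  attr(X, "sex_reference") <- sex_ref
  X
}

#' Per-CpG ordinary least squares fits
#'
#' Fits the same design to every row of the M-value matrix by one QR
#' decomposition.
#'
#' @param m M-value matrix (CpGs x samples).
#' @param X Design matrix from [build_design()]; `nrow(X) == ncol(m)` and
#'   more samples than columns.
#' @return List with `coefficients` (CpGs x design columns), `s2` (residual
#'   variances), `df_resid`, and `se_unscaled` (per-column standard-error
#'   multipliers, `sqrt(diag((X'X)^-1))`).
#' @export
fit_linear_models <- function(m, X) {
  stopifnot(is.matrix(m), nrow(X) == ncol(m), nrow(X) > ncol(X))
  if (!is.null(rownames(X)) && !is.null(colnames(m)) &&
      !identical(rownames(X), colnames(m)))
    m <- m[, rownames(X), drop = FALSE]
  qrX <- qr(X)
  coefs <- t(qr.coef(qrX, t(m)))
  res <- m - coefs %*% t(X)
  d <- nrow(X) - ncol(X)
  s2 <- rowSums(res^2) / d
  xtx_inv <- solve(crossprod(X))
  list(coefficients = coefs, s2 = s2, df_resid = d,
       se_unscaled = sqrt(diag(xtx_inv)), design = X)
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Estimates a scaled inverse-chi-square prior (`d0`, `s0_sq`) for the
#' residual variances by moment matching on
#' `e_g = log(s2_g) - digamma(d/2) + log(d/2)`:
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` is inverted monotonically for
#' `d0`, and `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the
#' observed dispersion of log-variances is no larger than expected under a
#' common variance (`var(e) <= trigamma(d/2)`), the prior is degenerate:
#' `d0 = Inf` and every posterior variance equals `s0_sq = exp(mean(e))`.
#' Otherwise posterior variances are
#' `s2_post = (d0*s0_sq + d*s2) / (d0 + d)`.
#'
#' Exact-fit rows (`s2 == 0`) are replaced by the smallest positive `s2`
#' times 1e-6 before taking logs, and flagged.
#'
#' @param s2 Per-CpG residual variances.
#' @param df_resid Residual degrees of freedom (common to all CpGs).
#' @param d0 Optional fixed prior df; `0` disables moderation
#'   (`s2_post = s2`), `NULL` (default) estimates it.
#' @param s0_sq Optional fixed prior variance (used with fixed `d0 > 0`).
#' @return List with `d0`, `s0_sq`, `s2_post`, `df_total = d0 + df_resid`,
#'   and `zero_variance` (logical flag per CpG).
#' @export
ebayes_moderate <- function(s2, df_resid, d0 = NULL, s0_sq = NULL) {
  zero <- s2 <= 0
  if (any(zero)) {
    if (all(zero)) stop("all residual variances are zero; nothing to moderate")
    s2[zero] <- min(s2[!zero]) * 1e-6
  }
  d <- df_resid
  if (!is.null(d0) && d0 == 0)
    return(list(d0 = 0, s0_sq = NA_real_, s2_post = s2,
                df_total = d, zero_variance = zero))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  if (is.null(d0)) {
    ve <- stats::var(e)
    excess <- ve - trigamma(d / 2)
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else if (is.null(s0_sq)) {
    s0_sq <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post,
       df_total = d0 + d, zero_variance = zero)
}

# monotone inversion of trigamma by Newton's method on 1/y scale
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement over all supplied
#' p-values (a thin surface over [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Convert an M-scale effect to a beta-scale effect
#'
#' \deqn{\Delta\beta = \frac{2^{\beta_0+\Delta M}}{1+2^{\beta_0+\Delta M}} -
#'       \frac{2^{\beta_0}}{1+2^{\beta_0}}}
#' i.e. the change in methylation fraction implied by moving the model
#' intercept by the fitted M-value effect.
#'
#' @param delta_m Effect on the M scale.
#' @param beta0 Model intercept on the M scale.
#' @return Effect on the beta scale, in (-1, 1).
#' @export
delta_m_to_delta_beta <- function(delta_m, beta0) {
  m_to_beta(beta0 + delta_m) - m_to_beta(beta0)
}

#' Epigenome-wide association study on M-values
#'
#' Per-CpG linear model of M-values on a variable of interest with
#' covariate adjustment (age centered, sex 0/1), empirical-Bayes variance
#' moderation, two-sided moderated-t p-values, BH-FDR across all CpGs, and
#' conversion of each effect from the M scale to the beta scale. CpG sets
#' significant at `fdr < alpha` are split by effect sign into
#' hypermethylated (`delta_m > 0`) and hypomethylated (`delta_m < 0`),
#' optionally also requiring `|delta_beta| > dm_threshold`.
#'
#' @param m M-value matrix (CpGs x samples); see [beta_to_m()].
#' @param meta Metadata data frame (one row per sample, `sample_id` column).
#' @param variable Column of interest in `meta`.
#' @param adjust Adjuster columns (default `c("age", "sex")`).
#' @param alpha FDR significance threshold (default 0.05).
#' @param dm_threshold Optional minimum `|delta_beta|` for the hyper/hypo
#'   sets (e.g. 0.2); `NULL` for none.
#' @param d0 Optional fixed prior df passed to [ebayes_moderate()]
#'   (`0` reproduces ordinary per-CpG OLS t-tests exactly).
#' @return Object of class `"ewas_fit"`: list with `table` (per-CpG data
#'   frame: `cpg_id`, `beta0`, `delta_m`, `s2`, `t_mod`, `p`, `fdr_p`,
#'   `delta_beta`, `direction`), `hyper`, `hypo` (CpG id vectors),
#'   moderation parameters `d0`, `s0_sq`, `df_total`, and the `design`.
#' @export
run_ewas <- function(m, meta, variable, adjust = c("age", "sex"),
                     alpha = 0.05, dm_threshold = NULL, d0 = NULL) {
  X <- build_design(meta, variable, adjust)
  if (!setequal(rownames(X), colnames(m)))
    stop("metadata sample_ids do not match the M-value matrix columns")
  m <- m[, rownames(X), drop = FALSE]
  fits <- fit_linear_models(m, X)
  mod <- ebayes_moderate(fits$s2, fits$df_resid, d0 = d0)
  j <- match(variable, colnames(X))
  delta_m <- fits$coefficients[, j]
  beta0 <- fits$coefficients[, "(Intercept)"]
  t_mod <- delta_m / (fits$se_unscaled[j] * sqrt(mod$s2_post))
  p <- 2 * stats::pt(-abs(t_mod), df = mod$df_total)
  fdr <- bh_fdr(p)
  dbeta <- delta_m_to_delta_beta(delta_m, beta0)
  tab <- data.frame(cpg_id = rownames(m), beta0 = beta0, delta_m = delta_m,
                    s2 = fits$s2, t_mod = t_mod, p = p, fdr_p = fdr,
                    delta_beta = dbeta,
                    direction = ifelse(delta_m > 0, "hyper",
                                       ifelse(delta_m < 0, "hypo", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  pass <- fdr < alpha
  if (!is.null(dm_threshold)) pass <- pass & abs(dbeta) > dm_threshold
  structure(list(table = tab,
                 hyper = tab$cpg_id[pass & delta_m > 0],
                 hypo = tab$cpg_id[pass & delta_m < 0],
                 d0 = mod$d0, s0_sq = mod$s0_sq, df_total = mod$df_total,
                 zero_variance = mod$zero_variance,
                 alpha = alpha, dm_threshold = dm_threshold,
                 variable = variable, design = X),
            class = "ewas_fit")
}

#' @export
print.ewas_fit <- function(x, ...) {
  cat(sprintf("EWAS of M-values on '%s' (%d CpGs, %d samples)\n",
              x$variable, nrow(x$table), nrow(x$design)))
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %s\n",
              format(x$d0, digits = 4), format(x$s0_sq, digits = 4)))
  thr <- if (is.null(x$dm_threshold)) "" else
    sprintf(" and |delta_beta| > %g", x$dm_threshold)
  cat(sprintf("  at FDR < %g%s: %d hypermethylated, %d hypomethylated\n",
              x$alpha, thr, length(x$hyper), length(x$hypo)))
  invisible(x)
}

#' @export
summary.ewas_fit <- function(object, n = 10, ...) {
  ord <- order(object$table$p)
  structure(list(top = object$table[ord[seq_len(min(n, nrow(object$table)))], ],
                 fit = object), class = "summary.ewas_fit")
}

#' @export
print.summary.ewas_fit <- function(x, ...) {
  print(x$fit)
  cat("Top CpGs by p-value:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ewas_fit <- function(x, ...) {
  sig <- x$table$fdr_p < x$alpha
  graphics::plot(x$table$delta_m, -log10(x$table$p),
                 pch = 16, cex = 0.4,
                 col = ifelse(sig, "firebrick", "grey60"),
                 xlab = expression(Delta * M), ylab = "-log10 p", ...)
  invisible(x)
}
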