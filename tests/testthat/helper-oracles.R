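# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, direct formula evaluation, and
# grid search.

# hierarchical grid search for min ||y - Xp||^2, p >= 0 (objective is convex,
# so coarse-to-fine refinement is safe); resolution of the final pass = step
grid_nnls_oracle <- function(X, y, upper = 2, step = 1e-4) {
  k <- ncol(X)
  widths <- c(0.01, 1e-3, step)
  centre <- rep(upper / 2, k)
  half <- upper / 2
  best <- centre
  for (w in widths) {
    axes <- lapply(seq_len(k), function(j) {
      g <- seq(max(0, best[j] - half), best[j] + half, by = w)
      unique(pmax(g, 0))
    })
    pts <- as.matrix(expand.grid(axes))
    rss <- colSums((y - X %*% t(pts))^2)
    best <- pts[which.min(rss), ]
    half <- w * 2
  }
  unname(best)
}

# exact hypergeometric Fisher p by enumerating the whole support
fisher_enum_oracle <- function(a, b, c_, d, alternative) {
  m <- a + b          # foreground size
  n <- c_ + d         # background-only size
  k <- a + c_         # feature total
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  if (alternative == "greater") {
    sum(pr[support >= a])
  } else {
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group splits
# (two-sided = twice the smaller tail, the convention of the worked example
# 2 / choose(6, 3) for {1,2,3} vs {4,5,6})
wilcoxon_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  ws <- apply(splits, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# direct Welch TOST evaluation from summary statistics
tost_oracle <- function(x, y, eps) {
  n1 <- length(x); n2 <- length(y)
  a <- var(x) / n1; b <- var(y) / n2
  se <- sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  diff <- mean(x) - mean(y)
  p_lower <- pt((diff + eps) / se, df, lower.tail = FALSE)
  p_upper <- pt((diff - eps) / se, df, lower.tail = TRUE)
  max(p_lower, p_upper)
}

# BH step-up by direct definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# small deterministic two-type reference for unit tests
tiny_ref <- function(n_info = 6, n_flat = 4) {
  mem <- c(seq(0.95, 0.6, length.out = n_info), rep(0.5, n_flat))
  nv <- c(seq(0.05, 0.4, length.out = n_info), rep(0.5, n_flat))
  ref <- cbind(`B-memory` = mem, `B-naive` = nv)
  rownames(ref) <- sprintf("cg%03d", seq_len(n_info + n_flat))
  ref
}
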