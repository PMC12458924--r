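#' Non-negative least squares by the active-set method
#'
#' Solves `argmin_p ||y - X p||^2` subject to `p >= 0` with the
#' Lawson-Hanson active-set algorithm. Deterministic: no random
#' initialization, so repeated calls on the same input give identical output.
#' This is the constrained-projection primitive behind [deconvolve()] and
#' [bindex()].
#'
#' @param X Numeric matrix (rows = observations, columns = variables).
#' @param y Numeric vector, `length(y) == nrow(X)`.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @return Numeric vector of non-negative coefficients, one per column of `X`.
#' @export
nnls_fit <- function(X, y, tol = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(X)) * max(dim(X))

  passive <- logical(p)           # TRUE = unconstrained (positive) set
  x <- numeric(p)
  w <- drop(crossprod(X, y))      # gradient of -0.5*RSS at x = 0
  outer_max <- 30L * p

  for (it in seq_len(outer_max)) {
    cand <- which(!passive & w > tol)
    if (length(cand) == 0) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE

    repeat {
      s <- numeric(p)
      qrP <- qr(X[, passive, drop = FALSE])
      sP <- qr.coef(qrP, y)
      sP[is.na(sP)] <- 0          # collinear columns get coefficient 0
      s[passive] <- sP
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      # step toward s until the first passive coefficient hits zero
      drop_idx <- passive & (s <= tol)
      alpha <- min(x[drop_idx] / (x[drop_idx] - s[drop_idx]))
      x <- x + alpha * (s - x)
      passive[passive & (x <= tol)] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(X, y - X %*% x))
  }
  x[x < 0] <- 0
  names(x) <- colnames(X)
  x
}
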