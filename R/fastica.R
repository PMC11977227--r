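# Seeded deflation FastICA on the rows of X (k x L, rows zero-mean).
#
# Whitening keeps eigendirections with eigenvalue > 1e-12 * max, so a
# numerically rank-deficient mixture is reduced rather than blown up; a
# fully degenerate (constant) input is rejected. The tanh (log-cosh)
# nonlinearity is used with deflationary orthogonalization and a fixed
# random initialization drawn from `seed`, which makes the decomposition
# bit-reproducible. Returns the component matrix (rows are unit-variance
# independent components).
fastica_deflation <- function(X, seed, tol = 1e-9, max_iter = 500L) {
  k <- nrow(X); L <- ncol(X)
  if (any(!is.finite(X)))
    stop_pv("non-finite values in ICA input", class = "decomposition_error")
  C <- X %*% t(X) / L
  eg <- eigen(C, symmetric = TRUE)
  if (max(eg$values) <= 0)
    stop_pv("ICA input has zero variance", class = "decomposition_error")
  keep <- eg$values > max(eg$values) * 1e-12
  m <- sum(keep)
  if (m < 1L)
    stop_pv("rank-deficient ICA input", class = "decomposition_error")
  K <- diag(1 / sqrt(eg$values[keep]), m) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% X
  res <- with_private_rng(seed, {
    W <- matrix(0, m, m)
    for (i in seq_len(m)) {
      w <- rnorm(m)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- drop(crossprod(w, Z))
        g <- tanh(wx)
        w1 <- drop(Z %*% g) / L - mean(1 - g^2) * w
        if (i > 1L) {
          Wp <- W[seq_len(i - 1L), , drop = FALSE]
          w1 <- w1 - drop(crossprod(Wp, Wp %*% w1))
        }
        nrm <- sqrt(sum(w1^2))
        if (nrm < 1e-12) { w1 <- w; break }
        w1 <- w1 / nrm
        converged <- abs(abs(sum(w1 * w)) - 1) < tol
        w <- w1
        if (converged) break
      }
      W[i, ] <- w
    }
    W %*% Z
  })
  attr(res, "rng_state") <- NULL
  res
}
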