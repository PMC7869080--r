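# Shared fixtures: small generated datasets and model specs used across the
# unit tests. Everything is built in code under fixed seeds.

# one-factor data with known loadings (1, .8, 1.2) and unit residuals
gen_one_factor <- function(n, seed = 1, loadings = c(1, 0.8, 1.2),
                           resid_sd = rep(1, length(loadings))) {
  set.seed(seed)
  f <- rnorm(n)
  d <- as.data.frame(lapply(seq_along(loadings), function(j)
    loadings[j] * f + rnorm(n, 0, resid_sd[j])))
  names(d) <- paste0("x", seq_along(loadings))
  d
}

# two orthogonal factors with 3 indicators each and a free cross covariance
two_factor_spec <- function() {
  sem_model("
    F =~ x1 + x2 + x3
    G =~ y1 + y2 + y3
    F ~~ G
  ")
}

gen_two_factor <- function(n, seed = 1, cov_fg = 0) {
  set.seed(seed)
  S <- matrix(c(1, cov_fg, cov_fg, 1), 2)
  fg <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
  data.frame(x1 = fg[, 1] + rnorm(n), x2 = 0.8 * fg[, 1] + rnorm(n),
             x3 = 0.7 * fg[, 1] + rnorm(n),
             y1 = fg[, 2] + rnorm(n), y2 = 0.8 * fg[, 2] + rnorm(n),
             y3 = 0.7 * fg[, 2] + rnorm(n))
}

# independent row-wise FIML oracle: per-row normal densities at given
# implied moments, means profiled by an independent R-side GLS step
rowwise_fiml_loglik <- function(Y, Sigma) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  A <- matrix(0, p, p); b <- numeric(p)
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    Si <- solve(Sigma[o, o, drop = FALSE])
    A[o, o] <- A[o, o] + Si
    b[o] <- b[o] + Si %*% Y[i, o]
  }
  mu <- solve(A, b)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    S <- Sigma[o, o, drop = FALSE]
    d <- Y[i, o] - mu[o]
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                        as.numeric(determinant(S)$modulus) +
                        drop(t(d) %*% solve(S) %*% d))
  }
  ll
}

# construct a sample of n rows whose sample mean and ML covariance (divisor
# n) equal the supplied moments exactly
exact_moment_sample <- function(n, mu, Sigma, seed = 1) {
  set.seed(seed)
  p <- length(mu)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Sz <- crossprod(Z) / n
  Z <- Z %*% solve(chol(Sz))
  X <- Z %*% chol(Sigma)
  sweep(X, 2, mu, `+`)
}
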