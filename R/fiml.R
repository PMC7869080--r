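# Full-information maximum likelihood plumbing: missingness-pattern
# extraction, the likelihood wrapper around the compiled objective, and the
# saturated / baseline reference models needed for chi-square and CFI.

# Split rows of a numeric matrix by missingness pattern and reduce each
# pattern to sufficient statistics. Fully missing rows contribute nothing
# and are dropped.
.missingness_patterns <- function(Y, keep_rows = FALSE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    oidx <- which(obs[rows[1], ])
    if (length(oidx) == 0L) next
    X <- Y[rows, oidx, drop = FALSE]
    xbar <- colMeans(X)
    W <- crossprod(sweep(X, 2, xbar))
    pat <- list(oidx = as.integer(oidx - 1L), n = as.double(length(rows)),
                xbar = xbar, W = W)
    if (keep_rows) { pat$X <- X; pat$rows <- rows }
    out[[length(out) + 1L]] <- pat
  }
  out
}

# Build the C++ evaluation context for a compiled model and per-group data.
.fiml_ctx <- function(ram, Y_list) {
  stopifnot(length(Y_list) == ram$ngroups)
  obs_idx <- match(ram$observed, ram$vars)
  groups <- vector("list", ram$ngroups)
  for (g in seq_len(ram$ngroups)) {
    f <- ram$free[ram$free$group == g, , drop = FALSE]
    fc <- cbind(match(f$label, ram$labels) - 1L,
                match(f$matrix, c("A", "S", "M")) - 1L,
                f$i - 1L, f$j - 1L)
    storage.mode(fc) <- "integer"
    groups[[g]] <- list(
      A0 = ram$A[[g]], S0 = ram$S[[g]], M0 = as.numeric(ram$M[[g]]),
      obs = as.integer(obs_idx - 1L), free_cells = fc,
      mean_mode = if (ram$meanstructure) 1L else 0L,
      patterns = .missingness_patterns(Y_list[[g]]))
  }
  list(groups = groups)
}

#' FIML log-likelihood of a model at a parameter vector
#'
#' Sums, over missingness patterns, the multivariate-normal log density of
#' each row's observed sub-vector under the pattern-restricted implied mean
#' and covariance. With no missing cells this equals the complete-data normal
#' log-likelihood. Saturated means are profiled out unless the model carries
#' an explicit mean structure.
#'
#' @param ram A `ram_matrices` object.
#' @param theta Free-parameter vector (in `ram$labels` order, or named).
#' @param data Data frame or matrix containing the observed columns (for a
#'   multigroup model, a list of per-group data).
#' @return The log-likelihood (a real scalar; `-Inf` if `theta` implies a
#'   non-positive-definite covariance for some pattern).
#' @export
fiml_loglik <- function(ram, theta, data) {
  stopifnot(inherits(ram, "ram_matrices"))
  if (!is.null(names(theta))) theta <- theta[ram$labels]
  Y_list <- .as_group_matrices(ram, data)
  ctx <- .fiml_ctx(ram, Y_list)
  v <- .fiml_neg2ll_cpp(as.numeric(theta), ctx)
  if (v >= 1e10) return(-Inf)
  -v / 2
}

.as_group_matrices <- function(ram, data) {
  if (is.data.frame(data) || is.matrix(data)) data <- list(data)
  lapply(data, function(d) {
    d <- as.data.frame(d)
    miss <- setdiff(ram$observed, names(d))
    if (length(miss))
      stop("data lack observed columns: ", paste(miss, collapse = ", "))
    as.matrix(d[, ram$observed, drop = FALSE])
  })
}

# ---------------------------------------------------------------------------
# Saturated and baseline reference models

# EM for an unstructured multivariate normal under missingness.
.em_mvn <- function(Y, max_iter = 2000L, tol = 1e-10) {
  Y <- as.matrix(Y)
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  pats <- .missingness_patterns(Y, keep_rows = TRUE)
  mu <- colMeans(Y, na.rm = TRUE)
  Sg <- cov(Y, use = "pairwise.complete.obs")
  Sg[is.na(Sg)] <- 0
  Sg <- Sg * (n - 1) / n
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev))
    Sg <- Sg + diag(p) * (abs(min(ev)) + 1e-6 * max(ev))
  stat_pats <- lapply(pats, function(p) p[c("oidx", "n", "xbar", "W")])
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (pat in pats) {
      o <- pat$oidx + 1L
      m <- setdiff(seq_len(p), o)
      X <- pat$X
      if (length(m) == 0L) {
        T1 <- T1 + colSums(X)
        T2 <- T2 + crossprod(X)
      } else {
        Soo_inv <- solve(Sg[o, o, drop = FALSE])
        reg <- Sg[m, o, drop = FALSE] %*% Soo_inv
        Xc <- sweep(X, 2, mu[o])
        Xm <- sweep(Xc %*% t(reg), 2, mu[m], `+`)
        C <- Sg[m, m, drop = FALSE] - reg %*% Sg[o, m, drop = FALSE]
        Xfull <- matrix(0, nrow(X), p)
        Xfull[, o] <- X; Xfull[, m] <- Xm
        T1 <- T1 + colSums(Xfull)
        T2 <- T2 + crossprod(Xfull)
        T2[m, m] <- T2[m, m] + nrow(X) * C
      }
    }
    mu <- T1 / n
    Sg <- T2 / n - tcrossprod(mu)
    Sg <- (Sg + t(Sg)) / 2
    ll <- -.mvn_pattern_neg2ll_cpp(mu, Sg, stat_pats) / 2
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = Sg, loglik = ll, iterations = it)
}

# Saturated fit by direct quasi-Newton optimization of the free covariance
# (provided as a cross-check on the EM path).
.saturated_direct <- function(Y) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  pats <- .missingness_patterns(Y)
  start <- .em_start_cov(Y)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  th0 <- start[idx]
  fn <- function(th) {
    S <- matrix(0, p, p)
    S[idx] <- th; S[idx[, c(2, 1)]] <- th
    mu <- .profiled_mean(S, pats, p)
    if (is.null(mu)) return(1e10)
    .mvn_pattern_neg2ll_cpp(mu, S, pats)
  }
  opt <- optim(th0, fn, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  -opt$value / 2
}

.em_start_cov <- function(Y) {
  S <- cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev))
    S <- S + diag(ncol(Y)) * (abs(min(ev)) + 1e-6 * max(ev))
  S
}

.profiled_mean <- function(Sigma, pats, p) {
  Amat <- matrix(0, p, p); bvec <- numeric(p)
  for (pat in pats) {
    o <- pat$oidx + 1L
    Si <- tryCatch(solve(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(Si)) return(NULL)
    if (min(eigen(Si, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      return(NULL)
    Amat[o, o] <- Amat[o, o] + pat$n * Si
    bvec[o] <- bvec[o] + pat$n * (Si %*% pat$xbar)
  }
  tryCatch(drop(solve(Amat, bvec)), error = function(e) NULL)
}

#' Saturated and baseline log-likelihoods under missingness
#'
#' The saturated model has free means and an unrestricted covariance (fitted
#' by an EM algorithm, or by direct optimization as a cross-check); the
#' baseline (independence) model has free means and variances with all
#' covariances zero, which factorizes into per-column univariate normal fits.
#' With complete data the saturated log-likelihood equals the plug-in normal
#' log-likelihood at the sample mean and ML covariance.
#'
#' @param data Data frame or matrix (rows may contain missing cells).
#' @param vars Character vector of columns to use; default all columns.
#' @param method `"em"` (default) or `"direct"` for the saturated fit.
#' @return List with `loglik_saturated`, `loglik_baseline`, `df_baseline`
#'   (covariance moments minus the `p` free variances), `mu`, `sigma` (the
#'   saturated estimates), and `em_iterations`.
#' @export
saturated_and_baseline <- function(data, vars = NULL, method = c("em", "direct")) {
  method <- match.arg(method)
  d <- as.data.frame(data)
  if (is.null(vars)) vars <- names(d)
  Y <- as.matrix(d[, vars, drop = FALSE])
  p <- ncol(Y)
  em <- .em_mvn(Y)
  ll_sat <- if (method == "em") em$loglik else .saturated_direct(Y)
  ll_base <- 0
  for (j in seq_len(p)) {
    x <- Y[, j]; x <- x[!is.na(x)]
    nj <- length(x); vj <- mean((x - mean(x))^2)
    ll_base <- ll_base - 0.5 * (nj * log(2 * pi) + nj * log(vj) + nj)
  }
  list(loglik_saturated = ll_sat, loglik_baseline = ll_base,
       df_baseline = p * (p + 1) / 2 - p,
       mu = em$mu, sigma = em$sigma, em_iterations = em$iterations)
}
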