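# Model fitting by quasi-Newton maximization of the FIML likelihood, with
# observed-information standard errors, chi-square against the saturated
# model, fit indices, and likelihood-ratio / Wald inference.

.default_control <- function(control) {
  modifyList(list(maxit = 10000L, reltol = 1e-12, grad_tol = 1e-5,
                  grad_rtol = 5e-5, grad_eps = 1e-6, restarts = 2L,
                  newton_steps = 10L, hess_eps = 1e-4), control)
}

# Rule-based starting values: loadings 1 (or the sign hint supplied via
# set_start), regressions 0, observed residual variances at half the
# observed variance, latent variances at half the variance of the reference
# indicator, means at observed column means. Covariances involving latent
# variables start at half the sample covariance of the variables' reference
# indicators -- with reference loadings fixed at 1 this is a rough
# method-of-moments value that keeps the search out of degenerate basins.
.start_values <- function(ram, Y_list) {
  pt <- ram$spec$partable
  col_var <- lapply(Y_list, function(Y)
    apply(Y, 2, function(x) var(x[!is.na(x)])))
  col_mean <- lapply(Y_list, function(Y) colMeans(Y, na.rm = TRUE))
  col_cov <- lapply(Y_list, function(Y)
    suppressWarnings(cov(Y, use = "pairwise.complete.obs")))
  ref_ind <- vapply(ram$latents, function(lv) {
    fixed <- pt$rhs[pt$op == "=~" & pt$lhs == lv & !pt$free & pt$value != 0]
    if (length(fixed)) fixed[1] else
      pt$rhs[pt$op == "=~" & pt$lhs == lv][1]
  }, character(1))
  theta <- setNames(numeric(length(ram$labels)), ram$labels)
  seen <- logical(length(ram$labels))
  f <- ram$free
  for (r in seq_len(nrow(f))) {
    k <- match(f$label[r], ram$labels)
    if (seen[k]) next
    seen[k] <- TRUE
    if (!is.na(f$start[r])) { theta[k] <- f$start[r]; next }
    g <- f$group[r]
    vi <- ram$vars[f$i[r]]; vj <- ram$vars[f$j[r]]
    if (f$matrix[r] == "A") {
      # loading rows have latent source in column j; regressions start at 0
      theta[k] <- if (vj %in% ram$latents && vi %in% ram$observed &&
                      any(pt$op == "=~" & pt$lhs == vj & pt$rhs == vi)) 1 else 0
    } else if (f$matrix[r] == "S") {
      if (vi == vj) {
        v <- if (vi %in% ram$observed) col_var[[g]][[vi]] else {
          ref <- ref_ind[[vi]]
          if (!is.na(ref) && ref %in% ram$observed) col_var[[g]][[ref]] else 1
        }
        theta[k] <- 0.5 * v
      } else if (vi %in% ram$latents || vj %in% ram$latents) {
        proxy <- function(v) {
          if (v %in% ram$observed) return(v)
          r <- ref_ind[[v]]
          if (!is.na(r) && r %in% ram$observed) r else NA_character_
        }
        pi <- proxy(vi); pj <- proxy(vj)
        cv <- if (!is.na(pi) && !is.na(pj)) col_cov[[g]][pi, pj] else NA_real_
        theta[k] <- if (is.finite(cv)) 0.5 * cv else 0
      } else theta[k] <- 0
    } else { # means
      theta[k] <- if (vi %in% ram$observed) col_mean[[g]][[vi]] else 0
    }
  }
  theta
}

#' Fit a structural equation model by FIML
#'
#' Maximizes the full-information maximum likelihood over all rows (each row
#' contributes its observed sub-vector) by quasi-Newton (BFGS) iteration with
#' compiled central-difference gradients. Standard errors come from the
#' inverse observed information (numerical Hessian at the optimum). The
#' chi-square statistic is `2 * (loglik_saturated - loglik_model)` with the
#' saturated model fitted by EM under the same missingness.
#'
#' @param spec A `sem_spec`.
#' @param data Data frame with the observed columns. For multigroup models
#'   either a list of data frames or a single frame plus `group`.
#' @param group Optional name of a grouping column; the specification is
#'   expanded to a configural multigroup model if it is single-group.
#' @param se Compute standard errors (default `TRUE`).
#' @param fix_heywood If a residual-variance estimate is negative, refit with
#'   that variance fixed to zero (default `FALSE`: the Heywood case is only
#'   flagged).
#' @param baseline Also fit saturated/baseline reference models and compute
#'   fit indices (default `TRUE`).
#' @param control List overriding optimizer settings: `maxit` (10000),
#'   `reltol` (1e-12, BFGS relative function tolerance), `grad_tol` (1e-5,
#'   absolute max-norm of the log-likelihood gradient at the solution),
#'   `grad_rtol` (5e-5, gradient norm relative to the deviance magnitude),
#'   `restarts` (2).
#' @return An object of class `sem_fit`.
#' @export
sem_fit <- function(spec, data, group = NULL, se = TRUE, fix_heywood = FALSE,
                    baseline = TRUE, control = list()) {
  stopifnot(inherits(spec, "sem_spec"))
  ctrl <- .default_control(control)
  group_levels <- NULL
  if (!is.null(group)) {
    stopifnot(is.data.frame(data), group %in% names(data))
    gv <- data[[group]]
    group_levels <- sort(unique(gv[!is.na(gv)]))
    ngroups <- length(group_levels)
    if (length(unique(spec$partable$group)) == 1L && ngroups > 1L)
      spec <- multigroup_spec(spec, ngroups)
    data <- lapply(group_levels, function(l) data[!is.na(gv) & gv == l, , drop = FALSE])
  }
  ram <- compile_ram(spec)
  Y_list <- .as_group_matrices(ram, data)
  for (g in seq_along(Y_list)) {
    keep <- rowSums(!is.na(Y_list[[g]])) > 0L
    Y_list[[g]] <- Y_list[[g]][keep, , drop = FALSE]
  }
  n_groups <- vapply(Y_list, nrow, integer(1))
  if (any(n_groups < length(ram$observed) + 1L))
    warning("a group has fewer rows than observed variables; estimates may be unstable")
  ctx <- .fiml_ctx(ram, Y_list)
  theta0 <- .start_values(ram, Y_list)

  ctx_ptr <- .fiml_make_ctx_cpp(ctx)
  # Latent variances are kept (weakly) positive by a smooth quadratic
  # barrier: inadmissible basins with negative factor variances can fit MTMM
  # covariance structures equally well or better, and dense BFGS would
  # otherwise wander into them. Residual variances of observed variables
  # stay unbounded so Heywood cases remain visible.
  f1 <- ram$free[!duplicated(ram$free$label), , drop = FALSE]
  lat_var <- f1$matrix == "S" & f1$i == f1$j & ram$vars[f1$i] %in% ram$latents
  lat_idx <- match(f1$label[lat_var], ram$labels)
  bw <- 1e6; bthr <- 1e-6
  barrier <- function(th) {
    d <- pmin(th[lat_idx] - bthr, 0); bw * sum(d * d)
  }
  barrier_grad <- function(th) {
    g <- numeric(length(th))
    g[lat_idx] <- 2 * bw * pmin(th[lat_idx] - bthr, 0)
    g
  }
  fn <- function(th) .fiml_neg2ll_ptr_cpp(th, ctx_ptr) + barrier(th)
  gr <- function(th) as.numeric(.fiml_grad_ptr_cpp(th, ctx_ptr, ctrl$grad_eps)) +
    barrier_grad(th)

  # reference moments (EM-fitted saturated model); reused for the chi-square
  # and fit indices below
  sats <- lapply(Y_list, function(Y) saturated_and_baseline(Y))
  multi_pattern <- any(vapply(ctx$groups,
                              function(g) length(g$patterns) > 1L, logical(1)))
  iterations <- 0L
  if (multi_pattern) {
    # stage 1: fit to the saturated moments as if data were complete -- a
    # fast, smooth surrogate whose optimum is close to the FIML solution
    ctx1 <- ctx
    for (g in seq_along(ctx1$groups)) {
      p <- length(ram$observed)
      ng <- sum(vapply(ctx$groups[[g]]$patterns, `[[`, numeric(1), "n"))
      ctx1$groups[[g]]$patterns <- list(list(
        oidx = 0:(p - 1L), n = as.double(ng), xbar = sats[[g]]$mu,
        W = ng * sats[[g]]$sigma))
    }
    ptr1 <- .fiml_make_ctx_cpp(ctx1)
    o1 <- optim(theta0,
                function(th) .fiml_neg2ll_ptr_cpp(th, ptr1) + barrier(th),
                function(th) as.numeric(.fiml_grad_ptr_cpp(th, ptr1, ctrl$grad_eps)) +
                  barrier_grad(th),
                method = "BFGS",
                control = list(maxit = ctrl$maxit, reltol = 1e-9))
    theta0 <- o1$par
    iterations <- iterations + o1$counts[["function"]]
  }
  # dense quasi-Newton on the true objective
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  iterations <- iterations + opt$counts[["function"]]
  for (r in seq_len(ctrl$restarts)) {
    if (opt$convergence == 0L) break
    opt2 <- optim(opt$par, fn, gr, method = "BFGS",
                  control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    iterations <- iterations + opt2$counts[["function"]]
    if (opt2$value <= opt$value) opt <- opt2 else break
  }
  # Newton polish with the numerical Hessian: quasi-Newton alone leaves the
  # deviance O(1e-2) above the optimum on ill-conditioned surfaces, which is
  # too coarse for chi-square differences between equivalent models
  H <- NULL
  for (step in seq_len(ctrl$newton_steps)) {
    val_before <- opt$value
    g <- gr(opt$par)
    if (max(abs(g)) / 2 <= ctrl$grad_tol) break
    H <- tryCatch(optimHess(opt$par, fn, gr,
                            control = list(ndeps = rep(ctrl$hess_eps,
                                                       length(opt$par)))),
                  error = function(e) NULL)
    if (is.null(H)) break
    Hs <- (H + t(H)) / 2
    scale <- max(abs(diag(Hs)), 1)
    ridge <- 1e-10 * scale
    improved <- FALSE
    for (try_i in 1:10) {
      dir <- tryCatch(solve(Hs + ridge * diag(nrow(Hs)), g),
                      error = function(e) NULL)
      if (!is.null(dir) && all(is.finite(dir)) && sum(g * dir) > 0) {
        t_step <- 1
        for (ls in 1:25) {
          cand <- opt$par - t_step * dir
          v <- fn(cand)
          iterations <- iterations + 1L
          if (is.finite(v) && v < opt$value) {
            opt$par <- cand; opt$value <- v; improved <- TRUE; break
          }
          t_step <- t_step / 2
        }
        if (improved) break
      }
      ridge <- max(ridge * 100, 1e-8 * scale)
    }
    if (!improved) break
    if (val_before - opt$value < 1e-10 * (1 + abs(opt$value))) break
  }
  theta <- setNames(opt$par, ram$labels)
  boundary <- ram$labels[lat_idx][theta[lat_idx] <= bthr + 1e-4]
  grad_norm <- max(abs(gr(opt$par))) / 2
  converged <- is.finite(opt$value) && opt$value < 1e10 &&
    opt$convergence == 0L &&
    (grad_norm <= ctrl$grad_tol ||
       grad_norm <= ctrl$grad_rtol * (1 + abs(opt$value)) ||
       length(boundary) > 0L)
  loglik <- -(opt$value - barrier(opt$par)) / 2

  # Heywood screen: negative residual variances of observed variables
  f <- ram$free
  heywood <- character()
  for (k in seq_along(ram$labels)) {
    rows <- f[f$label == ram$labels[k] & f$matrix == "S", , drop = FALSE]
    if (nrow(rows) && any(rows$i == rows$j & ram$vars[rows$i] %in% ram$observed) &&
        theta[k] < 0)
      heywood <- c(heywood, ram$labels[k])
  }
  if (fix_heywood && length(heywood)) {
    spec2 <- spec
    for (h in heywood) spec2 <- fix_parameter(spec2, h, 0)
    refit <- sem_fit(spec2, data, group = NULL, se = se,
                     fix_heywood = FALSE, baseline = baseline, control = control)
    refit$heywood_fixed <- heywood
    return(refit)
  }

  vcov_theta <- NULL; se_theta <- rep(NA_real_, length(theta))
  if (se) {
    if (is.null(H))
      H <- tryCatch(optimHess(opt$par, fn, gr,
                              control = list(ndeps = rep(ctrl$hess_eps,
                                                         length(opt$par)))),
                    error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(V)) {
        dv <- diag(V)
        se_theta <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
        vcov_theta <- V
        dimnames(vcov_theta) <- list(ram$labels, ram$labels)
      }
    }
  }

  details <- .fiml_details_cpp(opt$par, ctx)
  sat <- base_ll <- NULL
  chi2 <- df <- chi2_base <- df_base <- cfi <- rmsea <- srmr <- NA_real_
  if (baseline) {
    ll_sat <- sum(vapply(sats, `[[`, numeric(1), "loglik_saturated"))
    ll_base <- sum(vapply(sats, `[[`, numeric(1), "loglik_baseline"))
    df <- model_df(spec)
    chi2 <- max(2 * (ll_sat - loglik), 0)
    df_base <- sum(vapply(sats, `[[`, numeric(1), "df_baseline")) +
      if (spec$meanstructure) 0 else 0
    chi2_base <- max(2 * (ll_sat - ll_base), 0)
    srmr_g <- vapply(seq_along(sats), function(g) {
      .srmr_matrix(sats[[g]]$sigma, details[[g]]$Sigma)
    }, numeric(1))
    srmr <- sqrt(sum(n_groups * srmr_g^2) / sum(n_groups))
    fi <- fit_indices(chi2, df, chi2_base, df_base, sum(n_groups))
    cfi <- fi$cfi; rmsea <- fi$rmsea
    sat <- ll_sat; base_ll <- ll_base
  }

  structure(list(
    spec = spec, ram = ram, theta = theta, se = setNames(se_theta, ram$labels),
    vcov = vcov_theta, loglik = loglik,
    loglik_saturated = sat, loglik_baseline = base_ll,
    chi2 = chi2, df = if (baseline) df else model_df(spec),
    chi2_baseline = chi2_base, df_baseline = df_base,
    cfi = cfi, rmsea = rmsea, srmr = srmr,
    n = n_groups, group_levels = group_levels,
    converged = converged, iterations = iterations, grad_norm = grad_norm,
    heywood = heywood, heywood_fixed = character(), boundary = boundary,
    implied = lapply(details, function(d)
      list(mean = setNames(drop(d$mu), ram$observed), cov = {
        S <- d$Sigma; dimnames(S) <- list(ram$observed, ram$observed); S
      }))),
    class = "sem_fit")
}

# root-mean-square standardized residual over the lower triangle including
# the diagonal; standardization by the saturated (sample-level) SDs
.srmr_matrix <- function(S_obs, S_imp) {
  sds <- sqrt(diag(S_obs))
  R <- (S_obs - S_imp) / tcrossprod(sds)
  sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
}

#' Chi-square-based fit indices
#'
#' CFI, RMSEA, and (when a residual matrix is supplied) SRMR.
#' `CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)`;
#' `RMSEA = sqrt(max(chi2_m - df_m, 0) / (df_m * n))` (the `n` convention,
#' switchable to `n - 1`); SRMR is the root mean square of the standardized
#' residual covariance over the lower triangle including the diagonal.
#'
#' @param chi2,df Model chi-square and degrees of freedom.
#' @param chi2_baseline,df_baseline Baseline (independence) model values.
#' @param n Total sample size.
#' @param residuals Optional standardized residual covariance matrix for
#'   SRMR.
#' @param rmsea_n `"n"` (default) or `"n-1"` denominator convention.
#' @return List with `cfi`, `rmsea`, `srmr` (latter `NA` without residuals).
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n,
                        residuals = NULL, rmsea_n = c("n", "n-1")) {
  rmsea_n <- match.arg(rmsea_n)
  stopifnot(df_baseline >= df)
  num <- max(chi2 - df, 0)
  den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  nn <- if (rmsea_n == "n") n else n - 1
  rmsea <- if (df == 0) 0 else sqrt(num / (df * nn))
  srmr <- NA_real_
  if (!is.null(residuals)) {
    R <- as.matrix(residuals)
    srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  }
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

#' Likelihood-ratio (chi-square difference) test of nested models
#'
#' @param full,restricted `sem_fit` objects for the freely estimated and the
#'   constrained model fitted to the same data.
#' @return List of class `sem_lrt`: `delta_chi2`, `delta_df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, restricted) {
  stopifnot(inherits(full, "sem_fit"), inherits(restricted, "sem_fit"))
  d_chi2 <- 2 * (full$loglik - restricted$loglik)
  d_df <- restricted$df - full$df
  if (d_df < 1) stop("`restricted` must have more degrees of freedom than `full`")
  if (d_chi2 < -1e-6)
    stop("negative chi-square difference (", format(d_chi2),
         "): models are not nested or one fit did not converge")
  d_chi2 <- max(d_chi2, 0)
  structure(list(delta_chi2 = d_chi2, delta_df = d_df,
                 p_value = pchisq(d_chi2, d_df, lower.tail = FALSE)),
            class = "sem_lrt")
}

#' @export
print.sem_lrt <- function(x, ...) {
  cat(sprintf("LRT: delta chi-square = %.4f, delta df = %d, p = %.4g\n",
              x$delta_chi2, x$delta_df, x$p_value))
  invisible(x)
}

#' Wald (z) tests for all free parameters
#'
#' `z = estimate / SE` with a two-sided normal p-value; parameters whose
#' standard error is unavailable (non-positive-definite information) get
#' `NA`.
#'
#' @param fit A `sem_fit`.
#' @return Data frame with `label`, `estimate`, `se`, `z`, `p`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  z <- fit$theta / fit$se
  data.frame(label = names(fit$theta), estimate = as.numeric(fit$theta),
             se = as.numeric(fit$se), z = as.numeric(z),
             p = 2 * pnorm(-abs(as.numeric(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

# standardized parameter values at an arbitrary theta (used for delta-method
# standard errors); returns numeric vector aligned with eligible partable rows
.std_values <- function(fit, theta, rows, group_idx) {
  ram <- fit$ram
  out <- numeric(nrow(rows))
  for (gi in unique(group_idx)) {
    im <- implied_moments(ram, theta, group = gi)
    sds <- sqrt(pmax(diag(im$cov_all), 0))
    names(sds) <- ram$vars
    sel <- which(group_idx == gi)
    for (r in sel) {
      row <- rows[r, ]
      val <- if (row$free) theta[[match(row$label, ram$labels)]] else row$value
      out[r] <- switch(row$op,
        "=~" = val * sds[[row$lhs]] / sds[[row$rhs]],
        "~"  = val * sds[[row$rhs]] / sds[[row$lhs]],
        "~~" = val / (sds[[row$lhs]] * sds[[row$rhs]]),
        val)
    }
  }
  out
}

#' Standardized solution
#'
#' Rescales every loading, regression, and (co)variance by the model-implied
#' standard deviations of its variables: standardized loadings are
#' correlations of indicator and factor scale, standardized factor
#' covariances are correlations (outside Heywood conditions), and each
#' indicator's standardized communality plus residual sums to one. Standard
#' errors come from the delta method (numerical Jacobian against the free
#' parameters).
#'
#' @param fit A converged `sem_fit`.
#' @param se Compute delta-method standard errors (default `TRUE` when the
#'   fit has a parameter covariance).
#' @return Data frame: `lhs`, `op`, `rhs`, `group`, `label`, `estimate`
#'   (unstandardized), `std` (standardized), `std_se`.
#' @export
standardized_solution <- function(fit, se = !is.null(fit$vcov)) {
  stopifnot(inherits(fit, "sem_fit"))
  pt <- fit$spec$partable
  rows <- pt[pt$op %in% c("=~", "~", "~~"), , drop = FALSE]
  gl <- sort(unique(fit$spec$partable$group))
  group_idx <- match(rows$group, gl)
  theta <- fit$theta
  std <- .std_values(fit, theta, rows, group_idx)
  std_se <- rep(NA_real_, nrow(rows))
  if (se && !is.null(fit$vcov)) {
    k <- length(theta)
    J <- matrix(0, nrow(rows), k)
    for (i in seq_len(k)) {
      h <- 1e-5 * (1 + abs(theta[i]))
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      J[, i] <- (.std_values(fit, tp, rows, group_idx) -
                 .std_values(fit, tm, rows, group_idx)) / (2 * h)
    }
    v <- rowSums((J %*% fit$vcov) * J)
    std_se <- ifelse(v >= 0, sqrt(v), NA_real_)
  }
  est <- ifelse(rows$free, theta[match(rows$label, names(theta))], rows$value)
  data.frame(lhs = rows$lhs, op = rows$op, rhs = rows$rhs, group = rows$group,
             label = rows$label, estimate = as.numeric(est), std = std,
             std_se = std_se, row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of latent variance explained
#'
#' For a latent outcome with directed predictors (a MIMIC-style latent
#' regression), returns `1 - residual variance / implied total variance`.
#'
#' @param fit A `sem_fit`.
#' @param outcome Name of the latent outcome variable.
#' @param group Group index (default 1).
#' @return R-squared in `[0, 1]` (errors if the implied variance is not
#'   positive).
#' @export
r_squared <- function(fit, outcome, group = 1L) {
  stopifnot(inherits(fit, "sem_fit"))
  ram <- fit$ram
  if (!outcome %in% ram$vars) stop("unknown variable `", outcome, "`")
  im <- implied_moments(ram, fit$theta, group = group)
  total <- im$cov_all[outcome, outcome]
  if (total <= 0) stop("implied variance of `", outcome, "` is not positive")
  m <- .ram_fill(ram, as.numeric(fit$theta[ram$labels]), group)
  resid <- m$S[outcome, outcome]
  1 - resid / total
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("FIML structural equation model fit\n")
  cat("  n =", paste(x$n, collapse = " + "),
      " free parameters =", length(x$theta), "\n")
  cat(sprintf("  loglik = %.4f   chi-square(df = %d) = %.4f\n",
              x$loglik, x$df, x$chi2))
  if (is.finite(x$cfi))
    cat(sprintf("  CFI = %.4f   RMSEA = %.4f   SRMR = %.4f\n",
                x$cfi, x$rmsea, x$srmr))
  cat("  converged:", x$converged,
      sprintf("(iterations %d, |grad| %.2e)\n", x$iterations, x$grad_norm))
  if (length(x$heywood))
    cat("  Heywood case: negative residual variance for",
        paste(x$heywood, collapse = ", "), "\n")
  if (length(x$boundary))
    cat("  latent variance at admissibility boundary:",
        paste(x$boundary, collapse = ", "), "\n")
  if (length(x$heywood_fixed))
    cat("  refitted with", paste(x$heywood_fixed, collapse = ", "),
        "fixed to zero\n")
  invisible(x)
}
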