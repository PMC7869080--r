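# Estimation: parameter recovery, chi-square properties, inference, and the
# standardized solution.

test_that("free parameters are recovered within 3 SEs at large n", {
  d <- gen_one_factor(5000, seed = 31, loadings = c(1, 0.8, 1.2, -0.6),
                      resid_sd = c(1, 0.9, 0.8, 1))
  spec <- sem_model("F =~ x1 + x2 + x3 + x4")
  fit <- sem_fit(spec, d)
  expect_true(fit$converged)
  truth <- c("F=~x2" = 0.8, "F=~x3" = 1.2, "F=~x4" = -0.6, "F~~F" = 1,
             "x1~~x1" = 1, "x2~~x2" = 0.81, "x3~~x3" = 0.64, "x4~~x4" = 1)
  z <- (fit$theta[names(truth)] - truth) / fit$se[names(truth)]
  expect_true(all(abs(z) < 3))
})

test_that("a just-identified model reproduces the sample moments exactly", {
  d <- gen_one_factor(400, seed = 32)
  fit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d)
  expect_equal(fit$chi2, 0, tolerance = 1e-4)
  expect_identical(fit$df, 0L)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  n <- nrow(d)
  S <- cov(d) * (n - 1) / n
  expect_equal(unname(fit$implied[[1]]$cov), unname(S), tolerance = 1e-5)
  expect_equal(unname(fit$implied[[1]]$mean), unname(colMeans(d)),
               tolerance = 1e-8)
})

test_that("chi-square is invariant to affine rescaling of the columns", {
  set.seed(33)
  d <- gen_two_factor(300, seed = 33, cov_fg = 0.3)
  spec <- two_factor_spec()
  fit1 <- sem_fit(spec, d, se = FALSE)
  d2 <- rescale_columns(d)
  fit2 <- sem_fit(spec, d2, se = FALSE)
  expect_equal(fit1$chi2, fit2$chi2, tolerance = 1e-4)
  expect_identical(fit1$df, fit2$df)
})

test_that("FIML under missingness still recovers the generating structure", {
  set.seed(34)
  d <- gen_two_factor(2000, seed = 34, cov_fg = 0.5)
  # missing-at-random masks on both blocks
  d$y2[runif(2000) < 0.3] <- NA
  d$x3[runif(2000) < 0.2] <- NA
  fit <- sem_fit(two_factor_spec(), d)
  expect_true(fit$converged)
  z <- (fit$theta[["F~~G"]] - 0.5) / fit$se[["F~~G"]]
  expect_lt(abs(z), 3)
})

test_that("likelihood-ratio tests behave on nested pairs", {
  d <- gen_two_factor(500, seed = 35, cov_fg = 0.45)
  full <- sem_fit(two_factor_spec(), d, se = FALSE)
  restricted <- sem_fit(fix_parameter(two_factor_spec(), "F~~G", 0), d,
                        se = FALSE)
  lrt <- likelihood_ratio_test(full, restricted)
  expect_identical(lrt$delta_df, 1L)
  expect_gt(lrt$delta_chi2, 0)
  expect_lt(lrt$p_value, 0.01)   # generating covariance is far from zero
  # non-nested orderings (including identical models) are rejected: a
  # difference test needs at least one added constraint
  expect_error(likelihood_ratio_test(full, full), "degrees of freedom")
  expect_error(likelihood_ratio_test(restricted, full), "degrees of freedom")
})

test_that("Wald z-squared tracks the LRT chi-square for one covariance", {
  d <- gen_two_factor(5000, seed = 36, cov_fg = 0.2)
  full <- sem_fit(two_factor_spec(), d)
  restricted <- sem_fit(fix_parameter(two_factor_spec(), "F~~G", 0), d,
                        se = FALSE)
  lrt <- likelihood_ratio_test(full, restricted)
  w <- wald_tests(full)
  z2 <- w$z[w$label == "F~~G"]^2
  expect_gt(z2 / lrt$delta_chi2, 0.8)
  expect_lt(z2 / lrt$delta_chi2, 1.25)
})

test_that("Heywood cases are flagged and can be fixed on request", {
  # tiny sample with a near-zero generating residual invites a negative
  # residual-variance estimate
  set.seed(120)
  found <- FALSE
  for (s in 1:25) {
    d <- gen_one_factor(60, seed = 5000 + s, loadings = c(1, 0.9, 1.1),
                        resid_sd = c(0.05, 1, 1))
    fit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d, se = FALSE,
                   baseline = FALSE)
    if (length(fit$heywood)) { found <- TRUE; break }
  }
  expect_true(found)
  refit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d, se = FALSE,
                   baseline = FALSE, fix_heywood = TRUE)
  expect_identical(refit$heywood_fixed, fit$heywood)
  expect_false(any(fit$heywood %in% names(refit$theta)))
  expect_lte(refit$loglik, fit$loglik + 1e-6)
})

test_that("standardized solution is a correlation-scale rescaling", {
  d <- gen_two_factor(1500, seed = 37, cov_fg = 0.5)
  fit <- sem_fit(two_factor_spec(), d)
  ss <- standardized_solution(fit)
  # standardized factor covariance lies in [-1, 1] and near the truth
  r <- ss[ss$op == "~~" & ss$lhs == "F" & ss$rhs == "G", ]
  expect_lt(abs(r$std), 1)
  expect_lt(abs(r$std - 0.5), 3 * r$std_se)
  # per-indicator variance decomposition: communality + residual = 1
  for (v in c("x1", "x2", "y3")) {
    lam <- ss[ss$op == "=~" & ss$rhs == v, "std"]
    th <- ss[ss$op == "~~" & ss$lhs == v & ss$rhs == v, "std"]
    expect_equal(lam^2 + th, 1, tolerance = 1e-6)
  }
  # orthonormal toy model: standardized equals unstandardized
  spec1 <- sem_model("
    F =~ NA*x1 + x2 + x3
    F ~~ 1*F
  ")
  d1 <- gen_one_factor(800, seed = 38)
  d1 <- rescale_columns(d1, target_mean = 0, target_sd = 1)
  fit1 <- sem_fit(spec1, d1, se = FALSE)
  ss1 <- standardized_solution(fit1, se = FALSE)
  lam <- ss1[ss1$op == "=~", ]
  imp_sd <- sqrt(diag(implied_moments(fit1$ram, fit1$theta)$cov))
  expect_equal(lam$std, lam$estimate / imp_sd[lam$rhs], ignore_attr = TRUE)
})

test_that("non-convergence is reported, never silent", {
  d <- gen_one_factor(80, seed = 39)
  fit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d, se = FALSE,
                 baseline = FALSE, control = list(maxit = 1, restarts = 0,
                                                  newton_steps = 0))
  expect_false(fit$converged)
  expect_type(fit$loglik, "double")
})
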