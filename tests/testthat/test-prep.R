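# Deterministic preparation operators: MTR arithmetic, ICV adjustment,
# robust outlier screening, rescaling, selectivity, exclusion accounting.

test_that("magnetization transfer ratio follows (noMT - MT)/noMT", {
  expect_equal(compute_mtr(2, 1), 0.5)
  expect_equal(compute_mtr(c(1, 3, -2), c(1, 3, -2)), c(0, 0, 0))
  expect_equal(compute_mtr(1.0, 0.64419), 0.35581)
  expect_equal(compute_mtr(c(2, NA), c(1, 1)), c(0.5, NA))
  expect_error(compute_mtr(c(1, 0), c(0.5, 0.2)), "zero")
})

test_that("ICV adjustment removes the least-squares head-size slope", {
  # hand OLS: reference {(1,1),(2,2),(3,3)} has b = 1, mean ICV 2
  expect_equal(adjust_for_icv(2, 3, ref_volume = 1:3, ref_icv = 1:3), 1)
  # zero slope leaves volumes untouched
  set.seed(4)
  icv <- rnorm(40)
  vol <- rep(2, 40)
  expect_equal(adjust_for_icv(vol, icv), vol)
  # applied to the reference sample itself, adjusted values are exactly
  # uncorrelated with ICV
  set.seed(5)
  icv <- rnorm(60, 1500, 120)
  vol <- 0.3 + 0.002 * icv + rnorm(60, 0, 0.05)
  adj <- adjust_for_icv(vol, icv)
  expect_lt(abs(cor(adj, icv)), 1e-10)
  expect_error(adjust_for_icv(1:5, rep(2, 5)), "variance")
  expect_error(adjust_for_icv(1, 1, ref_volume = 1:2, ref_icv = 1:2), "3 complete")
})

test_that("robust outlier screen flags gross outliers and stays quiet on nulls", {
  set.seed(11)
  x <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  rep_null <- detect_multivariate_outliers(x, p_cutoff = 1e-4, seed = 1)
  expect_lte(length(rep_null$flagged), 1)
  expect_equal(rep_null$n_screened, 500)
  expect_equal(rep_null$cutoff, qchisq(1 - 1e-4, df = 4))
  # one row at 10 SD on every column must be flagged, by either estimator
  x_out <- x
  x_out[250, ] <- 10
  for (m in c("mve", "mcd")) {
    rep_out <- detect_multivariate_outliers(x_out, p_cutoff = 1e-4,
                                            method = m, seed = 1)
    expect_true(250 %in% rep_out$flagged)
    expect_true(all(rep_out$distance[as.character(rep_out$flagged)] >
                      rep_out$cutoff))
  }
  # complete cases only: rows with missing cells are never flagged
  x_na <- x_out
  x_na[250, 2] <- NA
  rep_na <- detect_multivariate_outliers(x_na, p_cutoff = 1e-4, seed = 1)
  expect_false(250 %in% rep_na$flagged)
  expect_equal(rep_na$n_screened, 499)
  expect_error(detect_multivariate_outliers(x[1:3, ]), "complete cases")
})

test_that("outlier flag rate under the null is near the nominal cutoff", {
  # with p_cutoff = 0.01 and n = 300, expected flags ~ 3 per replicate;
  # averaged over replicates the rate must straddle the nominal level
  set.seed(21)
  rates <- replicate(30, {
    x <- matrix(rnorm(300 * 3), 300, 3)
    r <- detect_multivariate_outliers(as.data.frame(x), p_cutoff = 0.01,
                                      method = "mcd", seed = 3)
    length(r$flagged) / r$n_screened
  })
  # robust distances overshoot slightly in small samples; generous band
  expect_gt(mean(rates), 0.002)
  expect_lt(mean(rates), 0.05)
})

test_that("rescaling hits the target moments and preserves correlations", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  r <- rescale_columns(d)
  expect_equal(mean(r$a), 5)
  expect_equal(sd(r$a), 2)
  expect_equal(sd(r$b), 2)
  # idempotent on its own output
  expect_equal(rescale_columns(r), r)
  # missing cells stay missing, observed moments still exact
  d2 <- data.frame(a = c(1, 2, 3, NA, 4))
  r2 <- rescale_columns(d2)
  expect_true(is.na(r2$a[4]))
  expect_equal(mean(r2$a, na.rm = TRUE), 5)
  expect_equal(sd(r2$a, na.rm = TRUE), 2)
  # affine invariance of the correlation matrix
  set.seed(2)
  d3 <- as.data.frame(matrix(rnorm(200 * 4), 200, 4) %*%
                        diag(c(1, 10, 100, 0.001)))
  expect_equal(cor(rescale_columns(d3)), cor(d3), tolerance = 1e-12)
  expect_error(rescale_columns(data.frame(a = rep(1, 5))), "zero variance")
})

test_that("selectivity reproduces the published arithmetic", {
  # age row: (70.60 - 70.08) / 3.84; education row: (14.16 - 14.08) / 2.89
  expect_equal((70.60 - 70.08) / 3.84, 0.1354, tolerance = 1e-3)
  d <- data.frame(age = c(10, 20, 30, 40), edu = c(1, 2, 3, 4))
  tab <- selectivity_table(d, sub = c(1, 2))
  expect_equal(tab$selectivity[tab$variable == "age"],
               (mean(d$age) - 15) / sd(d$age))
  # identical subsample and total sample gives zero selectivity throughout
  tab0 <- selectivity_table(d, sub = 1:4)
  expect_equal(tab0$selectivity, c(0, 0))
  expect_error(selectivity_table(d, sub = integer()), "empty")
})

test_that("selectivity table reports moment-based skewness and plain kurtosis", {
  set.seed(8)
  x <- rnorm(20000)
  tab <- selectivity_table(data.frame(x = x), sub = 1:100)
  expect_equal(tab$skew_total, mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  # plain (non-excess) kurtosis of a normal sample is near 3
  expect_equal(tab$kurt_total, 3, tolerance = 0.15)
})

test_that("exclusion accounting reproduces the study's sample sizes", {
  expect_identical(exclusion_accounting(1532, 9, 1), 1522L)
  expect_identical(exclusion_accounting(342, 2, 7), 333L)
  expect_identical(exclusion_accounting(100, 0, 0), 100L)
  expect_error(exclusion_accounting(5, 4, 3), "exceed")
  expect_error(exclusion_accounting(5, -1, 0), "nonnegative")
})
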