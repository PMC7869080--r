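# Synthetic-data generator: default configuration, closed-form moments
# against a brute-force sampling oracle, missingness design, determinism,
# and serialization.

test_that("default configuration encodes the study design", {
  cfg <- default_base2_config()
  expect_identical(cfg$n_total, 1522L)
  expect_identical(cfg$n_mr, 333L)
  expect_equal(cfg$latent_cor["HC", "PHG"], 0.84)
  expect_equal(cfg$latent_cor["VBM", "MD"], -0.53)
  expect_equal(cfg$latent_cor["MT", "MD"], -0.77)
  expect_equal(1 - cfg$n_mr / cfg$n_total, 0.7812, tolerance = 1e-4)
  expect_equal(unname(cfg$obs_prob$vbm * cfg$n_mr), 330)
  expect_equal(unname(cfg$obs_prob$mt * cfg$n_mr), 197)
  expect_equal(unname(cfg$obs_prob$md * cfg$n_mr), 274)
  # standardized trait loadings on the analysis scale stay in the plausible
  # published range (0.27 - 0.86) and MD loads negatively
  lam <- cfg$lambda
  for (ind in rownames(lam)[1:15]) {
    tr_col <- setdiff(names(which(lam[ind, ] != 0)), c("VBM", "MT", "MD"))
    std <- lam[ind, tr_col] * cfg$latent_sd[[tr_col]] / 2
    expect_gt(abs(std), 0.27)
    expect_lt(abs(std), 0.86)
    if (grepl("^md_", ind)) expect_lt(std, 0)
  }
})

test_that("configuration invariants are enforced", {
  cfg <- default_base2_config()
  bad <- cfg; bad$n_mr <- 2000L
  expect_error(validate_sim_config(bad), "n_mr")
  bad <- cfg; bad$obs_prob$mt <- 1.4
  expect_error(validate_sim_config(bad), "\\[0, 1\\]")
  bad <- cfg; bad$latent_cor["HC", "PHG"] <- bad$latent_cor["PHG", "HC"] <- 1.2
  expect_error(validate_sim_config(bad), "positive definite")
  # covariate effects too large for the requested total correlation
  bad <- cfg; bad$beta_std[, "age"] <- 0.99
  expect_error(validate_sim_config(bad), "covariate effects")
})

test_that("closed-form moments have the factor-analytic structure", {
  cfg <- default_base2_config()
  pm <- population_moments(cfg)
  # indicator variances equal 4 by construction (analysis scale, SD 2)
  expect_equal(unname(diag(pm$cov)[cfg$indicators]),
               rep(4, 19), tolerance = 1e-12)
  expect_equal(unname(pm$mean[cfg$indicators]), rep(5, 19))
  expect_equal(unname(pm$mean["age"]), 70.60)
  # zero residual variances make the indicator block low-rank
  cfg2 <- cfg
  cfg2$resid_var[] <- 1e-12
  cfg2$resid_cov$value <- 0
  pm2 <- population_moments(cfg2)
  ev <- eigen(pm2$cov[cfg$indicators, cfg$indicators], symmetric = TRUE,
              only.values = TRUE)$values
  expect_lte(sum(ev > 1e-6), length(cfg$latents))
})

test_that("generated samples converge to the closed-form moments", {
  cfg <- default_base2_config()
  pm <- population_moments(cfg)
  n <- 200000
  d <- generate_complete(cfg, n = n, seed = 42)
  X <- as.matrix(d[, names(pm$mean)])
  emp <- cov(X) * (n - 1) / n
  # elementwise Monte-Carlo standard error of a covariance under normality
  v <- diag(pm$cov)
  mc_se <- sqrt((outer(v, v) + pm$cov^2) / n)
  expect_true(all(abs(emp - pm$cov) <= 3.5 * mc_se))
  mean_se <- sqrt(v / n)
  expect_true(all(abs(colMeans(X) - pm$mean) <= 4 * mean_se))
})

test_that("zero covariate effects break the age-indicator association", {
  cfg <- default_base2_config()
  cfg$beta_std[] <- 0
  cfg$sex_effect[] <- 0
  d <- generate_complete(cfg, n = 20000, seed = 3)
  r <- cor(d$age, d[, cfg$indicators])
  expect_true(all(abs(r) < 4 / sqrt(20000)))
})

test_that("generation is deterministic and CSV round-trips byte-identically", {
  cfg <- default_base2_config()
  cfg$n_mr <- 60L
  d1 <- generate_complete(cfg, n = 200, seed = 9)
  d2 <- generate_complete(cfg, n = 200, seed = 9)
  expect_identical(d1, d2)
  m1 <- apply_missingness(d1, cfg, seed = 9)
  m2 <- apply_missingness(d2, cfg, seed = 9)
  expect_identical(m1[, names(m1)], m2[, names(m2)])
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(m1, f1); write_dataset(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_dataset(f1)
  expect_equal(rt$vbm_hc, m1$vbm_hc)
  unlink(c(f1, f2))
})

test_that("missingness reproduces the observed block counts", {
  cfg <- default_base2_config()
  d <- apply_missingness(generate_complete(cfg, seed = 13), cfg, seed = 13)
  n_mr <- length(attr(d, "mr_rows"))
  expect_identical(n_mr, 333L)
  counts <- c(vbm = sum(!is.na(d$vbm_hc)), mt = sum(!is.na(d$mt_hc)),
              md = sum(!is.na(d$md_hc)))
  # binomial 99% intervals around the design counts
  for (bl in names(counts)) {
    p <- cfg$obs_prob[[bl]]
    lo <- qbinom(0.005, 333, p); hi <- qbinom(0.995, 333, p)
    expect_gte(counts[[bl]], lo)
    expect_lte(counts[[bl]], hi)
  }
  # memory scores observed for roughly 1500 of 1522
  expect_gte(sum(!is.na(d$vlmt)), qbinom(0.005, 1522, 1497 / 1522))
  # masking is block-wise: the 5 ROI columns of one modality share a mask
  vbm_cols <- paste0("vbm_", c("hc", "phg", "pre", "mofc", "dlpfc"))
  masks <- is.na(d[, vbm_cols])
  expect_true(all(apply(masks, 1, function(r) all(r) || !any(r))))
  # sex selectivity of the MR subsample matches the design value
  expect_equal(mean(d$sex[attr(d, "mr_rows")]), 0.3844, tolerance = 0.01)
})

test_that("all-observed probabilities leave the dataset unchanged", {
  cfg <- default_base2_config()
  cfg$obs_prob <- lapply(cfg$obs_prob, function(p) { p[] <- 1; p })
  cfg$n_mr <- 300L
  d <- generate_complete(cfg, n = 300, seed = 2)
  m <- apply_missingness(d, cfg, seed = 2)
  expect_equal(m[, names(d)], d, ignore_attr = TRUE)
})

test_that("raw-scale generation matches the published descriptive scales", {
  cfg <- default_base2_config()
  cfg$scale <- "raw"
  d <- generate_complete(cfg, n = 50000, seed = 7)
  expect_equal(mean(d$vbm_hc), 0.5218, tolerance = 0.002)
  expect_equal(sd(d$mt_hc), 31.15, tolerance = 0.5)
  pm <- population_moments(cfg)
  expect_equal(unname(pm$mean["md_hc"]), 0.0014)
  # rescaling recovers the analysis scale
  r <- rescale_columns(d, cfg$indicators)
  expect_equal(mean(r$vlmt), 5)
  expect_equal(sd(r$vlmt), 2)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- default_base2_config()
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$lambda, cfg$lambda)
  expect_equal(cfg2$latent_cor, cfg$latent_cor)
  expect_equal(cfg2$obs_prob$memory, cfg$obs_prob$memory)
  expect_identical(cfg2$n_total, cfg$n_total)
  pm1 <- population_moments(cfg); pm2 <- population_moments(cfg2)
  expect_equal(pm2$cov, pm1$cov, tolerance = 1e-12)
  unlink(f)
})
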