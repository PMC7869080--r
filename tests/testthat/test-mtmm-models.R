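# Study model builders: degrees-of-freedom skeleton, structural-layer
# equivalence, explained variance, covariate adjustment, invariance ladder.

test_that("builder degrees of freedom match the hand counts", {
  expect_identical(model_df(roi_cfa_spec("HC")), 0L)
  expect_identical(model_df(roi_cfa_spec("PHG")), 0L)
  # merged prefrontal factor: 21 moments - (5 loadings + 1 variance +
  # 6 residuals) = 9
  expect_identical(model_df(roi_cfa_spec("PFC")), 9L)
  expect_identical(model_df(mtmm_measurement_spec()), 64L)
  expect_identical(n_free_parameters(mtmm_measurement_spec()), 56L)
  expect_identical(model_df(mtmm_measurement_spec(fix_md_mofc_residual = TRUE)),
                   65L)
  expect_identical(model_df(add_age(mtmm_measurement_spec(TRUE))), 73L)
  expect_identical(model_df(correlational_spec()), 120L)
  expect_identical(model_df(correlational_spec(zero_em_method_covs = TRUE)),
                   123L)
  expect_identical(model_df(regression_spec()), 123L)
  # the restricted correlational model differs by exactly the 3 fixed
  # memory-method covariances
  expect_identical(model_df(correlational_spec(TRUE)) -
                     model_df(correlational_spec(FALSE)), 3L)
})

test_that("measurement structure follows the design", {
  spec <- mtmm_measurement_spec()
  pt <- spec$partable
  # trait reference indicators are the VBM measures, fixed to 1
  for (roi in c("HC", "PHG", "PRE")) {
    ref <- pt[pt$op == "=~" & pt$lhs == roi & !pt$free, ]
    expect_identical(ref$rhs, paste0("vbm_", tolower(roi)))
    expect_equal(ref$value, 1)
  }
  # method reference indicators are the precuneus measures
  for (m in c("VBM", "MT", "MD")) {
    ref <- pt[pt$op == "=~" & pt$lhs == m & !pt$free, ]
    expect_identical(ref$rhs, paste0(tolower(m), "_pre"))
  }
  # trait-method orthogonality is fixed, methods covary freely
  orth <- pt[pt$op == "~~" & pt$lhs %in% c("HC", "PHG", "PRE", "PFC", "MD", "MT", "VBM") &
               pt$rhs %in% c("MD", "MT", "VBM") & pt$lhs != pt$rhs, ]
  trait_rows <- orth[orth$lhs %in% c("HC", "PHG", "PRE", "PFC") |
                       orth$rhs %in% c("HC", "PHG", "PRE", "PFC"), ]
  expect_true(all(!trait_rows$free & trait_rows$value == 0))
  # PFC has six indicators, two per modality
  expect_identical(sum(pt$op == "=~" & pt$lhs == "PFC"), 6L)
  # unmerged variant exposes the separate frontal factors
  spec5 <- mtmm_measurement_spec(merge_frontal = FALSE)
  expect_true(all(c("MOFC", "DLPFC") %in% spec5$latents))
})

test_that("correlational and regression layers are likelihood-equivalent", {
  cfg <- default_base2_config()
  d <- generate_complete(cfg, 1200, seed = 41)
  fit_c <- sem_fit(correlational_spec(TRUE), d, se = FALSE, baseline = FALSE)
  fit_r <- sem_fit(regression_spec(), d, se = FALSE, baseline = FALSE)
  expect_identical(fit_c$df, fit_r$df)
  expect_equal(fit_c$loglik, fit_r$loglik, tolerance = 1e-6)
})

test_that("explained variance in the latent outcome follows the MIMIC formula", {
  # single latent predictor with standardized effect 0.5 explains 25%
  set.seed(42)
  n <- 5000
  f <- rnorm(n)
  em <- 0.5 * f + rnorm(n, 0, sqrt(0.75))
  d <- data.frame(x1 = f + rnorm(n, 0, 0.7), x2 = 0.9 * f + rnorm(n, 0, 0.7),
                  x3 = 0.8 * f + rnorm(n, 0, 0.7),
                  m1 = em + rnorm(n, 0, 0.7), m2 = 0.9 * em + rnorm(n, 0, 0.7),
                  m3 = 0.8 * em + rnorm(n, 0, 0.7))
  spec <- sem_model("
    F =~ x1 + x2 + x3
    EM =~ m1 + m2 + m3
    EM ~ F
  ")
  fit <- sem_fit(spec, d, se = FALSE)
  expect_equal(r_squared(fit, "EM"), 0.25, tolerance = 0.035)
  # all regression weights zero: R-squared is zero
  spec0 <- fix_parameter(spec, "EM~F", 0)
  fit0 <- sem_fit(spec0, d, se = FALSE, baseline = FALSE)
  expect_equal(r_squared(fit0, "EM"), 0, tolerance = 1e-8)
  expect_error(r_squared(fit, "nope"), "unknown variable")
})

test_that("age covariances are recovered in the age-augmented model", {
  cfg <- default_base2_config()
  d <- generate_complete(cfg, 5000, seed = 43)
  # the correctly specified variant (no residual fixed to zero) is the one
  # whose parameters have generating analogues
  fit <- sem_fit(add_age(mtmm_measurement_spec(FALSE)), d)
  expect_true(fit$converged)
  ss <- standardized_solution(fit)
  r_hc <- ss[ss$op == "~~" & ss$lhs == "HC" & ss$rhs == "age", ]
  if (nrow(r_hc) == 0)
    r_hc <- ss[ss$op == "~~" & ss$lhs == "age" & ss$rhs == "HC", ]
  # generating standardized age effect on hippocampal integrity is -0.28
  expect_lt(abs(r_hc$std - (-0.28)), 3 * r_hc$std_se + 0.02)
})

test_that("covariate adjustment attenuates age-induced associations", {
  # age drives both memory and the trait factors; no direct trait-memory
  # link beyond it: adjusted covariances must shrink toward zero
  cfg <- default_base2_config()
  b_age <- cfg$beta_std[, "age"]
  for (roi in c("PFC", "HC", "PHG", "PRE"))
    cfg$latent_cor["EM", roi] <- cfg$latent_cor[roi, "EM"] <-
      b_age[["EM"]] * b_age[[roi]]
  cfg$beta_std[, "education"] <- 0
  cfg$sex_effect[] <- 0
  validate_sim_config(cfg)
  d <- generate_complete(cfg, 2000, seed = 44)
  un <- sem_fit(correlational_spec(TRUE), d, se = FALSE, baseline = FALSE)
  ad <- sem_fit(covariate_adjusted_spec("age"), d, se = FALSE,
                baseline = FALSE)
  ss_un <- standardized_solution(un, se = FALSE)
  ss_ad <- standardized_solution(ad, se = FALSE)
  pick <- function(ss, roi) ss[ss$op == "~~" &
                                 ((ss$lhs == "EM" & ss$rhs == roi) |
                                    (ss$lhs == roi & ss$rhs == "EM")), "std"]
  un_r <- vapply(c("HC", "PHG", "PFC"), function(r) pick(ss_un, r), numeric(1))
  ad_r <- vapply(c("HC", "PHG", "PFC"), function(r) pick(ss_ad, r), numeric(1))
  expect_true(all(abs(ad_r) < abs(un_r)))
  expect_gt(mean(un_r), 0.03)   # induced association is visible unadjusted
})

test_that("irrelevant covariates leave the associations unchanged", {
  cfg <- default_base2_config()
  cfg$beta_std[] <- 0
  cfg$sex_effect[] <- 0
  d <- generate_complete(cfg, 2000, seed = 45)
  un <- sem_fit(correlational_spec(TRUE), d, se = FALSE, baseline = FALSE)
  ad <- sem_fit(covariate_adjusted_spec("age"), d, se = FALSE,
                baseline = FALSE)
  r_un <- standardized_solution(un, se = FALSE)
  r_ad <- standardized_solution(ad, se = FALSE)
  pick <- function(ss) ss[ss$op == "~~" & (ss$lhs == "EM" & ss$rhs == "HC") |
                            (ss$lhs == "HC" & ss$rhs == "EM"), "std"][1]
  expect_lt(abs(pick(r_ad) - pick(r_un)), 0.08)
})

test_that("the invariance ladder orders constraints and counts df", {
  cfg <- default_base2_config()
  d <- generate_complete(cfg, 1000, seed = 46)
  d$grp <- median_split(d$age)
  lad <- invariance_ladder(roi_cfa_spec("HC"), d, "grp")
  expect_named(lad$fits, c("configural", "metric", "scalar"))
  # metric step equates the 2 free loadings across 2 groups
  expect_identical(lad$tests$metric_vs_configural$delta_df, 2L)
  # scalar step equates 3 intercepts and frees 1 latent mean
  expect_identical(lad$tests$scalar_vs_metric$delta_df, 2L)
  # both groups drawn from one population: no rejection expected here
  expect_gt(lad$tests$metric_vs_configural$p_value, 0.001)
  expect_error(invariance_ladder(roi_cfa_spec("HC"), d[1:40, ], "grp"),
               "30 rows")
})

test_that("median split assigns ties to the lower group", {
  x <- c(1, 2, 3, 3, 4, 5)
  g <- median_split(x)
  expect_identical(as.character(g[x == 3]), c("low", "low"))
  expect_true(is.na(median_split(c(1, NA, 3))[2]))
})

test_that("generating parameters map onto the measurement labels", {
  cfg <- default_base2_config()
  tr <- generating_parameters(cfg)
  ram <- compile_ram(mtmm_measurement_spec())
  expect_setequal(names(tr), ram$labels)
  expect_equal(unname(tr["HC~~PHG"]),
               0.84 * cfg$latent_sd[["HC"]] * cfg$latent_sd[["PHG"]])
})
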