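# Synthetic-data generator emulating a large aging cohort (n = 1522) in which
# only a subsample (n = 333) underwent multimodal MR imaging, with
# modality-block missingness inside the MR subsample. The generating model is
# a linear latent-variable model: four regional gray-matter integrity factors
# (PFC, HC, PHG, PRE), three orthogonal-to-trait method factors (VBM, MT, MD),
# one episodic-memory factor (EM), covariate effects of age, education, and
# sex on the factors, and indicator-level residuals.

.SIM_INDICATORS <- c(
  "vbm_hc", "vbm_phg", "vbm_pre", "vbm_mofc", "vbm_dlpfc",
  "mt_hc",  "mt_phg",  "mt_pre",  "mt_mofc",  "mt_dlpfc",
  "md_hc",  "md_phg",  "md_pre",  "md_mofc",  "md_dlpfc",
  "vlmt", "fp", "se", "ol")
.SIM_LATENTS <- c("PFC", "HC", "PHG", "PRE", "VBM", "MT", "MD", "EM")
.SIM_COVARIATES <- c("age", "education", "sex")
.MR_COLS <- .SIM_INDICATORS[1:15]
.MEM_COLS <- .SIM_INDICATORS[16:19]

#' Default synthetic-study configuration
#'
#' Returns the generating configuration that emulates the cohort design this
#' package models: 1522 participants with memory scores and covariates, 333
#' of whom have MR data, and within those, voxel-based morphometry observed
#' for 330, magnetization transfer for 197, and mean diffusivity for 274.
#' Factor correlations, covariate effects, and the female share of the MR
#' subsample default to the published study-level estimates (e.g., the
#' hippocampus--parahippocampal integrity correlation of 0.84); loadings and
#' residual variances are configuration values chosen so that standardized
#' trait loadings fall in the reported 0.27--0.86 range on the analysis scale
#' (indicator mean 5, SD 2).
#'
#' @return An object of class `sim_config` (a named list). Key fields:
#'   `n_total`, `n_mr`, `lambda` (indicator-by-factor loading matrix with
#'   reference loadings fixed at 1: the VBM indicator for each trait factor,
#'   the precuneus indicator for each method factor, the verbal-learning score
#'   for EM), `latent_cor` (total factor correlation matrix), `latent_sd`,
#'   `resid_var`, `resid_cov`, `beta_std` (standardized age/education effects
#'   on the factors), `sex_effect` (female advantage in latent units),
#'   `obs_prob` (block observation probabilities), `sex_p`, `sex_p_mr`,
#'   `scale` ("rescaled" or "raw").
#' @export
default_base2_config <- function() {
  K <- length(.SIM_LATENTS); P <- length(.SIM_INDICATORS)
  lambda <- matrix(0, P, K, dimnames = list(.SIM_INDICATORS, .SIM_LATENTS))
  roi_of <- c(vbm_hc = "HC", vbm_phg = "PHG", vbm_pre = "PRE",
              vbm_mofc = "PFC", vbm_dlpfc = "PFC",
              mt_hc = "HC", mt_phg = "PHG", mt_pre = "PRE",
              mt_mofc = "PFC", mt_dlpfc = "PFC",
              md_hc = "HC", md_phg = "PHG", md_pre = "PRE",
              md_mofc = "PFC", md_dlpfc = "PFC")
  # trait loadings: VBM indicators are the reference (1); MT positive, MD
  # negative (higher diffusivity = less dense tissue); values vary across
  # regions, as the reported standardized loadings do -- a degenerate config
  # with loadings constant across regions would make trait and method
  # covariance locally indistinguishable
  # the medio-orbitofrontal MD indicator is given a near-zero residual
  # (loadings chosen so trait + method variance nearly exhaust it): its
  # residual-variance estimate then hovers at zero in fitted samples, the
  # Heywood case that motivates the fix_md_mofc_residual constraint
  trait_load <- c(vbm_hc = 1, vbm_phg = 1, vbm_pre = 1, vbm_mofc = 1,
                  vbm_dlpfc = 0.9,
                  mt_hc = 1.05, mt_phg = 0.85, mt_pre = 0.75,
                  mt_mofc = 0.9, mt_dlpfc = 1.0,
                  md_hc = -0.95, md_phg = -0.8, md_pre = -0.7,
                  md_mofc = -1.32, md_dlpfc = -0.9)
  # method loadings: precuneus indicators are the reference (1)
  method_load <- c(vbm_hc = 1.2, vbm_phg = 1.1, vbm_pre = 1,
                   vbm_mofc = 0.9, vbm_dlpfc = 0.8,
                   mt_hc = 1.25, mt_phg = 0.9, mt_pre = 1,
                   mt_mofc = 1.1, mt_dlpfc = 0.85,
                   md_hc = 1.15, md_phg = 1.05, md_pre = 1,
                   md_mofc = 1.453, md_dlpfc = 0.8)
  for (ind in .MR_COLS) {
    lambda[ind, roi_of[[ind]]] <- trait_load[[ind]]
    lambda[ind, toupper(sub("_.*", "", ind))] <- method_load[[ind]]
  }
  lambda["vlmt", "EM"] <- 1
  lambda["fp", "EM"] <- 0.92
  lambda["se", "EM"] <- 1.04
  lambda["ol", "EM"] <- 1.12

  latent_cor <- diag(K)
  dimnames(latent_cor) <- list(.SIM_LATENTS, .SIM_LATENTS)
  set_cor <- function(a, b, v) {
    latent_cor[a, b] <<- v; latent_cor[b, a] <<- v
  }
  # trait block
  set_cor("PFC", "HC", 0.59); set_cor("PFC", "PHG", 0.68)
  set_cor("PFC", "PRE", 0.18); set_cor("HC", "PHG", 0.84)
  set_cor("HC", "PRE", 0.13); set_cor("PHG", "PRE", 0.37)
  # method block
  set_cor("VBM", "MD", -0.53); set_cor("VBM", "MT", 0.25)
  set_cor("MT", "MD", -0.77)
  # memory block (trait-EM first-order associations; EM-method zero)
  set_cor("EM", "PFC", 0.24); set_cor("EM", "HC", 0.33)
  set_cor("EM", "PHG", 0.27); set_cor("EM", "PRE", 0.16)

  latent_sd <- c(PFC = 1.3, HC = 1.3, PHG = 1.3, PRE = 1.3,
                 VBM = 0.7, MT = 0.7, MD = 0.7, EM = 1.0)

  # indicator variance target 4 on the analysis scale; trait and method parts
  # are orthogonal so the residual is what remains
  resid_var <- numeric(P); names(resid_var) <- .SIM_INDICATORS
  for (ind in .MR_COLS) {
    l_roi <- lambda[ind, roi_of[[ind]]]
    l_m <- lambda[ind, toupper(sub("_.*", "", ind))]
    resid_var[ind] <- 4 - l_roi^2 * latent_sd[[roi_of[[ind]]]]^2 -
      l_m^2 * latent_sd[[toupper(sub("_.*", "", ind))]]^2
  }
  for (ind in .MEM_COLS) resid_var[ind] <- 4 - lambda[ind, "EM"]^2
  resid_cov <- data.frame(
    a = c("vbm_mofc", "vbm_hc"), b = c("vbm_dlpfc", "vbm_phg"),
    value = c(0.4, 0.4), stringsAsFactors = FALSE)

  beta_std <- matrix(0, K, 2, dimnames = list(.SIM_LATENTS, c("age", "education")))
  beta_std[, "age"] <- c(-0.28, -0.28, -0.17, -0.06, -0.16, -0.29, 0.40, -0.22)
  beta_std[, "education"] <- c(0.06, 0.02, -0.02, -0.12, 0, 0, 0, 0.29)
  sex_effect <- c(PFC = 0.32, HC = 0.69, PHG = 0.43, PRE = 0.31,
                  VBM = 0, MT = 0, MD = 0, EM = 0.32)

  cfg <- structure(list(
    n_total = 1522L, n_mr = 333L,
    indicators = .SIM_INDICATORS, latents = .SIM_LATENTS,
    covariates = .SIM_COVARIATES,
    lambda = lambda, latent_cor = latent_cor, latent_sd = latent_sd,
    resid_var = resid_var, resid_cov = resid_cov,
    beta_std = beta_std, sex_effect = sex_effect,
    covariate_mean = c(age = 70.60, education = 14.16),
    covariate_sd = c(age = 3.84, education = 2.89),
    sex_p = 0.5072, sex_p_mr = 0.3844,
    obs_prob = list(
      vbm = 330 / 333, mt = 197 / 333, md = 274 / 333,
      memory = c(vlmt = 1497, fp = 1495, se = 1495, ol = 1505) / 1522,
      age = 1511 / 1522, education = 1339 / 1522),
    scale = "rescaled",
    raw_mean = c(vbm_hc = 0.5218, vbm_phg = 0.4316, vbm_pre = 0.3969,
                 vbm_mofc = 0.4156, vbm_dlpfc = 0.4147,
                 mt_hc = 332.58, mt_phg = 363.62, mt_pre = 335.81,
                 mt_mofc = 354.50, mt_dlpfc = 300.51,
                 md_hc = 0.0014, md_phg = 0.0013, md_pre = 0.0012,
                 md_mofc = 0.0012, md_dlpfc = 0.0012,
                 vlmt = 8.50, fp = 0.27, se = 0.28, ol = 13.26),
    raw_sd = c(vbm_hc = 0.0458, vbm_phg = 0.0317, vbm_pre = 0.0304,
               vbm_mofc = 0.0307, vbm_dlpfc = 0.0297,
               mt_hc = 31.15, mt_phg = 14.92, mt_pre = 18.81,
               mt_mofc = 16.79, mt_dlpfc = 21.40,
               md_hc = 0.000135, md_phg = 0.000111, md_pre = 0.000112,
               md_mofc = 0.000102, md_dlpfc = 0.000081,
               vlmt = 2.68, fp = 0.21, se = 0.14, ol = 4.00)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks dimensional consistency, that all observation probabilities lie in
#' `[0, 1]`, that `n_mr <= n_total`, and that both the total factor
#' correlation matrix and the implied factor-residual covariance (after
#' covariate effects are removed) are positive definite.
#'
#' @param config A `sim_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_mr > config$n_total) stop("n_mr must not exceed n_total")
  if (config$n_total < 1) stop("n_total must be positive")
  pr <- unlist(config$obs_prob)
  if (any(pr < 0 | pr > 1)) stop("observation probabilities must lie in [0, 1]")
  if (any(config$resid_var <= 0))
    stop("residual variances must be positive")
  ev <- eigen(config$latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("latent correlation matrix is not positive definite")
  psi <- .latent_residual_cov(config)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("factor covariance net of covariate effects is not positive definite; ",
         "reduce covariate effects or raise factor correlations")
  invisible(config)
}

# covariance of raw (centered) covariates: age, education in native units,
# sex as 0/1 with success probability sex_p
.covariate_cov <- function(config) {
  p <- config$sex_p
  diag(c(config$covariate_sd[["age"]]^2,
         config$covariate_sd[["education"]]^2,
         p * (1 - p)))
}

# raw-scale covariate -> latent effect matrix (K x 3)
.covariate_beta_raw <- function(config) {
  sdl <- config$latent_sd
  b <- cbind(
    age = config$beta_std[, "age"] * sdl / config$covariate_sd[["age"]],
    education = config$beta_std[, "education"] * sdl / config$covariate_sd[["education"]],
    sex = config$sex_effect)
  rownames(b) <- config$latents
  b
}

# total latent covariance and the residual part net of covariates
.latent_total_cov <- function(config) {
  d <- diag(config$latent_sd)
  ph <- d %*% config$latent_cor %*% d
  dimnames(ph) <- dimnames(config$latent_cor)
  ph
}
.latent_residual_cov <- function(config) {
  b <- .covariate_beta_raw(config)
  psi <- .latent_total_cov(config) - b %*% .covariate_cov(config) %*% t(b)
  (psi + t(psi)) / 2
}

.theta_matrix <- function(config) {
  th <- diag(config$resid_var)
  dimnames(th) <- list(config$indicators, config$indicators)
  if (nrow(config$resid_cov))
    for (i in seq_len(nrow(config$resid_cov))) {
      a <- config$resid_cov$a[i]; b <- config$resid_cov$b[i]
      th[a, b] <- th[b, a] <- config$resid_cov$value[i]
    }
  th
}

#' Exact moments of the generating model
#'
#' Closed-form mean vector and covariance matrix of all observed columns
#' (19 indicators plus age, education, sex) implied by a simulation
#' configuration: factor-analytic composition of loadings, total factor
#' covariance, residual covariance, and covariate paths.
#'
#' @param config A `sim_config`.
#' @return List with `mean` (named vector) and `cov` (named matrix).
#' @export
population_moments <- function(config) {
  validate_sim_config(config)
  lam <- config$lambda
  phi <- .latent_total_cov(config)
  theta <- .theta_matrix(config)
  b <- .covariate_beta_raw(config)
  sc <- .covariate_cov(config)

  sig_ind <- lam %*% phi %*% t(lam) + theta
  sig_ic <- lam %*% b %*% sc          # indicators x covariates
  p_names <- c(config$indicators, config$covariates)
  k <- length(p_names)
  sig <- matrix(0, k, k, dimnames = list(p_names, p_names))
  ii <- config$indicators; cc <- config$covariates
  sig[ii, ii] <- sig_ind
  sig[ii, cc] <- sig_ic
  sig[cc, ii] <- t(sig_ic)
  sig[cc, cc] <- sc
  mu <- c(setNames(rep(5, length(ii)), ii),
          age = config$covariate_mean[["age"]],
          education = config$covariate_mean[["education"]],
          sex = config$sex_p)
  if (identical(config$scale, "raw")) {
    s <- config$raw_sd[ii] / 2
    mu[ii] <- config$raw_mean[ii]
    sig[ii, ] <- sig[ii, ] * s
    sig[, ii] <- sweep(sig[, ii, drop = FALSE], 2, s, `*`)
  }
  list(mean = mu, cov = (sig + t(sig)) / 2)
}

.rmvnorm_chol <- function(n, cov) {
  k <- ncol(cov)
  if (k == 0L) return(matrix(0, n, 0))
  matrix(rnorm(n * k), n, k) %*% chol(cov)
}

#' Generate a complete synthetic dataset
#'
#' Draws `n` rows from the generating model of `config` with no missing
#' cells: covariates first (sex Bernoulli, age and education normal), then
#' latent factors given covariates, then indicators given factors.
#' Deterministic given `seed`.
#'
#' @param config A `sim_config`.
#' @param n Number of rows (default `config$n_total`).
#' @param seed Integer seed.
#' @return A data frame with an `id` column, all indicator columns, and
#'   `age`, `education`, `sex` (female = 1). Column roles are stored in
#'   `attr(, "roles")`.
#' @export
generate_complete <- function(config, n = config$n_total, seed = 1L) {
  validate_sim_config(config)
  stopifnot(n >= 1)
  set.seed(seed)
  sex <- rbinom(n, 1, config$sex_p)
  age_c <- rnorm(n, 0, config$covariate_sd[["age"]])
  edu_c <- rnorm(n, 0, config$covariate_sd[["education"]])
  cov_c <- cbind(age = age_c, education = edu_c, sex = sex - config$sex_p)
  b <- .covariate_beta_raw(config)
  zeta <- .rmvnorm_chol(n, .latent_residual_cov(config))
  eta <- cov_c %*% t(b) + zeta
  eps <- .rmvnorm_chol(n, .theta_matrix(config))
  y <- matrix(5, n, length(config$indicators)) +
    eta %*% t(config$lambda) + eps
  colnames(y) <- config$indicators
  if (identical(config$scale, "raw")) {
    s <- config$raw_sd[config$indicators] / 2
    y <- sweep(sweep(y, 2, rep(5, ncol(y))), 2, s, `*`)
    y <- sweep(y, 2, config$raw_mean[config$indicators], `+`)
  }
  out <- data.frame(id = seq_len(n), y,
                    age = config$covariate_mean[["age"]] + age_c,
                    education = config$covariate_mean[["education"]] + edu_c,
                    sex = sex)
  attr(out, "roles") <- c(id = "id",
                          setNames(rep("indicator", length(config$indicators)),
                                   config$indicators),
                          age = "covariate", education = "covariate",
                          sex = "covariate")
  out
}

#' Impose the study's missingness design on a complete dataset
#'
#' Masks the full MR block (all 15 imaging columns) for all but `n_mr` rows;
#' the retained MR rows are sampled stratified by sex so that the female
#' share of the MR subsample matches `sex_p_mr` (up to rounding) while
#' remaining missing-at-random (missingness depends only on observed sex,
#' never on the masked values). Within MR rows, each modality block (VBM, MT,
#' MD) is kept as a whole with its configured probability; memory scores and
#' covariates are masked cell-wise with their configured probabilities.
#' Deterministic given `seed`.
#'
#' @param data Complete dataset from [generate_complete()].
#' @param config The `sim_config` used to generate it.
#' @param seed Integer seed.
#' @return `data` with `NA` in masked cells; the selected MR row indices are
#'   stored in `attr(, "mr_rows")`.
#' @export
apply_missingness <- function(data, config, seed = 1L) {
  validate_sim_config(config)
  n <- nrow(data)
  if (config$n_mr > n) stop("config$n_mr exceeds the number of rows")
  set.seed(seed + 1L)
  # sex-stratified selection so the MR subsample hits the target female share
  # exactly (up to rounding) while staying missing-at-random: inclusion
  # depends only on observed sex, never on the masked values
  f_rows <- which(data$sex == 1); m_rows <- which(data$sex != 1)
  n_f <- min(round(config$n_mr * config$sex_p_mr), length(f_rows))
  n_m <- min(config$n_mr - n_f, length(m_rows))
  mr_rows <- c(sample(f_rows, n_f), sample(m_rows, n_m))
  short <- config$n_mr - length(mr_rows)
  if (short > 0)  # target share unattainable in this sample; top up at random
    mr_rows <- c(mr_rows, sample(setdiff(seq_len(n), mr_rows), short))
  out <- data
  out[setdiff(seq_len(n), mr_rows), .MR_COLS] <- NA_real_

  block_cols <- list(vbm = .MR_COLS[1:5], mt = .MR_COLS[6:10], md = .MR_COLS[11:15])
  for (bl in names(block_cols)) {
    drop <- mr_rows[runif(length(mr_rows)) > config$obs_prob[[bl]]]
    out[drop, block_cols[[bl]]] <- NA_real_
  }
  for (task in .MEM_COLS) {
    p <- config$obs_prob$memory[[task]]
    out[runif(n) > p, task] <- NA_real_
  }
  out$age[runif(n) > config$obs_prob$age] <- NA_real_
  out$education[runif(n) > config$obs_prob$education] <- NA_real_
  attr(out, "mr_rows") <- sort(mr_rows)
  attr(out, "roles") <- attr(data, "roles")
  out
}

#' Read/write datasets as CSV
#'
#' `write_dataset()` writes a rectangular table with a header row and empty
#' strings for missing cells; `read_dataset()` accepts both empty strings and
#' `"NA"` as missing markers. Round-trips are byte-stable for a fixed dataset.
#'
#' @param data Data frame to write.
#' @param path File path.
#' @return `read_dataset()` returns a data frame.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

#' Serialize a simulation configuration to YAML
#'
#' @param config A `sim_config`.
#' @param path File path ending in `.yaml`/`.yml`.
#' @return `read_sim_config()` returns the reconstructed `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  ser_one <- function(x) {
    if (is.matrix(x))
      list(.matrix = TRUE, rownames = rownames(x), colnames = colnames(x),
           data = apply(x, 1, as.numeric, simplify = FALSE))
    else if (is.numeric(x) && !is.null(names(x)))
      as.list(x)  # yaml map preserves the names
    else x
  }
  ser <- lapply(unclass(config), function(x) {
    if (is.list(x) && !is.data.frame(x)) lapply(x, ser_one) else ser_one(x)
  })
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  out <- yaml::read_yaml(path)
  de_matrix <- function(x) {
    m <- do.call(rbind, lapply(x$data, unlist))
    dimnames(m) <- list(unlist(x$rownames), unlist(x$colnames))
    m
  }
  for (f in c("lambda", "latent_cor", "beta_std"))
    out[[f]] <- de_matrix(out[[f]])
  for (f in c("latent_sd", "resid_var", "sex_effect", "covariate_mean",
              "covariate_sd", "raw_mean", "raw_sd"))
    out[[f]] <- unlist(out[[f]])
  out$n_total <- as.integer(out$n_total); out$n_mr <- as.integer(out$n_mr)
  out$indicators <- as.character(unlist(out$indicators))
  out$latents <- as.character(unlist(out$latents))
  out$covariates <- as.character(unlist(out$covariates))
  out$resid_cov <- as.data.frame(lapply(out$resid_cov, unlist),
                                 stringsAsFactors = FALSE)
  out$obs_prob <- lapply(out$obs_prob,
                         function(p) if (is.list(p)) unlist(p) else p)
  cfg <- structure(out, class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-study configuration\n")
  cat("  n_total:", x$n_total, "  n_mr:", x$n_mr,
      sprintf("(missing-MR fraction %.4f)\n", 1 - x$n_mr / x$n_total))
  cat("  indicators:", length(x$indicators), " latents:",
      paste(x$latents, collapse = ", "), "\n")
  cat("  scale:", x$scale, "\n")
  invisible(x)
}
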