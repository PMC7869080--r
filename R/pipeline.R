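# Configuration-driven pipeline: simulate (or read) data, prepare it, fit the
# model family, and render study-style summary tables plus a JSON manifest.

#' Pipeline run configuration
#'
#' @param sim_config Generating configuration ([default_base2_config()]), or
#'   `NULL` when `data_csv` supplies the input.
#' @param data_csv Optional path to a CSV with the observed columns (missing
#'   cells empty or `NA`); used instead of simulation.
#' @param stages Subset of `c("simulate", "prep", "fit", "report")` in
#'   pipeline order.
#' @param models Model names to fit: subset of `c("roi-cfa", "mtmm",
#'   "mtmm-age", "correlational", "regression", "covariate", "invariance")`.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving simulation and masking.
#' @param thresholds Acceptable-fit thresholds used to flag models:
#'   RMSEA < 0.08, CFI > 0.90, SRMR < 0.08.
#' @param covariates Covariates for the `covariate` model.
#' @return A `run_config` list.
#' @export
run_config <- function(sim_config = default_base2_config(),
                       data_csv = NULL,
                       stages = c("simulate", "prep", "fit", "report"),
                       models = c("mtmm", "correlational"),
                       out_dir = tempfile("mtmm_run_"),
                       seed = 1L,
                       thresholds = c(rmsea = 0.08, cfi = 0.90, srmr = 0.08),
                       covariates = c("age", "education", "sex")) {
  stages <- match.arg(stages, several.ok = TRUE)
  known <- c("roi-cfa", "mtmm", "mtmm-age", "correlational", "regression",
             "covariate", "invariance")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (!is.null(data_csv) && !file.exists(data_csv))
    stop("data_csv does not exist: ", data_csv)
  structure(list(sim_config = sim_config, data_csv = data_csv,
                 stages = stages, models = models, out_dir = out_dir,
                 seed = as.integer(seed), thresholds = thresholds,
                 covariates = covariates),
            class = "run_config")
}

.log_stage <- function(...) message("[mtmmbrain] ", ...)

#' Run the full analysis pipeline
#'
#' Executes, per the configured stage list: simulation of the cohort with its
#' missingness design (or reading a CSV), data preparation (multivariate
#' outlier screening of the memory and imaging blocks, exclusion accounting,
#' selectivity table), model fitting, and table rendering. All numeric
#' output is written as CSV; a JSON manifest records the seed, exclusion
#' accounting, sample sizes, and fit summaries. Reruns with the same seed
#' produce byte-identical numeric tables.
#'
#' @param config A [run_config()].
#' @param ... Passed to [sem_fit()] (e.g. `se = FALSE`).
#' @return Invisibly, a list with `data`, `fits`, `tables`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), ...) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = config$stages,
                   models = config$models)
  cfg <- config$sim_config

  # --- simulate ------------------------------------------------------------
  if (!is.null(config$data_csv)) {
    data <- read_dataset(config$data_csv)
    .log_stage("read ", nrow(data), " rows from ", config$data_csv)
  } else if ("simulate" %in% config$stages) {
    complete <- generate_complete(cfg, seed = config$seed)
    data <- apply_missingness(complete, cfg, seed = config$seed)
    write_dataset(data, file.path(config$out_dir, "synthetic_data.csv"))
    .log_stage("simulated ", nrow(data), " rows (",
               length(attr(data, "mr_rows")), " with MR block)")
  } else stop("no input: enable the simulate stage or supply data_csv")
  mr_rows <- attr(data, "mr_rows")
  if (is.null(mr_rows))
    mr_rows <- which(rowSums(!is.na(data[, .MR_COLS, drop = FALSE])) > 0)

  # --- prep ----------------------------------------------------------------
  tables <- list()
  if ("prep" %in% config$stages) {
    mem_screen <- detect_multivariate_outliers(
      data, columns = .MEM_COLS, p_cutoff = 1e-4, seed = config$seed)
    mr_screen <- detect_multivariate_outliers(
      data, columns = .MR_COLS, p_cutoff = 1e-4, seed = config$seed)
    drop_rows <- union(mem_screen$flagged, mr_screen$flagged)
    n0 <- nrow(data); n0_mr <- length(mr_rows)
    if (length(drop_rows)) data <- data[-drop_rows, , drop = FALSE]
    mr_rows <- which(rowSums(!is.na(data[, .MR_COLS, drop = FALSE])) > 0)
    manifest$exclusions <- list(
      initial_n = n0,
      memory_outliers = length(mem_screen$flagged),
      mr_outliers = length(mr_screen$flagged),
      effective_n = exclusion_accounting(n0, 0, length(drop_rows)),
      effective_n_mr = length(mr_rows))
    .log_stage("outlier screen: ", length(mem_screen$flagged),
               " memory + ", length(mr_screen$flagged),
               " MR outliers; effective n = ", nrow(data))
    if (!is.null(cfg) && identical(cfg$scale, "raw")) {
      data <- rescale_columns(data, .SIM_INDICATORS)
      .log_stage("rescaled indicators to mean 5, SD 2")
    }
    in_mr <- seq_len(nrow(data)) %in% mr_rows
    tables$descriptives <- selectivity_table(
      data, in_mr, variables = c("age", "education", "sex", .MEM_COLS))
    tables$descriptives_mr <- selectivity_table(
      data[in_mr, , drop = FALSE], rep(TRUE, sum(in_mr)),
      variables = .MR_COLS)[, c("variable", "n_total", "mean_total",
                                "sd_total", "skew_total", "kurt_total")]
    names(tables$descriptives_mr) <- c("variable", "n", "mean", "sd",
                                       "skewness", "kurtosis")
    num_cols <- c(.SIM_INDICATORS, "age", "education", "sex")
    tables$correlations <- round(cor(data[, num_cols], use = "pairwise.complete.obs"), 4)
  }

  # --- fit -----------------------------------------------------------------
  fits <- list()
  if ("fit" %in% config$stages) {
    # negative residual variances are refit with the variance fixed to zero,
    # the same admissibility policy the study family applies
    fit1 <- function(spec) sem_fit(spec, data, fix_heywood = TRUE, ...)
    for (m in config$models) {
      .log_stage("fitting model: ", m)
      fits[[m]] <- switch(
        m,
        "roi-cfa" = lapply(setNames(nm = c("PFC", "HC", "PHG", "PRE")),
                           function(r) fit1(roi_cfa_spec(r))),
        "mtmm" = fit1(mtmm_measurement_spec()),
        "mtmm-age" = fit1(add_age(mtmm_measurement_spec(TRUE))),
        "correlational" = fit1(correlational_spec(TRUE)),
        "regression" = fit1(regression_spec()),
        "covariate" = fit1(covariate_adjusted_spec(config$covariates)),
        "invariance" = {
          d2 <- data
          d2$age_group <- median_split(d2$age)
          invariance_ladder(correlational_spec(TRUE), d2, "age_group", ...)
        })
    }
  }

  # --- report --------------------------------------------------------------
  if ("report" %in% config$stages) {
    tables <- c(tables, render_tables(fits, thresholds = config$thresholds,
                                      out_dir = config$out_dir))
    for (nm in setdiff(names(tables), "correlations"))
      write.csv(tables[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    if (!is.null(tables$correlations))
      write.csv(tables$correlations,
                file.path(config$out_dir, "correlations.csv"))
    manifest$fits <- lapply(fits, function(f) {
      if (inherits(f, "sem_fit"))
        list(loglik = f$loglik, chi2 = f$chi2, df = f$df, cfi = f$cfi,
             rmsea = f$rmsea, srmr = f$srmr, converged = f$converged,
             n = sum(f$n))
      else NULL
    })
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log_stage("wrote tables and manifest to ", config$out_dir)
  }

  invisible(list(data = data, fits = fits, tables = tables,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Render model-summary tables
#'
#' Produces a fit-index summary (with threshold-violation flags), a
#' factor-correlation table (standardized latent covariances of the MTMM
#' fit, symmetric with unit diagonal), and a covariate-effect table when the
#' corresponding models are present.
#'
#' @param fits Named list of `sem_fit` objects (as built by
#'   [run_pipeline()]).
#' @param thresholds Named vector with `rmsea`, `cfi`, `srmr`.
#' @param out_dir Unused here; kept so callers can pass through.
#' @return Named list of data frames.
#' @export
render_tables <- function(fits, thresholds = c(rmsea = 0.08, cfi = 0.90,
                                               srmr = 0.08),
                          out_dir = NULL) {
  out <- list()
  flat <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "sem_fit")) flat[[nm]] <- f
    else if (is.list(f))
      for (sub in names(f)) if (inherits(f[[sub]], "sem_fit"))
        flat[[paste(nm, sub, sep = ":")]] <- f[[sub]]
  }
  if (length(flat)) {
    out$fit_indices <- do.call(rbind, lapply(names(flat), function(nm) {
      f <- flat[[nm]]
      data.frame(model = nm, n = sum(f$n), chi2 = f$chi2, df = f$df,
                 cfi = f$cfi, rmsea = f$rmsea, srmr = f$srmr,
                 converged = f$converged,
                 acceptable = isTRUE(f$cfi > thresholds[["cfi"]] &&
                                       f$rmsea < thresholds[["rmsea"]] &&
                                       f$srmr < thresholds[["srmr"]]),
                 stringsAsFactors = FALSE)
    }))
  }
  # the full-sample model is better conditioned than the MR-block-only fit
  base_fit <- flat[["correlational"]] %||% flat[["mtmm"]]
  if (!is.null(base_fit)) {
    ss <- standardized_solution(base_fit, se = FALSE)
    lat <- base_fit$ram$latents
    fc <- matrix(NA_real_, length(lat), length(lat), dimnames = list(lat, lat))
    diag(fc) <- 1
    cov_rows <- ss[ss$op == "~~" & ss$lhs %in% lat & ss$rhs %in% lat, ]
    for (r in seq_len(nrow(cov_rows)))
      if (cov_rows$lhs[r] != cov_rows$rhs[r]) {
        fc[cov_rows$lhs[r], cov_rows$rhs[r]] <- cov_rows$std[r]
        fc[cov_rows$rhs[r], cov_rows$lhs[r]] <- cov_rows$std[r]
      }
    out$factor_correlations <- as.data.frame(round(fc, 4))
  }
  if (!is.null(flat[["covariate"]])) {
    ss <- standardized_solution(flat[["covariate"]])
    reg <- ss[ss$op == "~" & ss$lhs %in% flat[["covariate"]]$ram$latents, ]
    out$covariate_effects <- data.frame(
      factor = reg$lhs, covariate = reg$rhs,
      estimate = reg$estimate, std = round(reg$std, 4),
      std_se = round(reg$std_se, 4), stringsAsFactors = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
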