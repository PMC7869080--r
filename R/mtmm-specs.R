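# Declarative builders for the study's model family: per-region CFAs, the
# multitrait-multimethod (MTMM) measurement model with four regional
# integrity factors and three orthogonal method factors, its extension with
# age, the correlational and regression structural layers linking integrity
# to episodic memory, and covariate-adjusted variants.

.ROI_INDICATORS <- list(
  PFC = c("vbm_mofc", "vbm_dlpfc", "mt_mofc", "mt_dlpfc", "md_mofc", "md_dlpfc"),
  MOFC = c("vbm_mofc", "mt_mofc", "md_mofc"),
  DLPFC = c("vbm_dlpfc", "mt_dlpfc", "md_dlpfc"),
  HC = c("vbm_hc", "mt_hc", "md_hc"),
  PHG = c("vbm_phg", "mt_phg", "md_phg"),
  PRE = c("vbm_pre", "mt_pre", "md_pre"))
.EM_INDICATORS <- c("vlmt", "fp", "se", "ol")

.md_starts <- function(spec) {
  pt <- spec$partable
  lab <- pt$label[pt$op == "=~" & pt$free & grepl("^md_", pt$rhs) &
                    pt$lhs != "MD"]
  if (length(lab)) set_start(spec, setNames(rep(-1, length(lab)), lab)) else spec
}

#' Single-region integrity CFA
#'
#' One latent integrity factor per region, measured by the region's VBM, MT,
#' and MD indicators (six indicators for the merged prefrontal factor). The
#' VBM indicator is the reference (loading fixed to 1); MD loadings carry a
#' negative starting hint because higher diffusivity means less dense tissue.
#'
#' @param roi One of `"PFC"`, `"HC"`, `"PHG"`, `"PRE"` (also `"MOFC"`,
#'   `"DLPFC"` for the unmerged frontal regions).
#' @return A `sem_spec`.
#' @examples
#' model_df(roi_cfa_spec("HC"))   # 0 (just-identified)
#' model_df(roi_cfa_spec("PFC"))  # 9
#' @export
roi_cfa_spec <- function(roi = c("PFC", "HC", "PHG", "PRE", "MOFC", "DLPFC")) {
  roi <- match.arg(roi)
  ind <- .ROI_INDICATORS[[roi]]
  syntax <- paste0(roi, " =~ 1*", ind[1], " + ",
                   paste(ind[-1], collapse = " + "))
  .md_starts(sem_model(syntax))
}

.measurement_syntax <- function(fix_md_mofc_residual = FALSE,
                                merge_frontal = TRUE) {
  rois <- if (merge_frontal) c("PFC", "HC", "PHG", "PRE") else
    c("MOFC", "DLPFC", "HC", "PHG", "PRE")
  roi_lines <- vapply(rois, function(r) {
    ind <- .ROI_INDICATORS[[r]]
    paste0(r, " =~ 1*", ind[1], " + ", paste(ind[-1], collapse = " + "))
  }, character(1))
  mods <- c(vbm = "VBM", mt = "MT", md = "MD")
  regions <- c("pre", "hc", "phg", "mofc", "dlpfc")  # reference first
  method_lines <- vapply(names(mods), function(m) {
    ind <- paste0(m, "_", regions)
    paste0(mods[[m]], " =~ 1*", ind[1], " + ", paste(ind[-1], collapse = " + "))
  }, character(1))
  pairs <- function(v) {
    out <- character()
    for (i in seq_along(v)) for (j in seq_along(v)) if (i < j)
      out <- c(out, paste(v[i], "~~", v[j]))
    out
  }
  orth <- as.vector(outer(rois, unname(mods),
                          function(a, b) paste0(a, " ~~ 0*", b)))
  resid_cov <- c("vbm_mofc ~~ vbm_dlpfc", "vbm_hc ~~ vbm_phg")
  fix <- if (fix_md_mofc_residual) "md_mofc ~~ 0*md_mofc" else character()
  c(roi_lines, method_lines, pairs(rois), pairs(unname(mods)), orth,
    resid_cov, fix)
}

#' MTMM measurement model of regional gray-matter integrity
#'
#' Four regional integrity (trait) factors -- merged prefrontal cortex (six
#' indicators, two regions per modality), hippocampus, parahippocampal gyrus,
#' precuneus -- plus three method factors (VBM, MT, MD) that are orthogonal
#' to the trait factors and covary among themselves. Trait reference
#' indicators are the VBM measures; method reference indicators are the
#' precuneus measures. Residual covariances between VBM indicators of
#' closely neighboring regions (medio-orbitofrontal with dorsolateral
#' prefrontal; hippocampus with parahippocampal gyrus) are freely estimated.
#'
#' @param fix_md_mofc_residual Fix the residual variance of the
#'   medio-orbitofrontal MD indicator to zero (the constraint adopted after
#'   that estimate turned out slightly negative -- a Heywood case).
#' @param merge_frontal Keep the two frontal regions merged into one
#'   prefrontal factor (default). `FALSE` gives the five-factor variant with
#'   separate medio-orbitofrontal and dorsolateral factors, which exhibits
#'   the factor-collinearity failure (estimated correlation beyond 1) that
#'   motivated the merge.
#' @return A `sem_spec` with 15 observed variables; `model_df()` is 64
#'   (65 with the residual fixed).
#' @export
mtmm_measurement_spec <- function(fix_md_mofc_residual = FALSE,
                                  merge_frontal = TRUE) {
  .md_starts(sem_model(.measurement_syntax(fix_md_mofc_residual,
                                           merge_frontal)))
}

#' Add age to a measurement model
#'
#' Lets observed age covary with every latent factor (its variance free), to
#' estimate age differences in the integrity and method factors.
#'
#' @param spec A `sem_spec` from [mtmm_measurement_spec()] (typically with
#'   the residual fix applied).
#' @return A `sem_spec` with 16 observed variables; for the fixed-residual
#'   measurement model, `model_df()` is 73.
#' @export
add_age <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  pt <- spec$partable
  rows <- lapply(spec$latents, function(lv)
    .partable_row("age", "~~", lv, TRUE, NA_real_, ""))
  rows <- c(rows, list(.partable_row("age", "~~", "age", TRUE, NA_real_, "")))
  .finalize_spec(rbind(pt, do.call(rbind, rows)), auto_var = TRUE)
}

.em_lines <- function() {
  c(paste0("EM =~ 1*", .EM_INDICATORS[1], " + ",
           paste(.EM_INDICATORS[-1], collapse = " + ")))
}

#' Correlational model: integrity factors and episodic memory
#'
#' Adds a latent episodic-memory factor (indicators: verbal learning, face-
#' profession, scene encoding, object location; reference indicator the
#' verbal learning score) to the MTMM measurement model (with the MD
#' medio-orbitofrontal residual fixed to zero) and estimates its covariances
#' with the four integrity factors and, optionally, the three method
#' factors.
#'
#' @param zero_em_method_covs Fix the three memory-method covariances to
#'   zero (`model_df()` 123) instead of estimating them (`model_df()` 120).
#' @return A `sem_spec` with 19 observed variables.
#' @export
correlational_spec <- function(zero_em_method_covs = FALSE) {
  em_cov <- c(paste("EM ~~", c("PFC", "HC", "PHG", "PRE")),
              paste0("EM ~~ ", if (zero_em_method_covs) "0*" else "",
                     c("VBM", "MT", "MD")))
  .md_starts(sem_model(c(.measurement_syntax(TRUE), .em_lines(), em_cov)))
}

#' Regression model: episodic memory regressed on the integrity factors
#'
#' The statistically equivalent re-expression of the correlational model
#' (with memory-method covariances fixed to zero) in which latent episodic
#' memory is regressed on all four integrity factors -- a latent multiple
#' regression (MIMIC-style structural layer) whose explained variance is
#' available via [r_squared()]. Log-likelihood and degrees of freedom equal
#' those of `correlational_spec(zero_em_method_covs = TRUE)` on any dataset.
#'
#' @return A `sem_spec` with 19 observed variables, `model_df()` 123.
#' @export
regression_spec <- function() {
  reg <- "EM ~ PFC + HC + PHG + PRE"
  em_m <- paste("EM ~~", paste0("0*", c("VBM", "MT", "MD")))
  .md_starts(sem_model(c(.measurement_syntax(TRUE), .em_lines(), reg, em_m)))
}

#' Covariate-adjusted correlational model
#'
#' Regresses all latent factors (four integrity, three method, episodic
#' memory) on the requested observed covariates and keeps the residual
#' memory-integrity covariances -- the adjusted associations -- freely
#' estimated. The covariate block is exogenous and saturated (free variances
#' and covariances among covariates).
#'
#' @param covariates Subset of `c("age", "education", "sex")`.
#' @return A `sem_spec`.
#' @export
covariate_adjusted_spec <- function(covariates = c("age", "education", "sex")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  factors <- c("PFC", "HC", "PHG", "PRE", "VBM", "MT", "MD", "EM")
  reg <- paste(factors, "~", paste(covariates, collapse = " + "))
  cov_block <- character()
  if (length(covariates) > 1L)
    for (i in seq_along(covariates)) for (j in seq_along(covariates))
      if (i < j) cov_block <- c(cov_block,
                                paste(covariates[i], "~~", covariates[j]))
  em_cov <- c(paste("EM ~~", c("PFC", "HC", "PHG", "PRE")),
              paste("EM ~~", paste0("0*", c("VBM", "MT", "MD"))))
  .md_starts(sem_model(c(.measurement_syntax(TRUE), .em_lines(), em_cov,
                         reg, cov_block)))
}

# canonical symmetric label, matching the parameter-table convention
.cov_label <- function(a, b) paste0(pmin(a, b), "~~", pmax(a, b))

#' True parameter values of the measurement model under a configuration
#'
#' Maps a simulation configuration to the generating values of every free
#' parameter of [mtmm_measurement_spec()] (marginalizing the covariate
#' effects into the total factor covariance), named by parameter label.
#' Used to check parameter recovery.
#'
#' @param config A `sim_config`.
#' @param spec The spec whose labels to use (default the measurement model).
#' @return Named numeric vector of generating values for each free parameter
#'   found in `spec`; parameters without a generating analogue are omitted.
#' @export
generating_parameters <- function(config, spec = mtmm_measurement_spec()) {
  validate_sim_config(config)
  phi <- .latent_total_cov(config)
  lam <- config$lambda
  pt <- spec$partable
  pt <- pt[pt$free, , drop = FALSE]
  out <- numeric(0)
  for (r in seq_len(nrow(pt))) {
    row <- pt[r, ]
    val <- NA_real_
    if (row$op == "=~" && row$rhs %in% rownames(lam) &&
        row$lhs %in% colnames(lam)) {
      val <- lam[row$rhs, row$lhs]
    } else if (row$op == "~~") {
      a <- row$lhs; b <- row$rhs
      if (a %in% colnames(phi) && b %in% colnames(phi)) {
        val <- phi[a, b]
      } else if (a == b && a %in% names(config$resid_var)) {
        val <- config$resid_var[[a]]
      } else {
        rc <- config$resid_cov
        hit <- (rc$a == a & rc$b == b) | (rc$a == b & rc$b == a)
        if (any(hit)) val <- rc$value[hit][1]
      }
    }
    if (!is.na(val)) out[row$label] <- val
  }
  out
}
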