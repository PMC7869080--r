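# Multigroup measurement-invariance testing: configural (same structure,
# group-specific parameters), metric (loadings equated), scalar (loadings and
# intercepts equated, latent means free in the non-reference groups), with
# sequential likelihood-ratio tests between adjacent levels.

# Append an explicit mean structure to a single-group spec: free intercepts
# for observed variables, latent means fixed at zero (freed later for the
# non-reference groups at the scalar level).
.add_meanstructure <- function(spec) {
  pt <- spec$partable
  if (any(pt$op == "~1")) return(spec)
  rows <- c(
    lapply(spec$observed, function(v)
      .partable_row(v, "~1", "", TRUE, NA_real_, "")),
    lapply(spec$latents, function(v)
      .partable_row(v, "~1", "", FALSE, 0, "")))
  .finalize_spec(rbind(pt, do.call(rbind, rows)), auto_var = FALSE)
}

.invariance_spec <- function(spec, ngroups,
                             level = c("configural", "metric", "scalar")) {
  level <- match.arg(level)
  spec <- .add_meanstructure(spec)
  equal <- switch(level, configural = character(), metric = "loadings",
                  scalar = c("loadings", "intercepts"))
  mg <- multigroup_spec(spec, ngroups, equal = equal)
  if (level == "scalar") {
    pt <- mg$partable
    free_mean <- pt$op == "~1" & pt$lhs %in% mg$latents & pt$group > 1L
    pt$free[free_mean] <- TRUE
    pt$value[free_mean] <- NA_real_
    pt$label[free_mean] <- paste0(pt$lhs[free_mean], "~1.g", pt$group[free_mean])
    mg$partable <- pt
  }
  mg
}

#' Measurement-invariance ladder across groups
#'
#' Fits the model at increasingly constrained levels -- configural (same
#' structure, all parameters group-specific), metric (factor loadings
#' equated across groups), scalar (loadings and intercepts equated, latent
#' means freely estimated in the non-reference groups) -- and tests each
#' step against the previous one with a likelihood-ratio test. The metric
#' step's degrees-of-freedom difference equals the number of equated
#' loadings times (groups - 1).
#'
#' @param spec A single-group `sem_spec` (no mean structure; intercepts are
#'   added internally).
#' @param data Data frame containing the observed columns and the grouping
#'   column.
#' @param group Name of the grouping column (2 or more levels; at least 30
#'   rows per group are required).
#' @param levels Which levels to fit, in ladder order.
#' @param ... Passed to [sem_fit()].
#' @return List of class `invariance_ladder` with `fits` (named list of
#'   `sem_fit`) and `tests` (named list of `sem_lrt`, one per adjacent pair).
#' @export
invariance_ladder <- function(spec, data, group,
                              levels = c("configural", "metric", "scalar"),
                              ...) {
  stopifnot(inherits(spec, "sem_spec"), is.data.frame(data),
            group %in% names(data))
  levels <- match.arg(levels, several.ok = TRUE)
  gv <- data[[group]]
  keep <- !is.na(gv)
  data <- data[keep, , drop = FALSE]; gv <- gv[keep]
  glev <- sort(unique(gv))
  if (length(glev) < 2L) stop("grouping column must have at least 2 levels")
  sizes <- table(gv)
  if (any(sizes < 30L))
    stop("every group needs at least 30 rows; smallest has ", min(sizes))
  groups_data <- lapply(glev, function(l) data[gv == l, , drop = FALSE])
  fits <- list()
  for (lv in levels) {
    mspec <- .invariance_spec(spec, length(glev), lv)
    fits[[lv]] <- sem_fit(mspec, groups_data, ...)
    fits[[lv]]$group_levels <- glev
  }
  tests <- list()
  if (length(fits) > 1L) {
    for (i in seq_len(length(fits) - 1L)) {
      nm <- paste0(names(fits)[i + 1L], "_vs_", names(fits)[i])
      tests[[nm]] <- likelihood_ratio_test(fits[[i]], fits[[i + 1L]])
    }
  }
  structure(list(fits = fits, tests = tests, group = group,
                 group_levels = glev),
            class = "invariance_ladder")
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("Measurement-invariance ladder over `", x$group, "` (",
      length(x$group_levels), " groups)\n", sep = "")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-10s loglik %.3f  df %d  chi2 %.3f\n",
                nm, f$loglik, f$df, f$chi2))
  }
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-22s delta chi2 %.3f (df %d), p = %.4g\n",
                nm, t$delta_chi2, t$delta_df, t$p_value))
  }
  invisible(x)
}

#' Median-split grouping variable
#'
#' Splits a numeric column at the sample median, assigning ties to the lower
#' group -- the convention used for age-group invariance testing.
#'
#' @param x Numeric vector.
#' @return Factor with levels `"low"` and `"high"`; `NA` propagates.
#' @export
median_split <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
}
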