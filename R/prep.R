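# Deterministic data-preparation operators: MTR arithmetic, intracranial-volume
# adjustment, robust multivariate outlier screening, rescaling, subsample
# selectivity, and exclusion accounting.

#' Magnetization transfer ratio
#'
#' Computes the magnetization transfer ratio \eqn{(noMT - MT) / noMT} from the
#' signal intensity without a saturation pulse (`no_mt`) and with one (`mt`).
#' Higher values indicate denser macromolecular tissue.
#'
#' @param no_mt Numeric vector of signal intensities acquired without the
#'   magnetization saturation pulse. Must be nonzero.
#' @param mt Numeric vector of signal intensities acquired with the pulse;
#'   recycled against `no_mt` by ordinary rules.
#' @return Numeric vector of unitless ratios. `NA` cells propagate.
#' @examples
#' compute_mtr(2, 1)      # 0.5
#' compute_mtr(1, 0.644)  # 0.356
#' @export
compute_mtr <- function(no_mt, mt) {
  if (!is.numeric(no_mt) || !is.numeric(mt))
    stop("`no_mt` and `mt` must be numeric")
  if (any(no_mt == 0, na.rm = TRUE))
    stop("`no_mt` contains zero values; the ratio is undefined there")
  (no_mt - mt) / no_mt
}

#' Adjust regional volumes for intracranial volume
#'
#' Removes head-size variance from a regional gray-matter volume via the
#' analysis-of-covariance formula: adjusted = raw - b * (ICV - mean(ICV)),
#' where `b` is the ordinary least-squares slope of volume on ICV in a
#' reference sample. Applied to the reference sample itself, the adjusted
#' values are exactly uncorrelated with ICV.
#'
#' @param volume Numeric vector of raw volumes to adjust.
#' @param icv Numeric vector of intracranial volumes paired with `volume`.
#' @param ref_volume,ref_icv Reference sample used to estimate the slope and
#'   the ICV mean; defaults to `volume`/`icv` themselves. Pairs with missing
#'   values are dropped; at least 3 complete pairs are required.
#' @return Numeric vector of adjusted volumes.
#' @export
adjust_for_icv <- function(volume, icv, ref_volume = volume, ref_icv = icv) {
  ok <- is.finite(ref_volume) & is.finite(ref_icv)
  if (sum(ok) < 3L)
    stop("reference sample must contain at least 3 complete (volume, icv) pairs")
  rv <- ref_volume[ok]; ri <- ref_icv[ok]
  v_icv <- var(ri)
  if (v_icv == 0)
    stop("reference ICV has zero variance; adjustment slope is undefined")
  b <- cov(rv, ri) / v_icv
  volume - b * (icv - mean(ri))
}

#' Robust multivariate outlier screening
#'
#' Flags rows whose squared robust Mahalanobis distance exceeds the
#' chi-squared quantile at `1 - p_cutoff` with degrees of freedom equal to the
#' number of screened columns. Location and scatter come from a
#' high-breakdown ellipsoid estimator (minimum volume ellipsoid by default;
#' minimum covariance determinant available). Screening uses complete cases
#' only; rows with any missing value in the screened columns are never
#' flagged.
#'
#' @param data A data frame or numeric matrix.
#' @param columns Character or integer vector naming the columns to screen
#'   jointly; defaults to all numeric columns.
#' @param p_cutoff Tail probability of the chi-squared reference distribution
#'   (default `1e-4`).
#' @param method Robust scatter estimator passed to [MASS::cov.rob()]:
#'   `"mve"` (default) or `"mcd"`. The two agree in the gross-outlier regime
#'   this screen targets.
#' @param seed Optional integer seed for the resampling inside the robust
#'   estimator, making the report reproducible.
#' @return An object of class `outlier_report`: a list with `flagged` (row
#'   indices in `data`), `distance` (squared robust distances for complete
#'   cases, named by row index), `cutoff`, `df`, `p_cutoff`, `n_screened`,
#'   `method`.
#' @export
detect_multivariate_outliers <- function(data, columns = NULL, p_cutoff = 1e-4,
                                         method = c("mve", "mcd"),
                                         seed = NULL) {
  method <- match.arg(method)
  x <- as.data.frame(data)
  if (is.null(columns))
    columns <- names(x)[vapply(x, is.numeric, logical(1))]
  x <- x[, columns, drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all screened columns must be numeric")
  if (!(p_cutoff > 0 && p_cutoff < 1)) stop("`p_cutoff` must lie in (0, 1)")
  cc <- which(complete.cases(x))
  k <- ncol(x)
  if (length(cc) < k + 1L)
    stop("need at least ", k + 1L, " complete cases to screen ", k, " columns")
  xm <- as.matrix(x[cc, , drop = FALSE])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rob <- MASS::cov.rob(xm, method = method)
  if (inherits(try(solve(rob$cov), silent = TRUE), "try-error"))
    stop("robust scatter is singular; drop collinear columns and retry")
  d2 <- mahalanobis(xm, rob$center, rob$cov)
  names(d2) <- cc
  cutoff <- qchisq(1 - p_cutoff, df = k)
  structure(
    list(flagged = cc[d2 > cutoff], distance = d2, cutoff = cutoff, df = k,
         p_cutoff = p_cutoff, n_screened = length(cc), method = method,
         columns = columns),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Robust multivariate outlier screen (", x$method, ")\n", sep = "")
  cat("  columns:", length(x$columns), " complete cases screened:",
      x$n_screened, "\n")
  cat("  chi-square cutoff:", format(x$cutoff, digits = 6),
      "(df =", x$df, ", p <", format(x$p_cutoff), ")\n")
  cat("  flagged rows:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Linearly rescale columns to a target mean and standard deviation
#'
#' Applies, per column, the affine map that sends the non-missing cells to the
#' requested mean and standard deviation (default mean 5, SD 2 -- a scale that
#' keeps numerical optimization well conditioned when raw scales differ by
#' orders of magnitude). Missing cells stay missing; correlations are
#' unchanged.
#'
#' @param data Data frame holding the columns.
#' @param columns Character vector of columns to rescale; default all numeric.
#' @param target_mean,target_sd Targets of the affine map.
#' @return `data` with the selected columns rescaled.
#' @export
rescale_columns <- function(data, columns = NULL, target_mean = 5, target_sd = 2) {
  stopifnot(is.data.frame(data), target_sd > 0)
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  for (cl in columns) {
    v <- data[[cl]]
    if (!is.numeric(v)) stop("column `", cl, "` is not numeric")
    obs <- v[!is.na(v)]
    if (length(obs) < 2L) stop("column `", cl, "` has fewer than 2 observed values")
    s <- sd(obs)
    if (s == 0) stop("column `", cl, "` has zero variance; rescaling undefined")
    data[[cl]] <- (v - mean(obs)) / s * target_sd + target_mean
  }
  data
}

# Moment-based skewness and plain (non-excess) kurtosis, ML divisor n.
.skewness <- function(x) {
  x <- x[!is.na(x)]; n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  m3 / m2^1.5
}
.kurtosis <- function(x) {
  x <- x[!is.na(x)]; m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  m4 / m2^2
}

#' Selectivity of a subsample relative to the full sample
#'
#' For each variable, computes descriptives in the full sample and in a
#' subsample, and the selectivity in standard-deviation units:
#' `(mean_total - mean_sub) / sd_total`. This quantifies how far the
#' subsample (e.g., the participants who underwent MR imaging) departs from
#' the parent sample.
#'
#' @param data Data frame for the full sample.
#' @param sub Logical vector (length `nrow(data)`), or integer row indices,
#'   selecting the subsample.
#' @param variables Character vector of numeric columns to describe; default
#'   all numeric columns.
#' @return A data frame with one row per variable: `n_total`, `n_sub`,
#'   `mean_total`, `mean_sub`, `sd_total`, `sd_sub`, `skew_total`, `skew_sub`,
#'   `kurt_total`, `kurt_sub` (plain kurtosis), and `selectivity`.
#' @export
selectivity_table <- function(data, sub, variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.logical(sub)) {
    stopifnot(length(sub) == nrow(data))
    sub <- which(sub)
  }
  sub <- as.integer(sub)
  if (length(sub) == 0L) stop("subsample is empty")
  if (any(sub < 1L | sub > nrow(data))) stop("subsample indices out of range")
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  rows <- lapply(variables, function(v) {
    tot <- data[[v]]; sb <- data[[v]][sub]
    data.frame(
      variable = v,
      n_total = sum(!is.na(tot)), n_sub = sum(!is.na(sb)),
      mean_total = mean(tot, na.rm = TRUE), mean_sub = mean(sb, na.rm = TRUE),
      sd_total = sd(tot, na.rm = TRUE), sd_sub = sd(sb, na.rm = TRUE),
      skew_total = .skewness(tot), skew_sub = .skewness(sb),
      kurt_total = .kurtosis(tot), kurt_sub = .kurtosis(sb),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selectivity <- (out$mean_total - out$mean_sub) / out$sd_total
  out
}

#' Exclusion accounting
#'
#' Effective sample size after removing erroneous cases and multivariate
#' outliers: `initial_n - erroneous - outliers`.
#'
#' @param initial_n,erroneous,outliers Nonnegative integer counts.
#' @return The effective n (integer).
#' @examples
#' exclusion_accounting(1532, 9, 1)  # 1522
#' exclusion_accounting(342, 2, 7)   # 333
#' @export
exclusion_accounting <- function(initial_n, erroneous, outliers) {
  stopifnot(length(initial_n) == 1L, length(erroneous) == 1L,
            length(outliers) == 1L)
  if (initial_n < 0 || erroneous < 0 || outliers < 0)
    stop("counts must be nonnegative")
  n <- initial_n - erroneous - outliers
  if (n < 0) stop("exclusions exceed the initial sample size")
  as.integer(n)
}
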