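# Declarative latent-variable model specification. Models are written in a
# compact path syntax and stored as a parameter table, one row per edge:
#
#   F =~ x1 + x2 + x3    loadings (first indicator fixed to 1 unless modified)
#   F ~~ G               covariance; F ~~ F variance
#   y ~ x1 + x2          directed regression paths
#   x ~ 1                intercept / mean (means are otherwise saturated and
#                        profiled out of the likelihood)
#
# A term may carry a modifier: `1*x` or `0.5*x` fixes the value, `NA*x` frees
# a loading that would otherwise be fixed, and `lab*x` attaches a label.
# Parameters sharing a label are constrained equal (also across groups).

.parse_term <- function(term) {
  term <- trimws(term)
  m <- regexec("^(?:(.+)\\*)?\\s*([A-Za-z._][A-Za-z0-9._]*|1)$", term)
  parts <- regmatches(term, m)[[1]]
  if (length(parts) == 0L) stop("cannot parse model term: `", term, "`")
  mod <- trimws(parts[2]); var <- parts[3]
  out <- list(var = var, fixed = NA_real_, label = "", free_forced = FALSE)
  if (nzchar(mod)) {
    if (identical(toupper(mod), "NA")) {
      out$free_forced <- TRUE
    } else if (!is.na(suppressWarnings(as.numeric(mod)))) {
      out$fixed <- as.numeric(mod)
    } else {
      out$label <- mod
    }
  }
  out
}

.partable_row <- function(lhs, op, rhs, free, value, label, group = 1L) {
  data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
             label = label, group = as.integer(group), stringsAsFactors = FALSE)
}

#' Specify a structural equation model
#'
#' Parses path syntax into a `sem_spec` object holding a parameter table.
#' Latent variables are those that appear on the left of `=~`. Unless
#' disabled, the first indicator of each latent is fixed to 1 (reference
#' indicator identification) and free variances are added for every variable
#' (residual variances for endogenous ones). Means are saturated by default:
#' every observed variable gets a freely estimated mean that is profiled out
#' of the likelihood; add explicit `~ 1` lines only for models that need a
#' structured mean part (e.g., multigroup intercept equality).
#'
#' @param syntax Character scalar (or vector of lines) of model syntax.
#' @param fix_first Fix the first indicator loading of each latent to 1.
#' @param auto_var Add free (residual) variances for all variables.
#' @param start Optional named numeric vector of starting values; names are
#'   parameter labels (default labels are `"lhs=~rhs"`, `"lhs~~rhs"`,
#'   `"lhs~rhs"`).
#' @return An object of class `sem_spec`.
#' @examples
#' spec <- sem_model("
#'   F =~ x1 + x2 + x3
#'   F ~~ F
#' ")
#' @export
sem_model <- function(syntax, fix_first = TRUE, auto_var = TRUE, start = NULL) {
  lines <- unlist(strsplit(paste(syntax, collapse = "\n"), "[\n;]"))
  lines <- sub("[#!].*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  rows <- list()
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      op <- "=~"; sides <- strsplit(ln, "=~", fixed = TRUE)[[1]]
    } else if (grepl("~~", ln, fixed = TRUE)) {
      op <- "~~"; sides <- strsplit(ln, "~~", fixed = TRUE)[[1]]
    } else if (grepl("~", ln, fixed = TRUE)) {
      op <- "~"; sides <- strsplit(ln, "~", fixed = TRUE)[[1]]
    } else stop("no operator in model line: `", ln, "`")
    if (length(sides) != 2L) stop("malformed model line: `", ln, "`")
    lhs <- trimws(sides[1])
    if (!grepl("^[A-Za-z._][A-Za-z0-9._]*$", lhs))
      stop("malformed left-hand side in: `", ln, "`")
    terms <- strsplit(sides[2], "+", fixed = TRUE)[[1]]
    first <- TRUE
    for (tm in terms) {
      t <- .parse_term(tm)
      this_op <- op
      if (op == "~" && t$var == "1") {
        this_op <- "~1"; t$var <- ""
      }
      fixed <- t$fixed
      if (this_op == "=~" && first && fix_first && is.na(fixed) &&
          !t$free_forced && !nzchar(t$label))
        fixed <- 1
      rows[[length(rows) + 1L]] <- .partable_row(
        lhs, this_op, t$var, free = is.na(fixed),
        value = if (is.na(fixed)) NA_real_ else fixed, label = t$label)
      first <- FALSE
    }
  }
  pt <- do.call(rbind, rows)
  spec <- .finalize_spec(pt, auto_var = auto_var)
  if (!is.null(start)) spec <- set_start(spec, start)
  spec
}

# Deduplicate, add automatic variances, derive latent/observed sets, default
# labels, and validate.
.finalize_spec <- function(pt, auto_var = TRUE) {
  # canonical order of symmetric edges for duplicate detection
  sym <- pt$op == "~~"
  a <- pmin(pt$lhs[sym], pt$rhs[sym]); b <- pmax(pt$lhs[sym], pt$rhs[sym])
  pt$lhs[sym] <- a; pt$rhs[sym] <- b
  key <- paste(pt$lhs, pt$op, pt$rhs, pt$group)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate model edges: ", paste(unique(dup), collapse = "; "))
  }
  latents <- unique(pt$lhs[pt$op == "=~"])
  vars <- unique(c(pt$lhs[pt$op != "~1"], pt$rhs[pt$op != "~1"],
                   pt$lhs[pt$op == "~1"]))
  observed <- setdiff(vars, latents)
  if (auto_var) {
    for (g in unique(pt$group)) {
      have_var <- pt$lhs[pt$op == "~~" & pt$lhs == pt$rhs & pt$group == g]
      need <- setdiff(vars, have_var)
      for (v in need)
        pt <- rbind(pt, .partable_row(v, "~~", v, TRUE, NA_real_, "", g))
    }
  }
  # default labels; group-specific unless user supplied a shared label
  auto <- !nzchar(pt$label)
  base_lab <- paste0(pt$lhs, pt$op, pt$rhs)
  multi <- length(unique(pt$group)) > 1L
  pt$label[auto] <- if (multi)
    paste0(base_lab[auto], ".g", pt$group[auto]) else base_lab[auto]
  pt$label[!pt$free] <- paste0(pt$label[!pt$free], "")  # fixed rows keep label for reference
  rownames(pt) <- NULL
  structure(list(partable = pt, latents = latents, observed = observed,
                 meanstructure = any(pt$op == "~1")),
            class = "sem_spec")
}

#' Set starting values on a model specification
#'
#' @param spec A `sem_spec`.
#' @param start Named numeric vector; names are parameter labels.
#' @return The modified `sem_spec`.
#' @export
set_start <- function(spec, start) {
  stopifnot(inherits(spec, "sem_spec"), is.numeric(start), !is.null(names(start)))
  pt <- spec$partable
  for (nm in names(start)) {
    hit <- pt$free & pt$label == nm
    if (!any(hit)) stop("no free parameter labelled `", nm, "`")
    pt$value[hit] <- start[[nm]]
  }
  spec$partable <- pt
  spec
}

#' Fix a free parameter to a value
#'
#' Returns a nested model in which the parameter(s) with the given label are
#' fixed (default to zero) -- the restricted model of a likelihood-ratio test.
#'
#' @param spec A `sem_spec`.
#' @param label Parameter label to fix.
#' @param value Numeric value (default 0).
#' @return The modified `sem_spec`.
#' @export
fix_parameter <- function(spec, label, value = 0) {
  pt <- spec$partable
  hit <- pt$label == label & pt$free
  if (!any(hit)) stop("no free parameter labelled `", label, "`")
  pt$free[hit] <- FALSE
  pt$value[hit] <- value
  spec$partable <- pt
  spec
}

#' Number of free parameters (unique labels)
#' @param spec A `sem_spec`.
#' @return Integer count of free parameters, counting equality-constrained
#'   sets once.
#' @export
n_free_parameters <- function(spec) {
  length(unique(spec$partable$label[spec$partable$free]))
}

#' Model degrees of freedom
#'
#' Covariance-structure degrees of freedom: observed moments minus free
#' parameters, summed over groups, with equality-constrained parameters
#' counted once. Means are saturated (every observed variable has a free,
#' profiled mean in every model including the saturated and baseline
#' references), so mean moments and mean parameters cancel and df is driven
#' by the covariance part; models with an explicit mean structure count the
#' mean moments and intercept parameters instead.
#'
#' @param spec A `sem_spec`.
#' @param observed_count Number of observed variables per group; defaults to
#'   `length(spec$observed)`.
#' @return Integer degrees of freedom; errors if negative.
#' @export
model_df <- function(spec, observed_count = length(spec$observed)) {
  p <- observed_count
  ngroups <- length(unique(spec$partable$group))
  moments <- ngroups * (p * (p + 1) / 2 + if (spec$meanstructure) p else 0)
  df <- moments - n_free_parameters(spec)
  if (df < 0) stop("model is over-parameterized (df = ", df, ")")
  as.integer(df)
}

#' Expand a single-group specification into a multigroup one
#'
#' Replicates the parameter table across `ngroups` groups. Parameters are
#' group-specific by default; `equal` requests cross-group equality of
#' loadings and/or intercepts by assigning shared labels (the metric and
#' scalar steps of a measurement-invariance ladder).
#'
#' @param spec A single-group `sem_spec`.
#' @param ngroups Number of groups.
#' @param equal Character subset of `c("loadings", "intercepts")`.
#' @return A multigroup `sem_spec`.
#' @export
multigroup_spec <- function(spec, ngroups, equal = character()) {
  stopifnot(inherits(spec, "sem_spec"), ngroups >= 2)
  bad <- setdiff(equal, c("loadings", "intercepts"))
  if (length(bad)) stop("unknown equality set: ", paste(bad, collapse = ", "))
  pt1 <- spec$partable
  pt1$group <- 1L
  pts <- lapply(seq_len(ngroups), function(g) { p <- pt1; p$group <- g; p })
  pt <- do.call(rbind, pts)
  base_lab <- paste0(pt$lhs, pt$op, pt$rhs)
  shared <- rep(FALSE, nrow(pt))
  if ("loadings" %in% equal) shared <- shared | pt$op == "=~"
  if ("intercepts" %in% equal) shared <- shared | pt$op == "~1"
  pt$label <- ifelse(pt$free & shared, base_lab,
                     ifelse(pt$free, paste0(base_lab, ".g", pt$group),
                            base_lab))
  out <- spec
  out$partable <- pt
  out$meanstructure <- any(pt$op == "~1")
  out
}

#' Serialize / read a model specification as YAML
#'
#' The YAML file stores the parameter table verbatim, so fixed values,
#' labels, and group structure round-trip exactly.
#'
#' @param spec A `sem_spec`.
#' @param path File path.
#' @return `read_sem_spec()` returns the `sem_spec`.
#' @export
write_sem_spec <- function(spec, path) {
  yaml::write_yaml(list(partable = lapply(
    seq_len(nrow(spec$partable)), function(i) as.list(spec$partable[i, ]))),
    path)
  invisible(path)
}

#' @rdname write_sem_spec
#' @export
read_sem_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  pt <- do.call(rbind, lapply(raw$partable, function(r) {
    r$value <- if (is.null(r$value)) NA_real_ else as.numeric(r$value)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  .finalize_spec(pt, auto_var = FALSE)
}

#' @export
print.sem_spec <- function(x, ...) {
  pt <- x$partable
  cat("Structural equation model specification\n")
  cat("  latent:", if (length(x$latents)) paste(x$latents, collapse = ", ")
      else "(none)", "\n")
  cat("  observed:", length(x$observed), "variables\n")
  cat("  free parameters:", n_free_parameters(x),
      " groups:", length(unique(pt$group)), "\n")
  invisible(x)
}
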