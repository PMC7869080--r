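# Compilation of a sem_spec into RAM matrices: A holds directed paths
# (loadings and regressions), S symmetric (co)variances, F filters the
# observed variables, M the means. Implied moments follow the standard RAM
# algebra: Sigma = F (I-A)^-1 S (I-A)^-T F', mu = F (I-A)^-1 M.

#' Compile a model specification into RAM matrices
#'
#' Produces, per group, numeric template matrices with fixed values filled in
#' and a map from free-parameter labels to matrix cells. Validates
#' identification (every latent needs a fixed loading or a fixed variance)
#' and rejects cyclic directed paths.
#'
#' @param spec A `sem_spec`.
#' @param observed Optional character vector giving the order of observed
#'   variables (e.g., data column order); defaults to the order of appearance
#'   in the specification.
#' @return An object of class `ram_matrices`: list with `vars` (all variable
#'   names, observed first), `observed`, `latents`, `A`, `S`, `M` (lists, one
#'   per group), `free` (data frame label/matrix/i/j/group), `labels` (unique
#'   free labels, estimation order), `ngroups`, `meanstructure`.
#' @export
compile_ram <- function(spec, observed = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  pt <- spec$partable
  if (is.null(observed)) observed <- spec$observed
  if (!setequal(observed, spec$observed))
    stop("`observed` must be a permutation of the specification's observed variables")
  vars <- c(observed, spec$latents)
  nv <- length(vars)
  idx <- setNames(seq_len(nv), vars)
  groups <- sort(unique(pt$group))
  ngroups <- length(groups)

  A <- S <- M <- vector("list", ngroups)
  free_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    Ag <- matrix(0, nv, nv, dimnames = list(vars, vars))
    Sg <- matrix(0, nv, nv, dimnames = list(vars, vars))
    Mg <- setNames(numeric(nv), vars)
    ptg <- pt[pt$group == g, , drop = FALSE]
    for (r in seq_len(nrow(ptg))) {
      row <- ptg[r, ]
      if (row$op == "=~") {
        i <- idx[[row$rhs]]; j <- idx[[row$lhs]]; mat <- "A"
      } else if (row$op == "~") {
        i <- idx[[row$lhs]]; j <- idx[[row$rhs]]; mat <- "A"
      } else if (row$op == "~~") {
        i <- idx[[row$lhs]]; j <- idx[[row$rhs]]; mat <- "S"
      } else { # ~1
        i <- idx[[row$lhs]]; j <- 1L; mat <- "M"
      }
      if (row$free) {
        free_rows[[length(free_rows) + 1L]] <- data.frame(
          label = row$label, matrix = mat, i = i, j = j, group = gi,
          start = row$value, stringsAsFactors = FALSE)
      } else {
        v <- row$value
        if (mat == "A") Ag[i, j] <- v
        else if (mat == "S") { Sg[i, j] <- v; Sg[j, i] <- v }
        else Mg[i] <- v
      }
    }
    A[[gi]] <- Ag; S[[gi]] <- Sg; M[[gi]] <- Mg
  }
  free <- if (length(free_rows)) do.call(rbind, free_rows) else
    data.frame(label = character(), matrix = character(), i = integer(),
               j = integer(), group = integer(), start = numeric())
  labels <- unique(free$label)

  .check_identification(spec, free)
  .check_acyclic(spec, vars, idx, free, A[[1]])

  structure(list(vars = vars, observed = observed, latents = spec$latents,
                 A = A, S = S, M = M, free = free, labels = labels,
                 ngroups = ngroups, meanstructure = spec$meanstructure,
                 spec = spec),
            class = "ram_matrices")
}

.check_identification <- function(spec, free) {
  pt <- spec$partable
  for (lv in spec$latents) {
    fixed_load <- any(pt$op == "=~" & pt$lhs == lv & !pt$free)
    fixed_var <- any(pt$op == "~~" & pt$lhs == lv & pt$rhs == lv & !pt$free)
    if (!fixed_load && !fixed_var)
      stop("latent `", lv, "` is unidentified: fix a reference loading or ",
           "its variance")
  }
}

.check_acyclic <- function(spec, vars, idx, free, A1) {
  # adjacency over all potentially nonzero directed paths
  adj <- A1 != 0
  af <- free[free$matrix == "A", , drop = FALSE]
  if (nrow(af)) adj[cbind(af$i, af$j)] <- TRUE
  nv <- length(vars)
  color <- integer(nv) # 0 white, 1 gray, 2 black
  visit <- function(u) {
    color[u] <<- 1L
    for (v in which(adj[u, ])) {
      if (color[v] == 1L) stop("cyclic directed paths are not supported")
      if (color[v] == 0L) visit(v)
    }
    color[u] <<- 2L
  }
  for (u in seq_len(nv)) if (color[u] == 0L) visit(u)
  invisible(TRUE)
}

# Fill group-g matrices with theta (named by ram$labels).
.ram_fill <- function(ram, theta, gi = 1L) {
  A <- ram$A[[gi]]; S <- ram$S[[gi]]; M <- ram$M[[gi]]
  f <- ram$free[ram$free$group == gi, , drop = FALSE]
  if (nrow(f)) {
    v <- theta[match(f$label, ram$labels)]
    for (r in seq_len(nrow(f))) {
      if (f$matrix[r] == "A") A[f$i[r], f$j[r]] <- v[r]
      else if (f$matrix[r] == "S") { S[f$i[r], f$j[r]] <- v[r]; S[f$j[r], f$i[r]] <- v[r] }
      else M[f$i[r]] <- v[r]
    }
  }
  list(A = A, S = S, M = M)
}

#' Model-implied moments at a parameter vector
#'
#' Evaluates the RAM algebra at `theta`: implied covariance
#' `F (I-A)^-1 S (I-A)^-T F'` and, when a mean structure is present, implied
#' means `F (I-A)^-1 M`.
#'
#' @param ram A `ram_matrices` object from [compile_ram()].
#' @param theta Numeric vector of free-parameter values in `ram$labels`
#'   order (named vectors are matched by name).
#' @param group Group index (default 1).
#' @return List with `mean` (or `NULL` when means are saturated/profiled) and
#'   `cov` over the observed variables, plus `cov_all` over observed and
#'   latent variables.
#' @export
implied_moments <- function(ram, theta, group = 1L) {
  stopifnot(inherits(ram, "ram_matrices"))
  if (!is.null(names(theta))) theta <- theta[ram$labels]
  if (length(theta) != length(ram$labels))
    stop("theta must have one value per free parameter (", length(ram$labels), ")")
  m <- .ram_fill(ram, theta, group)
  nv <- length(ram$vars)
  IA <- diag(nv) - m$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("(I - A) is singular at the supplied parameter values"))
  C_all <- B %*% m$S %*% t(B)
  dimnames(C_all) <- list(ram$vars, ram$vars)
  obs <- ram$observed
  mu <- NULL
  if (ram$meanstructure) {
    mu_all <- drop(B %*% m$M)
    names(mu_all) <- ram$vars
    mu <- mu_all[obs]
  }
  list(mean = mu, cov = C_all[obs, obs, drop = FALSE], cov_all = C_all)
}
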