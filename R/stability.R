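#' Stability-selection configuration
#'
#' @param B number of random half-subsamples.
#' @param subsample_fraction fraction of rows per subsample (default 1/2).
#' @param M regularization-path size.
#' @param epsilon path ratio `lambda_min / lambda_max`.
#' @param pi_threshold importance cutoff for the stable support.
#' @param seed master RNG seed; all subsampling and per-subsample
#'   randomization derives from it.
#' @return A `stability_config` list.
#' @export
stability_config <- function(B = 250L, subsample_fraction = 0.5, M = 20L,
                             epsilon = 0.1, pi_threshold = 0.8, seed = 0L) {
  stopifnot(B >= 1, subsample_fraction > 0, subsample_fraction <= 1,
            M >= 2, epsilon > 0, epsilon < 1,
            pi_threshold > 0, pi_threshold <= 1)
  structure(list(B = as.integer(B), subsample_fraction = subsample_fraction,
                 M = as.integer(M), epsilon = epsilon,
                 pi_threshold = pi_threshold, seed = as.integer(seed)),
            class = "stability_config")
}

#' Draw standardized random row-subsamples of a design system
#'
#' Draws `B` independent subsets of `floor(N * subsample_fraction)` rows,
#' each without replacement, and standardizes each sub-design independently
#' (columns centred and scaled to unit mean square over the rows present,
#' response centred).
#'
#' @param system a raw (unstandardized) `design_system`.
#' @param cfg a `stability_config`.
#' @return List of `B` standardized `design_system`s; each carries its row
#'   index set as `$rows`.
#' @export
subsample_systems <- function(system, cfg = stability_config()) {
  stopifnot(inherits(system, "design_system"), !isTRUE(system$standardized))
  N <- nrow(system$theta)
  if (N < 4) stop("need at least 4 rows to subsample")
  p <- ncol(system$theta)
  if (N < 2 * p)
    warning("N < 2p: subsamples have fewer rows than dictionary columns")
  rows <- draw_subsample_rows(N, cfg)
  lapply(seq_len(cfg$B), function(i) {
    sub <- standardize(subset_rows(system, rows[, i]))
    sub$rows <- rows[, i]
    sub
  })
}

# The B subsample index sets as an m x B matrix, drawn under the config
# seed. Shared by the R and compiled stability loops so both see identical
# subsamples.
draw_subsample_rows <- function(N, cfg) {
  m <- max(2L, floor(N * cfg$subsample_fraction))
  rs <- local_rng(cfg$seed)
  on.exit(rs(), add = TRUE)
  vapply(seq_len(cfg$B), function(i) sample.int(N, m), integer(m))
}

#' Importance profile from per-subsample regularization paths
#'
#' The importance of component `k` at penalty `lambda` is the fraction of
#' subsamples whose support at that `lambda` contains `k`.
#'
#' @param subpaths list of completed `reg_path`s sharing one lambda grid.
#' @param cfg a `stability_config` (echoed into the result).
#' @return An `importance_profile`: list with `pi` (M x p matrix of values
#'   in \[0, 1\]), `lambdas` and `labels`.
#' @export
importance_profile <- function(subpaths, cfg = stability_config()) {
  stopifnot(length(subpaths) >= 1)
  lambdas <- subpaths[[1]]$lambdas
  labels <- subpaths[[1]]$labels
  for (pth in subpaths) {
    if (length(pth$lambdas) != length(lambdas) ||
        max(abs(pth$lambdas - lambdas)) > 1e-10 * max(lambdas))
      stop("subsample paths do not share a lambda grid")
  }
  M <- length(lambdas)
  p <- length(labels)
  acc <- matrix(0, M, p)
  for (pth in subpaths) acc <- acc + t(pth$coefficients != 0)
  pi <- acc / length(subpaths)
  dimnames(pi) <- list(NULL, labels)
  structure(list(pi = pi, lambdas = lambdas, labels = labels,
                 B = length(subpaths), pi_threshold = cfg$pi_threshold),
            class = "importance_profile")
}

#' Stable support at the bottom of the regularization path
#'
#' Components whose importance at `lambda_min` is at least `pi_threshold`
#' (inclusive).
#'
#' @param profile an `importance_profile`.
#' @param cfg a `stability_config`, or a numeric threshold.
#' @return Character vector of stable component labels.
#' @export
stable_support <- function(profile, cfg = stability_config()) {
  th <- if (is.numeric(cfg)) cfg else cfg$pi_threshold
  stopifnot(inherits(profile, "importance_profile"))
  last <- profile$pi[nrow(profile$pi), ]
  profile$labels[last >= th]
}

#' Least-squares refit on a fixed support
#'
#' Ordinary least squares of the response on the supported raw
#' (unstandardized) columns, so the coefficients carry physical units.
#'
#' @param system_raw a raw `design_system`.
#' @param support character vector of column labels.
#' @return Named coefficient vector over `support`.
#' @export
refit <- function(system_raw, support) {
  stopifnot(inherits(system_raw, "design_system"),
            !isTRUE(system_raw$standardized), length(support) >= 1)
  cols <- match(support, system_raw$labels)
  if (anyNA(cols))
    stop("unknown labels: ", paste(support[is.na(cols)], collapse = ", "))
  X <- system_raw$theta[, cols, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < length(cols)) {
    drop_idx <- qx$pivot[seq.int(qx$rank + 1L, length(cols))]
    stop("collinear columns in restricted design: ",
         paste(support[drop_idx], collapse = ", "))
  }
  stats::setNames(drop(qr.coef(qx, system_raw$ut)), support)
}

# Importance profile over a fixed lambda grid for a raw system. The
# hard-thresholding family runs entirely in compiled code (subsampling
# indices are still drawn in R so that subsample_systems() sees identical
# sets); other methods go through the per-subsample R path.
stability_profile <- function(system, solver, stability, grid,
                              labels = NULL) {
  if (is.null(labels)) labels <- setdiff(system$labels, "1")
  if (solver$method %in% c("iht", "iht_d")) {
    keep <- system$labels != "1"
    rows <- draw_subsample_rows(nrow(system$theta), stability)
    counts <- cpp_stability_counts(system$theta[, keep, drop = FALSE],
                                   system$ut, rows, grid$lambdas,
                                   solver$method == "iht_d",
                                   solver$max_iter, solver$tol,
                                   solver$debias_max_steps,
                                   solver$descent_monitor_c,
                                   solver$use_debias_bound,
                                   1e-4, 1e-3,
                                   solver$init == "ls",
                                   exact_debias(solver))
    pi <- counts / stability$B
    dimnames(pi) <- list(NULL, labels)
    structure(list(pi = pi, lambdas = grid$lambdas, labels = labels,
                   B = stability$B, pi_threshold = stability$pi_threshold),
              class = "importance_profile")
  } else {
    subs <- subsample_systems(system, stability)
    paths <- vector("list", length(subs))
    for (i in seq_along(subs)) {
      cfg_i <- solver
      cfg_i$seed <- derive_seed(stability$seed, i)
      paths[[i]] <- solve_path(subs[[i]], cfg_i, path = grid)
    }
    importance_profile(paths, stability)
  }
}

#' Stability-selection identification of a sparse dynamical model
#'
#' The full pipeline: standardize, build the shared lambda grid, draw `B`
#' random half-subsamples (each independently re-standardized), run the
#' configured sparse solver over the path on every subsample, aggregate
#' per-lambda supports into importance profiles, threshold the profile at
#' `lambda_min` to obtain the stable support, and refit the coefficients by
#' ordinary least squares on the raw columns over all rows.
#'
#' The shared grid is anchored at the full-system `lambda_max`; for the L1
#' family the grid is scaled by the subsample fraction, since the penalty
#' gradient grows with the number of rows, while the thresholding family's
#' `lambda` is row-scale invariant after the spectral-norm rescaling.
#'
#' If the dictionary contains a constant column it cannot survive
#' standardization; its effect is restored as the refit intercept and it is
#' reported as part of the stable support (label `"1"`).
#'
#' @param system a raw `design_system` from [build_design()].
#' @param solver a `solver_config`.
#' @param stability a `stability_config`.
#' @return A `selection_result`: list with `stable_support`, `coefficients`
#'   (refit, original units), `profile` (an `importance_profile`), `path`
#'   (the lambda grid), and the two configs.
#' @export
pde_stride <- function(system, solver = solver_config("iht_d"),
                       stability = stability_config()) {
  stopifnot(inherits(system, "design_system"), !isTRUE(system$standardized))
  std_full <- standardize(system)
  lam_top <- lambda_max(std_full, solver)
  if (lam_top <= 0) stop("degenerate system: lambda_max = 0")
  if (solver$method %in% c("lasso", "randomized_lasso"))
    lam_top <- lam_top * floor(nrow(system$theta) * stability$subsample_fraction) /
      nrow(system$theta)
  grid <- make_path(lam_top, epsilon = stability$epsilon, M = stability$M)
  profile <- stability_profile(system, solver, stability, grid,
                               labels = std_full$labels)
  sel <- stable_support(profile, stability)
  support <- c(if (system$include_constant) "1", sel)
  coefficients <- if (length(support)) refit(system, support) else
    stats::setNames(numeric(0), character(0))
  structure(list(stable_support = support, coefficients = coefficients,
                 profile = profile, path = grid,
                 solver = solver, stability = stability,
                 n = nrow(system$theta), p = ncol(system$theta)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> N = ", x$n, ", p = ", x$p,
      ", method = ", x$solver$method, "\n", sep = "")
  if (length(x$coefficients)) {
    cat("stable support:\n")
    for (lab in names(x$coefficients))
      cat(sprintf("  %-14s %+ .6g\n", lab, x$coefficients[[lab]]))
  } else {
    cat("stable support: (empty)\n")
  }
  invisible(x)
}
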