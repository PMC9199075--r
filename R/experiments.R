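#' Bundle a benchmark inference problem
#'
#' Couples a clean simulated field with a dictionary, the true support of
#' the generating equation, and the sampling protocol (region, stencil
#' margin, eligible frames). Used by the achievability harness and by the
#' recovery workflows.
#'
#' @param field clean `stf_field`.
#' @param spec a `dictionary_spec`.
#' @param truth character vector: the reported-support labels of the
#'   generating equation (including `"1"` when the dictionary has a constant
#'   column).
#' @param region optional sampling region (list of `c(lo, hi)` per spatial
#'   dimension).
#' @param margin optional stencil margin override for [sample_points()].
#' @param frames optional eligible frames override.
#' @param denoise apply truncated-SVD denoising (auto elbow) to noisy data
#'   before differentiation; clean data are never denoised.
#' @param solver the `solver_config` this workflow runs with by default.
#' @param solver_noisy optional `solver_config` used instead of `solver`
#'   whenever noise is present (some workflows switch the IHT-d
#'   initialization: the least-squares start is the right one for clean
#'   collinear designs but carries noise-driven coefficients into the
#'   support once the data are noisy).
#' @param name label used in printouts.
#' @return A `stride_problem`.
#' @export
stride_problem <- function(field, spec, truth, region = NULL, margin = NULL,
                           frames = NULL, denoise = TRUE,
                           solver = solver_config("iht_d"),
                           solver_noisy = NULL,
                           name = "problem") {
  stopifnot(inherits(field, "stf_field"), inherits(spec, "dictionary_spec"),
            length(truth) >= 1)
  structure(list(field = field, spec = spec, truth = truth, region = region,
                 margin = margin, frames = frames, denoise = denoise,
                 solver = solver, solver_noisy = solver_noisy, name = name),
            class = "stride_problem")
}

# The workflow's solver for a given noise level.
problem_solver <- function(problem, sigma) {
  if (sigma > 0 && !is.null(problem$solver_noisy)) problem$solver_noisy
  else problem$solver
}

#' 1-D Burgers inference problem
#' @param cfg a [burgers_config()].
#' @param field optional pre-computed clean field (re-used across sweeps).
#' @return A `stride_problem` with the 19-column dictionary and truth
#'   `{u u_x, u_xx}`.
#' @export
burgers_problem <- function(cfg = burgers_config(), field = NULL) {
  if (is.null(field)) field <- simulate_burgers(cfg)
  # clean data: the LS start gives consistent recovery at every sample
  # size; noisy data: the classical zero start (LS carries noise-driven
  # coefficients into the support)
  stride_problem(field, dictionary_spec_1d(),
                 truth = c("u*u_{x}", "u_{xx}"),
                 solver = solver_config("iht_d", init = "ls"),
                 solver_noisy = solver_config("iht_d", init = "zero"),
                 name = "burgers")
}

#' 2-D cavity vorticity inference problem
#' @param cfg a [cavity_config()].
#' @param field optional pre-computed clean field.
#' @return A `stride_problem` with the 48-column dictionary, truth
#'   `{w_xx, w_yy, u w_x, v w_y}`, and sampling restricted to the
#'   near-lid box `[0,1] x [0.6,1]`.
#' @export
cavity_problem <- function(cfg = cavity_config(), field = NULL) {
  if (is.null(field)) field <- simulate_cavity_vorticity(cfg)
  # the vorticity dictionary's diffusion pair (w_xx, w_yy) is strongly
  # anti-correlated with standardized coefficients far above the gradient
  # scale; the least-squares initialization is required to reach it
  stride_problem(field, dictionary_spec_vorticity(),
                 truth = c("w_{xx}", "w_{yy}", "u*w_{x}", "v*w_{y}"),
                 region = list(c(0, 1), c(0.6, 1)), margin = 2L,
                 solver = solver_config("iht_d", init = "ls"),
                 name = "cavity")
}

#' 3-D Gray-Scott inference problem
#' @param cfg a [gray_scott_config()].
#' @param field optional pre-computed clean field.
#' @param target species whose equation is inferred.
#' @return A `stride_problem` with the 69-column dictionary and sampling
#'   restricted to the dynamically active subcube `[1.0, 1.5]^3`.
#' @export
grayscott_problem <- function(cfg = gray_scott_config(), field = NULL,
                              target = c("u", "v")) {
  target <- match.arg(target)
  if (is.null(field)) field <- simulate_gray_scott(cfg)
  truth <- if (target == "u")
    c("1", "u", "u_{xx}", "u_{yy}", "u_{zz}", "u*v^2")
  else
    c("1", "v", "u*v^2", "v_{xx}", "v_{yy}", "v_{zz}")
  # like the cavity dictionary, the 69-column design couples collinear
  # blocks whose solution amplitudes exceed the gradient scale
  stride_problem(field, dictionary_spec_grayscott(target), truth = truth,
                 region = list(c(1, 1.5), c(1, 1.5), c(1, 1.5)),
                 solver = solver_config("iht_d", init = "ls"),
                 name = "grayscott")
}

#' Two-species protein-interaction inference problem
#' @param cfg a [par_ode_config()].
#' @param field optional pre-computed clean field.
#' @param target species whose kinetics are inferred (`"P"` or `"A"`).
#' @return A `stride_problem` with the 20-column reaction dictionary.
#' @export
par_problem <- function(cfg = par_ode_config(), field = NULL,
                        target = c("P", "A")) {
  target <- match.arg(target)
  if (is.null(field)) field <- simulate_par_ode(cfg)
  truth <- if (target == "P") c("1", "P", "A*P^2") else c("1", "A", "A^2*P")
  stride_problem(field, reaction_dictionary_spec(target = target),
                 truth = truth,
                 solver = solver_config("iht_d", init = "ls"),
                 name = "par")
}

# Build the (possibly noisy, possibly denoised) design for one trial.
problem_design <- function(problem, N, sigma = 0, seed = 0L) {
  field <- problem$field
  if (sigma > 0) {
    field <- add_noise(field, sigma, seed = derive_seed(seed, 1L))
    if (isTRUE(problem$denoise))
      field <- svd_denoise(field, rank_margin = 2,
                           smooth_windows = "auto")$field
  }
  samples <- sample_points(field, N, region = problem$region,
                           seed = derive_seed(seed, 2L),
                           margin = problem$margin, frames = problem$frames)
  build_design(field, problem$spec, samples)
}

#' Run the full stability-selection pipeline on a benchmark problem
#'
#' Convenience wrapper: corrupt (and denoise), sample, build the design and
#' run [pde_stride()].
#'
#' @param problem a `stride_problem`.
#' @param N sample size.
#' @param sigma noise level.
#' @param seed RNG seed.
#' @param solver a `solver_config`.
#' @param stability a `stability_config`.
#' @return A `selection_result`.
#' @export
run_problem <- function(problem, N, sigma = 0, seed = 0L,
                        solver = problem_solver(problem, sigma),
                        stability = stability_config(seed = seed)) {
  system <- problem_design(problem, N, sigma, seed)
  pde_stride(system, solver, stability)
}

# Importance profile without the refit step; shared by pde_stride-style
# success checks.
profile_for_system <- function(system, solver, stability) {
  std_full <- standardize(system)
  lam_top <- lambda_max(std_full, solver)
  if (solver$method %in% c("lasso", "randomized_lasso"))
    lam_top <- lam_top * floor(nrow(system$theta) * stability$subsample_fraction) /
      nrow(system$theta)
  grid <- make_path(lam_top, epsilon = stability$epsilon, M = stability$M)
  stability_profile(system, solver, stability, grid,
                    labels = std_full$labels)
}

#' One exact-support-recovery trial
#'
#' In `"stability"` mode the trial succeeds if there is a `lambda` on the
#' path at which the importance-thresholded component set equals the true
#' support exactly (no extras, no misses). In `"raw-path"` mode the solver
#' is run once on the full sampled system and the trial succeeds if some
#' per-lambda support equals the truth.
#'
#' @param problem a `stride_problem`.
#' @param N sample size.
#' @param sigma noise level.
#' @param method solver id.
#' @param mode `"stability"` or `"raw-path"`.
#' @param seed RNG seed (fresh sampling and noise per trial).
#' @param solver optional `solver_config` (method overridden).
#' @param stability a `stability_config`.
#' @return Logical.
#' @export
success_trial <- function(problem, N, sigma = 0, method = "iht_d",
                          mode = c("stability", "raw-path"), seed = 0L,
                          solver = NULL, stability = stability_config()) {
  mode <- match.arg(mode)
  truth_solver <- setdiff(problem$truth, "1")
  if (!all(truth_solver %in% problem$spec$labels)) return(FALSE)
  system <- problem_design(problem, N, sigma, seed)
  if (mode == "stability") {
    stab <- stability
    stab$seed <- derive_seed(seed, 3L)
    cfg <- if (is.null(solver)) problem_solver(problem, sigma) else solver
    cfg$method <- method
    profile <- profile_for_system(system, cfg, stab)
    th <- stab$pi_threshold
    for (m in seq_along(profile$lambdas)) {
      sel <- profile$labels[profile$pi[m, ] >= th]
      if (setequal(sel, truth_solver)) return(TRUE)
    }
    FALSE
  } else {
    cfg <- if (is.null(solver)) problem_solver(problem, sigma) else solver
    cfg$method <- method
    cfg$seed <- derive_seed(seed, 4L)
    std <- standardize(system)
    path <- solve_path(std, cfg)
    for (S in path$supports)
      if (setequal(std$labels[S], truth_solver)) return(TRUE)
    FALSE
  }
}

#' Success-frequency sweep over designs
#'
#' For every design point `(N, sigma, method, mode)` runs `reps` independent
#' recovery trials (fresh point sampling, fresh noise and fresh subsampling
#' per repetition, on seeds derived disjointly from the master seed) and
#' records the empirical success frequency together with the Bernoulli
#' variance `f (1 - f) / reps`.
#'
#' @param problem a `stride_problem`.
#' @param points data frame with columns `N` and optionally `sigma`,
#'   `method`, `mode` (recycled defaults `0`, `"iht_d"`, `"stability"`).
#' @param reps repetitions per design point.
#' @param seed master seed.
#' @param stability a `stability_config`.
#' @return An `achievability_result` data frame with columns `N, p, sigma,
#'   method, mode, reps, frequency, variance`.
#' @export
achievability_grid <- function(problem, points, reps = 20L, seed = 0L,
                               stability = stability_config()) {
  points <- as.data.frame(points)
  if (is.null(points$sigma)) points$sigma <- 0
  if (is.null(points$method)) points$method <- "iht_d"
  if (is.null(points$mode)) points$mode <- "stability"
  out <- points
  out$p <- dictionary_size(problem$spec)
  out$reps <- as.integer(reps)
  out$frequency <- NA_real_
  for (i in seq_len(nrow(points))) {
    succ <- 0L
    for (r in seq_len(reps)) {
      s <- derive_seed(seed, i * 100003L + r)
      succ <- succ + success_trial(problem, points$N[i], points$sigma[i],
                                   points$method[i], points$mode[i],
                                   seed = s, stability = stability)
    }
    out$frequency[i] <- succ / reps
  }
  out$variance <- out$frequency * (1 - out$frequency) / reps
  out <- out[, c("N", "p", "sigma", "method", "mode", "reps",
                 "frequency", "variance")]
  class(out) <- c("achievability_result", class(out))
  out
}

#' Empirical sample complexity from an achievability sweep
#'
#' The smallest sample size in the grid whose success frequency reaches
#' `level`.
#'
#' @param result an `achievability_result`.
#' @param level target success probability.
#' @return The smallest such `N`, or `NA` (with a warning) if the grid
#'   never crosses `level`.
#' @export
sample_complexity <- function(result, level = 0.9) {
  stopifnot(inherits(result, "achievability_result"))
  ok <- result$N[result$frequency >= level]
  if (!length(ok)) {
    warning("success frequency never reaches ", level, ": not reached")
    return(NA_real_)
  }
  min(ok)
}

#' Compare sparse-regression methods on raw regularization paths
#'
#' Runs [achievability_grid()] in `"raw-path"` mode for each method over the
#' same design points.
#'
#' @param problem a `stride_problem`.
#' @param points data frame with columns `N` and optionally `sigma`.
#' @param methods solver ids to compare.
#' @param reps repetitions per cell.
#' @param seed master seed.
#' @return An `achievability_result` covering all methods.
#' @export
method_comparison <- function(problem, points,
                              methods = c("randomized_lasso", "stridge",
                                          "iht_d", "omp"),
                              reps = 30L, seed = 0L) {
  points <- as.data.frame(points)
  grids <- lapply(methods, function(m) {
    pts <- points
    pts$method <- m
    pts$mode <- "raw-path"
    achievability_grid(problem, pts, reps = reps, seed = seed)
  })
  out <- do.call(rbind, grids)
  class(out) <- c("achievability_result", class(out))
  out
}
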