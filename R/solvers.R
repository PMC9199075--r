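#' Solver configuration
#'
#' Bundles the tunable parameters of the sparsity-promoting regression
#' family. `lambda` is interpreted per method: for the L1 family it is the
#' penalty weight of `0.5 ||Ut - Theta xi||^2 + lambda sum(|xi_k| / W_k)`;
#' for the hard-thresholding family it is the direct magnitude threshold of
#' the hard-thresholding operator (entries with `|x| <= lambda` are zeroed),
#' applied after the joint spectral-norm rescaling of the system; for
#' STRidge it is the magnitude threshold applied to ridge coefficients; for
#' OMP the path position maps to a sparsity level.
#'
#' @param method one of `"lasso"`, `"randomized_lasso"`, `"iht"`, `"iht_d"`,
#'   `"stridge"`, `"omp"`.
#' @param alpha weakness of the randomized LASSO: per-coefficient weights
#'   are i.i.d. Uniform\[alpha, 1\].
#' @param ridge_lambda ridge penalty of STRidge.
#' @param max_iter iteration cap of the iterative solvers.
#' @param tol convergence tolerance on the coefficient update.
#' @param debias_max_steps gradient-descent step cap of the IHT-d debias
#'   phase.
#' @param descent_monitor_c constant `c` of the residual descent monitor
#'   `||r_new||^2 < (1 - c) ||r_old||^2`.
#' @param use_debias_bound stop the debias phase early once
#'   `||r||^2 <= lambda |S|` instead of polishing the restricted
#'   least-squares refinement to tolerance (the default). The loose bound
#'   leaves a long plain-IHT convergence tail; the polished variant reaches
#'   the same supports far faster.
#' @param lambda_mode `"threshold"` (default; `lambda` is the direct
#'   hard-threshold level) or `"penalty"` (`lambda` is an L0 penalty weight,
#'   thresholded at `sqrt(2 lambda)`).
#' @param init starting point of the IHT/IHT-d iterations: `"zero"`
#'   (default; the classical iteration from the origin, with `lambda_max`
#'   anchored at the first gradient step) or `"ls"` (the ridge-stabilized
#'   least-squares solution — the debias-consistent start, needed when the
#'   sought solution has standardized coefficients far above the gradient
#'   scale, as for strongly collinear diffusion dictionaries).
#' @param seed RNG seed for the randomization weights.
#' @return A `solver_config` list.
#' @export
solver_config <- function(method = c("iht_d", "lasso", "randomized_lasso",
                                     "iht", "stridge", "omp"),
                          alpha = 0.2, ridge_lambda = 1e-5,
                          max_iter = 200L, tol = 1e-8,
                          debias_max_steps = 100L,
                          descent_monitor_c = 1e-6,
                          use_debias_bound = FALSE,
                          lambda_mode = c("threshold", "penalty"),
                          init = c("zero", "ls"),
                          seed = 0L) {
  method <- match.arg(method)
  lambda_mode <- match.arg(lambda_mode)
  init <- match.arg(init)
  stopifnot(alpha > 0, alpha <= 1, ridge_lambda >= 0,
            descent_monitor_c > 0, descent_monitor_c < 1)
  structure(list(method = method, alpha = alpha, ridge_lambda = ridge_lambda,
                 max_iter = as.integer(max_iter), tol = tol,
                 debias_max_steps = as.integer(debias_max_steps),
                 descent_monitor_c = descent_monitor_c,
                 use_debias_bound = use_debias_bound,
                 lambda_mode = lambda_mode, init = init,
                 seed = as.integer(seed)),
            class = "solver_config")
}

# Spectral-norm rescaling required by the hard-thresholding guarantees:
# Theta and Ut are jointly scaled by 1/(||Theta||_2 (1 + delta)) so that
# ||Theta||_2 < 1. Joint scaling leaves the least-squares coefficients
# unchanged, so no back-scaling of coefficients is needed; lambda for the
# thresholding family is interpreted in this rescaled space.
scaled_system <- function(system, delta = 1e-3) {
  stopifnot(isTRUE(system$standardized))
  ns <- cpp_spec_norm(system$theta)
  s <- if (ns >= 1 / (1 + delta)) 1 / (ns * (1 + delta)) else 1
  list(X = system$theta * s, y = system$ut * s, s = s)
}

# The LS-initialized variant refits the restricted least-squares problem
# exactly at each debias step (HTP-style); the classical zero-start variant
# keeps the printed gradient-descent debias.
exact_debias <- function(config) {
  config$init == "ls" && !config$use_debias_bound
}

iht_threshold <- function(lambda, config) {
  if (config$lambda_mode == "penalty") sqrt(2 * lambda) else lambda
}

#' Largest useful regularization value for a method
#'
#' The smallest `lambda` at which the method's solution has empty support:
#' for the L1 family `max_k |theta_k' Ut|`; for IHT/IHT-d, on the
#' spectral-norm rescaled system, the larger of the first-gradient-step
#' magnitude from zero and the largest entry of the initialization point
#' (so the first threshold empties the iterate); for STRidge the largest
#' absolute ridge coefficient (plus a hair, since entries strictly below
#' the threshold are zeroed).
#'
#' @param system a standardized `design_system`.
#' @param method solver id or a `solver_config`.
#' @param config optional `solver_config` (for STRidge's ridge penalty).
#' @return Positive scalar; 0 (with a warning) if the response is orthogonal
#'   to every column.
#' @export
lambda_max <- function(system, method = "iht_d", config = NULL) {
  if (inherits(method, "solver_config")) {
    config <- method
    method <- config$method
  }
  if (is.null(config)) config <- solver_config(method)
  stopifnot(isTRUE(system$standardized))
  if (all(system$ut == 0)) stop("zero response: lambda_max undefined")
  lm <- switch(method,
    lasso = ,
    randomized_lasso = ,
    omp = max(abs(crossprod(system$theta, system$ut))),
    iht = ,
    iht_d = {
      sc <- scaled_system(system)
      g0 <- max(abs(crossprod(sc$X, sc$y)))
      if (config$init == "ls")
        max(g0, max(abs(cpp_ridge_init(sc$X, sc$y))) * (1 + 1e-6))
      else g0
    },
    stridge = {
      b <- ridge_solve(system$theta, system$ut, config$ridge_lambda)
      max(abs(b)) * (1 + 1e-6)
    },
    stop("unknown method: ", method))
  if (lm <= 1e-10 * sqrt(mean(system$ut^2))) {
    warning("response orthogonal to all columns: lambda_max = 0 (degenerate)")
    lm <- 0
  }
  lm
}

#' Geometric regularization-path grid
#'
#' `M` values spaced geometrically from `lambda_max` down to
#' `epsilon * lambda_max`.
#'
#' @param lambda_max top of the path (positive).
#' @param epsilon ratio `lambda_min / lambda_max`.
#' @param M path size (at least 2).
#' @return A `reg_path` skeleton: list with `lambdas`, `lambda_max`,
#'   `lambda_min`, `epsilon`; `supports`/`coefficients` filled by
#'   [solve_path()].
#' @export
make_path <- function(lambda_max, epsilon = 0.1, M = 20L) {
  if (M < 2) stop("path size M must be at least 2")
  stopifnot(lambda_max > 0, epsilon > 0, epsilon < 1)
  lambdas <- lambda_max * epsilon^((seq_len(M) - 1) / (M - 1))
  structure(list(lambdas = lambdas, lambda_max = lambda_max,
                 lambda_min = epsilon * lambda_max, epsilon = epsilon,
                 supports = NULL, coefficients = NULL),
            class = "reg_path")
}

#' Uniform randomization weights for the randomized LASSO
#'
#' @param p number of weights.
#' @param alpha weakness; weights are i.i.d. Uniform\[alpha, 1\].
#' @param seed RNG seed.
#' @return Numeric vector of length `p`.
#' @export
draw_randomization_weights <- function(p, alpha, seed = 0L) {
  stopifnot(alpha > 0, alpha <= 1)
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  stats::runif(p, min = alpha, max = 1)
}

#' LASSO / randomized-LASSO fit at one penalty value
#'
#' Cyclical coordinate descent for
#' `0.5 ||Ut - Theta xi||^2 + lambda sum(|xi_k| / W_k)`.
#'
#' @param system a standardized `design_system`.
#' @param lambda penalty value.
#' @param weights optional per-column weights `W_k` in (0, 1\]; all 1 gives
#'   the plain LASSO.
#' @param config a `solver_config`.
#' @return Named coefficient vector (standardized scale).
#' @export
fit_lasso <- function(system, lambda, weights = NULL,
                      config = solver_config("lasso")) {
  stopifnot(isTRUE(system$standardized), lambda >= 0)
  p <- ncol(system$theta)
  pen <- if (is.null(weights)) rep(1, p) else {
    stopifnot(length(weights) == p, all(weights > 0), all(weights <= 1))
    1 / weights
  }
  fit <- cpp_cd_lasso(system$theta, system$ut, lambda, pen,
                      rep(0, p), config$max_iter, config$tol)
  if (!fit$converged)
    warning("coordinate descent did not converge in ", config$max_iter,
            " sweeps; returning best iterate")
  stats::setNames(drop(fit$beta), system$labels)
}

#' Iterative hard thresholding at one threshold value
#'
#' Iterates `xi <- H_lambda(xi + Theta'(Ut - Theta xi))` from zero on the
#' spectral-norm rescaled system, with the residual descent monitor.
#'
#' @inheritParams fit_lasso
#' @return Named coefficient vector (standardized scale).
#' @export
fit_iht <- function(system, lambda, config = solver_config("iht")) {
  sc <- scaled_system(system)
  b0 <- if (config$init == "ls") cpp_ridge_init(sc$X, sc$y) else
    rep(0, ncol(sc$X))
  fit <- cpp_iht(sc$X, sc$y, iht_threshold(lambda, config),
                 b0, config$max_iter, config$tol,
                 config$descent_monitor_c)
  if (fit$monitor_stop)
    warning("descent monitor violated; returning last monotone iterate")
  stats::setNames(drop(fit$beta), system$labels)
}

#' Iterative hard thresholding with debiasing at one threshold value
#'
#' Each outer iteration applies the IHT gradient-plus-threshold step, then
#' refines the coefficients on the extracted support by gradient descent on
#' the restricted least-squares problem (step size `1/||Theta_S||_2^2`)
#' until `||Ut - Theta xi||^2 <= lambda |S|` or the step cap is hit.
#'
#' @inheritParams fit_lasso
#' @return Named coefficient vector (standardized scale).
#' @export
fit_iht_d <- function(system, lambda, config = solver_config("iht_d")) {
  sc <- scaled_system(system)
  b0 <- if (config$init == "ls") cpp_ridge_init(sc$X, sc$y) else
    rep(0, ncol(sc$X))
  fit <- cpp_iht_d(sc$X, sc$y, iht_threshold(lambda, config),
                   b0, config$max_iter, config$tol,
                   config$debias_max_steps, config$descent_monitor_c,
                   config$use_debias_bound, 1e-4,
                   exact_debias(config))
  if (fit$monitor_stop)
    warning("descent monitor violated; returning last monotone iterate")
  stats::setNames(drop(fit$beta), system$labels)
}

ridge_solve <- function(X, y, ridge_lambda) {
  p <- ncol(X)
  drop(solve(crossprod(X) + diag(ridge_lambda, p), crossprod(X, y)))
}

#' Sequential threshold ridge regression (STRidge) at one threshold
#'
#' Alternates a ridge solve on the active columns with zeroing of
#' coefficients whose magnitude falls below `lambda`, until the active set
#' is fixed.
#'
#' @inheritParams fit_lasso
#' @return Named coefficient vector (standardized scale).
#' @export
fit_stridge <- function(system, lambda, config = solver_config("stridge")) {
  stopifnot(isTRUE(system$standardized), lambda >= 0)
  X <- system$theta; y <- system$ut
  p <- ncol(X)
  active <- rep(TRUE, p)
  beta <- rep(0, p)
  repeat {
    beta[] <- 0
    if (!any(active)) break
    beta[active] <- ridge_solve(X[, active, drop = FALSE], y,
                                config$ridge_lambda)
    keep <- abs(beta) >= lambda & active
    if (identical(keep, active)) break
    active <- keep
  }
  beta[!active] <- 0
  stats::setNames(beta, system$labels)
}

#' Orthogonal matching pursuit at a fixed sparsity level
#'
#' Greedy selection of the column most correlated with the residual,
#' followed by a restricted least-squares refit, repeated `k` times. Ties
#' break to the lowest column index.
#'
#' @param system a standardized `design_system`.
#' @param k sparsity level (number of columns to select).
#' @return Named coefficient vector (standardized scale).
#' @export
fit_omp <- function(system, k) {
  stopifnot(isTRUE(system$standardized), k >= 0)
  X <- system$theta; y <- system$ut
  p <- ncol(X)
  k <- min(as.integer(k), p, nrow(X))
  beta <- rep(0, p)
  S <- integer(0)
  r <- y
  for (step in seq_len(k)) {
    corr <- abs(drop(crossprod(X, r)))
    corr[S] <- -Inf
    j <- which.max(corr)
    S <- c(S, j)
    bs <- qr.coef(qr(X[, S, drop = FALSE]), y)
    bs[is.na(bs)] <- 0
    r <- y - X[, S, drop = FALSE] %*% bs
  }
  if (length(S)) beta[S] <- bs
  stats::setNames(beta, system$labels)
}

#' Solve a full regularization path
#'
#' Runs the configured method at every value of a descending geometric
#' lambda grid, warm-starting each fit from the previous one, and records
#' per-lambda supports and coefficients. For OMP the grid position maps to
#' the sparsity level (0 at `lambda_max`, increasing by 1 per grid point).
#'
#' @param system a standardized `design_system`.
#' @param config a `solver_config`.
#' @param path optional `reg_path` skeleton from [make_path()]; built from
#'   [lambda_max()] with defaults if omitted.
#' @param epsilon,M path parameters used when `path` is omitted.
#' @return The completed `reg_path`: `coefficients` is a p x M matrix,
#'   `supports` a list of integer index vectors.
#' @export
solve_path <- function(system, config = solver_config("iht_d"),
                       path = NULL, epsilon = 0.1, M = 20L) {
  stopifnot(isTRUE(system$standardized))
  if (is.null(path))
    path <- make_path(lambda_max(system, config), epsilon = epsilon, M = M)
  lambdas <- path$lambdas
  p <- ncol(system$theta)
  coefs <- switch(config$method,
    lasso = cpp_lasso_path(system$theta, system$ut, lambdas, rep(1, p),
                           config$max_iter, config$tol),
    randomized_lasso = {
      w <- draw_randomization_weights(p, config$alpha, config$seed)
      cpp_lasso_path(system$theta, system$ut, lambdas, 1 / w,
                     config$max_iter, config$tol)
    },
    iht = {
      sc <- scaled_system(system)
      cpp_iht_path(sc$X, sc$y,
                   vapply(lambdas, iht_threshold, 0, config = config),
                   config$max_iter, config$tol, config$descent_monitor_c,
                   config$init == "ls")
    },
    iht_d = {
      sc <- scaled_system(system)
      cpp_iht_d_path(sc$X, sc$y,
                     vapply(lambdas, iht_threshold, 0, config = config),
                     config$max_iter, config$tol, config$debias_max_steps,
                     config$descent_monitor_c, config$use_debias_bound,
                     1e-4, config$init == "ls",
                     exact_debias(config))
    },
    stridge = vapply(lambdas, function(l)
      fit_stridge(system, l, config), numeric(p)),
    omp = vapply(seq_along(lambdas) - 1L, function(k)
      fit_omp(system, k), numeric(p)),
    stop("unknown method: ", config$method))
  rownames(coefs) <- system$labels
  path$coefficients <- coefs
  path$supports <- lapply(seq_len(ncol(coefs)),
                          function(m) which(unname(coefs[, m]) != 0))
  path$labels <- system$labels
  path$method <- config$method
  path
}

#' @export
print.reg_path <- function(x, ...) {
  cat("<reg_path> M = ", length(x$lambdas),
      ", lambda in [", signif(x$lambda_min, 4), ", ",
      signif(x$lambda_max, 4), "]",
      if (!is.null(x$method)) paste0(", method = ", x$method), "\n", sep = "")
  invisible(x)
}
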