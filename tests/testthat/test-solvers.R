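orthonormal_system <- function(n = 32, p = 6, seed = 3) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(Q) <- paste0("q", seq_len(p))
  beta <- c(3, -2, 1, 0, 0, 0)[seq_len(p)]
  y <- drop(Q %*% beta)
  # bypass standardization: columns are orthonormal by construction
  make_system(Q, y, standardized = TRUE)
}

test_that("lambda_max conventions mark the edge of the empty model", {
  sys <- orthonormal_system()
  expect_error(lambda_max(make_system(sys$theta, rep(0, 32),
                                      standardized = TRUE)), "zero response")
  # response orthogonal to all columns: degenerate zero with a warning
  y_perp <- qr.resid(qr(sys$theta), rnorm(32))
  expect_warning(
    lm0 <- lambda_max(make_system(sys$theta, y_perp, standardized = TRUE),
                      "lasso"),
    "degenerate")
  expect_equal(lm0, 0)

  # single column with theta'Ut = 2 and ||theta|| < 1: one gradient step
  # from zero gives coefficient 2, so lambda_max is exactly 2
  th <- matrix(0.6 * c(1, rep(0, 9)), ncol = 1)
  y <- rep(0, 10); y[1] <- 2 / 0.6
  one <- make_system(th, y, standardized = TRUE)
  expect_equal(lambda_max(one, "iht_d"), 2, tolerance = 1e-9)

  # LASSO boundary: all-zero just above lambda_max, active just below
  sysb <- orthonormal_system()
  lmx <- lambda_max(sysb, "lasso")
  expect_equal(max(abs(fit_lasso(sysb, 1.01 * lmx))), 0)
  expect_gt(max(abs(fit_lasso(sysb, 0.99 * lmx))), 0)
})

test_that("the regularization grid is geometric with exact endpoints", {
  p2 <- make_path(1, epsilon = 0.1, M = 2)
  expect_equal(p2$lambdas, c(1, 0.1))
  p20 <- make_path(5, epsilon = 0.1, M = 20)
  expect_identical(length(p20$lambdas), 20L)
  ratios <- p20$lambdas[-1] / p20$lambdas[-20]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_lt(max(abs(diff(diff(log10(p20$lambdas))))), 1e-12)
  expect_error(make_path(1, M = 1), "at least 2")
})

test_that("LASSO matches the soft-threshold closed form on orthonormal designs", {
  sys <- orthonormal_system()
  z <- unname(drop(crossprod(sys$theta, sys$ut)))
  for (lam in c(0.5, 1.5, 2.5)) {
    expected <- sign(z) * pmax(abs(z) - lam, 0)
    got <- fit_lasso(sys, lam, config = solver_config("lasso", tol = 1e-12))
    expect_equal(unname(got), expected, tolerance = 1e-8)
  }
  # unit weights are a no-op
  expect_equal(fit_lasso(sys, 1, weights = rep(1, 6)), fit_lasso(sys, 1))
})

test_that("coordinate descent agrees with glmnet and satisfies KKT", {
  skip_if_not_installed("glmnet")
  d <- random_sparse_system(80, 10, 3, seed = 9)
  sys <- d$system
  n <- nrow(sys$theta)
  lam <- 0.25 * lambda_max(sys, "lasso")
  ours <- fit_lasso(sys, lam, config = solver_config("lasso", tol = 1e-12,
                                                     max_iter = 5000))
  gn <- glmnet::glmnet(sys$theta, sys$ut, lambda = lam / n,
                       standardize = FALSE, intercept = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(ours), as.numeric(gn$beta), tolerance = 1e-6)
  # KKT: |theta_k' r| <= lam (active columns at equality)
  r <- sys$ut - sys$theta %*% ours
  g <- abs(drop(crossprod(sys$theta, r)))
  expect_true(all(g <= lam * (1 + 1e-6)))
  expect_true(all(abs(g[ours != 0] - lam) < 1e-6 * lam))
})

test_that("randomization weights are Uniform[alpha, 1]", {
  expect_equal(draw_randomization_weights(50, alpha = 1), rep(1, 50))
  w <- draw_randomization_weights(1e5, alpha = 0.2, seed = 2)
  expect_true(all(w >= 0.2 & w <= 1))
  expect_equal(mean(w), 0.6, tolerance = 0.01)
  expect_equal(stats::sd(w), 0.8 / sqrt(12), tolerance = 0.01)
  expect_identical(w, draw_randomization_weights(1e5, alpha = 0.2, seed = 2))
})

test_that("IHT thresholding behaves at the extremes", {
  sys <- orthonormal_system()
  lmx <- lambda_max(sys, "iht")
  expect_equal(max(abs(fit_iht(sys, 1.01 * lmx))), 0)
  # lambda = 0: Landweber iteration towards the least-squares solution
  ls <- qr.coef(qr(sys$theta), sys$ut)
  got <- fit_iht(sys, 0, config = solver_config("iht", max_iter = 5000,
                                                tol = 1e-12))
  expect_equal(unname(got), unname(ls), tolerance = 1e-4)
})

test_that("IHT-d recovers planted sparse supports", {
  hits <- 0L
  for (i in 1:20) {
    d <- random_sparse_system(60, 8, 2, seed = 100 + i)
    lam <- 0.3 * lambda_max(d$system, "iht_d")
    b <- fit_iht_d(d$system, lam)
    if (setequal(which(b != 0), d$support)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("IHT-d debias equals restricted least squares when run to tolerance", {
  d <- random_sparse_system(60, 8, 2, seed = 41)
  sys <- d$system
  lam <- 0.3 * lambda_max(sys, "iht_d")
  cfg <- solver_config("iht_d", use_debias_bound = FALSE,
                       debias_max_steps = 5000, tol = 1e-10)
  b <- fit_iht_d(sys, lam, cfg)
  S <- which(b != 0)
  ls <- qr.coef(qr(sys$theta[, S, drop = FALSE]), sys$ut)
  expect_equal(unname(b[S]), unname(ls), tolerance = 1e-5)
  # threshold above lambda_max: empty support, debias skipped
  expect_equal(max(abs(fit_iht_d(sys, 1.01 * lambda_max(sys, "iht_d")))), 0)
})

test_that("STRidge matches an independently coded threshold-refit trace", {
  d <- random_sparse_system(50, 7, 2, seed = 13)
  sys <- d$system
  lamR <- 1e-5
  oracle <- function(lam) {
    active <- rep(TRUE, 7); b <- numeric(7)
    repeat {
      b[] <- 0
      Xa <- sys$theta[, active, drop = FALSE]
      b[active] <- solve(crossprod(Xa) + diag(lamR, sum(active)),
                         crossprod(Xa, sys$ut))
      keep <- abs(b) >= lam & active
      if (identical(keep, active)) break
      active <- keep
      if (!any(active)) break
    }
    b * as.numeric(active)
  }
  for (lam in c(0.05, 0.3, 1)) {
    expect_equal(unname(fit_stridge(sys, lam)), oracle(lam), tolerance = 1e-10)
  }
  # lambda = 0: the plain ridge solution on the full support
  full <- solve(crossprod(sys$theta) + diag(lamR, 7),
                crossprod(sys$theta, sys$ut))
  expect_equal(unname(fit_stridge(sys, 0)), unname(drop(full)),
               tolerance = 1e-10)
  # threshold above every ridge coefficient: empty after one pass
  expect_equal(max(abs(fit_stridge(sys, 10 * max(abs(full))))), 0)
})

test_that("OMP greedy selection is exact in canonical cases", {
  sys <- orthonormal_system()
  b1 <- fit_omp(sys, 1)
  expect_identical(which(b1 != 0),
                   which.max(abs(drop(crossprod(sys$theta, sys$ut)))))
  expect_equal(max(abs(fit_omp(sys, 0))), 0)
  d <- random_sparse_system(80, 8, 2, snr = Inf, seed = 21)
  b2 <- fit_omp(d$system, 2)
  expect_setequal(which(b2 != 0), d$support)
})

test_that("paths start empty and grow monotonically where theory says so", {
  sys <- orthonormal_system()
  for (m in c("lasso", "iht_d", "stridge", "omp")) {
    pth <- solve_path(sys, solver_config(m))
    expect_identical(pth$supports[[1]], integer(0))
  }
  pl <- solve_path(sys, solver_config("lasso"))
  sizes <- lengths(pl$supports)
  expect_true(all(diff(sizes) >= 0))    # soft-threshold monotonicity
})

test_that("solvers are pure functions of their inputs", {
  d <- random_sparse_system(40, 6, 2, seed = 77)
  lam <- 0.3 * lambda_max(d$system, "iht_d")
  expect_identical(fit_iht_d(d$system, lam), fit_iht_d(d$system, lam))
  cfg <- solver_config("randomized_lasso", seed = 5)
  p1 <- solve_path(d$system, cfg)
  p2 <- solve_path(d$system, cfg)
  expect_identical(p1$coefficients, p2$coefficients)
})

test_that("the IHT objective is non-increasing across accepted iterations", {
  # Lemma-style check: with ||Theta||_2 < 1 the L0 objective never rises
  d <- random_sparse_system(50, 8, 3, seed = 55)
  sc <- pdestride:::scaled_system(d$system)
  lam <- 0.3 * max(abs(crossprod(sc$X, sc$y)))
  obj <- function(b) 0.5 * sum((sc$y - sc$X %*% b)^2) + lam^2 / 2 * sum(b != 0)
  b <- rep(0, 8)
  prev <- obj(b)
  for (i in 1:50) {
    bn <- b + drop(crossprod(sc$X, sc$y - sc$X %*% b))
    bn[abs(bn) <= lam] <- 0
    cur <- obj(bn)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
    b <- bn
  }
})
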