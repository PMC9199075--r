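test_that("Burgers solution honours the initial condition and grid", {
  f <- burgers_field()
  expect_identical(dim(f$values$u), c(1000L, 256L))
  x <- f$extent[[1]][1] + (0:255) * f$dx
  i <- which.min(abs(x + 2))
  expect_equal(f$values$u[1, i], exp(-(x[i] + 2)^2))
  expect_equal(f$values$u[1, i], 1.0)           # exp(0) at x = -2
  expect_true(all(is.finite(f$values$u)))
})

test_that("Burgers conservative advection preserves discrete mass", {
  f <- burgers_field()
  mass <- rowSums(f$values$u) * f$dx
  expect_lt(max(abs(mass - mass[1])), 1e-10)
})

test_that("pure diffusion off and constant state stays constant", {
  cfg <- burgers_config(D = 0, nx = 32L, nt = 5L, dt = 0.01, u0 = rep(0.7, 32))
  f <- simulate_burgers(cfg)
  expect_equal(f$values$u[5, ], rep(0.7, 32))
})

test_that("Burgers converges under grid refinement", {
  # fixed final time, dt scaled with dx^2 so spatial error dominates
  t_end <- 1
  run <- function(nx) {
    dt <- 0.2 * (16 / nx)^2 / 0.1
    nt <- round(t_end / dt) + 1L
    simulate_burgers(burgers_config(nx = nx, nt = nt, dt = t_end / (nt - 1L)))
  }
  ref <- run(512L)
  err <- vapply(c(64L, 128L), function(nx) {
    f <- run(nx)
    sub <- ref$values$u[nrow(ref$values$u), seq(1, 512, by = 512 / nx)]
    sqrt(mean((f$values$u[nrow(f$values$u), ] - sub)^2))
  }, 0)
  expect_gt(err[1] / err[2], 2)   # order >= 1
})

test_that("quiescent cavity stays quiescent and lid-driven flow is consistent", {
  still <- simulate_cavity_vorticity(
    cavity_config(n = 32L, dt = 2e-3, t_final = 0.1,
                  snapshot_times = c(0.05, 0.08), lid_velocity = 0))
  expect_equal(max(abs(still$values$w)), 0)

  f <- cavity_field()
  u <- f$values$u[1, , ]; v <- f$values$v[1, , ]; w <- f$values$w[1, , ]
  n <- dim(u)[1]; dx <- f$dx[1]
  ii <- 3:(n - 2)
  div <- (u[ii + 1, ii] - u[ii - 1, ii]) / (2 * dx) +
    (v[ii, ii + 1] - v[ii, ii - 1]) / (2 * dx)
  expect_lt(max(abs(div)), 1e-10)
  # curl of the returned velocities reproduces the vorticity up to
  # discretization error; compare away from the sharp wall layers
  jj <- 20:(n - 19)
  curl <- (v[jj + 1, jj] - v[jj - 1, jj]) / (2 * dx) -
    (u[jj, jj + 1] - u[jj, jj - 1]) / (2 * dx)
  expect_lt(median(abs(curl - w[jj, jj])), 0.05 * stats::sd(w[jj, jj]))
})

test_that("Gray-Scott degenerate dynamics are exactly stationary", {
  # all rates and diffusivities zero from the uniform state u=1, v=0
  cfg <- gray_scott_config(Du = 0, Dv = 0, f = 0, k = 0, n = 8L,
                           t_final = 0.05, save_times = c(0.01, 0.04),
                           pair_lag = 1L, perturb_amplitude = 0)
  f <- simulate_gray_scott(cfg)
  expect_equal(f$values$u[1, , , ], f$values$u[4, , , ])
  expect_equal(f$values$v[1, , , ], f$values$v[4, , , ])

  # zero perturbation amplitude keeps the uniform steady state
  cfg2 <- gray_scott_config(n = 8L, t_final = 0.05, save_times = c(0.04),
                            pair_lag = 1L, perturb_amplitude = 0)
  f2 <- simulate_gray_scott(cfg2)
  expect_equal(max(abs(f2$values$u - 1)), 0)
  expect_equal(max(abs(f2$values$v)), 0)
})

test_that("Gray-Scott step satisfies the discrete mass budget", {
  # periodic diffusion conserves mass exactly: the change of total u over
  # one step equals dt * sum of the reaction + feed terms
  cfg <- gray_scott_config(n = 12L, dt = 1e-3, t_final = 2e-3,
                           save_times = 0, pair_lag = 1L, seed = 4)
  f <- simulate_gray_scott(cfg)
  u0 <- f$values$u[1, , , ]; v0 <- f$values$v[1, , , ]
  u1 <- f$values$u[2, , , ]; v1 <- f$values$v[2, , , ]
  du_pred <- cfg$dt * sum(-u0 * v0^2 + cfg$f * (1 - u0))
  dv_pred <- cfg$dt * sum(u0 * v0^2 - (cfg$f + cfg$k) * v0)
  expect_equal(sum(u1 - u0), du_pred, tolerance = 1e-9)
  expect_equal(sum(v1 - v0), dv_pred, tolerance = 1e-9)
})

test_that("Gray-Scott concentrations stay within physical bounds", {
  f <- grayscott_field()
  expect_true(all(f$values$u >= -1e-6 & f$values$u <= 1 + 1e-3))
  expect_true(all(f$values$v >= -1e-6 & f$values$v <= 1 + 1e-3))
})

test_that("protein-interaction kinetics match the printed rate constants", {
  # with both species zero the initial rates are the bare source constants
  cfg <- par_ode_config(nx = 4L, nt = 2L, dt = 1, substeps = 10L,
                        A0 = rep(0, 4), P0 = rep(0, 4))
  f <- simulate_par_ode(cfg)
  h <- cfg$dt / cfg$substeps
  dP0 <- (f$values$P[2, 1] - f$values$P[1, 1]) / h
  dA0 <- (f$values$A[2, 1] - f$values$A[1, 1]) / h
  expect_equal(dP0, -1.98e-4, tolerance = 1e-12)
  expect_equal(dA0, 4.13e-3, tolerance = 1e-12)

  # all six coefficients zero: state frozen
  cfg0 <- par_ode_config(cP = 0, cA = 0, kP = 0, kA = 0, kPA = 0, kAP = 0,
                         nx = 4L, nt = 3L)
  f0 <- simulate_par_ode(cfg0)
  expect_equal(f0$values$A[1, ], f0$values$A[5, ])
  expect_equal(f0$values$P[1, ], f0$values$P[5, ])
})

test_that("one explicit Euler substep matches hand-computed arithmetic", {
  cfg <- par_ode_config(nx = 2L, nt = 2L, dt = 1, substeps = 1L,
                        A0 = c(2, 2), P0 = c(3, 3))
  f <- simulate_par_ode(cfg)
  dP <- cfg$cP + cfg$kP * 3 + cfg$kPA * 2 * 9
  dA <- cfg$cA + cfg$kA * 2 + cfg$kAP * 3 * 4
  expect_equal(f$values$P[2, 1], 3 + dP, tolerance = 1e-14)
  expect_equal(f$values$A[2, 1], 2 + dA, tolerance = 1e-14)
})

test_that("additive noise follows the variance-scaled model", {
  f <- burgers_field()
  expect_identical(add_noise(f, 0), f)

  nf1 <- add_noise(f, 0.04, seed = 5)
  nf2 <- add_noise(f, 0.04, seed = 5)
  expect_identical(nf1$values$u, nf2$values$u)     # seeded reproducibility
  expect_identical(nf1$dx, f$dx)
  expect_identical(nf1$times, f$times)

  eps <- nf1$values$u - f$values$u
  expect_equal(stats::sd(eps), 0.04 * stats::sd(f$values$u),
               tolerance = 0.05)                    # LLN at 256k points
  nf3 <- add_noise(f, 0.04, seed = 6)
  expect_false(identical(nf1$values$u, nf3$values$u))
})
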