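make_lowrank_field <- function(nt = 40, nx = 30, r = 3, d = c(5, 2, 1),
                               noise = 0, seed = 2) {
  set.seed(seed)
  tt <- seq(0, 1, length.out = nt)
  xx <- seq(0, 1, length.out = nx)
  U <- sapply(seq_len(r), function(k) sin(pi * k * tt) + 0.3 * k)
  V <- sapply(seq_len(r), function(k) cos(pi * k * xx))
  M <- U %*% (d[seq_len(r)] * t(V)) + matrix(rnorm(nt * nx, sd = noise), nt)
  stf_field(values = list(u = M), dx = 1 / nx, times = tt,
            extent = list(c(0, 1)), boundary = "periodic")
}

test_that("truncated SVD reproduces exactly low-rank data", {
  f <- make_lowrank_field(r = 1, d = 5)
  den <- svd_denoise(f, rank = 1)
  expect_equal(den$field$values$u, f$values$u, tolerance = 1e-12)
  expect_identical(den$reports$u$method, "fixed-rank")
  expect_identical(den$reports$u$rank_kept, 1L)
})

test_that("the elbow rule finds the rank of noisy low-rank data", {
  f <- make_lowrank_field(r = 3, noise = 1e-3)
  den <- svd_denoise(f)
  expect_identical(den$reports$u$rank_kept, 3L)
  err <- stats::sd(den$field$values$u - make_lowrank_field(r = 3)$values$u)
  expect_lt(err, 1e-3)        # reconstruction error below the noise floor
})

test_that("fixed rank one reproduces the leading-mode convention", {
  f <- par_field()
  den <- svd_denoise(f, rank = 1)
  expect_identical(den$reports$A$rank_kept, 1L)
  M <- matrix(den$field$values$A, nrow = dim(f$values$A)[1])
  expect_identical(qr(M)$rank, 1L)
})

test_that("denoising an all-zero variable is rejected", {
  f <- make_lowrank_field()
  f$values$u[] <- 0
  expect_error(svd_denoise(f), "all-zero")
})

test_that("forward time differences are first-order exact and marked invalid", {
  nt <- 11
  tt <- seq(0, 1, length.out = nt)
  lin <- stf_field(values = list(u = matrix(3 * tt, nt, 4)), dx = 0.25,
                   times = tt, extent = list(c(0, 1)), boundary = "periodic")
  d <- time_derivative(lin)
  expect_equal(d$values[1:(nt - 1), ], matrix(3, nt - 1, 4))
  expect_true(all(is.na(d$values[nt, ])))

  quad <- stf_field(values = list(u = matrix(c(0, 1)^2, 2, 3)), dx = 1 / 3,
                    times = c(0, 1), extent = list(c(0, 1)),
                    boundary = "periodic")
  expect_equal(time_derivative(quad)$values[1, 1], 1.0)  # (1 - 0)/1, not 0

  one <- stf_field(values = list(u = matrix(1, 1, 4)), dx = 0.25,
                   times = 0, extent = list(c(0, 1)), boundary = "periodic",
                   anchor_frames = integer(0))
  expect_error(time_derivative(one), "two frames")
})

test_that("time-derivative error halves when dt halves", {
  err <- vapply(c(50, 100), function(nt) {
    tt <- seq(0, 1, length.out = nt)
    f <- stf_field(values = list(u = matrix(exp(tt), nt, 2)), dx = 0.5,
                   times = tt, extent = list(c(0, 1)), boundary = "periodic")
    d <- time_derivative(f)
    max(abs(d$values[1:(nt - 1), 1] - exp(tt[1:(nt - 1)])))
  }, 0)
  expect_equal(err[1] / err[2], 2, tolerance = 0.15)
})

test_that("central spatial derivatives are exact on polynomials", {
  nx <- 21
  x <- seq(0, 2, length.out = nx)
  f <- stf_field(values = list(u = matrix(x^2, 2, nx, byrow = TRUE)),
                 dx = x[2] - x[1], times = c(0, 1),
                 extent = list(c(0, 2 + x[2] - x[1])), boundary = "periodic")
  f$boundary <- "dirichlet-noslip"
  f$extent <- list(c(0, 2))
  d2 <- spatial_derivative(f, axis = 1, order = 2)
  expect_equal(d2$values[1, 2:(nx - 1)], rep(2, nx - 2), tolerance = 1e-9)
  expect_true(all(is.na(d2$values[, c(1, nx)])))

  const <- f
  const$values$u[] <- 5
  for (ord in 1:4)
    expect_equal(max(abs(spatial_derivative(const, 1, ord)$values),
                     na.rm = TRUE), 0)
  expect_error(spatial_derivative(f, 1, 5), "order")
})

test_that("spatial derivative converges at second order on periodic data", {
  err <- vapply(c(64, 128), function(nx) {
    x <- 2 * pi * (0:(nx - 1)) / nx
    f <- stf_field(values = list(u = matrix(sin(x), 1, nx, byrow = TRUE)),
                   dx = 2 * pi / nx, times = 0,
                   extent = list(c(0, 2 * pi)), boundary = "periodic",
                   anchor_frames = integer(0))
    d <- spatial_derivative(f, 1, 1)
    max(abs(d$values[1, ] - cos(x)))
  }, 0)
  expect_equal(err[1] / err[2], 4, tolerance = 0.2)   # halving dx quarters it
})

test_that("sampling is uniform over the eligible set and reproducible", {
  f <- make_lowrank_field(nt = 10, nx = 12)
  all_pts <- sample_points(f, n = 9 * 12, seed = 1)    # every eligible point
  expect_identical(nrow(all_pts), 108L)
  expect_identical(anyDuplicated(all_pts), 0L)
  expect_true(all(all_pts[, "frame"] <= 9))            # last frame excluded

  s1 <- sample_points(f, 20, seed = 7)
  s2 <- sample_points(f, 20, seed = 7)
  expect_identical(s1, s2)
  expect_error(sample_points(f, 109, seed = 1), "eligible")
})

test_that("region and margin constraints are honoured", {
  fg <- grayscott_field()
  s <- sample_points(fg, 200, region = list(c(1, 1.5), c(1, 1.5), c(1, 1.5)),
                     seed = 3)
  for (k in 1:3) {
    coords <- fg$extent[[k]][1] + (s[, k + 1] - 1) * fg$dx[k]
    expect_true(all(coords >= 1 - 1e-9 & coords <= 1.5 + 1e-9))
  }
  # non-periodic margins: no sampled point touches the invalid boundary rim
  fc <- cavity_field()
  sc <- sample_points(fc, 300, region = list(c(0, 1), c(0.6, 1)),
                      margin = 2L, seed = 3)
  expect_true(all(sc[, 2] >= 3 & sc[, 2] <= 126))
  expect_true(all(sc[, 3] <= 126))
})

test_that("denoise-then-differentiate is exact on noiseless low-rank data", {
  f <- make_lowrank_field(r = 2, d = c(4, 1.5))
  den <- svd_denoise(f, rank = 2)$field
  d1 <- spatial_derivative(f, 1, 1)
  d2 <- spatial_derivative(den, 1, 1)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
})
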