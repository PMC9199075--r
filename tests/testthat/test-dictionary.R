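test_that("dictionary sizes follow the closed-form combinatorics", {
  # 1-D: max_poly + max_deriv * (max_poly + 1) (+ constant)
  expect_identical(dictionary_size(dictionary_spec_1d()), 19L)
  expect_identical(dictionary_size(dictionary_spec_1d(max_poly_degree = 2,
                                                      max_derivative_order = 3)),
                   2L + 3L * 3L)
  expect_identical(dictionary_size(dictionary_spec_1d(include_constant = TRUE)),
                   20L)
  expect_identical(dictionary_size(dictionary_spec_vorticity()), 48L)
  expect_identical(dictionary_size(dictionary_spec_grayscott("u")), 69L)
  expect_identical(dictionary_size(reaction_dictionary_spec()), 20L)
})

test_that("key labels are present in the presets", {
  expect_true(all(c("u*u_{x}", "u_{xx}") %in% dictionary_spec_1d()$labels))
  vs <- dictionary_spec_vorticity()
  expect_true(all(c("w_{xx}", "w_{yy}", "u*w_{x}", "v*w_{y}") %in% vs$labels))
  gs <- dictionary_spec_grayscott("u")
  expect_true(all(c("1", "u", "u_{xx}", "u_{yy}", "u_{zz}", "u*v^2") %in%
                    gs$labels))
  rs <- reaction_dictionary_spec()
  expect_true(all(c("1", "P", "A*P^2", "A", "A^2*P") %in% rs$labels))
})

test_that("a single-species minimal reaction dictionary is just the species", {
  spec <- reaction_dictionary_spec(species = "A", max_stoichiometry = 1,
                                   include_constant = FALSE,
                                   include_transport = FALSE)
  expect_identical(spec$labels, "A")
})

test_that("constant fields produce constant monomials and zero derivatives", {
  nt <- 6; nx <- 16
  f <- stf_field(values = list(u = matrix(2, nt, nx)), dx = 1 / nx,
                 times = seq(0, 1, length.out = nt),
                 extent = list(c(0, 1)), boundary = "periodic")
  s <- sample_points(f, 10, seed = 1)
  sys <- build_design(f, dictionary_spec_1d(), s)
  expect_equal(unname(sys$theta[, "u^3"]), rep(8, 10))
  deriv_cols <- grepl("_\\{", sys$labels)
  expect_equal(max(abs(sys$theta[, deriv_cols])), 0)
  expect_equal(max(abs(sys$ut)), 0)
})

test_that("the Burgers design satisfies the generating equation", {
  f <- burgers_field()
  s <- sample_points(f, 300, seed = 2)
  sys <- build_design(f, dictionary_spec_1d(), s)
  truth <- c("u*u_{x}" = -1, "u_{xx}" = 0.1)
  resid <- sys$ut - sys$theta[, names(truth)] %*% truth
  rel <- sqrt(mean(resid^2)) / stats::sd(sys$ut)
  expect_lt(rel, 0.01)

  # discretization error shrinks on a finer time axis relative to dx
  cfg <- burgers_config(nx = 128L, nt = 250L, dt = 0.04)
  fc <- simulate_burgers(cfg)
  sc <- sample_points(fc, 300, seed = 2)
  sysc <- build_design(fc, dictionary_spec_1d(), sc)
  residc <- sysc$ut - sysc$theta[, names(truth)] %*% truth
  expect_gt(sqrt(mean(residc^2)) / stats::sd(sysc$ut), rel)
})

test_that("the reaction design reproduces the generating kinetics", {
  f <- par_field()
  spec <- reaction_dictionary_spec(target = "P")
  s <- sample_points(f, 250, seed = 4)
  sys <- build_reaction_design(f, spec, s, target_species = "P")
  b <- qr.coef(qr(sys$theta[, c("1", "P", "A*P^2")]), sys$ut)
  expect_equal(unname(b), c(-1.98e-4, 1.07e-2, -2.79e-4), tolerance = 0.01)
})

test_that("standardization enforces its moments and is invertible", {
  d <- random_sparse_system(60, 8, 2, seed = 5)
  sys <- d$system
  expect_lt(max(abs(colMeans(sys$theta))), 1e-12)
  expect_lt(max(abs(colMeans(sys$theta^2) - 1)), 1e-12)
  expect_lt(abs(mean(sys$ut)), 1e-12)
  expect_identical(standardize(sys), sys)        # idempotent

  # back-transformation equals a direct least-squares fit with intercept
  set.seed(8)
  X <- matrix(rnorm(50 * 3), 50, 3); colnames(X) <- c("a", "b", "c")
  y <- drop(X %*% c(1, -2, 0.5)) + 3 + rnorm(50, sd = 0.1)
  raw <- make_system(X, y)
  std <- standardize(raw)
  beta_std <- qr.coef(qr(std$theta), std$ut)
  back <- unstandardize_coefficients(std, beta_std)
  ref <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(unname(back$coefficients), unname(ref[-1]), tolerance = 1e-10)
  expect_equal(back$intercept, unname(ref[1]), tolerance = 1e-10)
})

test_that("zero-variance columns are rejected by name", {
  X <- cbind(a = rnorm(20), b = rep(2, 20))
  expect_error(standardize(make_system(X, rnorm(20))), "b")
})

test_that("the constant column is dropped at standardization, kept for refit", {
  X <- cbind("1" = rep(1, 30), a = rnorm(30))
  sys <- make_system(X, rnorm(30))
  std <- standardize(sys)
  expect_false("1" %in% std$labels)
  expect_true(sys$include_constant)
})
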