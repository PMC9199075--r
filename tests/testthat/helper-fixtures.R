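# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

burgers_field <- function() fixture("burgers", function() simulate_burgers())

cavity_field <- function() fixture("cavity", function() {
  simulate_cavity_vorticity()
})

grayscott_field <- function() fixture("grayscott", function() {
  simulate_gray_scott()
})

par_field <- function() fixture("par", function() simulate_par_ode())

# Hand-built design system for solver tests (bypasses the field pipeline).
make_system <- function(theta, ut, standardized = FALSE) {
  if (is.null(colnames(theta)))
    colnames(theta) <- paste0("c", seq_len(ncol(theta)))
  structure(list(theta = theta, ut = ut, labels = colnames(theta),
                 sample_indices = NULL, standardized = standardized,
                 include_constant = "1" %in% colnames(theta),
                 column_means = NULL, column_scales = NULL, ut_mean = NULL),
            class = "design_system")
}

# Random standardized system with a sparse ground truth.
random_sparse_system <- function(n, p, k, snr = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  supp <- sample.int(p, k)
  beta[supp] <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 1, 2)
  y <- drop(X %*% beta)
  y <- y + rnorm(n, sd = sd(y) / snr)
  sys <- standardize(make_system(X, y))
  list(system = sys, support = sort(supp), beta = beta)
}

# Exhaustive L0 oracle: minimises 0.5*||y - X b||^2 + pen * |S| over all
# supports of size <= kmax, solving least squares per support.
exhaustive_l0_support <- function(X, y, pen, kmax = 4) {
  p <- ncol(X)
  best <- list(obj = 0.5 * sum(y^2), support = integer(0))
  for (k in seq_len(kmax)) {
    combs <- utils::combn(p, k)
    for (j in seq_len(ncol(combs))) {
      S <- combs[, j]
      r <- qr.resid(qr(X[, S, drop = FALSE]), y)
      obj <- 0.5 * sum(r^2) + pen * k
      if (obj < best$obj) best <- list(obj = obj, support = S)
    }
  }
  best$support
}
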