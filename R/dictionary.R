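# Term-based dictionary specifications. A term is the product of a monomial
# in the state variables and (optionally) one spatial-derivative factor of
# one variable; this covers all dictionary families used by the benchmarks.

new_term <- function(powers = integer(0), dvar = NULL, dorder = NULL) {
  list(powers = powers, dvar = dvar, dorder = dorder)
}

dim_letters <- c("x", "y", "z")

term_label <- function(term) {
  parts <- character(0)
  pw <- term$powers[term$powers > 0]
  if (length(pw)) {
    pw <- pw[order(names(pw))]
    parts <- ifelse(pw == 1L, names(pw), paste0(names(pw), "^", pw))
  }
  if (!is.null(term$dvar)) {
    suffix <- paste(rep(dim_letters[seq_along(term$dorder)], term$dorder),
                    collapse = "")
    parts <- c(parts, paste0(term$dvar, "_{", suffix, "}"))
  }
  if (!length(parts)) "1" else paste(parts, collapse = "*")
}

new_dictionary_spec <- function(terms, variables, target, d, preset) {
  labels <- vapply(terms, term_label, "")
  if (anyDuplicated(labels)) stop("duplicate dictionary labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  structure(list(terms = terms, labels = labels, variables = variables,
                 target = target, d = d, preset = preset),
            class = "dictionary_spec")
}

#' @export
print.dictionary_spec <- function(x, ...) {
  cat("<dictionary_spec '", x$preset, "'> p = ", length(x$terms),
      " columns, target d", x$target, "/dt\n", sep = "")
  cat(strwrap(paste(x$labels, collapse = ", "), width = 78, prefix = "  "),
      sep = "\n")
  invisible(x)
}

#' Number of columns of a dictionary
#' @param spec a `dictionary_spec`.
#' @return integer, the dictionary size p.
#' @export
dictionary_size <- function(spec) length(spec$terms)

#' Single-variable 1-D dictionary
#'
#' Pure monomials `u^j` (degree 1..`max_poly_degree`) plus every spatial
#' derivative `d^k u/dx^k` (order 1..`max_derivative_order`) multiplied by
#' `u^j` (degree 0..`max_poly_degree`), optionally with a constant column.
#' The defaults give the standard 19-column dictionary
#' (3 monomials + 4 x 4 derivative products).
#'
#' @param var variable name.
#' @param max_poly_degree maximum monomial degree.
#' @param max_derivative_order maximum derivative order (1..4).
#' @param include_constant include a constant column.
#' @return A `dictionary_spec`.
#' @export
dictionary_spec_1d <- function(var = "u", max_poly_degree = 3L,
                               max_derivative_order = 4L,
                               include_constant = FALSE) {
  stopifnot(max_poly_degree >= 1, max_derivative_order %in% 1:4)
  terms <- list()
  if (include_constant) terms <- c(terms, list(new_term()))
  for (j in seq_len(max_poly_degree))
    terms <- c(terms, list(new_term(powers = stats::setNames(j, var))))
  for (k in seq_len(max_derivative_order))
    for (j in 0:max_poly_degree)
      terms <- c(terms, list(new_term(
        powers = stats::setNames(j, var), dvar = var, dorder = k)))
  new_dictionary_spec(terms, variables = var, target = var, d = 1L,
                      preset = "1d")
}

#' 2-D vorticity-transport dictionary preset (p = 48)
#'
#' Candidate terms for the evolution of a scalar vorticity `w` advected by a
#' velocity field `(u, v)`: all monomials in `(w, u, v)` up to degree 2 plus
#' the pure cubes; and every spatial derivative of `w` up to total order 3
#' (mixed partials included) multiplied by 1, `w`, `u` or `v`. This is a
#' reconstruction of the benchmark's 48-column design: the exact composition
#' of the original term list is not published, so the preset is parameterized
#' and can be overridden by building a custom `dictionary_spec`.
#'
#' @return A `dictionary_spec` with 48 columns.
#' @export
dictionary_spec_vorticity <- function() {
  vars <- c("w", "u", "v")
  terms <- list()
  # monomials of degree 1 and 2, plus pure cubes
  for (deg in 1:2) {
    combs <- expand.grid(w = 0:deg, u = 0:deg, v = 0:deg)
    combs <- combs[rowSums(combs) == deg, , drop = FALSE]
    for (r in seq_len(nrow(combs)))
      terms <- c(terms, list(new_term(powers = unlist(combs[r, ]))))
  }
  for (v in vars)
    terms <- c(terms, list(new_term(powers = stats::setNames(3L, v))))
  # derivatives of w up to total order 3, times {1, w, u, v}
  dorders <- list()
  for (tot in 1:3) {
    g <- expand.grid(kx = 0:tot, ky = 0:tot)
    g <- g[rowSums(g) == tot, , drop = FALSE]
    for (r in seq_len(nrow(g))) dorders <- c(dorders, list(as.integer(g[r, ])))
  }
  mults <- c(list(integer(0)),
             lapply(vars, function(v) stats::setNames(1L, v)))
  for (dord in dorders)
    for (mu in mults)
      terms <- c(terms, list(new_term(powers = mu, dvar = "w", dorder = dord)))
  new_dictionary_spec(terms, variables = vars, target = "w", d = 2L,
                      preset = "vorticity48")
}

#' 3-D two-species reaction-diffusion dictionary preset (p = 69)
#'
#' Candidate terms for one species of a coupled two-species system on a 3-D
#' grid: a constant column; all monomials in `(u, v)` up to degree 4; and
#' every spatial derivative of `u` and of `v` up to total order 2 (mixed
#' partials included) multiplied by 1, `u` or `v`. As for the 2-D preset,
#' this is a documented reconstruction of the benchmark's 69-column design.
#'
#' @param target which species' time derivative is the response, `"u"` or
#'   `"v"`.
#' @return A `dictionary_spec` with 69 columns.
#' @export
dictionary_spec_grayscott <- function(target = c("u", "v")) {
  target <- match.arg(target)
  vars <- c("u", "v")
  terms <- list(new_term())             # constant
  for (deg in 1:4)
    for (i in 0:deg)
      terms <- c(terms, list(new_term(powers = c(u = i, v = deg - i))))
  dorders <- list()
  for (tot in 1:2) {
    g <- expand.grid(kx = 0:tot, ky = 0:tot, kz = 0:tot)
    g <- g[rowSums(g) == tot, , drop = FALSE]
    for (r in seq_len(nrow(g))) dorders <- c(dorders, list(as.integer(g[r, ])))
  }
  mults <- c(list(integer(0)), list(c(u = 1L)), list(c(v = 1L)))
  for (dv in vars)
    for (dord in dorders)
      for (mu in mults)
        terms <- c(terms, list(new_term(powers = mu, dvar = dv, dorder = dord)))
  new_dictionary_spec(terms, variables = vars, target = target, d = 3L,
                      preset = "grayscott69")
}

#' Reaction dictionary for two interacting species
#'
#' Mass-action monomials `A^i P^j` with per-species stoichiometry at most
#' `max_stoichiometry` and total molecularity at most `max_total_order`
#' (default 3: at most termolecular reactions, which excludes only `A^2 P^2`
#' from the full stoichiometry-2 grid), optionally with transport-like terms:
#' first and second spatial derivatives of each species multiplied by 1 or a
#' single species. The defaults give the 20-column reaction design.
#'
#' @param species character vector of species names (1 or 2).
#' @param max_stoichiometry maximum exponent per species.
#' @param max_total_order maximum total monomial degree.
#' @param include_constant include the constant column.
#' @param include_transport include the derivative-bearing transport block.
#' @param target species whose time derivative is the response.
#' @return A `dictionary_spec`.
#' @export
reaction_dictionary_spec <- function(species = c("A", "P"),
                                     max_stoichiometry = 2L,
                                     max_total_order = 3L,
                                     include_constant = TRUE,
                                     include_transport = TRUE,
                                     target = species[1]) {
  stopifnot(length(species) %in% 1:2, max_stoichiometry >= 1,
            target %in% species)
  terms <- list()
  expo <- expand.grid(rep(list(0:max_stoichiometry), length(species)))
  names(expo) <- species
  expo <- expo[rowSums(expo) <= max_total_order, , drop = FALSE]
  expo <- expo[order(rowSums(expo)), , drop = FALSE]
  for (r in seq_len(nrow(expo))) {
    pw <- unlist(expo[r, , drop = FALSE])
    if (sum(pw) == 0 && !include_constant) next
    terms <- c(terms, list(new_term(powers = pw)))
  }
  if (include_transport) {
    mults <- c(list(integer(0)),
               lapply(species, function(s) stats::setNames(1L, s)))
    for (sp in species)
      for (ord in 1:2)
        for (mu in mults)
          terms <- c(terms, list(new_term(powers = mu, dvar = sp,
                                          dorder = ord)))
  }
  new_dictionary_spec(terms, variables = species, target = target, d = 1L,
                      preset = "reaction")
}

#' Assemble the regression system from a field, a dictionary and samples
#'
#' Evaluates every dictionary column at the sampled space-time points and
#' the forward-difference time derivative of the target variable at the same
#' points (each sampled frame uses its successor frame).
#'
#' @param field an `stf_field` containing every variable the spec needs.
#' @param spec a `dictionary_spec`.
#' @param samples integer matrix from [sample_points()].
#' @return A `design_system`: list with `theta` (N x p, labelled columns),
#'   `ut` (length N), `labels`, `sample_indices`, and standardization state.
#' @export
build_design <- function(field, spec, samples) {
  stopifnot(inherits(field, "stf_field"), inherits(spec, "dictionary_spec"))
  if (!is.matrix(samples) || nrow(samples) == 0) stop("empty sample set")
  if (!all(spec$variables %in% field$variable_names))
    stop("field lacks variables: ",
         paste(setdiff(spec$variables, field$variable_names), collapse = ", "))
  d <- field_ndim(field)
  if (d != spec$d) stop("dictionary expects ", spec$d, "-D data, field is ", d, "-D")
  n <- nrow(samples)
  periodic <- field$boundary == "periodic"

  # response: forward time difference of the target variable
  frames <- samples[, 1L]
  if (any(frames >= length(field$times)))
    stop("sampled frames must have a successor frame")
  tgt <- field$values[[spec$target]]
  idx_now <- cbind(frames, samples[, -1L, drop = FALSE])
  idx_next <- cbind(frames + 1L, samples[, -1L, drop = FALSE])
  dt <- field$times[frames + 1L] - field$times[frames]
  ut <- (tgt[idx_next] - tgt[idx_now]) / dt

  p <- length(spec$terms)
  theta <- matrix(0, n, p)
  var_at <- lapply(field$values[spec$variables], function(a) a[idx_now])
  for (j in seq_len(p)) {
    term <- spec$terms[[j]]
    col <- rep(1, n)
    pw <- term$powers[term$powers > 0]
    for (v in names(pw)) col <- col * var_at[[v]]^pw[[v]]
    if (!is.null(term$dvar)) {
      dord <- rep_len(as.integer(term$dorder), d)
      col <- col * eval_derivative_points(field$values[[term$dvar]], samples,
                                          dord, field$dx, periodic)
    }
    theta[, j] <- col
  }
  if (!all(is.finite(theta)) || !all(is.finite(ut)))
    stop("design contains non-finite entries")
  colnames(theta) <- spec$labels
  structure(list(theta = theta, ut = ut, labels = spec$labels,
                 sample_indices = samples, standardized = FALSE,
                 include_constant = "1" %in% spec$labels,
                 column_means = NULL, column_scales = NULL, ut_mean = NULL),
            class = "design_system")
}

#' Assemble a reaction design system
#'
#' Convenience wrapper around [build_design()] for a
#' [reaction_dictionary_spec()] with an explicit target species.
#'
#' @param field an `stf_field` with the species concentrations.
#' @param spec a reaction `dictionary_spec`.
#' @param samples integer matrix from [sample_points()].
#' @param target_species species whose time derivative is the response.
#' @return A `design_system`.
#' @export
build_reaction_design <- function(field, spec, samples,
                                  target_species = spec$target) {
  spec$target <- target_species
  build_design(field, spec, samples)
}

#' @export
print.design_system <- function(x, ...) {
  cat("<design_system> N = ", nrow(x$theta), ", p = ", ncol(x$theta),
      if (x$standardized) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

#' Standardize a design system
#'
#' Centres every column to mean zero and scales it to unit mean square over
#' the rows present; the response is centred to mean zero. The constant
#' column (label `"1"`), if present, cannot satisfy both conditions and is
#' dropped from the standardized system (its effect is restored as the
#' intercept at refit time). Column means and scales are recorded for
#' back-transformation.
#'
#' @param system a `design_system`.
#' @return A standardized `design_system` (idempotent).
#' @export
standardize <- function(system) {
  stopifnot(inherits(system, "design_system"))
  if (isTRUE(system$standardized)) return(system)
  theta <- system$theta
  labels <- system$labels
  keep <- labels != "1"
  theta <- theta[, keep, drop = FALSE]
  labels <- labels[keep]
  mu <- colMeans(theta)
  centered <- sweep(theta, 2L, mu)
  scales <- sqrt(colMeans(centered^2))
  bad <- which(scales < 1e-12)
  if (length(bad))
    stop("zero-variance column(s): ", paste(labels[bad], collapse = ", "))
  std <- sweep(centered, 2L, scales, `/`)
  colnames(std) <- labels
  out <- system
  out$theta <- std
  out$labels <- labels
  out$ut_mean <- mean(system$ut)
  out$ut <- system$ut - out$ut_mean
  out$column_means <- stats::setNames(mu, labels)
  out$column_scales <- stats::setNames(scales, labels)
  out$standardized <- TRUE
  out
}

#' Map standardized-scale coefficients back to the original scale
#'
#' Inverts the standardization of [standardize()]: raw-scale coefficients
#' are `beta / scale`, and the implied intercept is
#' `mean(ut) - sum(beta_raw * mean_k)`.
#'
#' @param std_system a standardized `design_system`.
#' @param beta named (or ordered) coefficient vector on the standardized
#'   scale.
#' @return A list with `coefficients` (raw scale, named) and `intercept`.
#' @export
unstandardize_coefficients <- function(std_system, beta) {
  stopifnot(isTRUE(std_system$standardized))
  beta_raw <- beta / std_system$column_scales
  intercept <- std_system$ut_mean - sum(beta_raw * std_system$column_means)
  list(coefficients = stats::setNames(beta_raw, std_system$labels),
       intercept = intercept)
}

#' Take a row subset of a design system
#'
#' @param system a raw (unstandardized) `design_system`.
#' @param rows integer row indices.
#' @return A `design_system` restricted to those rows.
#' @export
subset_rows <- function(system, rows) {
  stopifnot(inherits(system, "design_system"), !isTRUE(system$standardized))
  out <- system
  out$theta <- system$theta[rows, , drop = FALSE]
  out$ut <- system$ut[rows]
  out$sample_indices <- system$sample_indices[rows, , drop = FALSE]
  out
}
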