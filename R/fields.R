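#' Spatio-temporal field container
#'
#' Holds one or more gridded state variables sampled on a regular Cartesian
#' grid in space and a (possibly non-uniform) sequence of time points. The
#' first array dimension always indexes time; the remaining dimensions index
#' space. This is the carrier for the state variables of all benchmark
#' systems: the scalar `u` of the 1-D Burgers equation, the vorticity and
#' velocities `(w, u, v)` of the cavity flow, the species `(u, v)` of the
#' Gray-Scott model, and the protein concentrations `(A, P)`.
#'
#' @param values named list of numeric arrays, all with identical dimensions;
#'   dimension 1 is time, dimensions 2.. are space.
#' @param dx numeric vector of grid spacings, one per spatial dimension.
#' @param times numeric vector of time stamps, one per frame, strictly
#'   increasing.
#' @param extent list of length-2 numeric vectors `c(lo, hi)`, one per
#'   spatial dimension.
#' @param boundary one of `"periodic"`, `"dirichlet-noslip"`, `"lid-driven"`.
#' @param anchor_frames integer vector of frame indices eligible as sampling
#'   anchors (each must have a successor frame for the forward time
#'   difference). Defaults to all frames but the last.
#'
#' @return An object of class `stf_field`.
#' @export
stf_field <- function(values, dx, times, extent,
                      boundary = c("periodic", "dirichlet-noslip", "lid-driven"),
                      anchor_frames = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(is.list(values), length(values) >= 1, !is.null(names(values)))
  dims <- dim(as.array(values[[1]]))
  for (v in values) {
    va <- as.array(v)
    if (!identical(dim(va), dims)) stop("all variables must share dimensions")
    if (!all(is.finite(va))) stop("field values must be finite")
  }
  d <- length(dims) - 1L
  if (length(dx) != d) stop("dx must have one entry per spatial dimension")
  if (any(dx <= 0)) stop("dx must be positive")
  if (length(times) != dims[1]) stop("times must match the number of frames")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(extent) != d) stop("extent must have one interval per spatial dimension")
  for (k in seq_len(d)) {
    width <- extent[[k]][2] - extent[[k]][1]
    n <- dims[k + 1L]
    span <- if (boundary == "periodic") n * dx[k] else (n - 1L) * dx[k]
    if (abs(span - width) > 1e-8 * max(1, abs(width)))
      stop("array shape inconsistent with extent/dx along dimension ", k)
  }
  if (is.null(anchor_frames)) anchor_frames <- seq_len(dims[1] - 1L)
  structure(list(values = lapply(values, as.array),
                 variable_names = names(values),
                 dx = dx, times = times, extent = extent,
                 boundary = boundary,
                 anchor_frames = as.integer(anchor_frames)),
            class = "stf_field")
}

#' @export
print.stf_field <- function(x, ...) {
  dims <- dim(x$values[[1]])
  cat("<stf_field> ", paste(x$variable_names, collapse = ", "),
      " | frames: ", dims[1],
      " | grid: ", paste(dims[-1], collapse = " x "),
      " | boundary: ", x$boundary, "\n", sep = "")
  invisible(x)
}

#' Number of spatial dimensions of a field
#' @param field an `stf_field`.
#' @return integer scalar.
#' @export
field_ndim <- function(field) length(dim(field$values[[1]])) - 1L

#' Additive Gaussian noise scaled by the empirical field variance
#'
#' Corrupts every variable `u` of the field with i.i.d. additive Gaussian
#' noise `sigma * z`, `z ~ N(0, Var(u))`, where `Var(u)` is the empirical
#' variance of that variable's full clean data vector. `sigma` is therefore a
#' dimensionless noise level (0.01 = 1% noise).
#'
#' @param field an `stf_field`.
#' @param sigma non-negative noise level.
#' @param seed integer RNG seed; the same seed reproduces the same noise.
#' @return A new `stf_field` with identical metadata and noisy values.
#' @export
add_noise <- function(field, sigma, seed = 0L) {
  stopifnot(inherits(field, "stf_field"), sigma >= 0)
  if (sigma == 0) return(field)
  out <- field
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  for (v in field$variable_names) {
    u <- field$values[[v]]
    sd_u <- stats::sd(as.vector(u))
    noise <- array(stats::rnorm(length(u), mean = 0, sd = sd_u), dim = dim(u))
    out$values[[v]] <- u + sigma * noise
  }
  out
}

# Seed an RNG scope and return a restorer for the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Derive a child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483647)
}

#' Export a 1-D field (or a 1-D slice) to CSV
#'
#' Writes long-format rows `(time, x, variable, value)`. Only defined for
#' fields with one spatial dimension.
#'
#' @param field an `stf_field` with one spatial dimension.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
write_field_csv <- function(field, path) {
  if (field_ndim(field) != 1L) stop("CSV export is defined for 1-D fields")
  nx <- dim(field$values[[1]])[2]
  x <- field$extent[[1]][1] + (seq_len(nx) - 1L) * field$dx[1]
  rows <- do.call(rbind, lapply(field$variable_names, function(v) {
    data.frame(time = rep(field$times, times = nx),
               x = rep(x, each = length(field$times)),
               variable = v,
               value = as.vector(field$values[[v]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
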