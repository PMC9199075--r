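# Finite-difference stencils and sampling machinery shared by the
# derivative operations and the dictionary builder.

# 1-D central stencil (coefficients unscaled by dx) for derivative orders
# 1..4. Orders 3 and 4 are built by composing the order-1 and order-2
# second-order central stencils, so every order keeps the second-order
# convention.
stencil_coeffs <- function(order) {
  o1 <- c(-0.5, 0, 0.5)
  o2 <- c(1, -2, 1)
  switch(as.character(order),
         "0" = 1,
         "1" = o1,
         "2" = o2,
         "3" = convolve(o2, rev(o1), type = "open"),
         "4" = convolve(o2, rev(o2), type = "open"),
         stop("derivative order must be between 0 and 4"))
}

stencil_margin <- function(order) {
  if (order == 0) 0L else if (order <= 2) 1L else 2L
}

# Evaluate a (possibly mixed) spatial derivative of one variable at sampled
# space-time points. `samples` is the integer matrix from sample_points().
# `orders` is the per-axis derivative multi-index.
eval_derivative_points <- function(values, samples, orders, dx, periodic) {
  d <- length(orders)
  dims <- dim(values)[-1]
  stencils <- lapply(seq_len(d), function(k) {
    cf <- stencil_coeffs(orders[k]) / dx[k]^orders[k]
    m <- (length(cf) - 1L) / 2
    list(off = seq(-m, m), cf = cf)
  })
  combos <- expand.grid(lapply(stencils, function(s) seq_along(s$off)))
  n <- nrow(samples)
  out <- numeric(n)
  for (ci in seq_len(nrow(combos))) {
    w <- 1
    idx <- matrix(0L, n, d + 1L)
    idx[, 1L] <- samples[, 1L]
    for (k in seq_len(d)) {
      pos <- combos[ci, k]
      w <- w * stencils[[k]]$cf[pos]
      shifted <- samples[, k + 1L] + stencils[[k]]$off[pos]
      if (periodic) {
        shifted <- ((shifted - 1L) %% dims[k]) + 1L
      } else if (any(shifted < 1L | shifted > dims[k])) {
        stop("sample touches an invalid boundary point (stencil does not fit)")
      }
      idx[, k + 1L] <- shifted
    }
    if (w != 0) out <- out + w * values[idx]
  }
  out
}

#' Truncated-SVD denoising of a spatio-temporal field
#'
#' Each variable is reshaped to a (time x space) matrix, decomposed by SVD,
#' and reconstructed from its leading singular triplets. If `rank` is not
#' given, it is chosen automatically at the elbow of the log singular-value
#' curve (the knee point, located as the maximum deviation of the curve from
#' its end-to-end chord), optionally inflated by `rank_margin`.
#'
#' Rank truncation alone leaves the white-noise component that lives inside
#' the kept singular vectors, which finite-difference stencils then amplify
#' by `1/dt` and `1/dx^k`. For derivative-based downstream work the kept
#' singular vectors can therefore additionally be smoothed with
#' local-quadratic (Savitzky-Golay) filters via `smooth_windows`; the
#' benchmark recovery pipeline enables this for noisy data.
#'
#' @param field an `stf_field`.
#' @param rank optional fixed truncation rank (applied to all variables).
#' @param rank_margin multiplier applied to the automatic elbow rank
#'   (ignored when `rank` is given).
#' @param smooth_windows `NULL` (no smoothing), `"auto"` (windows of about
#'   4% of the time axis and 7.5% of each spatial axis, minimum 5 points),
#'   or an integer vector of odd window lengths `(time, space...)`.
#' @return A list with elements `field` (the denoised `stf_field`) and
#'   `reports`, a per-variable list with `singular_values`, `rank_kept` and
#'   `method` (`"elbow-auto"` or `"fixed-rank"`).
#' @export
svd_denoise <- function(field, rank = NULL, rank_margin = 1,
                        smooth_windows = NULL) {
  stopifnot(inherits(field, "stf_field"))
  out <- field
  reports <- list()
  dims <- dim(field$values[[1]])
  win <- NULL
  if (!is.null(smooth_windows)) {
    win <- if (identical(smooth_windows, "auto"))
      vapply(seq_along(dims), function(k) {
        frac <- if (k == 1L) 0.04 else 0.075
        w <- max(5L, round(frac * dims[k]))
        as.integer(w + (w + 1L) %% 2L)  # force odd
      }, 1L)
    else rep_len(as.integer(smooth_windows), length(dims))
  }
  for (v in field$variable_names) {
    arr <- field$values[[v]]
    M <- matrix(arr, nrow = dims[1])
    if (all(M == 0)) stop("cannot denoise an all-zero variable: ", v)
    sv <- svd(M)
    r_max <- sum(sv$d > max(sv$d) * 1e-12)
    if (is.null(rank)) {
      r <- as.integer(max(1, min(round(elbow_rank(sv$d[seq_len(r_max)]) *
                                         rank_margin), r_max)))
      method <- "elbow-auto"
    } else {
      r <- max(1L, min(as.integer(rank), length(sv$d)))
      method <- "fixed-rank"
    }
    U <- sv$u[, seq_len(r), drop = FALSE]
    V <- sv$v[, seq_len(r), drop = FALSE]
    if (!is.null(win)) {
      bw <- win[1] / dims[1] * diff(range(field$times)) / 2
      for (k in seq_len(r)) {
        U[, k] <- loc_quad_smooth(field$times, U[, k], bw)
        V[, k] <- smooth_mode_spatial(V[, k], dims[-1], win[-1])
      }
    }
    rec <- U %*% (sv$d[seq_len(r)] * t(V))
    out$values[[v]] <- array(rec, dim = dims)
    reports[[v]] <- list(singular_values = sv$d, rank_kept = r,
                         method = method)
  }
  list(field = out, reports = reports)
}

# Elbow (knee) of a descending positive singular-value sequence: the index
# preceding the point of maximum deviation of the log curve from the chord
# joining its endpoints.
elbow_rank <- function(d) {
  d <- d[d > 0]
  len <- length(d)
  if (len <= 2L) return(len)
  l <- log(d)
  chord <- l[1] + (l[len] - l[1]) * (seq_len(len) - 1) / (len - 1)
  r <- which.max(chord - l) - 1L
  max(1L, min(r, len))
}

# Central Savitzky-Golay (local quadratic) smoothing weights.
sg_coef <- function(w, deg = 2L) {
  half <- (w - 1L) %/% 2L
  x <- -half:half
  A <- outer(x, 0:deg, `^`)
  (A %*% solve(crossprod(A)) %*% t(A))[half + 1L, ]
}

# Smooth a vector with a local quadratic filter; near the edges the local
# polynomial is refit on the truncated window.
sg_smooth <- function(v, w) {
  n <- length(v)
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w < 5) return(v)
  half <- (w - 1L) %/% 2L
  out <- as.numeric(stats::filter(v, sg_coef(w), sides = 2))
  for (i in c(seq_len(half), (n - half + 1L):n)) {
    xs <- max(1L, i - half):min(n, i + half)
    fit <- stats::lm.fit(outer(xs - i, 0:2, `^`), v[xs])
    out[i] <- fit$coefficients[1]
  }
  out
}

# Local quadratic smoothing against actual time stamps (handles the
# non-uniform anchor/partner frame grids).
loc_quad_smooth <- function(t, v, bw) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    sel <- which(abs(t - t[i]) <= bw)
    if (length(sel) < 5) sel <- order(abs(t - t[i]))[1:min(5, n)]
    X <- outer(t[sel] - t[i], 0:2, `^`)
    out[i] <- stats::lm.fit(X, v[sel])$coefficients[1]
  }
  out
}

# Smooth a flattened spatial mode along each grid axis in turn.
smooth_mode_spatial <- function(v, sdims, wins) {
  if (length(sdims) == 1L) return(sg_smooth(v, wins[1]))
  arr <- array(v, dim = sdims)
  for (ax in seq_along(sdims)) {
    arr <- apply(arr, setdiff(seq_along(sdims), ax), sg_smooth, w = wins[ax])
    arr <- aperm(arr, order(c(ax, setdiff(seq_along(sdims), ax))))
  }
  as.vector(arr)
}

#' Forward-difference time derivative of a field variable
#'
#' First-order forward differences `(u[t+1] - u[t]) / (t[t+1] - t[t])` along
#' the time axis; the last frame has no successor and is marked invalid
#' (`NA`).
#'
#' @param field an `stf_field`.
#' @param var variable name; defaults to the first variable.
#' @return A `derivative_field`: list with `values` (aligned with the parent
#'   array, `NA` at invalid frames), `order` (the time/space multi-index) and
#'   `scheme`.
#' @export
time_derivative <- function(field, var = field$variable_names[1]) {
  arr <- field$values[[var]]
  nt <- dim(arr)[1]
  if (nt < 2) stop("time derivative needs at least two frames")
  dt <- diff(field$times)
  out <- array(NA_real_, dim = dim(arr))
  flat <- matrix(arr, nrow = nt)
  dflat <- (flat[-1L, , drop = FALSE] - flat[-nt, , drop = FALSE]) / dt
  out_flat <- matrix(NA_real_, nt, ncol(flat))
  out_flat[seq_len(nt - 1L), ] <- dflat
  out <- array(out_flat, dim = dim(arr))
  structure(list(values = out,
                 order = c(1L, rep(0L, field_ndim(field))),
                 scheme = "forward-time-order1", var = var),
            class = "derivative_field")
}

#' Central-difference spatial derivative of a field variable
#'
#' Second-order central stencils along one spatial axis; orders 3 and 4 are
#' stencil compositions of the order-1 and order-2 stencils. On periodic
#' domains the stencil wraps; otherwise a margin of points where the stencil
#' does not fit is marked invalid (`NA`).
#'
#' @param field an `stf_field`.
#' @param axis spatial axis (1-based, counting spatial dimensions only).
#' @param order derivative order, 1..4.
#' @param var variable name; defaults to the first variable.
#' @return A `derivative_field` (see [time_derivative()]).
#' @export
spatial_derivative <- function(field, axis, order,
                               var = field$variable_names[1]) {
  if (!order %in% 1:4) stop("derivative order must be in 1..4")
  d <- field_ndim(field)
  stopifnot(axis >= 1, axis <= d)
  arr <- field$values[[var]]
  dims <- dim(arr)
  periodic <- field$boundary == "periodic"
  cf <- stencil_coeffs(order) / field$dx[axis]^order
  m <- (length(cf) - 1L) / 2
  ax <- axis + 1L                       # array axis (1 = time)
  n <- dims[ax]
  out <- array(0, dim = dims)
  for (s in seq_along(cf)) {
    if (cf[s] == 0) next
    off <- s - m - 1L
    idx <- seq_len(n) + off
    if (periodic) idx <- ((idx - 1L) %% n) + 1L else idx <- pmin(pmax(idx, 1L), n)
    pick <- rep(list(quote(expr = )), length(dims))
    pick[[ax]] <- idx
    shifted <- do.call(`[`, c(list(arr), pick, list(drop = FALSE)))
    out <- out + cf[s] * shifted
  }
  if (!periodic && m > 0) {
    na_pick <- rep(list(quote(expr = )), length(dims))
    na_pick[[ax]] <- c(seq_len(m), n - seq_len(m) + 1L)
    out <- do.call(`[<-`, c(list(out), na_pick, list(value = NA_real_)))
  }
  ord <- rep(0L, d)
  ord[axis] <- as.integer(order)
  structure(list(values = out, order = c(0L, ord),
                 scheme = "central-space-order2", var = var),
            class = "derivative_field")
}

#' Sample space-time points from a field
#'
#' Draws `n` unique space-time indices uniformly from the eligible set:
#' anchor frames (frames with a successor, so the forward time difference is
#' defined) crossed with spatial indices that lie inside `region` and are at
#' least `margin` points away from non-periodic boundaries (so every
#' dictionary stencil fits).
#'
#' @param field an `stf_field`.
#' @param n number of points to draw.
#' @param region optional list of `c(lo, hi)` intervals, one per spatial
#'   dimension, in domain units. Defaults to the full domain.
#' @param seed RNG seed.
#' @param margin integer stencil margin per spatial dimension; default 0 on
#'   periodic domains and 2 (the widest composed stencil) otherwise.
#' @param frames eligible frame indices; defaults to the field's anchors.
#' @return An integer matrix with columns `frame, i1, ..., id`.
#' @export
sample_points <- function(field, n, region = NULL, seed = 0L,
                          margin = NULL, frames = NULL) {
  d <- field_ndim(field)
  dims <- dim(field$values[[1]])[-1]
  if (is.null(frames)) frames <- field$anchor_frames
  if (is.null(margin))
    margin <- if (field$boundary == "periodic") rep(0L, d) else rep(2L, d)
  margin <- rep_len(as.integer(margin), d)
  ax_idx <- vector("list", d)
  for (k in seq_len(d)) {
    coords <- field$extent[[k]][1] + (seq_len(dims[k]) - 1L) * field$dx[k]
    ok <- seq_len(dims[k]) > margin[k] & seq_len(dims[k]) <= dims[k] - margin[k]
    if (!is.null(region)) {
      if (region[[k]][1] < field$extent[[k]][1] - 1e-9 ||
          region[[k]][2] > field$extent[[k]][2] + 1e-9)
        stop("region must lie within the domain")
      ok <- ok & coords >= region[[k]][1] - 1e-9 & coords <= region[[k]][2] + 1e-9
    }
    ax_idx[[k]] <- which(ok)
  }
  counts <- c(length(frames), vapply(ax_idx, length, 1L))
  total <- prod(counts)
  if (n > total)
    stop("requested ", n, " points but only ", total, " are eligible")
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  lin <- sample.int(total, n)
  out <- matrix(0L, n, d + 1L)
  rem <- lin - 1L
  out[, 1L] <- frames[rem %% counts[1] + 1L]
  rem <- rem %/% counts[1]
  for (k in seq_len(d)) {
    out[, k + 1L] <- ax_idx[[k]][rem %% counts[k + 1L] + 1L]
    rem <- rem %/% counts[k + 1L]
  }
  colnames(out) <- c("frame", paste0("i", seq_len(d)))
  out
}
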