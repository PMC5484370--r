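# Internal numerical helpers shared across modules.

# Gyromagnetic ratio of 1H, rad s^-1 T^-1.
.GAMMA_1H <- 2.675221e8

#' Gyromagnetic ratio
#'
#' Returns the gyromagnetic ratio used throughout the package, in
#' rad s^-1 T^-1. Only 1H is built in; pass any positive value directly to
#' the functions that take a `gamma` argument for other nuclei.
#'
#' @param nucleus Character, currently only `"1H"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
#' @examples
#' gyromagnetic_ratio()
gyromagnetic_ratio <- function(nucleus = "1H") {
  if (!identical(nucleus, "1H")) {
    stop("only the 1H gyromagnetic ratio is built in; pass gamma explicitly")
  }
  .GAMMA_1H
}

# Cumulative trapezoidal integral of y sampled uniformly with spacing dx.
# Returns a vector of the same length, starting at 0.
.cumtrapz <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2) * dx)
}

# Two-sided FFT frequency axis (Hz) in FFT bin order for n samples at dt.
.fftfreq <- function(n, dt) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * dt)
}

# Linear interpolation with edge-value extrapolation; complex-aware.
.interp <- function(x, y, xout) {
  if (is.complex(y)) {
    complex(
      real = stats::approx(x, Re(y), xout, rule = 2, ties = "ordered")$y,
      imaginary = stats::approx(x, Im(y), xout, rule = 2, ties = "ordered")$y
    )
  } else {
    stats::approx(x, y, xout, rule = 2, ties = "ordered")$y
  }
}

# Monotone inverse interpolation t(s): x must be non-decreasing; plateaus are
# collapsed to their first occurrence.
.interp_inverse <- function(x, y, xout) {
  keep <- c(TRUE, diff(x) > 0)
  stats::approx(x[keep], y[keep], xout, rule = 2, ties = "ordered")$y
}

# Directed max over vertices of `a` of the exact distance to polyline `b`
# (point-to-segment projections, chunked to bound memory).
.directed_hausdorff <- function(a, b, chunk = 256L) {
  nb <- nrow(b)
  s0 <- b[-nb, , drop = FALSE]
  dseg <- b[-1, , drop = FALSE] - s0
  len2 <- pmax(rowSums(dseg^2), 1e-300)
  worst <- 0
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    ai <- a[i0:i1, , drop = FALSE]
    best <- rep(Inf, nrow(ai))
    # projection parameter of every point onto every segment
    for (d in seq_len(ncol(a))) {
      if (d == 1) tt <- outer(ai[, 1], s0[, 1], "-") * rep(dseg[, 1], each = nrow(ai))
      else tt <- tt + outer(ai[, d], s0[, d], "-") * rep(dseg[, d], each = nrow(ai))
    }
    tt <- pmin(pmax(tt / rep(len2, each = nrow(ai)), 0), 1)
    d2 <- 0
    for (d in seq_len(ncol(a))) {
      dd <- outer(ai[, d], s0[, d], "-") - tt * rep(dseg[, d], each = nrow(ai))
      d2 <- d2 + dd * dd
    }
    best <- apply(d2, 1, min)
    worst <- max(worst, sqrt(max(best)))
  }
  worst
}

#' Hausdorff distance between two k-space paths
#'
#' Symmetric Hausdorff distance between two polylines: the maximum over
#' the vertices of either path of the exact distance to the other path
#' (point-to-segment projections). Used to verify that VERSE reshaping
#' preserves the excitation k-space geometry.
#'
#' @param k1,k2 Matrices with one point per row (2 or 3 columns), rad/m, or
#'   [trajectory] objects.
#' @param step Ignored (kept for call compatibility); distances are exact
#'   point-to-segment values.
#' @return Hausdorff distance in rad/m.
#' @export
hausdorff_path <- function(k1, k2, step = NULL) {
  as_pts <- function(k) {
    if (inherits(k, "trajectory")) t(k$k) else as.matrix(k)
  }
  p1 <- as_pts(k1)
  p2 <- as_pts(k2)
  max(.directed_hausdorff(p1, p2), .directed_hausdorff(p2, p1))
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
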