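# Time-domain waveform types (gradients, multi-channel RF, excitation
# k-space) and the kinematic transforms between them. Unit conventions used
# package-wide: gradients in mT/m, RF envelopes in uT, time in seconds,
# k-space in rad/m, gamma in rad s^-1 T^-1.

#' Three-axis gradient waveform
#'
#' Container for gradient waveforms sampled on a uniform time grid.
#'
#' @param samples 3 x N numeric matrix, mT/m; rows are the x, y, z axes. An
#'   N x 3 matrix is transposed automatically.
#' @param dt Sample interval, seconds.
#' @return An object of class `gradient_waveform` with elements `samples`
#'   (3 x N matrix) and `dt`.
#' @export
#' @examples
#' g <- gradient_waveform(rbind(rep(10, 100), 0, 0), dt = 6.4e-6)
#' g
gradient_waveform <- function(samples, dt) {
  samples <- as.matrix(samples)
  if (ncol(samples) == 3 && nrow(samples) != 3) samples <- t(samples)
  if (nrow(samples) != 3) stop("gradient samples must be a 3 x N matrix")
  if (ncol(samples) < 2) stop("a gradient waveform needs at least 2 samples")
  if (!all(is.finite(samples))) stop("gradient samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  structure(list(samples = samples, dt = dt), class = "gradient_waveform")
}

#' Multi-channel RF waveform
#'
#' @param samples C x N complex matrix of per-channel RF envelopes, uT. A
#'   numeric matrix or vector is promoted to complex.
#' @param dt Sample interval, seconds (same grid as the paired gradient).
#' @return An object of class `mc_rf` with elements `samples` and `dt`.
#' @export
mc_rf <- function(samples, dt) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "complex"
  if (nrow(samples) < 1 || ncol(samples) < 2) stop("RF must be C x N with C >= 1, N >= 2")
  if (!all(is.finite(Re(samples)) & is.finite(Im(samples)))) stop("RF samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  structure(list(samples = samples, dt = dt), class = "mc_rf")
}

#' Excitation k-space trajectory
#'
#' @param k 3 x N numeric matrix, rad/m. The final sample must be the
#'   k-space origin (the excitation k-space integral runs from t to the
#'   pulse end).
#' @param dt Sample interval, seconds.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(k, dt) {
  k <- as.matrix(k)
  if (ncol(k) == 3 && nrow(k) != 3) k <- t(k)
  if (nrow(k) != 3) stop("k must be a 3 x N matrix")
  if (any(k[, ncol(k)] != 0)) stop("trajectory must end at the k-space origin")
  structure(list(k = k, dt = dt), class = "trajectory")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  n <- ncol(x$samples)
  cat(sprintf(
    "<gradient_waveform> %d samples, dt = %.3g us, duration = %.4g ms\n",
    n, x$dt * 1e6, n * x$dt * 1e3
  ))
  cat(sprintf(
    "  peak |G| per axis [mT/m]: %s; max slew %.3g T/m/s\n",
    paste(sprintf("%.3g", apply(abs(x$samples), 1, max)), collapse = ", "),
    max(abs(slew_rate(x)))
  ))
  invisible(x)
}

#' @export
print.mc_rf <- function(x, ...) {
  cat(sprintf(
    "<mc_rf> %d channel(s), %d samples, dt = %.3g us, peak |B1| = %.4g uT\n",
    nrow(x$samples), ncol(x$samples), x$dt * 1e6, max(Mod(x$samples))
  ))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d samples, dt = %.3g us, |k| max = %.4g rad/m\n",
    ncol(x$k), x$dt * 1e6, max(sqrt(colSums(x$k^2)))
  ))
  invisible(x)
}

#' Excitation k-space trajectory of a gradient waveform
#'
#' Computes `k(t) = -gamma * integral_t^T0 G(t') dt'` by cumulative
#' trapezoidal integration from the end of the pulse, so the final sample is
#' exactly the k-space origin.
#'
#' @param G A [gradient_waveform].
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @return A [trajectory] in rad/m on the same time grid.
#' @export
#' @examples
#' g <- gradient_waveform(rbind(rep(10, 157), 0, 0), dt = 6.4e-6)
#' k <- compute_k(g)
#' k$k[, 1]   # approximately (-gamma * 0.01 T/m * T0, 0, 0)
compute_k <- function(G, gamma = gyromagnetic_ratio()) {
  stopifnot(inherits(G, "gradient_waveform"))
  n <- ncol(G$samples)
  k <- matrix(0, 3, n)
  for (ax in 1:3) {
    cum <- .cumtrapz(G$samples[ax, ] * 1e-3, G$dt)  # T/m integrated -> T s / m
    k[ax, ] <- -gamma * (cum[n] - cum)
  }
  trajectory(k, G$dt)
}

#' Arc length traversed in excitation k-space
#'
#' `s(t) = gamma * integral_0^t |G(tau)| dtau`, the total distance traversed
#' along the k-space path up to time t. Non-decreasing with `s(0) = 0`.
#'
#' @inheritParams compute_k
#' @return Numeric vector of per-sample arc length, rad/m.
#' @export
arc_length <- function(G, gamma = gyromagnetic_ratio()) {
  stopifnot(inherits(G, "gradient_waveform"))
  gmag <- sqrt(colSums(G$samples^2)) * 1e-3
  gamma * .cumtrapz(gmag, G$dt)
}

#' Gradient slew rate
#'
#' Forward finite difference of the gradient samples, in T/m/s, used for
#' hardware-constraint checking.
#'
#' @param G A [gradient_waveform].
#' @return 3 x (N-1) numeric matrix, T/m/s.
#' @export
slew_rate <- function(G) {
  stopifnot(inherits(G, "gradient_waveform"))
  n <- ncol(G$samples)
  (G$samples[, -1, drop = FALSE] - G$samples[, -n, drop = FALSE]) * 1e-3 / G$dt
}

#' Prepend start-up gradient ramps
#'
#' If the gradient waveform starts at a non-zero value, a minimal-duration
#' linear ramp from zero is prepended, respecting the slew limit and rounded
#' up to whole dwells; the RF is zero-padded over the ramp.
#'
#' @param G A [gradient_waveform].
#' @param B1 The paired [mc_rf] on the same grid.
#' @param smax Slew-rate limit, T/m/s.
#' @return List with elements `g` and `rf`, the padded pair.
#' @export
append_ramps <- function(G, B1, smax) {
  stopifnot(inherits(G, "gradient_waveform"), inherits(B1, "mc_rf"))
  if (!isTRUE(smax > 0)) stop("smax must be positive")
  if (ncol(G$samples) != ncol(B1$samples) || G$dt != B1$dt) {
    stop("gradient and RF must share the sample grid")
  }
  g0 <- G$samples[, 1]
  if (all(g0 == 0)) return(list(g = G, rf = B1))
  dur <- max(abs(g0)) * 1e-3 / smax
  nr <- as.integer(ceiling(dur / G$dt - 1e-12))
  frac <- (0:(nr - 1)) / nr
  ramp <- g0 %o% frac
  g <- gradient_waveform(cbind(ramp, G$samples), G$dt)
  rf <- mc_rf(cbind(matrix(0 + 0i, nrow(B1$samples), nr), B1$samples), B1$dt)
  list(g = g, rf = rf)
}
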