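# Linear time-invariant characterization of the gradient chain: chirp test
# waveforms, frequency-domain GIRF estimation from input/output pairs, and
# prediction of the actually played-out gradients from nominal waveforms.
# Only the per-axis self-terms (x->x, y->y, z->z) are modelled; cross-terms
# and the B0 (zeroth-order) response are out of scope.

#' Per-axis gradient impulse response spectrum
#'
#' @param freqs Two-sided, uniformly spaced frequency axis, Hz (ascending).
#' @param H n x 3 complex matrix, one column per gradient axis.
#' @param df Frequency resolution, Hz (1 / record duration of the
#'   estimation window).
#' @return An object of class `girf_spectrum`.
#' @export
girf_spectrum <- function(freqs, H, df = diff(freqs[1:2])) {
  H <- as.matrix(H)
  storage.mode(H) <- "complex"
  if (length(freqs) != nrow(H) || ncol(H) != 3) stop("H must be length(freqs) x 3")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly ascending")
  sp <- diff(freqs)
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1]) stop("freqs must be uniformly spaced")
  structure(list(freqs = freqs, H = H, df = df), class = "girf_spectrum")
}

#' @export
print.girf_spectrum <- function(x, ...) {
  cat(sprintf(
    "<girf_spectrum> %d bins, df = %.4g Hz, span +/- %.4g kHz, |H(0)| = %s\n",
    length(x$freqs), x$df, max(abs(x$freqs)) / 1e3,
    paste(sprintf("%.3f", Mod(x$H[which.min(abs(x$freqs)), ])), collapse = "/")
  ))
  invisible(x)
}

#' Linear frequency-swept (chirp) gradient test waveform
#'
#' `g(t) = A sin(pi * (bandwidth / duration) * t^2)`: the instantaneous
#' frequency sweeps linearly from 0 to `bandwidth` over `duration`. If the
#' requested amplitude would violate the slew limit, the amplitude is scaled
#' down and the scale factor reported in the `"slew_scale"` attribute.
#'
#' @param bandwidth Sweep bandwidth, Hz.
#' @param duration Sweep duration, s.
#' @param amplitude Peak amplitude, mT/m.
#' @param dt Dwell time, s.
#' @param smax Slew-rate cap, T/m/s (`Inf` to disable).
#' @return An object of class `chirp_waveform` with the sample vector and
#'   the generating parameters.
#' @export
make_chirp <- function(bandwidth, duration, amplitude, dt = 6.4e-6, smax = Inf) {
  if (!isTRUE(bandwidth > 0) || !isTRUE(duration > 0) || !isTRUE(amplitude > 0)) {
    stop("bandwidth, duration and amplitude must be positive")
  }
  if (duration < 2 / bandwidth) stop("duration too short to represent the sweep")
  n <- max(2L, round(duration / dt))
  t <- (0:(n - 1)) * dt
  g <- amplitude * sin(pi * (bandwidth / duration) * t^2)
  scale <- 1
  peak_slew <- max(abs(diff(g))) * 1e-3 / dt
  if (is.finite(smax) && peak_slew > smax) {
    scale <- smax / peak_slew
    g <- g * scale
  }
  structure(
    list(
      samples = g, dt = dt, bandwidth = bandwidth, duration = duration,
      amplitude = amplitude * scale
    ),
    slew_scale = scale, class = "chirp_waveform"
  )
}

#' @export
print.chirp_waveform <- function(x, ...) {
  cat(sprintf(
    "<chirp_waveform> 0-%.3g kHz over %.3g ms, amplitude %.3g mT/m (slew scale %.3g)\n",
    x$bandwidth / 1e3, x$duration * 1e3, x$amplitude, attr(x, "slew_scale")
  ))
  invisible(x)
}

#' GIRF frequency resolution of an estimation window
#'
#' The frequency resolution of a GIRF estimate equals the reciprocal of the
#' record duration used in the deconvolution.
#'
#' @param window_duration Record duration, s.
#' @return Frequency resolution, Hz.
#' @export
#' @examples
#' girf_frequency_resolution(70e-3)   # 14.3 Hz
#' girf_frequency_resolution(6.4e-3)  # 156 Hz
girf_frequency_resolution <- function(window_duration) {
  if (!isTRUE(window_duration > 0)) stop("window_duration must be positive")
  1 / window_duration
}

#' Estimate a GIRF from input/output waveform pairs
#'
#' Least-squares multi-measurement frequency-domain deconvolution: per axis
#' `H(f) = sum_i O_i(f) conj(I_i(f)) / (sum_i |I_i(f)|^2 + eps)`, with all
#' records zero-padded to a common window. The regularizer
#' `eps = eps_rel * max_f sum_i |I_i(f)|^2` stabilizes out-of-band bins;
#' bins where the denominator falls below the floor are flagged in the
#' `"low_confidence"` attribute (an n x 3 logical matrix) rather than
#' rejected. Hermitian symmetry is enforced so the time-domain response is
#' real.
#'
#' @param inputs,outputs Lists of [gradient_waveform] objects on a shared
#'   dwell grid; `outputs[[i]]` is the measured (or simulated) response to
#'   `inputs[[i]]`.
#' @param window_duration Record duration used for the transform, s; sets
#'   the frequency resolution `df = 1 / window_duration` and must be at
#'   least as long as every record.
#' @param eps_rel Relative regularization of the denominator.
#' @return A [girf_spectrum].
#' @export
estimate_girf <- function(inputs, outputs, window_duration, eps_rel = 1e-6) {
  if (length(inputs) < 1 || length(inputs) != length(outputs)) {
    stop("need matching, non-empty input/output lists")
  }
  dt <- inputs[[1]]$dt
  nw <- round(window_duration / dt)
  for (w in c(inputs, outputs)) {
    stopifnot(inherits(w, "gradient_waveform"))
    if (abs(w$dt - dt) > 1e-15) stop("all records must share the dwell time")
    if (ncol(w$samples) > nw) {
      stop("window_duration must be at least as long as every record")
    }
  }
  pad <- function(x) c(x, numeric(nw - length(x)))
  H <- matrix(0 + 0i, nw, 3)
  lowconf <- matrix(FALSE, nw, 3)
  for (ax in 1:3) {
    num <- complex(real = numeric(nw))
    den <- numeric(nw)
    for (i in seq_along(inputs)) {
      I <- stats::fft(pad(inputs[[i]]$samples[ax, ]))
      O <- stats::fft(pad(outputs[[i]]$samples[ax, ]))
      num <- num + O * Conj(I)
      den <- den + Mod(I)^2
    }
    eps <- eps_rel * max(den)
    H[, ax] <- num / (den + eps)
    lowconf[, ax] <- den < eps
  }
  # Hermitian symmetrization: average H(f) with conj(H(-f)).
  idx_neg <- c(1L, nw:2L)
  H <- (H + Conj(H[idx_neg, , drop = FALSE])) / 2
  f <- .fftfreq(nw, dt)
  ord <- order(f)
  out <- girf_spectrum(f[ord], H[ord, , drop = FALSE], df = 1 / (nw * dt))
  attr(out, "low_confidence") <- lowconf[ord, , drop = FALSE]
  out
}

# Evaluate a girf_spectrum (or a closed-form function(f) -> n x 3 complex)
# on an arbitrary frequency axis.
.girf_eval <- function(H, freqs) {
  if (is.function(H)) {
    val <- H(freqs)
  } else if (inherits(H, "girf_spectrum")) {
    val <- sapply(1:3, function(ax) .interp(H$freqs, H$H[, ax], freqs))
  } else {
    stop("H must be a girf_spectrum or a function of frequency")
  }
  val <- as.matrix(val)
  storage.mode(val) <- "complex"
  val
}

#' Predict the played-out gradient waveform
#'
#' Applies the per-axis frequency response to a nominal gradient waveform:
#' the input is zero-padded by a factor of two (to suppress
#' circular-convolution wrap-around of responses with millisecond-scale
#' tails), transformed, multiplied by H resampled onto the padded frequency
#' grid, and transformed back. The output is truncated to the input length
#' plus a settling tail of `tail` times the input length.
#'
#' @param G_nom Nominal [gradient_waveform].
#' @param H A [girf_spectrum], or a function `f -> n x 3 complex matrix`
#'   giving the closed-form response (used by the synthetic scanner truth).
#' @param tail Fraction (0 to 0.1) of the input length kept as settling
#'   tail after the nominal end.
#' @return The predicted [gradient_waveform].
#' @export
predict_gradient <- function(G_nom, H, tail = 0.1) {
  stopifnot(inherits(G_nom, "gradient_waveform"))
  if (!isTRUE(tail >= 0 && tail <= 0.1)) stop("tail must be in [0, 0.1]")
  n <- ncol(G_nom$samples)
  n2 <- 2L * n
  f2 <- .fftfreq(n2, G_nom$dt)
  if (inherits(H, "girf_spectrum")) {
    fmax_H <- max(abs(H$freqs))
    for (ax in 1:3) {
      X <- Mod(stats::fft(c(G_nom$samples[ax, ], numeric(n))))^2
      tot <- sum(X)
      if (tot > 0 && sum(X[abs(f2) > fmax_H]) > 1e-9 * tot) {
        stop(sprintf(
          "GIRF frequency span (+/- %.3g kHz) is narrower than the signal band on axis %d",
          fmax_H / 1e3, ax
        ))
      }
    }
  }
  Hv <- .girf_eval(H, f2)
  nout <- n + as.integer(floor(tail * n))
  out <- matrix(0, 3, nout)
  for (ax in 1:3) {
    X <- stats::fft(c(G_nom$samples[ax, ], numeric(n)))
    y <- Re(stats::fft(X * Hv[, ax], inverse = TRUE)) / n2
    out[ax, ] <- y[seq_len(nout)]
  }
  gradient_waveform(out, G_nom$dt)
}

#' Deviation between nominal and actual gradients
#'
#' `G_tilde = G_nom - G_act`, the gradient-field deviation term that
#' perturbs the incremental spin rotation and violates the VERSE condition.
#'
#' @param G_nom,G_act [gradient_waveform] objects on a shared grid (the
#'   actual waveform may carry a settling tail; only the common part is
#'   differenced and the tail is dropped).
#' @return An object of class `gradient_deviation` with the difference
#'   samples and `max_rel`, the per-axis maximum deviation relative to the
#'   per-axis peak of the nominal waveform.
#' @export
gradient_deviation <- function(G_nom, G_act) {
  stopifnot(inherits(G_nom, "gradient_waveform"), inherits(G_act, "gradient_waveform"))
  if (abs(G_nom$dt - G_act$dt) > 1e-15) stop("waveforms must share the dwell time")
  n <- min(ncol(G_nom$samples), ncol(G_act$samples))
  d <- G_nom$samples[, 1:n, drop = FALSE] - G_act$samples[, 1:n, drop = FALSE]
  peak <- apply(abs(G_nom$samples), 1, max)
  max_rel <- apply(abs(d), 1, max) / ifelse(peak > 0, peak, NA_real_)
  structure(
    list(g_tilde = d, dt = G_nom$dt, max_rel = max_rel),
    class = "gradient_deviation"
  )
}

#' @export
print.gradient_deviation <- function(x, ...) {
  cat(sprintf(
    "<gradient_deviation> %d samples; max |G_tilde| per axis [mT/m]: %s; max relative: %s\n",
    ncol(x$g_tilde),
    paste(sprintf("%.3g", apply(abs(x$g_tilde), 1, max)), collapse = ", "),
    paste(sprintf("%.3g", x$max_rel), collapse = ", ")
  ))
  invisible(x)
}
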