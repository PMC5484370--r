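# Synthetic scanner model: everything needed to exercise the full method
# without scanner data — smooth 8-channel transmit sensitivity maps, a
# smooth off-resonance map, the blurred-square target, the 2x radially
# undersampled time-optimal spiral-in trajectory, and a "true" gradient
# system response standing in for the scanner and field camera.

#' Fixture configuration
#'
#' Defaults describe the phantom study conditions: a 30 x 30 mm^2 square
#' target blurred with a 10 mm FWHM Gaussian on a 64 x 64 grid over a
#' 128 x 128 mm^2 region, an 8-channel transmit array, and a single-shot
#' spiral-in trajectory encoding 2 mm resolution, 2x radially undersampled,
#' under 30 mT/m and 180 T/m/s with a 6.4 us dwell.
#'
#' @param fov Field of view, m.
#' @param n Grid size per dimension.
#' @param channels Number of transmit channels.
#' @param square Target square side, m.
#' @param blur_fwhm Gaussian blur full width at half maximum, m.
#' @param res Spiral encoding resolution, m.
#' @param undersampling Radial undersampling factor.
#' @param gmax Gradient amplitude limit, mT/m.
#' @param smax Slew-rate limit, T/m/s.
#' @param dwell Dwell time, s.
#' @param b0_span Peak-to-peak span of the off-resonance map, rad/s.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(fov = 0.128, n = 64L, channels = 8L, square = 0.030,
                           blur_fwhm = 0.010, res = 0.002, undersampling = 2,
                           gmax = 30, smax = 180, dwell = 6.4e-6,
                           b0_span = 400) {
  cfg <- list(
    fov = fov, n = as.integer(n), channels = as.integer(channels),
    square = square, blur_fwhm = blur_fwhm, res = res,
    undersampling = undersampling, gmax = gmax, smax = smax,
    dwell = dwell, b0_span = b0_span
  )
  if (any(unlist(cfg) <= 0)) stop("all fixture parameters must be positive")
  if (square >= fov) stop("target square must fit inside the FOV")
  structure(cfg, class = "fixture_config")
}

# cell-centred coordinates with the origin on grid point n/2 (0-based).
.grid_coords <- function(n, fov) ((0:(n - 1)) - n %/% 2) * (fov / n)

#' Blurred-square target excitation pattern
#'
#' Binary square of side `cfg$square` centred on the grid, convolved with a
#' normalized Gaussian kernel of `cfg$blur_fwhm` full width at half maximum
#' (cancelling aliased ringing at the edges), scaled to the requested flip
#' angle.
#'
#' @param cfg A [fixture_config].
#' @param flip Target flip angle, rad.
#' @return Nx x Ny numeric matrix (rad).
#' @export
make_target <- function(cfg = fixture_config(), flip = pi / 2) {
  xs <- .grid_coords(cfg$n, cfg$fov)
  inside <- abs(xs) <= cfg$square / 2 + 1e-12
  sq <- outer(inside, inside) * flip
  sigma <- cfg$blur_fwhm / (2 * sqrt(2 * log(2))) / (cfg$fov / cfg$n)  # cells
  rad <- ceiling(4 * sigma)
  ker <- stats::dnorm(-rad:rad, sd = sigma)
  ker <- ker / sum(ker)
  blur1d <- function(m) {
    pad <- matrix(0, rad, ncol(m))
    mp <- rbind(pad, m, pad)
    out <- m
    for (i in seq_len(nrow(m))) {
      out[i, ] <- colSums(mp[i:(i + 2 * rad), , drop = FALSE] * ker)
    }
    out
  }
  t(blur1d(t(blur1d(sq))))
}

#' Synthetic multi-channel field maps
#'
#' Deterministic (per seed) smooth complex transmit sensitivities — one
#' surface-coil-like lobe per channel placed around the FOV with a phase
#' roll across the field of view, peak-normalized — and a smooth
#' off-resonance map built from a few low-order spatial modes scaled to the
#' configured span. The summed-channel magnitude is positive everywhere
#' (no dead voxels).
#'
#' @param cfg A [fixture_config].
#' @param seed Integer seed; identical seeds give identical maps.
#' @param b0_span Override of `cfg$b0_span` (0 gives a zero off-resonance
#'   map).
#' @return A [field_maps].
#' @export
make_maps <- function(cfg = fixture_config(), seed = 1, b0_span = cfg$b0_span) {
  n <- cfg$n
  xs <- .grid_coords(n, cfg$fov)
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  .with_seed(seed, {
    C <- cfg$channels
    b1 <- array(0 + 0i, c(n, n, C))
    r_coil <- 0.075
    sig <- 0.055
    jitter <- stats::runif(C, -0.2, 0.2)
    ph0 <- stats::runif(C, -pi, pi)
    for (cc in 1:C) {
      th <- 2 * pi * (cc - 1) / C + jitter[cc]
      px <- r_coil * cos(th)
      py <- r_coil * sin(th)
      mag <- exp(-((X - px)^2 + (Y - py)^2) / (2 * sig^2))
      roll <- (pi / cfg$fov) * (cos(th) * X + sin(th) * Y)
      m <- mag * exp(1i * (ph0[cc] + roll))
      b1[, , cc] <- m / max(Mod(m))
    }
    dom <- matrix(0, n, n)
    for (j in 1:3) {
      cx <- stats::runif(1, -0.4, 0.4) * cfg$fov
      cy <- stats::runif(1, -0.4, 0.4) * cfg$fov
      w <- stats::runif(1, 0.25, 0.6) * cfg$fov
      dom <- dom + stats::runif(1, -1, 1) * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * w^2))
    }
    if (b0_span > 0 && diff(range(dom)) > 0) {
      dom <- (dom - mean(range(dom))) / diff(range(dom)) * b0_span
    } else {
      dom <- dom * 0
    }
    field_maps(b1, dom, cfg$fov)
  })
}

#' Time-optimal spiral-in excitation trajectory
#'
#' Archimedean spiral from `k_max = pi / res` inward to the origin with
#' radial pitch `undersampling * 2 pi / fov`, parametrized by arc length
#' and traversed time-optimally under the gradient amplitude and slew
#' limits, sampled at the dwell time. The gradient starts and ends at zero
#' amplitude and the trajectory ends exactly at the k-space origin.
#'
#' @param cfg A [fixture_config].
#' @param gamma Gyromagnetic ratio.
#' @return List with `g` ([gradient_waveform]) and `k` ([trajectory]).
#' @export
make_spiral_in <- function(cfg = fixture_config(), gamma = gyromagnetic_ratio()) {
  kmax <- pi / cfg$res
  pitch <- cfg$undersampling * 2 * pi / cfg$fov       # radial spacing, rad/m
  b <- pitch / (2 * pi)
  theta_max <- kmax / b
  # the Archimedean spiral r = kmax - b*theta has closed-form arc-length
  # element sqrt(r^2 + b^2) dtheta, tangent and curvature; only the smooth
  # theta(s) map is tabulated numerically
  nth <- max(20000L, 4L * cfg$n^2)
  th_d <- seq(0, theta_max, length.out = nth)
  r_d <- kmax - b * th_d
  s_d <- .cumtrapz(sqrt(r_d^2 + b^2), th_d[2] - th_d[1])
  S <- s_d[nth]
  ds <- gamma * cfg$gmax * 1e-3 * cfg$dwell / 16
  ns <- ceiling(S / ds) + 1L
  s <- seq(0, S, length.out = ns)
  th <- .interp(s_d, th_d, s)
  r <- kmax - b * th
  den <- sqrt(r^2 + b^2)
  # spiral-in: p = r(theta) * (cos, sin); dp/ds = dp/dtheta / |dp/dtheta|
  tx <- (-b * cos(th) - r * sin(th)) / den
  ty <- (-b * sin(th) + r * cos(th)) / den
  tangent <- rbind(tx, ty, 0)
  curv <- (r^2 + 2 * b^2) / den^3
  tr <- time_optimal_traverse(s, tangent, cfg$gmax, cfg$smax, gamma = gamma,
                              curvature = curv)
  arc <- structure(
    list(
      s = s, b1 = matrix(0 + 0i, 1, ns), gmag = rep(cfg$gmax, ns),
      tangent = tangent, W = matrix(0, 1, ns),
      v_orig = tr$v, dt_src = cfg$dwell, gamma = gamma,
      g_floor = 0, eps_rf = 1e-6
    ),
    class = "arc_pulse"
  )
  out <- from_sdomain(arc, tr$v, dt = cfg$dwell)
  list(g = out$g, k = compute_k(out$g, gamma))
}

#' Synthetic gradient-system truth response
#'
#' Per-axis closed-form frequency response used as the ground truth of the
#' synthetic scanner: a second-order low-pass (Butterworth-damped, -3 dB at
#' `fc`) times a narrow resonant feature of relative amplitude `res_amp` at
#' `res_freq` (emulating mechanical resonances of the gradient coils in the
#' 600-1800 Hz band). The x and y axes share a corner frequency; z is
#' slightly narrower. DC gain is exactly 1 and the response is Hermitian by
#' construction. This model is synthetic: it is plausible phenomenology,
#' not a measured system.
#'
#' @param fc Per-axis -3 dB corner frequencies, Hz.
#' @param res_freq Per-axis resonance frequencies, Hz.
#' @param res_amp Per-axis relative resonance amplitudes.
#' @param q Resonance quality factor.
#' @param noise Relative amplitude of band-limited measurement noise added
#'   by [play_through()] (0 disables).
#' @return An object of class `scanner_truth`; use it directly as the `H`
#'   argument of [predict_gradient()] via [play_through()], or evaluate it
#'   with [truth_spectrum()].
#' @export
scanner_truth <- function(fc = c(9000, 9000, 7000),
                          res_freq = c(1100, 1100, 1300),
                          res_amp = c(0.08, 0.08, 0.05),
                          q = 15, noise = 0) {
  structure(
    list(fc = fc, res_freq = res_freq, res_amp = res_amp, q = q, noise = noise),
    class = "scanner_truth"
  )
}

#' @export
print.scanner_truth <- function(x, ...) {
  cat(sprintf(
    "<scanner_truth> corners %s kHz; resonances %s Hz (amp %s), Q = %g; noise %.3g\n",
    paste(x$fc / 1e3, collapse = "/"), paste(x$res_freq, collapse = "/"),
    paste(x$res_amp, collapse = "/"), x$q, x$noise
  ))
  invisible(x)
}

#' Evaluate the truth response on a frequency axis
#'
#' @param truth A [scanner_truth].
#' @param freqs Frequencies, Hz.
#' @return length(freqs) x 3 complex matrix.
#' @export
truth_spectrum <- function(truth, freqs) {
  s <- 2i * pi * freqs
  H <- matrix(0 + 0i, length(freqs), 3)
  for (ax in 1:3) {
    w0 <- 2 * pi * truth$fc[ax]
    lp <- w0^2 / (s^2 + sqrt(2) * w0 * s + w0^2)
    wr <- 2 * pi * truth$res_freq[ax]
    bp <- (wr / truth$q) * s / (s^2 + (wr / truth$q) * s + wr^2)
    H[, ax] <- lp * (1 + truth$res_amp[ax] * bp)
  }
  H
}

#' Play a nominal waveform through the synthetic scanner
#'
#' The "monitored" oracle of the synthetic scanner: applies the closed-form
#' truth response via [predict_gradient()] and, if the truth carries a
#' non-zero noise level, adds band-limited noise scaled to that fraction of
#' the per-axis RMS amplitude.
#'
#' @param G_nom Nominal [gradient_waveform].
#' @param truth A [scanner_truth].
#' @param tail Settling-tail fraction passed to [predict_gradient()].
#' @param seed Seed for the noise draw (ignored at noise level 0).
#' @return The played-out [gradient_waveform].
#' @export
play_through <- function(G_nom, truth, tail = 0, seed = 1) {
  stopifnot(inherits(truth, "scanner_truth"))
  act <- predict_gradient(G_nom, function(f) truth_spectrum(truth, f), tail = tail)
  if (truth$noise > 0) {
    act$samples <- .with_seed(seed, {
      n <- ncol(act$samples)
      noisy <- act$samples
      for (ax in 1:3) {
        rms <- sqrt(mean(act$samples[ax, ]^2))
        w <- stats::rnorm(n)
        # band-limit white noise to a quarter of Nyquist
        W <- stats::fft(w)
        f <- .fftfreq(n, act$dt)
        W[abs(f) > 1 / (8 * act$dt)] <- 0
        w <- Re(stats::fft(W, inverse = TRUE)) / n
        noisy[ax, ] <- act$samples[ax, ] + truth$noise * rms * w / stats::sd(w)
      }
      noisy
    })
  }
  act
}

#' Simulate chirp-based GIRF calibration measurements
#'
#' Generates chirp test waveforms (all three axes driven simultaneously
#' with the same chirp; the response model has self-terms only), plays each
#' through the truth response with the record zero-padded to the
#' acquisition window so the settling tail is captured, and optionally adds
#' white measurement noise at a given SNR.
#'
#' @param truth A [scanner_truth].
#' @param bandwidths Chirp bandwidths, Hz.
#' @param duration Chirp duration, s.
#' @param amplitude Chirp amplitude, mT/m (down-scaled to the slew cap).
#' @param window Acquisition window, s (sets the GIRF frequency
#'   resolution).
#' @param dt Dwell time, s.
#' @param smax Slew cap for the chirps, T/m/s.
#' @param snr_db Output signal-to-noise ratio in dB (`Inf` for noiseless).
#' @param seed Seed for the noise draw.
#' @return List with `inputs` and `outputs`, ready for [estimate_girf()].
#' @export
simulate_chirp_measurements <- function(truth,
                                        bandwidths = c(10, 20, 30, 40) * 1e3,
                                        duration = 10e-3, amplitude = 8,
                                        window = 70e-3, dt = 6.4e-6,
                                        smax = 180, snr_db = Inf, seed = 1) {
  stopifnot(inherits(truth, "scanner_truth"))
  nw <- round(window / dt)
  inputs <- outputs <- vector("list", length(bandwidths))
  for (i in seq_along(bandwidths)) {
    ch <- make_chirp(bandwidths[i], duration, amplitude, dt = dt, smax = smax)
    g <- c(ch$samples, numeric(nw - length(ch$samples)))
    gin <- gradient_waveform(rbind(g, g, g), dt)
    gout <- predict_gradient(gin, function(f) truth_spectrum(truth, f), tail = 0)
    if (is.finite(snr_db)) {
      gout$samples <- .with_seed(seed + i, {
        # SNR is defined against the active portion of the record (the
        # chirp plus its settling), not the zero-padded tail
        nact <- min(nw, ceiling(1.2 * duration / dt))
        sig <- sqrt(mean(gout$samples[, 1:nact]^2))
        gout$samples + matrix(stats::rnorm(3 * nw, sd = sig * 10^(-snr_db / 20)), 3, nw)
      })
    }
    inputs[[i]] <- gin
    outputs[[i]] <- gout
  }
  list(inputs = inputs, outputs = outputs, window = nw * dt)
}

#' Generate the complete synthetic fixture
#'
#' Bundles maps, target, trajectory and gradient-system truth, and
#' (optionally) a GIRF estimated from simulated chirp calibration
#' measurements through that truth.
#'
#' @param cfg A [fixture_config].
#' @param seed Integer seed controlling every random draw.
#' @param flip Target flip angle, rad.
#' @param estimate_girf If `TRUE`, include `girf`, the GIRF estimated from
#'   four simulated chirp measurements (10-40 kHz, 10 ms, 70 ms window).
#' @param snr_db SNR of the simulated calibration measurements.
#' @param gamma Gyromagnetic ratio.
#' @return List with `cfg`, `maps`, `target`, `g_nom`, `k_nom`, `truth`,
#'   and optionally `girf`.
#' @export
make_fixture <- function(cfg = fixture_config(), seed = 1, flip = pi / 2,
                         estimate_girf = TRUE, snr_db = Inf,
                         gamma = gyromagnetic_ratio()) {
  maps <- make_maps(cfg, seed = seed)
  target <- make_target(cfg, flip = flip)
  sp <- make_spiral_in(cfg, gamma = gamma)
  truth <- scanner_truth()
  out <- list(
    cfg = cfg, maps = maps, target = target,
    g_nom = sp$g, k_nom = sp$k, truth = truth
  )
  if (estimate_girf) {
    meas <- simulate_chirp_measurements(
      truth, dt = cfg$dwell, smax = cfg$smax, snr_db = snr_db, seed = seed
    )
    out$girf <- estimate_girf(meas$inputs, meas$outputs, meas$window)
  }
  out
}
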