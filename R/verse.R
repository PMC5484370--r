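# Arc-length-domain time-optimal VERSE. The waveform pair {B1(t), G(t)} is
# transformed to the s-domain (s = distance traversed in excitation
# k-space), where the RF-to-gradient amplitude ratio W(s) = |B1(s)|/|G(s)|
# is invariant under any re-traversal speed. A peak-RF bound B1max then
# becomes the position-dependent gradient-amplitude bound
# |Gv(s)| <= min(alpha*B1max / max_c Wc(s), Gmax), and the reshaped pair is
# obtained by traversing the same k-space path time-optimally under that
# bound and the slew cap.

#' VERSE hardware and RF constraints
#'
#' @param b1_max Peak-RF bound, uT.
#' @param g_max Gradient amplitude limit, mT/m.
#' @param s_max Slew-rate limit, T/m/s.
#' @param alpha Attenuation factor in (0, 1]: VERSE targets
#'   `alpha * b1_max` to damp small oscillatory overshoots of the peak RF
#'   across iterations (default 0.95).
#' @return An object of class `verse_constraints`.
#' @export
verse_constraints <- function(b1_max, g_max = 30, s_max = 180, alpha = 0.95) {
  if (!isTRUE(b1_max > 0) || !isTRUE(g_max > 0) || !isTRUE(s_max > 0)) {
    stop("b1_max, g_max and s_max must be positive")
  }
  if (!isTRUE(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  structure(
    list(b1_max = b1_max, g_max = g_max, s_max = s_max, alpha = alpha),
    class = "verse_constraints"
  )
}

#' Transform a waveform pair to the arc-length domain
#'
#' Resamples the pair {B1(t), G(t)} onto a uniform arc-length grid
#' `s(t) = gamma * int_0^t |G| dtau`, and computes the per-channel invariant
#' ratio `W_c(s) = |B1_c(s)| / |G(s)|` together with the unit tangent of the
#' k-space path. RF energy at zero-gradient samples cannot be represented in
#' the s-domain and is rejected.
#'
#' @param B1 A [mc_rf].
#' @param G The paired [gradient_waveform] on the same grid.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param ds Arc-length grid spacing, rad/m; default
#'   `gamma * max|G| * dt / 16` (at least 16x oversampling of the fastest
#'   admissible traversal).
#' @param eps_g Gradient magnitudes below `eps_g * max|G|` count as zero.
#' @param eps_rf RF magnitudes below this (uT) count as zero when checking
#'   representability.
#' @return An object of class `arc_pulse` with elements `s`, `b1` (C x ns),
#'   `gmag`, `tangent` (3 x ns), `W` (C x ns), `v_orig` (the original
#'   traversal speed gamma*|G|, rad m^-1 s^-1), and bookkeeping fields.
#' @export
to_sdomain <- function(B1, G, gamma = gyromagnetic_ratio(), ds = NULL,
                       eps_g = 1e-4, eps_rf = 1e-6) {
  stopifnot(inherits(B1, "mc_rf"), inherits(G, "gradient_waveform"))
  if (ncol(B1$samples) != ncol(G$samples) || abs(B1$dt - G$dt) > 1e-15) {
    stop("RF and gradient must share the sample grid")
  }
  n <- ncol(G$samples)
  dt <- G$dt
  gmag_t <- sqrt(colSums(G$samples^2))
  gfloor <- eps_g * max(gmag_t)
  rfmag_t <- apply(Mod(B1$samples), 2, max)
  if (any(gmag_t <= gfloor & rfmag_t > eps_rf)) {
    stop("not VERSE-representable: RF energy at zero-gradient samples")
  }
  s_t <- arc_length(G, gamma)
  S <- s_t[n]
  if (S <= 0) stop("gradient waveform traverses zero arc length")
  if (is.null(ds)) ds <- gamma * max(gmag_t) * 1e-3 * dt / 16
  ns <- max(8L, ceiling(S / ds) + 1L)
  s <- seq(0, S, length.out = ns)
  tgrid <- (0:(n - 1)) * dt
  t_s <- .interp_inverse(s_t, tgrid, s)
  gx <- .interp(tgrid, G$samples[1, ], t_s)
  gy <- .interp(tgrid, G$samples[2, ], t_s)
  gz <- .interp(tgrid, G$samples[3, ], t_s)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  tangent <- rbind(gx, gy, gz)
  ok <- gmag > gfloor
  if (!any(ok)) stop("gradient magnitude is below the zero floor everywhere")
  tangent[, ok] <- sweep(tangent[, ok, drop = FALSE], 2, gmag[ok], "/")
  # propagate the nearest well-defined tangent into zero-gradient samples
  if (any(!ok)) {
    idx_ok <- which(ok)
    near <- idx_ok[pmax(1L, findInterval(which(!ok), idx_ok, all.inside = TRUE))]
    pick <- ifelse(
      abs(which(!ok) - near) <=
        abs(which(!ok) - idx_ok[pmin(length(idx_ok), findInterval(which(!ok), idx_ok) + 1L)]),
      near, idx_ok[pmin(length(idx_ok), findInterval(which(!ok), idx_ok) + 1L)]
    )
    tangent[, !ok] <- tangent[, pick, drop = FALSE]
  }
  C <- nrow(B1$samples)
  b1 <- matrix(0 + 0i, C, ns)
  for (cc in 1:C) b1[cc, ] <- .interp(tgrid, B1$samples[cc, ], t_s)
  W <- matrix(0, C, ns)
  gsafe <- pmax(gmag, gfloor)
  for (cc in 1:C) {
    w <- Mod(b1[cc, ]) / gsafe
    w[Mod(b1[cc, ]) <= eps_rf] <- 0
    W[cc, ] <- w
  }
  structure(
    list(
      s = s, b1 = b1, gmag = gmag, tangent = tangent, W = W,
      v_orig = gamma * gmag * 1e-3, t_orig = t_s, dt_src = dt,
      gamma = gamma, g_floor = gfloor, eps_rf = eps_rf
    ),
    class = "arc_pulse"
  )
}

#' @export
print.arc_pulse <- function(x, ...) {
  cat(sprintf(
    "<arc_pulse> %d s-samples over %.4g rad/m, %d channel(s), max W = %.3g uT/(mT/m)\n",
    length(x$s), max(x$s), nrow(x$b1), max(x$W)
  ))
  invisible(x)
}

#' Peak-RF bound mapped to a gradient-amplitude bound
#'
#' For every arc-length position, the VERSE gradients must satisfy
#' `|Gv(s)| <= min(alpha * b1_max / max_c W_c(s), g_max)`; channels with
#' zero RF impose no bound beyond the hardware limit.
#'
#' @param pulse An [arc_pulse] (or a C x ns matrix of W values).
#' @param constraints A [verse_constraints].
#' @return Numeric vector of the per-s gradient bound, mT/m (strictly
#'   positive).
#' @export
effective_gmax <- function(pulse, constraints) {
  stopifnot(inherits(constraints, "verse_constraints"))
  W <- if (inherits(pulse, "arc_pulse")) pulse$W else as.matrix(pulse)
  wmax <- apply(W, 2, max)
  bound <- ifelse(
    wmax > 0,
    pmin(constraints$alpha * constraints$b1_max / wmax, constraints$g_max),
    constraints$g_max
  )
  if (any(!is.finite(bound) | bound <= 0)) {
    stop("gradient-amplitude bound collapses to zero (infinite W)")
  }
  bound
}

# Curvature of the path from the unit tangent on the s-grid (central
# differences; one-sided at the endpoints). Units 1/(rad/m).
.curvature <- function(tangent, s) {
  ns <- length(s)
  ds <- s[2] - s[1]
  kap <- numeric(ns)
  if (ns >= 3) {
    d <- (tangent[, 3:ns, drop = FALSE] - tangent[, 1:(ns - 2), drop = FALSE]) / (2 * ds)
    kap[2:(ns - 1)] <- sqrt(colSums(d^2))
  }
  kap[1] <- sqrt(sum(((tangent[, 2] - tangent[, 1]) / ds)^2))
  kap[ns] <- sqrt(sum(((tangent[, ns] - tangent[, ns - 1]) / ds)^2))
  if (any(!is.finite(kap))) {
    stop(sprintf("non-finite curvature (cusp) at s = %.4g rad/m", s[which(!is.finite(kap))[1]]))
  }
  kap
}

#' Time-optimal traversal of a k-space path
#'
#' Phase-plane solution of the minimum-time traversal of a unit-speed
#' k-space path under a per-position amplitude bound and a slew cap. The
#' speed `v(s) = ds/dt` (rad m^-1 s^-1) is limited pointwise by the
#' amplitude cap `v <= gamma * bound(s)` and the centripetal cap
#' `kappa v^2 / gamma <= s_max`; forward (from `v(0) = v0`) and backward
#' (from `v(S) = v_end`) passes each enforce the tangential-slew inequality
#' `sqrt((v v')^2 + (kappa v^2)^2) / gamma <= s_max`, and the final profile
#' is the pointwise minimum.
#'
#' @param s Uniform arc-length grid, rad/m.
#' @param tangent 3 x ns unit tangent of the path (used for curvature), or
#'   `NULL` with `curvature` supplied directly.
#' @param bound Per-s gradient amplitude bound, mT/m (scalar or vector).
#' @param s_max Slew-rate limit, T/m/s.
#' @param gamma Gyromagnetic ratio.
#' @param curvature Optional per-s curvature, 1/(rad/m), overriding the
#'   tangent-derived value.
#' @param v0,v_end Boundary speeds (default 0: gradients start and end at
#'   zero).
#' @return List with `v` (speed per s), `t` (time map, s), and
#'   `duration = t[ns]`.
#' @export
time_optimal_traverse <- function(s, tangent, bound, s_max,
                                  gamma = gyromagnetic_ratio(),
                                  curvature = NULL, v0 = 0, v_end = 0) {
  ns <- length(s)
  stopifnot(ns >= 3)
  bound <- rep_len(bound, ns)
  if (any(bound <= 0)) stop("amplitude bound must be strictly positive")
  kap <- if (is.null(curvature)) .curvature(tangent, s) else rep_len(curvature, ns)
  ds <- s[2] - s[1]
  a_max <- gamma * s_max          # max |dG/dt| expressed as d(v)/dt, rad/m/s^2
  ampsq <- (gamma * bound * 1e-3)^2
  capsq <- pmin(ampsq, a_max / pmax(kap, 1e-300))
  passes <- function(capsq) {
    fwd <- numeric(ns)
    fwd[1] <- min(v0^2, capsq[1])
    for (i in 1:(ns - 1)) {
      acc <- sqrt(max(a_max^2 - (kap[i] * fwd[i])^2, 0))
      fwd[i + 1] <- min(capsq[i + 1], fwd[i] + 2 * ds * acc)
    }
    bwd <- numeric(ns)
    bwd[ns] <- min(v_end^2, capsq[ns])
    for (i in ns:2) {
      acc <- sqrt(max(a_max^2 - (kap[i] * bwd[i])^2, 0))
      bwd[i - 1] <- min(capsq[i - 1], bwd[i] + 2 * ds * acc)
    }
    pmin(fwd, bwd)
  }
  # Riding a sloped velocity cap spends part of the slew budget on the
  # tangential component, so the centripetal cap is tightened to the
  # combined inequality by fixed-point iteration: with w = v v' of the
  # current profile, kappa v^2 may use at most sqrt(a_max^2 - w^2).
  phi <- passes(capsq)
  for (rep in 1:6) {
    w <- c(0, (phi[3:ns] - phi[1:(ns - 2)]) / (4 * ds), 0)
    allowed <- sqrt(pmax(a_max^2 - pmin(w^2, a_max^2 * 0.99), 0))
    capsq <- pmin(ampsq, allowed / pmax(kap, 1e-300))
    phi <- passes(capsq)
  }
  v <- sqrt(phi)
  vm <- (v[-1] + v[-ns]) / 2
  if (any(vm <= 0)) stop("traversal stalls: zero admissible speed on an interior segment")
  t <- c(0, cumsum(ds / vm))
  list(v = v, t = t, duration = t[ns])
}

#' Resample an arc-length pulse back to the dwell grid
#'
#' Given a speed profile `v(s)`, reconstructs the time-domain pair:
#' `Gv(t) = (v(s(t)) / gamma) * g(s(t))` and
#' `B1v_c(t) = W_c(s(t)) * |Gv(t)| * exp(i * phase_c(s(t)))`, where
#' `g` is the unit tangent and the per-channel phase is carried over from
#' the original pulse. The end is padded to a whole dwell.
#'
#' @param pulse An [arc_pulse].
#' @param v Speed per s-sample from [time_optimal_traverse()] (or the
#'   original speed `pulse$v_orig` for an identity round trip).
#' @param dt Output dwell time, s.
#' @return List with `rf` ([mc_rf]), `g` ([gradient_waveform]), and `s_t`,
#'   the arc-length position of every output sample.
#' @export
from_sdomain <- function(pulse, v, dt = pulse$dt_src) {
  stopifnot(inherits(pulse, "arc_pulse"))
  ns <- length(pulse$s)
  if (length(v) != ns) stop("v must be given per s-sample")
  ds <- pulse$s[2] - pulse$s[1]
  vm <- (v[-1] + v[-ns]) / 2
  if (any(vm <= 0)) stop("speed profile stalls on an interior segment")
  t_s <- c(0, cumsum(ds / vm))
  Tend <- t_s[ns]
  if (Tend < 2 * dt) stop("traversal shorter than two dwells; decrease dt")
  nout <- as.integer(ceiling(Tend / dt - 1e-9)) + 1L
  tout <- pmin((0:(nout - 1)) * dt, Tend)
  s_t <- .interp_inverse(t_s, pulse$s, tout)
  v_t <- .interp(t_s, v, tout)
  tx <- .interp(pulse$s, pulse$tangent[1, ], s_t)
  ty <- .interp(pulse$s, pulse$tangent[2, ], s_t)
  tz <- .interp(pulse$s, pulse$tangent[3, ], s_t)
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tn[tn == 0] <- 1
  gmag_v <- v_t / pulse$gamma * 1e3            # mT/m
  g <- rbind(tx / tn, ty / tn, tz / tn) * rep(gmag_v, each = 3)
  C <- nrow(pulse$b1)
  rf <- matrix(0 + 0i, C, nout)
  for (cc in 1:C) {
    u <- pulse$b1[cc, ]
    mag <- Mod(u)
    phasor <- ifelse(mag > 0, u / mag, 1 + 0i)
    ph_t <- .interp(pulse$s, phasor, s_t)
    pm <- Mod(ph_t)
    ph_t <- ifelse(pm > 0, ph_t / pm, 1 + 0i)
    W_t <- .interp(pulse$s, pulse$W[cc, ], s_t)
    rf[cc, ] <- W_t * gmag_v * ph_t
  }
  list(rf = mc_rf(rf, dt), g = gradient_waveform(g, dt), s_t = s_t)
}

#' VERSE-reshape a waveform pair under constraints
#'
#' Convenience pipeline: transform to the arc-length domain, map the
#' (attenuated) peak-RF bound to a gradient-amplitude bound, solve the
#' time-optimal traversal, and resample back to the dwell grid. The output
#' traverses the identical k-space path with, wherever the RF was limiting,
#' peak RF at `alpha * b1_max`.
#'
#' @inheritParams to_sdomain
#' @param constraints A [verse_constraints].
#' @param dt Output dwell (defaults to the input dwell).
#' @param allow_speedup If `TRUE` (the default), the traversal is fully
#'   time-optimal and may locally speed up wherever the RF-to-gradient
#'   ratio permits. `FALSE` additionally caps the speed at the input's own
#'   traversal speed wherever the input gradient is significant, so
#'   reshaping only ever slows the waveform; the iterative loop uses this
#'   to keep successive reshapes monotone (re-accelerated regions would
#'   otherwise invite fresh peak-RF violations at the next redesign).
#' @param gain Optional per-time-sample gradient gain `|G_act| / |G_nom|`
#'   (length N). When the gradient chain plays out the commanded waveform
#'   with a frequency-dependent gain, the RF that a redesign on the actual
#'   trajectory will require scales with that gain; supplying it tightens
#'   (or relaxes) the gradient-amplitude bound accordingly, so the peak-RF
#'   target is met on the *actual* trajectory rather than the commanded
#'   one. Values are clamped to [0.5, 2].
#' @return List with `rf`, `g`, `arc` (the [arc_pulse]), `v`, and
#'   `duration` (s).
#' @export
verse_reshape <- function(B1, G, constraints, gamma = gyromagnetic_ratio(),
                          ds = NULL, dt = G$dt, gain = NULL,
                          allow_speedup = TRUE) {
  arc <- to_sdomain(B1, G, gamma = gamma, ds = ds)
  if (!is.null(gain)) {
    if (length(gain) != ncol(G$samples)) stop("gain must have one value per time sample")
    tgrid <- (0:(ncol(G$samples) - 1)) * G$dt
    gain_s <- pmin(pmax(.interp(tgrid, gain, arc$t_orig), 0.5), 2)
    arc$W <- sweep(arc$W, 2, gain_s, "*")
  }
  bound <- effective_gmax(arc, constraints)
  if (!allow_speedup) {
    sig <- arc$gmag > 0.05 * max(arc$gmag)
    bound[sig] <- pmin(bound[sig], arc$gmag[sig])
  }
  tr <- time_optimal_traverse(arc$s, arc$tangent, bound, constraints$s_max, gamma = gamma)
  out <- from_sdomain(arc, tr$v, dt = dt)
  list(rf = out$rf, g = out$g, arc = arc, v = tr$v, duration = tr$duration)
}

#' Diagnostic residual of the VERSE condition under gradient deviations
#'
#' The incremental-rotation axis is perturbed by the gradient deviation
#' `G_tilde = G_nom - G_act` and by off-resonance; this diagnostic reports
#' the per-sample relative magnitude of the perturbation,
#' `(|G_tilde| + |domega| / (gamma * r_ref)) / |G_nom|`, evaluated at a
#' reference radius. Zero everywhere iff the played-out gradients equal the
#' nominal ones and the pulse is on resonance.
#'
#' @param G_nom,G_act [gradient_waveform] objects on a shared grid.
#' @param domega Scalar reference off-resonance, rad/s (e.g. the peak of
#'   the off-resonance map).
#' @param gamma Gyromagnetic ratio.
#' @param r_ref Reference radius, m (default half of a 128 mm field of
#'   view).
#' @return Numeric vector of per-sample relative residuals.
#' @export
verse_condition_residual <- function(G_nom, G_act, domega = 0,
                                     gamma = gyromagnetic_ratio(), r_ref = 0.064) {
  dev <- gradient_deviation(G_nom, G_act)
  n <- ncol(dev$g_tilde)
  gnom_mag <- sqrt(colSums(G_nom$samples[, 1:n, drop = FALSE]^2))
  dtil_mag <- sqrt(colSums(dev$g_tilde^2))
  pert <- dtil_mag + abs(domega) / (gamma * r_ref) * 1e3  # mT/m equivalent
  ifelse(gnom_mag > 0, pert / gnom_mag, 0)
}
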