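# Arc-length-domain VERSE: s-domain transform, bound mapping, time-optimal
# traversal, resampling, and the reshaping invariants.

# helper: interpolate a per-s quantity onto another s-grid
.interp_w <- function(s, w, sout) {
  stats::approx(s, w, sout, rule = 2)$y
}

# Check the VERSE condition of a reshaped pair against the original
# arc-domain ratio: the per-sample |B1v|/|Gv| must equal W at the arc
# position recomputed independently by integrating the output gradient.
# The slew-limited ramps VERSE adds at the waveform ends (absent from the
# input pulse) are resampling-dominated and excluded; so are samples with
# negligible gradient or RF.
check_verse_condition <- function(vs, con, g_in, tol = 1e-3) {
  arc_in <- vs$arc
  wref <- max(arc_in$W)
  s_out <- arc_length(vs$g)
  gmag_v <- sqrt(colSums(vs$g$samples^2))
  n <- length(gmag_v)
  ramp <- ceiling((con$g_max * 1e-3 / con$s_max) / g_in$dt) + 1L
  core <- seq_len(n) > ramp & seq_len(n) <= n - ramp
  worst <- 0
  for (cc in seq_len(nrow(arc_in$W))) {
    w_out <- Mod(vs$rf$samples[cc, ]) / pmax(gmag_v, 1e-12)
    w_exp <- .interp_w(arc_in$s, arc_in$W[cc, ], s_out)
    sig <- core & gmag_v > 1e-3 * max(gmag_v) & w_exp > 1e-2 * wref
    if (any(sig)) {
      worst <- max(worst, max(abs(w_out[sig] - w_exp[sig]) / w_exp[sig]))
    }
  }
  worst
}

test_that("the s-domain transform preserves W, total arc length, and round trips", {
  dt <- 6.4e-6
  n <- 400L
  g <- gradient_waveform(rbind(rep(10, n), 0, 0), dt)
  rf <- mc_rf(matrix(20 + 0i, 1, n), dt)
  arc <- to_sdomain(rf, g)
  expect_equal(unname(arc$W[1, ]), rep(2, length(arc$s)), tolerance = 1e-9)
  expect_equal(max(arc$s), tail(arc_length(g), 1), tolerance = 1e-9)

  out <- from_sdomain(arc, arc$v_orig)
  expect_equal(ncol(out$g$samples), n)
  expect_lt(max(Mod(out$rf$samples - 20)), 1e-9)
  expect_lt(max(abs(out$g$samples - g$samples)), 1e-9)
})

test_that("smooth varying pulses round trip within interpolation tolerance", {
  dt <- 6.4e-6
  n <- 500L
  t <- (0:(n - 1)) * dt
  g <- gradient_waveform(rbind(8 + 3 * sin(2 * pi * 200 * t),
                               4 * cos(2 * pi * 200 * t), 2), dt)
  rf <- mc_rf(rbind(
    (5 + 3 * sin(2 * pi * 150 * t)) * exp(1i * 2 * pi * 100 * t),
    6 * exp(-((t - max(t) / 2) / (max(t) / 4))^2) + 0i
  ), dt)
  arc <- to_sdomain(rf, g, ds = gyromagnetic_ratio() * 11e-3 * dt / 40)
  out <- from_sdomain(arc, arc$v_orig)
  m <- min(ncol(out$g$samples), n)
  expect_lt(max(abs(out$g$samples[, 1:m] - g$samples[, 1:m])) / max(abs(g$samples)), 1e-4)
  expect_lt(max(Mod(out$rf$samples[, 1:m] - rf$samples[, 1:m])) / max(Mod(rf$samples)), 1e-4)
})

test_that("RF energy on zero-gradient samples is rejected", {
  dt <- 6.4e-6
  g <- gradient_waveform(rbind(c(0, 0, rep(10, 48)), 0, 0), dt)
  rf <- mc_rf(matrix(5 + 0i, 1, 50), dt)
  expect_error(to_sdomain(rf, g), "not VERSE-representable")
})

test_that("the peak-RF bound maps to the documented gradient bound", {
  dt <- 6.4e-6
  n <- 100L
  g <- gradient_waveform(rbind(rep(10, n), 0, 0), dt)

  # zero RF: hardware limit everywhere
  arc0 <- to_sdomain(mc_rf(matrix(0i, 1, n), dt), g)
  con <- verse_constraints(b1_max = 10, g_max = 40, s_max = 200, alpha = 1)
  expect_equal(unname(effective_gmax(arc0, con)), rep(40, length(arc0$s)))

  # single channel, W = 2 -> bound 5 mT/m
  arc2 <- to_sdomain(mc_rf(matrix(20 + 0i, 1, n), dt), g)
  expect_equal(unname(effective_gmax(arc2, con)), rep(5, length(arc2$s)), tolerance = 1e-9)

  # two channels: the larger W rules at every s (both orderings)
  for (ord in list(c(1, 2), c(2, 1))) {
    rf2 <- mc_rf(rbind(matrix(20 + 0i, 1, n), matrix(30 + 0i, 1, n))[ord, ], dt)
    arc3 <- to_sdomain(rf2, g)
    expect_equal(unname(effective_gmax(arc3, con)),
                 rep(10 / 3, length(arc3$s)), tolerance = 1e-9)
  }
})

test_that("a straight line is traversed with the 1-D time-optimal profile", {
  gam <- gyromagnetic_ratio()
  S <- 5000
  ns <- 4001L
  s <- seq(0, S, length.out = ns)
  tangent <- rbind(rep(1, ns), 0, 0)
  bound <- 20        # mT/m
  smax <- 180
  tr <- time_optimal_traverse(s, tangent, bound, smax, curvature = rep(0, ns))
  vmax <- gam * bound * 1e-3
  a <- gam * smax
  # accelerate-cruise-decelerate closed form
  s_acc <- vmax^2 / (2 * a)
  t_exact <- if (2 * s_acc <= S) 2 * vmax / a + (S - 2 * s_acc) / vmax else 2 * sqrt(S / a)
  expect_equal(tr$duration, t_exact, tolerance = 6.4e-6 / t_exact)
  expect_lte(max(tr$v), vmax * (1 + 1e-9))
})

test_that("a circular arc cruises at the amplitude cap with a safe centripetal load", {
  gam <- gyromagnetic_ratio()
  R <- 5000                      # rad/m; gentle curvature
  ns <- 4001L
  S <- pi * R / 2
  s <- seq(0, S, length.out = ns)
  th <- s / R
  tangent <- rbind(-sin(th), cos(th), 0)
  bound <- 10
  smax <- 180
  tr <- time_optimal_traverse(s, tangent, bound, smax, curvature = rep(1 / R, ns))
  vmax <- gam * bound * 1e-3
  mid <- (ns %/% 4):(3 * ns %/% 4)
  # amplitude-dominated regime: cruise at gamma * bound
  expect_equal(max(tr$v[mid]), vmax, tolerance = 1e-6)
  expect_lte(max(tr$v^2 / R) / gam, smax * (1 + 1e-6))

  # halving the bound halves the cruise speed; durations match the
  # accelerate-cruise-decelerate closed form, so the ratio approaches 2
  # up to the acceleration phases
  tr2 <- time_optimal_traverse(s, tangent, bound / 2, smax, curvature = rep(1 / R, ns))
  expect_equal(max(tr2$v[mid]), vmax / 2, tolerance = 1e-6)
  a <- gam * smax
  t_closed <- function(v) 2 * v / a + (S - v^2 / a) / v
  expect_equal(tr$duration, t_closed(vmax), tolerance = 1e-3)
  expect_equal(tr2$duration, t_closed(vmax / 2), tolerance = 1e-3)
  expect_equal(tr2$duration / tr$duration, 2, tolerance = 0.02)
})

test_that("a uniform pulse 2x over the bound halves in amplitude and doubles in duration", {
  dt <- 6.4e-6
  n <- 400L
  g <- gradient_waveform(rbind(rep(10, n), 0, 0), dt)
  rf <- mc_rf(matrix(20 + 0i, 1, n), dt)
  con <- verse_constraints(b1_max = 10, g_max = 1000, s_max = 1e5, alpha = 1)
  vs <- verse_reshape(rf, g, con)
  expect_equal(max(Mod(vs$rf$samples)), 10, tolerance = 1e-6)
  expect_equal(max(sqrt(colSums(vs$g$samples^2))), 5, tolerance = 1e-6)
  expect_equal(vs$duration / (n * dt), 2, tolerance = 2 * dt / (n * dt))
})

test_that("VERSE reshaping preserves W, satisfies the bounds, and retraces the path", {
  for (case in verse_cases()) {
    vs <- verse_reshape(case$rf, case$g, case$con)

    # (1) VERSE condition: per-channel |B1v|/|Gv| equals the original W(s)
    expect_lt(check_verse_condition(vs, case$con, case$g), 1e-3)

    # (2) constraint satisfaction: amplitude bound and slew cap
    expect_lte(max(Mod(vs$rf$samples)), case$con$alpha * case$con$b1_max * (1 + 2e-3))
    expect_lte(max(sqrt(colSums(vs$g$samples^2))), case$con$g_max * (1 + 1e-6))
    expect_lte(max(abs(slew_rate(vs$g))), case$con$s_max * (1 + 0.02))

    # (3) geometry preservation relative to the k-space extent
    h <- hausdorff_path(compute_k(case$g), compute_k(vs$g))
    expect_lt(h, 1e-3 * max(sqrt(colSums(compute_k(case$g)$k^2))))
  }
})

test_that("already-feasible pulses are not spuriously stretched", {
  dt <- 6.4e-6
  n <- 500L
  t <- (0:(n - 1)) * dt
  g <- gradient_waveform(rbind(8 + 2 * sin(2 * pi * 150 * t),
                               3 * cos(2 * pi * 150 * t), 1), dt)
  rf <- mc_rf(matrix(2 * exp(-((t - max(t) / 2) / (max(t) / 3))^2) + 0i, 1, n), dt)
  con <- verse_constraints(b1_max = 50, g_max = 30, s_max = 180, alpha = 0.95)
  vs <- verse_reshape(rf, g, con)
  # time-optimal re-traversal of a feasible pulse may speed it up but the
  # reshaped result must still be feasible and no slower than the original
  expect_lte(vs$duration, n * dt + dt)
  expect_lte(max(Mod(vs$rf$samples)), con$alpha * con$b1_max * (1 + 1e-3))
})

test_that("the condition residual reports relative gradient perturbations", {
  set.seed(11)
  g <- gradient_waveform(matrix(rnorm(300, sd = 5) + 8, 3), 6.4e-6)
  expect_true(all(verse_condition_residual(g, g) == 0))
  g90 <- gradient_waveform(0.9 * g$samples, g$dt)
  expect_equal(verse_condition_residual(g, g90), rep(0.1, 100), tolerance = 1e-9)
})
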