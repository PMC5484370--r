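# Heavy fixture computations are shared across test files through a
# session-level cache so the end-to-end runs happen once.

.ptx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .ptx_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .ptx_cache)
  }
  get(name, envir = .ptx_cache, inherits = FALSE)
}

default_fixture <- function() {
  cached("fixture", make_fixture(fixture_config(), seed = 1))
}

phantom_constraints <- function() {
  cfg <- fixture_config()
  verse_constraints(b1_max = 12, g_max = cfg$gmax, s_max = cfg$smax, alpha = 0.95)
}

girf_fit <- function() {
  cached("fit_girf", {
    fx <- default_fixture()
    reverse_design(fx$maps, fx$target, fx$g_nom, phantom_constraints(),
                   oracle = gradient_oracle("girf", girf = fx$girf),
                   max_iter = 10)
  })
}

nominal_fit <- function() {
  cached("fit_nominal", {
    fx <- default_fixture()
    reverse_design(fx$maps, fx$target, fx$g_nom, phantom_constraints(),
                   oracle = gradient_oracle("nominal"), max_iter = 10)
  })
}

# Bloch NRMSE of a fitted design when its commanded gradient is played out
# through the synthetic scanner truth.
true_playout_nrmse <- function(fit) {
  fx <- default_fixture()
  act <- play_through(fit$final$g_nominal, fx$truth)
  sim <- bloch_propagate(fit$final$rf, act, fx$maps)
  nrmse(sim, fx$target, fx$maps$mask)
}

# A small, quick design problem (coarser grid, shorter spiral) for tests
# that need a full design but not the headline fixture.
small_problem <- function() {
  cached("small_problem", {
    cfg <- fixture_config(n = 32L, res = 0.004, channels = 4L)
    list(
      cfg = cfg,
      maps = make_maps(cfg, seed = 3),
      target = make_target(cfg, flip = pi / 2),
      spiral = make_spiral_in(cfg)
    )
  })
}

# Smooth multi-channel VERSE test cases on gently curved, well-resolved
# k-space paths (where sub-1e-3 rad/m geometry preservation is meaningful).
verse_cases <- function() {
  cached("verse_cases", {
    dt <- 6.4e-6
    lapply(1:4, function(case) {
      set.seed(100 + case)
      n <- 600L
      t <- (0:(n - 1)) * dt
      f1 <- stats::runif(1, 150, 400)
      g <- rbind(
        6 + 2 * sin(2 * pi * f1 * t),
        3 * cos(2 * pi * f1 * t + stats::runif(1, 0, pi)),
        1.5 + sin(2 * pi * 0.5 * f1 * t)
      )
      env <- exp(-((t - mean(t)) / (0.25 * max(t)))^2)
      rf <- rbind(
        12 * env * exp(1i * 2 * pi * stats::runif(1, -200, 200) * t),
        (5 + 3 * sin(2 * pi * f1 / 3 * t)) * env *
          exp(1i * (stats::runif(1, -pi, pi) + 2 * pi * 80 * t))
      )
      list(
        rf = mc_rf(rf, dt),
        g = gradient_waveform(g, dt),
        con = verse_constraints(
          b1_max = stats::runif(1, 5, 8), g_max = 30, s_max = 180, alpha = 0.95
        )
      )
    })
  })
}
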