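# Small-tip spatial-domain design: operator correctness against a dense
# matrix, solver behaviour, L-curve selection, and design properties.

dense_system <- function(maps, k, dt, gamma = gyromagnetic_ratio()) {
  idx <- which(maps$mask)
  xs <- rep(maps$x, times = maps$ny)[idx]
  ys <- rep(maps$y, each = maps$nx)[idx]
  nt <- ncol(k$k)
  D <- matrix(0 + 0i, length(idx), nt * maps$nc)
  for (cc in seq_len(maps$nc)) {
    for (tt in seq_len(nt)) {
      ph <- k$k[1, tt] * xs + k$k[2, tt] * ys + maps$domega[idx] * (tt - nt) * dt
      D[, (cc - 1) * nt + tt] <- 1i * gamma * maps$m0 * dt * 1e-6 *
        maps$b1[, , cc][idx] * exp(1i * ph)
    }
  }
  D
}

rand_maps <- function(n = 8, nc = 2, seed = 7, dw_sd = 100) {
  set.seed(seed)
  b1 <- array(complex(real = rnorm(n * n * nc), imaginary = rnorm(n * n * nc)),
              c(n, n, nc))
  field_maps(b1, matrix(rnorm(n * n, sd = dw_sd), n, n), fov = 0.128)
}

rand_traj <- function(nt = 40, seed = 8) {
  set.seed(seed)
  kk <- cbind(rbind(rnorm(nt - 1, sd = 300), rnorm(nt - 1, sd = 300), 0), c(0, 0, 0))
  trajectory(kk, 6.4e-6)
}

test_that("the system operator degenerates correctly and matches the dense matrix", {
  n <- 8
  dt <- 6.4e-6
  # k = 0, domega = 0, single uniform channel: every column is i*gamma*dt
  maps1 <- field_maps(array(1 + 0i, c(n, n, 1)), matrix(0, n, n), 0.128)
  k0 <- trajectory(matrix(0, 3, 10), dt)
  A1 <- build_system(maps1, k0)
  x <- matrix(0i, 10, 1); x[4] <- 1
  expect_equal(A1$apply(x), rep(1i * gyromagnetic_ratio() * dt * 1e-6, n * n),
               tolerance = 1e-12)

  maps <- rand_maps()
  k <- rand_traj()
  A <- build_system(maps, k)
  D <- dense_system(maps, k, dt)
  set.seed(9)
  xr <- complex(real = rnorm(80), imaginary = rnorm(80))
  yr <- complex(real = rnorm(64), imaginary = rnorm(64))
  expect_lt(max(Mod(A$apply(matrix(xr, 40, 2)) - D %*% xr)), 1e-14)
  # adjoint identity <Ax, y> = <x, A^H y>
  lhs <- sum(Conj(yr) * A$apply(matrix(xr, 40, 2)))
  rhs <- sum(Conj(as.vector(A$adjoint(yr))) * xr)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  expect_error(field_maps(array(1 + 0i, c(4, 4, 1)), matrix(0, 4, 4), 0.1,
                          mask = matrix(FALSE, 4, 4)), "non-empty")
})

test_that("CG solves the regularized normal equations to the dense solution", {
  maps <- rand_maps()
  k <- rand_traj()
  A <- build_system(maps, k)
  D <- dense_system(maps, k, 6.4e-6)
  set.seed(10)
  y <- complex(real = rnorm(64), imaginary = rnorm(64)) * 0.1

  # zero target with positive lambda gives the zero pulse
  z <- solve_tikhonov_cg(A, y * 0, lambda = 1e-8)
  expect_true(all(z$x == 0))

  lam <- Re(mean(diag(Conj(t(D)) %*% D)))
  sol <- solve_tikhonov_cg(A, y, lam, max_iter = 400, tol = 1e-10)
  xd <- solve(Conj(t(D)) %*% D + lam * diag(80), Conj(t(D)) %*% y)
  expect_lt(sqrt(sum(Mod(as.vector(sol$x) - xd)^2) / sum(Mod(xd)^2)), 1e-6)
})

test_that("the uniform problem recovers the minimum-norm constant pulse", {
  n <- 8
  dt <- 6.4e-6
  nt <- 25
  maps <- field_maps(array(1 + 0i, c(n, n, 1)), matrix(0, n, n), 0.128)
  A <- build_system(maps, trajectory(matrix(0, 3, nt), dt))
  theta <- 0.1
  # target with the natural phase of i*gamma*b: theta * exp(i*pi/2)
  sol <- solve_tikhonov_cg(A, rep(theta * 1i, n * n), 0, max_iter = 200, tol = 1e-12)
  b <- sol$x[, 1]
  expect_lt(max(Mod(b - b[1])) / Mod(b[1]), 1e-8)          # constant in time
  achieved <- gyromagnetic_ratio() * 1e-6 * sum(Re(b)) * dt
  expect_equal(achieved, theta, tolerance = 1e-8)
})

test_that("L-curve selection finds the corner of a noisy problem", {
  # consistent solution plus additive noise, so the L-curve has a genuine
  # corner separating signal fitting from noise fitting
  n <- 8
  maps <- rand_maps(n = n, nc = 1, seed = 12, dw_sd = 0)
  k <- rand_traj(nt = 30, seed = 13)
  A <- build_system(maps, k)
  set.seed(14)
  x0 <- complex(real = rnorm(30), imaginary = rnorm(30))
  clean <- A$apply(matrix(x0, 30, 1))
  tgt <- clean + 0.02 * sqrt(mean(Mod(clean)^2)) *
    complex(real = rnorm(n * n), imaginary = rnorm(n * n))
  lam0 <- A$scale^2 * sum(Mod(A$b1m)^2) / A$nc
  grid <- exp(seq(log(1e-6), log(1e2), length.out = 14)) * lam0
  sel <- lcurve_select(A, tgt, grid, cg = list(max_iter = 300, tol = 1e-10))
  # brute force: same solves, same curvature convention, independent code
  rho <- eta <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- solve_tikhonov_cg(A, tgt, grid[i], max_iter = 300, tol = 1e-10)
    rho[i] <- s$residual
    eta[i] <- sqrt(sum(Mod(s$x)^2))
  }
  kap <- lcurve_curvature(log(rho), log(eta))
  expect_equal(sel$lambda, grid[which.max(replace(kap, c(1, length(kap)), -Inf))])
  expect_true(sel$lambda %in% grid)
  # the corner lies strictly inside the grid, bends toward the origin
  # (positive curvature in the documented orientation), and sits past the
  # flat small-lambda branch where the residual is still at its floor
  i_sel <- match(sel$lambda, grid)
  expect_gt(i_sel, 1)
  expect_lt(i_sel, length(grid))
  expect_gt(kap[i_sel], 0)
  expect_gt(rho[i_sel], 2 * min(rho))

  expect_error(lcurve_select(A, tgt, c(1, 1, 2)), "duplicate")
  expect_error(lcurve_select(A, tgt, c(1, 2)), "at least 3")
})

test_that("designs are linear in the target and equivariant to channel order", {
  sm <- small_problem()
  k <- sm$spiral$k
  t10 <- make_target(sm$cfg, flip = 10 * pi / 180)
  d1 <- design_pulse(sm$maps, k, t10, lambda = 0, cg = list(max_iter = 60, tol = 1e-8))
  d2 <- design_pulse(sm$maps, k, 2 * t10, lambda = 0, cg = list(max_iter = 60, tol = 1e-8))
  expect_lt(max(Mod(d2$rf$samples - 2 * d1$rf$samples)) / max(Mod(d1$rf$samples)), 1e-4)

  perm <- c(3, 1, 4, 2)
  mp <- field_maps(sm$maps$b1[, , perm], sm$maps$domega, sm$maps$fov)
  dp <- design_pulse(mp, k, t10, lambda = 0, cg = list(max_iter = 60, tol = 1e-8))
  expect_lt(max(Mod(dp$rf$samples - d1$rf$samples[perm, ])) / max(Mod(d1$rf$samples)), 1e-6)
  expect_equal(dp$nrmse, d1$nrmse, tolerance = 1e-8)
})

test_that("off-resonance compensation does not hurt the compensated design", {
  sm <- small_problem()
  t30 <- make_target(sm$cfg, flip = 30 * pi / 180)
  # design WITH the off-resonance model
  d_comp <- design_pulse(sm$maps, sm$spiral$k, t30, lambda = 1e-8)
  # design pretending domega = 0, evaluated on the true maps
  maps0 <- field_maps(sm$maps$b1, sm$maps$domega * 0, sm$maps$fov)
  d_un <- design_pulse(maps0, sm$spiral$k, t30, lambda = 1e-8)
  sim_comp <- small_tip(d_comp$rf, sm$spiral$g, sm$maps)
  sim_un <- small_tip(d_un$rf, sm$spiral$g, sm$maps)
  expect_lte(nrmse(Mod(sim_comp$mxy), t30, sm$maps$mask),
             nrmse(Mod(sim_un$mxy), t30, sm$maps$mask))
})

test_that("design-time prediction equals the small-tip simulator bit for bit", {
  sm <- small_problem()
  t10 <- make_target(sm$cfg, flip = 10 * pi / 180)
  des <- design_pulse(sm$maps, sm$spiral$k, t10, lambda = 1e-8)
  st <- small_tip(des$rf, sm$spiral$g, sm$maps)
  expect_identical(des$predicted, st$mxy)
})
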