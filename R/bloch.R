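# Bloch-level evaluation of a waveform pair on field maps: the exact
# small-tip-angle prediction (shared kernel with the design operator) and
# full hard-pulse rotation propagation, relaxation neglected.

#' Excitation result container
#'
#' @param mxy Complex transverse-magnetization map (units of `m0`).
#' @param mz Real longitudinal map.
#' @param m0 Equilibrium magnetization scale.
#' @return An object of class `excitation_result` with `mxy`, `mz`, and
#'   `flip` (radians, `atan2(|mxy|, mz)`).
#' @export
excitation_result <- function(mxy, mz, m0 = 1) {
  flip <- atan2(Mod(mxy), mz)
  structure(list(mxy = mxy, mz = mz, flip = flip, m0 = m0),
            class = "excitation_result")
}

#' @export
print.excitation_result <- function(x, ...) {
  cat(sprintf(
    "<excitation_result> %d x %d; max flip %.3g deg; max |Mxy| %.4g\n",
    nrow(x$flip), ncol(x$flip), max(x$flip) * 180 / pi, max(Mod(x$mxy))
  ))
  invisible(x)
}

#' Small-tip-angle excitation prediction
#'
#' Direct discretized evaluation of the small-tip integral (summed over
#' channels and time) on the field maps. Uses the identical encoding kernel
#' as [build_system()], so the design-time prediction and this evaluation
#' agree bit for bit. Valid for any flip magnitude, with accuracy degrading
#' by design outside the small-tip regime; `mz` is reported as the
#' equilibrium value.
#'
#' @param rf A [mc_rf].
#' @param G The paired [gradient_waveform] (may carry a settling tail
#'   beyond the RF; the RF is zero-padded to match).
#' @param maps A [field_maps].
#' @param gamma Gyromagnetic ratio.
#' @return An [excitation_result]; `mxy` is in units of `m0` (flip angle in
#'   radians for `m0 = 1`).
#' @export
small_tip <- function(rf, G, maps, gamma = gyromagnetic_ratio()) {
  stopifnot(inherits(rf, "mc_rf"), inherits(G, "gradient_waveform"))
  rfs <- .pad_rf(rf, G, maps)
  k <- compute_k(G, gamma)
  A <- build_system(maps, k, dt = G$dt, gamma = gamma)
  mxy <- matrix(0 + 0i, maps$nx, maps$ny)
  mxy[A$idx] <- A$apply(t(rfs))
  excitation_result(mxy, matrix(maps$m0, maps$nx, maps$ny), maps$m0)
}

# zero-pad RF samples to the gradient length (settling tails).
.pad_rf <- function(rf, G, maps = NULL) {
  n <- ncol(G$samples)
  if (ncol(rf$samples) > n) stop("RF longer than gradient waveform")
  if (abs(rf$dt - G$dt) > 1e-15) stop("RF and gradient must share the dwell time")
  if (!is.null(maps) && nrow(rf$samples) != maps$nc) {
    stop("RF channel count does not match the sensitivity maps")
  }
  cbind(rf$samples, matrix(0 + 0i, nrow(rf$samples), n - ncol(rf$samples)))
}

#' Hard-pulse Bloch propagation
#'
#' Per voxel, applies one rotation per dwell about the local effective
#' field (transverse components: the channel-combined RF; longitudinal:
#' `G(t) . r + domega / gamma`), starting from equilibrium `(0, 0, m0)` and
#' neglecting relaxation. Rotations are orthogonal, so the magnetization
#' norm is conserved to rounding.
#'
#' @inheritParams small_tip
#' @return An [excitation_result].
#' @export
bloch_propagate <- function(rf, G, maps, gamma = gyromagnetic_ratio()) {
  stopifnot(inherits(rf, "mc_rf"), inherits(G, "gradient_waveform"))
  rfs <- .pad_rf(rf, G, maps)
  idx <- which(maps$mask)
  nv <- length(idx)
  xs <- rep(maps$x, times = maps$ny)[idx]
  ys <- rep(maps$y, each = maps$nx)[idx]
  dwz <- maps$domega[idx] / gamma                      # T
  b1m <- matrix(sapply(seq_len(maps$nc), function(cc) maps$b1[, , cc][idx]), ncol = maps$nc)
  Brf <- (b1m %*% rfs) * 1e-6                          # voxel x time, T
  dt <- G$dt
  nt <- ncol(G$samples)
  Mx <- numeric(nv); My <- numeric(nv); Mz <- rep(maps$m0, nv)
  for (tt in seq_len(nt)) {
    bx <- Re(Brf[, tt])
    by <- Im(Brf[, tt])
    bz <- (xs * G$samples[1, tt] + ys * G$samples[2, tt]) * 1e-3 + dwz
    bn <- sqrt(bx^2 + by^2 + bz^2)
    live <- bn > 0
    if (!any(live)) next
    nx <- ifelse(live, bx / bn, 0)
    ny <- ifelse(live, by / bn, 0)
    nz <- ifelse(live, bz / bn, 1)
    phi <- -gamma * bn * dt
    cphi <- cos(phi); sphi <- sin(phi)
    dotp <- nx * Mx + ny * My + nz * Mz
    cx <- ny * Mz - nz * My
    cy <- nz * Mx - nx * Mz
    cz <- nx * My - ny * Mx
    oc <- 1 - cphi
    Mx2 <- Mx * cphi + cx * sphi + nx * dotp * oc
    My2 <- My * cphi + cy * sphi + ny * dotp * oc
    Mz2 <- Mz * cphi + cz * sphi + nz * dotp * oc
    Mx <- ifelse(live, Mx2, Mx)
    My <- ifelse(live, My2, My)
    Mz <- ifelse(live, Mz2, Mz)
  }
  mxy <- matrix(0 + 0i, maps$nx, maps$ny)
  mz <- matrix(maps$m0, maps$nx, maps$ny)
  mxy[idx] <- complex(real = Mx, imaginary = My)
  mz[idx] <- Mz
  excitation_result(mxy, mz, maps$m0)
}

#' Normalized root-mean-square excitation error
#'
#' `||  |pattern| - |target|  ||_2 / || target ||_2` over the mask, both in
#' flip-angle units. Accepts an [excitation_result] (its flip map is used)
#' or a plain magnitude map.
#'
#' @param pattern An [excitation_result] or numeric/complex matrix.
#' @param target Non-negative target magnitude map (flip angle, rad).
#' @param mask Logical evaluation mask (default: everywhere).
#' @return NRMSE as a fraction.
#' @export
nrmse <- function(pattern, target, mask = NULL) {
  p <- if (inherits(pattern, "excitation_result")) pattern$flip else Mod(as.matrix(pattern))
  target <- as.matrix(target)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(target), ncol(target))
  tn <- sqrt(sum(target[mask]^2))
  if (tn == 0) stop("all-zero target over the mask")
  sqrt(sum((p[mask] - abs(target[mask]))^2)) / tn
}
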