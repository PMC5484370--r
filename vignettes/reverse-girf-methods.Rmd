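---
title: "Methods: GIRF-corrected iterative VERSE design of parallel-transmit pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GIRF-corrected iterative VERSE design of parallel-transmit pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-dimensional spatially selective excitation shapes the flip-angle
distribution by playing a long RF pulse while the gradients trace a
trajectory through excitation k-space. With parallel transmission (pTx),
several coils with distinct complex sensitivities $B_1^c(\mathbf r)$ are
driven simultaneously, which shortens pulses at the cost of high peak RF
power. Two practical effects limit the accuracy of such pulses:

1. **Peak-RF limits.** Amplifiers cap the instantaneous RF magnitude, and
   accelerated pTx designs routinely exceed that cap.
2. **Gradient-chain imperfections.** Eddy currents, amplifier bandwidth and
   mechanical resonances make the *actual* gradient field differ from the
   commanded (nominal) waveform by several percent, so the k-space
   trajectory the RF was designed for is not the one that is played out.

This package implements the combination of three ingredients that address
both at once: small-tip-angle spatial-domain pTx design, time-optimal
variable-rate selective excitation (VERSE), and linear-time-invariant
characterization of the gradient chain by its gradient impulse response
function (GIRF).

# Models

## Small-tip-angle design

In the small-tip regime the transverse magnetization after a pulse of
duration $T_0$ is

$$ M_{xy}(\mathbf r, T_0) = i\gamma M_0 \sum_c B_1^c(\mathbf r)
   \int_0^{T_0} e^{i\mathbf k(t)\cdot \mathbf r}
   e^{i\Delta\omega(\mathbf r)(t - T_0)} b_c(t)\, dt, \qquad
   \mathbf k(t) = -\gamma \int_t^{T_0} \mathbf G(t')\,dt'. $$

`build_system()` discretizes this on the dwell grid; `design_pulse()`
solves the Tikhonov-regularized least-squares problem
$\min_b \|A b - m_{\rm target}\|^2 + \lambda \|b\|^2$ by conjugate
gradients on the normal equations from a zero start (deterministic), with
$\lambda$ either fixed or chosen by the L-curve criterion
(`lcurve_select()`). k-space is expressed in rad/m with
$\gamma = 2.675221\times 10^8\,$rad s$^{-1}$T$^{-1}$, so the phase term is
literally $e^{i\mathbf k\cdot\mathbf r}$ with $\mathbf r$ in metres; with
$M_0 = 1$ the result reads as flip angle in radians. The magnitude target
is given the phase of the quadrature (channel-sum) transmit field, a
standard choice when only a magnitude profile is prescribed.

## VERSE in the arc-length domain

VERSE reshapes a waveform pair $\{B_1(t), \mathbf G(t)\}$ so that the same
k-space path is traversed at a different speed while the on-resonance
rotations are untouched. Parametrizing by the distance traversed in
k-space, $s(t) = \gamma\int_0^t |\mathbf G|\,d\tau$, the invariant is the
RF-to-gradient ratio $W_c(s) = |B_1^c(s)| / |\mathbf G(s)|$. A peak-RF
bound $B_{1,\max}$ then becomes a gradient-amplitude bound

$$ |\mathbf G^v(s)| \le \min\!\left(\frac{\alpha B_{1,\max}}
   {\max_c W_c(s)},\; G_{\max}\right), $$

with $\alpha = 0.95$ damping small oscillatory overshoots across
iterations. For multi-channel pulses the bound uses the largest $W_c$ at
each $s$ so every channel respects the cap. `time_optimal_traverse()`
solves the minimum-time traversal in the phase plane: the speed
$v = ds/dt$ is capped pointwise by the amplitude bound
($v \le \gamma\,\mathrm{bound}$) and the centripetal slew load
($\kappa v^2/\gamma \le S_{\max}$), and forward/backward passes from
$v = 0$ at both ends enforce the tangential component of
$\sqrt{(v v')^2 + (\kappa v^2)^2}/\gamma \le S_{\max}$.

## GIRF characterization and the corrected loop

The gradient chain is modelled per axis as linear and time invariant.
`make_chirp()` generates linear frequency sweeps (bandwidths 10–40 kHz,
about 10 ms) that put energy across the band of interest;
`estimate_girf()` forms the multi-measurement least-squares deconvolution
$\hat H(f) = \sum_i \tilde O_i \tilde I_i^* / (\sum_i |\tilde I_i|^2 +
\varepsilon)$ on a common record window (the frequency resolution is the
reciprocal window duration: 14.3 Hz at 70 ms, 156 Hz at 6.4 ms).
`predict_gradient()` applies $\hat H$ to a nominal waveform with 2x
zero-padding to suppress circular wrap-around of millisecond-scale
response tails.

`reverse_design()` closes the loop: at every iteration the actual
gradient is obtained from an oracle (nominal / GIRF-predicted /
monitored), the RF is redesigned on the trajectory computed from it, and
if the peak RF still exceeds the bound the pair is VERSE-reshaped and the
oracle consulted afresh — because the reshaped waveform is itself
distorted by the gradient chain, the trajectory changes at every
iteration.

### Loop stabilization

Three safeguards keep the iteration monotone and terminating; all three
reduce to the classic behaviour when the gradient chain is ideal.

1. **Compounded attenuation.** The redesign step is free to relocate its
   peak, so the peak RF can overshoot the VERSE target persistently. While
   the bound stays violated the attenuation factor is compounded
   ($\alpha, \alpha^2, \alpha^3, \dots$), damping the overshoots
   geometrically — the same damping role the single factor plays, extended
   until it actually bites.
2. **No re-acceleration.** Inside the loop the time-optimal traversal is
   additionally capped at the current traversal speed wherever the
   gradient is significant (`allow_speedup = FALSE`), so successive
   reshapes only ever slow the waveform; regions freed of RF would
   otherwise be re-accelerated and invite fresh violations at the next
   redesign. Stand-alone `verse_reshape()` keeps full time-optimal
   semantics.
3. **Gain-aware bound** (next section).

### Why the VERSE bound carries the actual/nominal gain

The classic bound $\alpha B_{1,\max}/W$ is stated against the *commanded*
gradient. But the RF is redesigned on the *actual* trajectory, so the
peak RF that the next design will need scales with the played-out
gradient magnitude. Where the chain's gain exceeds one — e.g. on a narrow
mechanical resonance — a loop using the commanded-gradient bound
plateaus at $\alpha B_{1,\max}\,\max_f|H|$ and can sit just above the
target forever. `verse_reshape()` therefore accepts the per-sample gain
$|\mathbf G_{\rm act}|/|\mathbf G_{\rm nom}|$ (clamped to $[0.5, 2]$) and
tightens the bound with it; in nominal mode the gain is identically 1 and
the classic behaviour is recovered exactly. This is the same philosophy
as the trajectory correction itself: every piece of knowledge about the
gradient chain is folded into the design.

A related boundary case: a time-optimal trajectory starts and ends at
zero gradient amplitude, where the arc-length transform is undefined. RF
on those isolated dwells cannot be VERSE-represented; the loop zeroes it
before reshaping (`to_sdomain()` itself stays strict and rejects such
input) and the subsequent redesign recovers the excitation.

# The synthetic scanner

No measured maps or field-camera data ship with the package; everything
is generated by code so the full method runs end to end from one seed.

* **Maps** (`make_maps()`): 8 surface-coil-like complex sensitivity lobes
  placed around a 128 mm field of view with phase roll, peak-normalized,
  on a 64 × 64 grid; a smooth off-resonance map spanning ±200 rad/s.
  Deterministic per seed. These are smooth low-order modes, not
  electromagnetic simulations — adequate for the design equation, which
  only needs smooth complex sensitivities.
* **Target** (`make_target()`): 30 × 30 mm² square, blurred with a 10 mm
  FWHM Gaussian to suppress ringing, scaled to the flip angle (90° for
  the phantom-style runs).
* **Trajectory** (`make_spiral_in()`): single-shot Archimedean spiral-in
  encoding 2 mm resolution, 2× radially undersampled, traversed
  time-optimally under 30 mT/m and 180 T/m/s, 6.4 µs dwell.
* **Gradient-system truth** (`scanner_truth()`): per-axis second-order
  low-pass (−3 dB at 9 kHz on x/y, 7 kHz on z — the z coil typically has
  the narrower bandwidth) times one narrow resonant feature per axis in
  the 600–1800 Hz band (1.1–1.3 kHz, relative amplitude 5–8 %, Q = 15),
  mimicking mechanical resonances. DC gain is exactly 1 and the response
  is Hermitian. This is a *synthetic* plausibility model, not a measured
  system; none of its numbers are claimed to reproduce any particular
  scanner.

What passing tests on this fixture show: the machinery — estimation,
prediction, reshaping, redesign — is self-consistent and the correction
mechanism works when the distortion is LTI. What they cannot show:
robustness to non-reproducible field perturbations (thermal drift,
subject-induced fields), RF-amplifier distortion, or the detailed spectra
of real gradient hardware.

# Numerical choices

* Integration is trapezoidal throughout; the excitation k-space integral
  runs from the pulse end so $\mathbf k(T_0) = 0$ holds exactly.
* Arc-length grid: uniform spacing $\gamma G_{\max} \Delta t / 16$, i.e.
  16× oversampling of the fastest admissible traversal. The finer-looking
  factor matters at a spiral centre, where the tangent rotates quickly
  per unit arc length; at 4× the resampled gradients showed localized
  slew overshoots of tens of percent, at 16× the fixture spiral meets its
  slew cap to 0.1 %.
* The velocity cap in the traversal is tightened by a 6-step fixed-point
  iteration so that the *combined* slew magnitude (tangential plus
  centripetal) respects the cap even while riding a sloped cap.
* Linear interpolation is used for all s/t resampling; RF phase is
  interpolated as a unit phasor to avoid wrap artefacts.
* Conjugate gradients: relative normal-equation tolerance $10^{-6}$,
  at most 200 iterations, zero initialization. The L-curve scan uses 16
  log-spaced weights over $10^{-3}$–$10^3$ times a Frobenius-norm scale
  heuristic, solved loosely (30 iterations); curvature is oriented so the
  corner — the clockwise bend toward the origin — is positive, and a curve
  with no positive interior curvature falls back to the median weight
  with a warning.
* Regularization default in the loop: the L-curve criterion needs a noise
  floor to form its corner; on noiseless synthetic problems the residual
  branch is flat and the dominant bend sits at very heavy smoothing, so
  the criterion is uninformative there. `reverse_design()` therefore
  defaults to a fixed weight of $0.1$ times the mean-eigenvalue scale of
  the normal operator — designs land in the few-percent NRMSE regime and,
  as important, the redesign stays stable between the slightly different
  trajectories of successive iterations. The weight is set at the first
  iteration and frozen (re-selection available via a flag); `"lcurve"`
  remains available for measured, noisy maps.
* GIRF deconvolution regularizer: $\varepsilon = 10^{-6} \max_f
  \sum_i|\tilde I_i|^2$; bins where the excitation falls below that floor
  are flagged low-confidence rather than dropped.
* Zero-gradient floor: $10^{-4}$ of the peak gradient magnitude; RF below
  $10^{-6}$ µT counts as zero for representability checks.
* Chirp sweeps start at 0 Hz; the chirp amplitude is auto-scaled to the
  slew cap and the scale reported.
* Hard-pulse Bloch propagation applies one rotation per 6.4 µs dwell with
  no sub-stepping; at admissible amplitudes the per-step rotation is far
  below $\pi$, and rotations conserve the magnetization norm to rounding.
* NRMSE is defined as $\||p| - |t|\|_2 / \|t\|_2$ over the evaluation
  mask on flip-angle magnitude maps. (Published work rarely states the
  exact formula or mask; this one is fixed here and used consistently.)

## Resolution and geometry preservation

"The VERSEd gradients retrace the same k-space path" is exact in the
continuum but any dwell-sampled waveform carries a chord-sagitta error of
order $\kappa\,\Delta s^2/8$ per segment. On gently curved, well-resolved
paths this is well below $10^{-3}$ rad/m and the test suite asserts
retracing at that level; at a spiral centre ($\kappa$ up to
$\sim 0.13\,$(rad/m)$^{-1}$ with dwell-scale steps of several rad/m) the
discretization floor is orders of magnitude larger, which is a property
of sampling, not of the reshaping. The suite therefore checks the
fixture spiral against its own discretization bound instead.

# Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
study scale: 64 × 64 grid, 8 channels, ~1930-sample spiral (12.4 ms), a
70 ms GIRF window, and up to 10 loop iterations; the whole girf-mode loop
takes on the order of a minute on one core. Unit and property tests use
smaller grids (8–32) and shorter waveforms chosen so that every oracle
comparison is resolution-dominated, not noise-dominated.

# Known limitations

* Only first-order self-terms of the gradient response are modelled — no
  cross-terms, no $B_0$ (zeroth-order) response, no pre-emphasis design.
* Magnitude-least-squares (phase-relaxed) design and explicit SAR
  constraints are out of scope; the design is magnitude-target with a
  fixed phase convention.
* The s-domain formulation cannot represent RF played at zero gradient
  (hard-pulse segments); such inputs are rejected.
* Relaxation is neglected in the Bloch propagation (appropriate for
  millisecond pulses with $T_1, T_2 \gg T_0$, but not exact).
* The loop controls the peak RF, not the final pulse duration: the
  corrected trajectory differs from the nominal one, so duration is an
  outcome, not a constraint.
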