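Package: ptxverse
Title: GIRF-Corrected Iterative VERSE Design of Parallel-Transmit RF Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-tip-angle spatial-domain design of multi-channel (parallel
    transmit) RF pulses on arbitrary excitation k-space trajectories, with
    variable-rate selective excitation (VERSE) reshaping in the arc-length
    domain under peak-RF, gradient-amplitude and slew-rate constraints.
    Characterizes the gradient chain as a per-axis linear time-invariant
    system via chirp-based gradient impulse response function (GIRF)
    estimation, predicts the actually played-out gradients, and closes the
    loop with the iterative reVERSE algorithm in which the RF pulse is
    redesigned on the predicted (or monitored) trajectory at every
    iteration. Includes an exact hard-pulse Bloch simulator for evaluating
    excitation accuracy and a synthetic scanner model (coil sensitivity
    maps, off-resonance, spiral-in trajectory, gradient-system truth
    response) so the whole method runs end-to-end without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
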