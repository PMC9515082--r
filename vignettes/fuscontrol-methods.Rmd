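---
title: "Closed-loop cavitation control for FUS blood-brain-barrier opening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop cavitation control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuscontrol)
```

## The problem

Focused ultrasound (FUS) combined with circulating microbubbles opens the
blood-brain barrier (BBB) transiently and locally, but the in situ acoustic
pressure and microbubble state vary between subjects and between brain
targets. Passive cavitation detection (PCD) listens to the microbubble
emissions during each pulse; a feedback controller adjusts the drive
pressure pulse by pulse so that the *stable cavitation* (SC) level stays at
a chosen setpoint above that target's own baseline, keeping the exposure
effective without tipping into *inertial cavitation* (IC), the violent
collapse regime associated with hemorrhage.

`fuscontrol` implements that control loop in software, together with the
measurement chain (per-pulse FFT band levels, baseline calibration in dB),
the outcome quantifiers (contrast-enhanced MRI opening volume, histology
red-pixel area), and a synthetic microbubble-emission *plant* that closes
the loop in place of an animal, so the controller can be characterized
end to end with seeded, reproducible simulations.

## Measurement model

Each pulse of the 500 kHz drive lasts 10 ms at a pulse repetition frequency
of 1 Hz (duty cycle $100 \cdot \tau \cdot \mathrm{PRF} = 1\%$). The PCD
trace, sampled at 40 MHz, is Fourier transformed over the full pulse
(rectangular window, no zero padding) and two narrow bands are summed:

* **SC level** — magnitudes within $\pm 0.02$ MHz of the fourth harmonic
  (2 MHz), the harmonic closest to the receiver's 2.25 MHz center;
* **IC level** — magnitudes within $2.1 \pm 0.02$ MHz, an inter-harmonic
  band that avoids harmonics and ultra-harmonics and thus responds only to
  broadband emission.

Band edges are closed on both sides; with $f_s/N = 100$ Hz resolution the
edge bins exist, so a convention has to be fixed. Levels are converted to
dB against a per-target baseline:
$L_\mathrm{dB} = 20 \log_{10}(L / L_\mathrm{base})$. Summed magnitudes are
amplitude-like, hence the 20-factor default; a $10\log_{10}$ power
convention is selectable since the field uses both. The baseline is the
arithmetic mean of the *linear* levels of the five dummy pulses — averaging
in dB would make the mean dummy pulse nonzero-dB by Jensen's inequality.
An analysis sub-window (start/length) is available for users who gate out
time-of-flight segments; the default is the full trace.

## The controller

A session has two steps:

1. **Dummy sonication** — 5 pulses (5 s at 1 Hz) at 0.3 MPa, enough to
   drive emissions with microbubbles present but below the opening
   threshold; the SC and IC baselines are calibrated from these pulses.
2. **Treatment** — 180 pulses under closed-loop control toward a target
   cavitation level (TCL) of 0.25, 0.5 or 1 dB above baseline:
   * *ramp-up*: pressure increases by `ramp_step` (default 0.01 MPa) every
     pulse until the measured SC level reaches the TCL;
   * *maintain*: if the SC level is above TCL + tol the next pulse is
     `maintain_step` (default 0.005 MPa) lower; below TCL − tol,
     `maintain_step` higher; inside the band the pressure is kept the same.

The per-pulse SC value used for control is the current pulse's level only
(no smoothing): the pressure reacts *immediately* to each measurement.
Pressures are clamped to `[p_min, p_max]`; a session that saturates at
`p_max` before reaching the TCL stays in ramp at the cap and is flagged
rather than aborted, preserving the log. IC monitoring is a safety check:
an *IC event* is a maintain-phase pulse whose IC level exceeds baseline by
more than 1 dB. The default response is log-and-continue, with an optional
hard stop (`ic_action = "stop"`).

Two conventions were genuinely open and are both implemented:

* "the SC level reached the TCL" is read as $\ge$ TCL (default); reading
  it as "within TCL ± tol" is selectable via `ramp_entry = "in_band"`.
  The difference matters: entering at $\ge$ TCL typically overshoots the
  band by up to one ramp step (~0.4 dB at these slopes), costing one or
  two out-of-band recovery pulses, so even a noiseless plant scores
  slightly below 100% good pulses; in-band entry scores exactly 100%.
* The tolerance half-width is not stated in the protocol; the default is
  0.125 dB, half the smallest TCL, and it is surfaced in every report.

**Characterization statistics.** The *good pulse rate* is the percentage
of maintain-phase pulses within TCL ± tol; *IC probability* is the
percentage of maintain-phase pulses with an IC event. Both are undefined
(an error) when no maintain pulse exists. IC events outside the maintain
phase are excluded, per the definition.

## The synthetic plant

No emission model accompanies the protocol, so the plant is the package's
own construction, built to reproduce the qualitative spectral phenomenology
(harmonics always; sub/ultra-harmonics appearing near the 1 dB setpoint;
broadband only at clearly higher pressures):

$$
s(t) = \sum_{n=1}^{8} A_n\, p^{\gamma} \sin(2\pi n f_0 t + \varphi_n)
 + [p > p_{uh}] \sum_m U_m (p - p_{uh})^{\gamma} \sin(2\pi (m-\tfrac12) f_0 t + \psi_m)
 + [p > p_{ic}]\, g\,(p-p_{ic})\, w(t)
$$

seen through the receiver band-pass, plus electronic noise
$\sigma_e e(t)$. Phases are redrawn once per pulse from the seeded RNG to
avoid coherent cancellation artifacts across pulses. Defaults:
$\gamma = 1.5$ (supra-linear harmonic growth), $p_{uh} = 0.32$ MPa (just
below the pressure the controller sustains at TCL = 1 dB, so
ultra-harmonics appear near that setpoint), $p_{ic} = 0.45$ MPa (IC stays
rare under the default cap), $A_n = 0.5/n$, $U_m = 0.3 A_m$. Amplitudes
are arbitrary units — the protocol reports no absolute voltage scale — so
only ratios and dB quantities are meaningful.

**Receiver filter.** Only the center (2.25 MHz) and −6 dB bandwidth
(600 kHz) of the detector are known. The passband is realized as a
zero-phase frequency-domain magnitude response
$|H(f)| = (1 + 3\,(|f - f_c| / (b/2))^{2q})^{-1/2}$ (order $q = 4$
default), which passes the center at unit gain and hits amplitude 0.5
*exactly* at $f_c \pm b/2$. A recursive filtfilt design would need a
filter-design library not available here; since the contract is purely a
magnitude specification and zero phase, the FFT-domain realization is the
simpler and exactly-specified choice.

**Pulse-to-pulse variability.** Physiological variability is a log-normal
multiplicative factor on the harmonic amplitudes, with
$\sigma_\mathrm{eff} = \texttt{amp\_sigma} \cdot (p/p_\mathrm{ref})^{\kappa}$,
$p_\mathrm{ref} = 0.3$ MPa, $\kappa = 12$. The power-law growth is the one
deliberate modeling choice beyond the spectral structure: a
pressure-independent sigma produces the *same* dB jitter at every setpoint
(the factor is multiplicative, the setpoints differ only in pressure by a
few percent), so controllability would not degrade with TCL — contrary to
what is observed in vivo, where higher setpoints are distinctly harder to
hold. Microbubble oscillation becomes increasingly erratic approaching the
sub/ultra-harmonic onset, and $\kappa = 12$ concentrates that growth over
the narrow 0.30–0.33 MPa operating range. With `amp_sigma = 0.008` the
simulated mean good pulse rates decline roughly from ~68% to ~42% across
TCL 0.25 → 1 dB; the in vivo values (97.7/84.7/64.7%) are not targets, only
the monotone decline is asserted.

What the plant does **not** model: bubble-dynamics ODEs, skull
transmission, spatial focusing (the transducer's 26.7/3.7 mm focal
dimensions are hardware measurements outside scope), perfusion kinetics of
the microbubble bolus, and drifting baselines. A green controller test
therefore establishes correctness of the control *law* and measurement
chain against a stationary stochastic emitter — not performance in tissue.

## Outcome quantifiers

**Opening volume.** On the post-contrast T1-weighted volume
(0.85 × 0.85 × 1 mm voxels), two manually placed elliptical ROIs
(19 × 8 mm) mark the treated and control sites, avoiding ventricles. A
treated-ROI voxel represents opening when its intensity is *strictly
greater* than control mean + 3 × control sd. Supra-threshold voxels are
counted per slice, scaled by the voxel volume (0.7225 mm³), and the
maximum over slices is reported as the opening volume ("the slice with the
max contrast enhancement"); the all-slice total is also reported for
transparency. "Max contrast enhancement" is implemented as max
supra-threshold voxel *count* (the reading consistent with the per-slice
volume summation); sample sd (n−1) is the default with population sd
selectable; voxel membership in an ellipse is a center-point test, whose
error is bounded by the one-pixel perimeter band (asserted in tests
against the analytic area $\pi ab$). Control statistics come from the
post-contrast image only.

**Planted-lesion recovery and the threshold multiplier.** The synthetic
MRI generator plants an ellipsoidal hyper-enhancement of stated contrast
on a Gaussian background and returns the exact planted mask. Exact
count recovery requires the threshold to sit several sd away from *both*
populations: with the clinical k = 3 the background alone contributes
~1.3 false positives per 1000 ROI voxels, so recovery tests use contrast
= 12 sd with the midpoint threshold k = 6 (both tails ≥ 6 sd, per-voxel
error ~1e-9). k = 3 remains the default of the quantifier itself.

**Red-pixel area.** H&E sections are quantified by counting pixels whose
HSV hue lies in a red window (default [0°, 20°] ∪ [340°, 360°)) with
saturation ≥ 0.3 and value ≥ 0.2 (excluding washed-out eosin background
and near-black), times the squared pixel size. The window and floors are
unstated in the protocol; defaults are logged and configurable.

**Controller-to-outcome surrogate.** For end-to-end trend tests, the mean
maintain-phase pressure is mapped to lesion axes by an affine surrogate
(`lesion_surrogate`: diameter = 600 mm/MPa × pressure above 0.3 MPa,
axes ratio 1 : 0.7 : 0.5). This is a monotone link, not dosimetry: it
exists so that a higher TCL yields a larger quantified volume, which is
the qualitative in vivo observation being mirrored.

## Numerical and scaling choices

* **Scaled acquisition in tests.** Full scale is 40 MHz × 10 ms = 400,000
  samples per pulse. Controller-level tests and the acceptance report run
  at 10 MHz × 2 ms (20,000 samples; 500 Hz bin spacing): every emitted
  tone still falls on an exact FFT bin and all bands sit far below
  Nyquist, so the algebraic structure is unchanged while a 185-pulse
  session takes ~1.5 s. One consequence is statistical: the IC band then
  holds 81 bins instead of 401, so its noise-driven level fluctuates with
  ~0.5 dB sd instead of ~0.23 dB, and occasional spurious IC events
  (~1–2%) appear at high TCL that would be vanishingly rare at full
  resolution; the IC-probability-zero property is therefore tested at
  full 100 Hz resolution.
* **Determinism.** All randomness flows through R's RNG; `emit_pulse`
  localizes the seed when given one, and `run_treatment` seeds once per
  session, so identical seeds give bit-identical logs and HDF5 archives.
* **Serialization.** Pulse-log floats are written at 17 significant
  digits (round-trip precision); YAML configs are written with
  `precision = 17` for the same reason.
* **Degenerate inputs.** Zero drive with zero noise produces an all-zero
  trace, whose band level is 0 and whose dB value is undefined — baseline
  calibration rejects it rather than propagating `-Inf`. An all-zero
  opening result is 0 mm³, not an error. Ties at the opening threshold
  are excluded by the strict inequality.

## Known limitations

* The plant is phenomenological; its onset pressures and amplitude
  coefficients are tunable stand-ins, not measurements, and absolute
  levels are arbitrary units.
* The dB convention of the original levels is not documented; if the
  power convention was intended, all dB quantities halve, and the default
  TCLs correspond to twice the linear contrast.
* The controller assumes one pressure per pulse with instantaneous
  actuation; drive-voltage quantization and hardware latency are out of
  scope (a monotone voltage-to-pressure calibration table can be applied
  upstream).
* NIfTI support is a minimal little-endian NIfTI-1 codec for 3-D scalar
  volumes (sufficient for the quantifier's contract), not a general
  neuroimaging reader.
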