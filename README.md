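# fuscontrol

Closed-loop, cavitation-based feedback control for focused-ultrasound
blood–brain-barrier (BBB) opening — as a tested, reproducible R package.

## Who this is for

Focused ultrasound (FUS) with intravenous microbubbles opens the BBB
locally and transiently, but the effective exposure varies between
subjects and brain targets. The field's answer is passive cavitation
detection (PCD): listen to the microbubble emissions during every pulse
and adjust the next pulse's pressure so the *stable cavitation* (SC)
level holds at a setpoint defined relative to that target's own baseline,
while *inertial cavitation* (IC, the damage-associated broadband regime)
is monitored as a safety check. `fuscontrol` is for researchers who want
to study, characterize, or extend such a controller in software: it
provides the full measurement chain, the control law, the outcome
quantifiers used to validate opening, and a synthetic microbubble
"plant" that closes the loop in place of an animal.

## What it computes

Per pulse, from a PCD voltage trace sampled at rate $f_s$:

* one-sided FFT magnitude spectrum (rectangular window, resolution $f_s/N$);
* **SC level** $= \sum_{|f - 4f_0| \le 0.02\,\mathrm{MHz}} |X(f)|$
  (4th harmonic of the 500 kHz drive, i.e. 2 MHz);
* **IC level** $= \sum_{|f - 2.1\,\mathrm{MHz}| \le 0.02\,\mathrm{MHz}} |X(f)|$;
* dB re baseline: $L_\mathrm{dB} = 20\log_{10}(L/L_\mathrm{base})$, the
  baseline being the linear mean over the five dummy-sonication pulses.

Per session: a ramp phase (pressure $+0.01$ MPa per pulse until the SC
level reaches the target cavitation level, TCL) followed by a maintain
phase (bang-bang $\pm 0.005$ MPa steps toward TCL $\pm$ 0.125 dB), with
the **good pulse rate** (% of maintain pulses in band) and **IC
probability** (% of maintain pulses with IC level $> 1$ dB above
baseline) as characterization statistics.

Per outcome: BBB-opening volume on a contrast-enhanced T1-weighted volume
(voxels in a treated elliptical ROI exceeding control-ROI mean + 3 sd,
counted on the maximally enhancing slice, × 0.85 × 0.85 × 1 mm³), and
red-pixel area of H&E sections (HSV red-hue pixels × pixel area).

## Worked example

Simulate one feedback-controlled session against the synthetic plant with
pulse-to-pulse variability on, then quantify the opening an MRI scan of
the resulting lesion would show:

```r
library(fuscontrol)

plant <- plant_params(fs = 1e7, pulse_len = 2e-3, amp_sigma = 0.008)
cfg   <- sonication_config(tcl_db = 0.5)
log   <- run_treatment(plant, cfg, seed = 7)
log
#> Feedback-controlled sonication (TCL = 0.5 dB, seed = 7)
#>   pulses: 5 dummy, 1 ramp, 179 maintain
#>   good pulse rate: 61.5 %   IC probability: 3.91 %
#>   mean maintain pressure: 0.3135 MPa
```

The five dummy pulses at 0.3 MPa calibrate the baseline; ramping needed a
single 0.01 MPa increment to reach the 0.5 dB setpoint, and the maintain
phase held the SC level inside 0.5 ± 0.125 dB for 61.5% of its 179 pulses
(this plant's variability makes higher setpoints progressively harder to
hold; noiseless plants score ~100%). The mean maintain pressure feeds a
surrogate lesion model, whose synthetic post-contrast scan is quantified
exactly as a real one would be:

```r
s  <- treatment_summary(log)
sm <- synth_mri(shape = c(64, 64, 8), bg_sd = 5, contrast = 60,
                lesion_center = c(17, 17, 3.5),
                lesion_axes = lesion_surrogate(s$mean_maintain_pressure_MPa),
                seed = 1)
opening_volume(sm$volume, roi_spec(c(17, 17)), roi_spec(c(17, 42)), k = 6)
#> BBB-opening quantification
#>   threshold: 130.5 (control mean 100.3 + k * sd 5.043)
#>   opening volume (max slice 4): 33.96 mm^3 (47 voxels)
#>   all-slice total: 101.1 mm^3
```

47 voxels on the maximally enhancing slice × 0.7225 mm³ per voxel gives a
33.96 mm³ opening. Command-line equivalents (`simulate-treatment`,
`analyze-pcd`, `quantify-mri`, `quantify-histology`, `make-fixtures`,
`summarize`) are available through `fus_cli()` or the
`inst/scripts/fuscontrol` launcher; traces round-trip through HDF5
archives, volumes through NIfTI-1, and sections through PNG.

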