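---
title: "larvasense: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{larvasense: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvasense)
```

## The system being modeled

Larvae of the sleeping chironomid *Polypedilum vanderplanki* survive
near-complete desiccation (anhydrobiosis) and revive within hours of
rehydration. A biohybrid sensor concept uses them as living transducers: the
larvae carry a natural negative surface charge in water, so their 1–2 Hz
bend–stretch motion over a grounded interdigital comb electrode array
modulates the electrostatically induced charge on the electrodes and drives a
small alternating current through a load resistor — no external power needed.
Vitality (and with it temperature or pH suitability) is then read out from
the voltage record as a band-limited spectral statistic.

`larvasense` implements that computational chain end to end:

1. **synthetic generator** — voltage recordings of larval groups,
   machine-driven constant-frequency recordings, no-larvae controls,
   temperature/pH condition series, and rendered larva videos, all with
   ground truth in the metadata;
2. **electrostatic forward model** — a quasi-static finite-difference (FD)
   Laplace solver for a charged moving body over the comb, induced-charge
   integration, and the load-voltage waveform over a bend–stretch cycle;
3. **spectral pipeline** — 10 s segmentation, 200-point centred moving
   average, Hamming 4096-point framed FFT amplitude spectra, 0.2–4 Hz band
   limiting, the *activity* index, and dominant-peak detection;
4. **condition statistics** — mean ± SEM per condition with two-sided pooled
   Student's t-tests against a no-activity control;
5. **motion tracking** — Otsu binarization of video frames and displacement
   tracing of the outer body line, with frequency recovery.

## The activity index

For a voltage record $v(t)$ sampled at $f_s = 1$ kHz, each 10 s segment is
smoothed by a 200-point centred moving average, split into consecutive
4096-sample frames, Hamming-tapered and transformed. The single-sided
amplitude spectrum is normalized by $2/(N \cdot \bar w)$, where
$\bar w \approx 0.54$ is the window's coherent gain, so a unit sinusoid on a
bin reads $\approx 1$ V. The activity is the trapezoidal integral of the
frame-averaged amplitude $A(f)$ over the analysis band:

$$\mathrm{activity} = \int_{0.2\,\mathrm{Hz}}^{4\,\mathrm{Hz}} A(f)\, df
\qquad [\mathrm{V\,Hz}],$$

and a per-recording score averages the segment scores. The band edges
exclude the low-frequency artifact background (< 0.2 Hz) and frequencies
above the larvae's motion range (> 4 Hz). The dominant peak is the global
argmax of the band-limited spectrum, ties broken toward lower frequency; no
peak-shape criterion is applied because small spurious sub-peaks near 1 Hz
are a known feature of short-frame FFT analysis.

Numerical choices worth knowing:

* **Moving average, not residual.** The FFT is applied to the smoothed
  signal. The 200-point average at 1 kHz is a Dirichlet-kernel low-pass with
  gain $|\sin(\pi f N/f_s)/(N\sin(\pi f/f_s))|$: 0.757 at 2 Hz, first null
  at 5 Hz — it passes the whole analysis band while suppressing
  high-frequency noise. `use_residual = TRUE` switches to analyzing the
  high-pass residual instead.
* **Frame policy.** A 10 s segment (10,000 samples) yields two 4096-point
  frames; the trailing 1,808 samples are unused. No zero padding.
* **Per-frame demeaning.** Each frame's mean is removed before tapering.
  A DC offset (or a slow drift, which is effectively DC within a 4 s frame)
  otherwise leaks through the Hamming main lobe into the lowest in-band bins
  at 0.24–0.5 Hz and can masquerade as activity. Disable with
  `demean = FALSE`.
* **Edges.** The moving-average window shrinks symmetrically at the record
  edges (no phase shift, length preserved).

All acceptance-style checks in the package are normalization-invariant
(peak positions, ratios, ordinal patterns); absolute activity values are in
the units above and are *not* comparable to plotted arbitrary units from
bench software.

## The synthetic generator

The generator defines the study conditions for every downstream test, so its
defaults are fixed and documented here.

**Group signal.** Each active larva emits bouts of a sinusoid at the
bend–stretch rate (default 2 Hz, the rate observed at 30 °C two hours after
rehydration), gated by raised-cosine on/off ramps of 4 cycles, with bout
lengths geometric-distributed (minimum 10, mean 14 cycles — seconds-long
bouts), inter-bout gaps sized for a 50% duty cycle, and a fresh uniform
random phase per bout (`phase_jitter = 1`), because larvae are
unsynchronized. The soft gating keeps ≥ 99% of the noise-free signal power
within ±0.5 Hz of the carrier, so the group spectrum shows the observed
1–2 Hz peak rather than gating sidebands. Each larva draws from its own
deterministic substream of the top-level seed: a recording with $k$ active
larvae is exactly the sample-wise sum of the $k$ single-larva signals, which
the tests exploit.

**Amplitude scale.** `per_larva_amplitude = 3e-5` V makes the group envelope
with 8 of 10 larvae active ≈ 0.11 mV, the measured device amplitude at
30 °C. With the 150 Ω device resistance this corresponds to ≈ 730 nA and
≈ 80 pW.

**Noise.** White noise (default 5 µV sd — an unreported instrument property,
chosen to keep the driven-condition SNR well above 10) plus a sinusoidal
baseline drift below 0.2 Hz. The default drift amplitude is a tenth of the
white sd: as noted above, near-DC energy leaks into the band edge, and the
no-larvae control should remain spectrally flat (no in-band bin above 3× the
in-band median), as the bench control trace is. Users modeling worse
instruments can raise it.

**Condition series.** Response curves give, per condition, the revived
fraction and motion frequency. Defaults are piecewise anchors through the
qualitative observations: temperature — zero activity at 10 and 50 °C,
maximum (0.8 active fraction, 2 Hz) at 30 °C, intermediate shoulders (0.4)
at 20 and 40 °C; pH — zero at pH 2 and 13, maximum around pH 5–7, more
tolerance on the acid side. The shapes are phenomenological (no attempt to
model water uptake or trehalose vitrification) and overridable. Replicate
recordings (n = 3 by default) use seeds spawned deterministically from
(seed, grid index, replicate index).

**Rendered video.** A dark worm-like rod (1.5 mm × 0.2 mm at 10 µm/pixel) on
a bright background bows vertically like half a sine along the body at the
bend frequency, 30 fps. The continuous top-boundary trajectory at the
mid-body column is stored as ground truth; recovered displacements are
correct to one pixel pitch (quantization bound).

**What the generator does not emulate.** Real recordings contain broadband
1/f-like drift, electrode polarization transients, mains interference and
larvae whose rate drifts within a bout; the generator's bursts are clean
tones with stationary statistics. Passing tests therefore demonstrate that
the pipeline recovers known structure under controlled conditions, not that
it is robust to every bench artifact.

## The electrostatic forward model

The bend–stretch cycle is slow (Hz) compared with charge relaxation, so the
model is quasi-static: at each instant the potential $\phi$ solves Laplace's
equation in the water above the electrode plane with Dirichlet conditions —
electrodes at 0 V, the body outline at its surface potential — and the load
current follows from the time variation of the induced charge.

* **Geometry.** Teeth 80 µm wide with 20 µm gaps (period 100 µm), alternating
  between the grounded "base" comb and the "counter" comb feeding the load.
  Domain 680 × 130 µm containing 6.5 teeth, mirrored at the left edge
  (half of a symmetric body; induced charges are doubled). The body is a 2D
  rectangle, 100 µm high, length oscillating 80–600 µm, flying 10 µm above
  the plane.
* **Kinematics.** Triangular length-vs-time at 2 Hz, i.e. constant total
  edge speed $(600-80)\,\mu m \times 2 \times 2\,\mathrm{Hz} = 2.08$ mm/s.
* **Boundary conditions.** The measured zeta potential (−21 mV, obtained
  from ground dried larvae, used as a reference value) is applied as an
  effective Dirichlet surface potential; the body interior is excluded from
  the dielectric. Both combs are held at 0 V when computing charge
  (short-circuit approximation: the ohmic excursion across 150 Ω is
  negligible against the boundary potentials). The 100 nm SiO2 isolation
  film is ignored (≪ grid spacing). Outer boundaries are zero-flux.
* **Discretization.** 5-point FD Laplacian on a uniform grid (default
  2.5 µm — 8 cells per gap; at least 4 are required), assembled sparse and
  solved directly, so the residual is at machine precision. The discrete
  Gauss identity makes the induced charges over all conductors cancel the
  body charge exactly, which the tests verify, and the solver is checked
  against the closed-form parallel-plate and image-line-charge solutions to
  better than 2%.
* **Current.** Because the problem is quasi-static, the counter-comb charge
  depends on the body extent alone. $Q(\mathrm{extent})$ is evaluated once
  per grid-aligned extent (105 solves at the default grid) and
  differentiated by central differences; the chain rule with the constant
  edge speed gives $I(t) = (dQ/d\,\mathrm{ext}) \cdot v_\mathrm{edge}$,
  signed by the motion direction, and $V(t) = I R$. This keeps the waveform
  smooth and the cycle amplitude grid-converged to well under 10% when the
  spacing is halved.
* **Out-of-plane depth.** The 2D solution is charge per unit depth; it is
  scaled by a configurable depth, default 0.2 mm (the larval diameter). The
  scaling is linear, so any other convention is a multiplicative factor.

### Magnitude of the simulated voltage — a deliberate discrepancy

With these parameters the model yields a peak amplitude of about
$8.7\times10^{-11}$ V (0.087 nV). That magnitude follows from dimensional
analysis, independent of the discretization: the induced surface charge
density under a −21 mV body 10 µm above a grounded plane in water is
$\sigma \approx \varepsilon_0 \varepsilon_r \zeta / d \approx 1.5\,
\mu\mathrm{C/m^2}$, so sweeping an edge at 2.08 mm/s over a 0.2 mm depth
moves at most $\sigma v D \approx 6\times10^{-13}$ A, and 150 Ω turns that
into $\sim 10^{-10}$ V. A reference simulated amplitude of ~0.8 mV across
150 Ω would require ~5 µA of induced current — about seven orders of
magnitude more than any quasi-static electrostatic induction mechanism can
deliver with these inputs, for any physical out-of-plane depth. µA-scale
currents from a −21 mV boundary *are* plausible if the medium conducts
(conduction currents $J = \sigma_w E$ with water conductivity
$\sigma_w \sim 0.01$–0.1 S/m reach that range), which suggests reference
simulations of this kind solve a conduction problem or apply an unstated
normalization; measured device voltages of ~0.11 mV likewise imply hundreds
of nA that electrostatic induction alone cannot supply. The package
deliberately reports what the stated electrostatic mechanism actually
produces rather than rescaling to match a reference number; the acceptance
test for the absolute amplitude is expected to fail and says so. The model's
*structure* — zero-mean fluctuation, linearity in surface potential, grid
convergence, charge bookkeeping, periodicity under tooth shifts — is fully
verified.

A related structural observation: finer comb pitch (40/10 µm) only increases
the generated RMS power once the body flies closer than the gap width; at
the default 10 µm clearance the pitch granularity is smeared by distance and
the coarser designs generate slightly more. Pitch should be compared to
clearance when optimizing such a device.

## Statistics

Condition summaries report mean ± SEM ($sd/\sqrt n$, n = 3 by default).
Each condition is compared with the no-activity control (10 °C, or pH 2)
by a two-sided *equal-variance pooled* Student's t-test — the classical
Student form; a Welch option exists behind `welch = TRUE`. Significance
symbols follow fixed thresholds (`*` p < 0.05, `**` p < 0.01). No
multiple-testing correction is applied, matching the per-condition-vs-single-
control design; with seven pH conditions this inflates the family-wise error
rate, which is a caveat of the design, not of the implementation. One- vs
two-sided and the variance assumption are not dictated by the analysis
being reproduced; two-sided pooled is the package's choice and is flagged
here.

## Tracking

The "outer body line" is operationalized as the topmost foreground pixel in
a user-chosen column (default: the renderer's mid-body column), after
per-frame Otsu thresholding with a polarity flag. Displacement is referenced
to frame 1, gaps (frames with no foreground in the column) are linearly
interpolated and flagged, and the motion frequency reuses the spectral
machinery at the frame rate with the transform length set to the largest
power of two in the track. A flat track returns flagged `NA` rather than
the argmax of noise (the peak must exceed 3× the in-band median).

## Problem sizes and determinism

Defaults were chosen so a full synthetic experiment stays interactive on a
laptop: 60 s recordings at 1 kHz, n = 3 replicates, 5 temperature + 7 pH
conditions (~36 recordings, a few seconds total); one electrostatic cycle at
the 2.5 µm grid is 105 sparse solves of ~14,000 unknowns (~7 s). Every
source of randomness descends from one integer seed through deterministic
substreams, so identical configuration + seed reproduce byte-identical
output tables; `run_pipeline()` logs the configuration hash with every run.

## Known limitations

* The activity scale is normalization-dependent; only ratios, peaks and
  ordinal condition patterns are meaningful across implementations.
* The electrostatic model is 2D, purely electrostatic (no electrochemistry,
  double layers, or transients) and treats the zeta potential of ground
  dried larvae as the live-body surface potential.
* The condition response curves are phenomenological anchors, not a
  physiological model; real dose–response data may be sharper or shifted.
* Tracking handles a single larva and a single traced point; no
  skeletonization or multi-animal assignment.
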