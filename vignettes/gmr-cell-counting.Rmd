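---
title: "Modeling a magnetoresistive in-flow cell counter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a magnetoresistive in-flow cell counter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrflow)
```

## The measurement being modeled

A giant-magnetoresistance (GMR) spin-valve sensor sits under a microfluidic
channel. Cells of interest are labeled with antibody-coated superparamagnetic
beads (1 µm Dynabeads MyOne in the reference system), a vertical permanent
field of 90 mT magnetizes every bead, and the suspension is pushed through
the channel at about 1 mL per 30 min. Each magnetized object crossing the
sensor induces a transient in-plane field; the sensor converts it to a
millivolt-scale bipolar voltage pulse, and counting validated pulses counts
objects one by one. The confounder is that the bead suspension itself
contains aggregates, which also produce pulses: the whole design question is
how to keep counting labeled cells while not counting aggregates.

`gmrflow` implements that chain end to end: field physics, synthetic
samples, trace synthesis, pulse detection, spacer-layer design analysis, and
the counting statistics that turn per-mL counts into a positive/negative
verdict.

## Sensor-averaged dipolar field

A bead at $(x_B, y_B, z_B)$ with moment $\mu$ tilted by $\theta$ from the
vertical and azimuth $\psi$ from the sensor long axis creates a dipolar
field; the sensor senses only the y-component (pinned-layer direction),
averaged over its active rectangle $L \times l$ (120 µm × 4 µm, the bounding
rectangle of the yoke). The package evaluates that average in closed form:
writing $u, v$ for in-plane coordinates relative to the bead and
$h = z_B - z_C$ for its height above the sensor plane, the double integral
of each moment projection has an elementary corner-evaluated antiderivative
($1/R$ for the $x$ projection, $-uv/(q^2 R)$ for $y$, $hu/(q^2 R)$ for $z$,
with $R^2 = u^2+v^2+h^2$ and $q^2 = v^2+h^2$), and
`sensor_averaged_hy()` sums the three terms. Everything is SI internally;
the $\mu_0/4\pi$ prefactor is included so that outputs are tesla and compare
directly with the instrument's µT-scale thresholds; datasheet moments in emu
are converted at the boundary (1 emu = 10⁻³ A·m²).

Because a transcription of a closed form is easy to get subtly wrong, the
package carries its own ground truth: `sensor_averaged_hy_quadrature()`
integrates the point-dipole field of `point_dipole_field()` numerically over
the sensor rectangle. The quadrature is nested one-dimensional adaptive
integration, performed in coordinates scaled by $h$ with the outer domain
split around the bead position — a flat tolerance on the raw domain misses
the near-field spike when a 1–2 µm-high bead faces a 120 µm-long sensor.
The test suite requires agreement to 10⁻⁶ relative on 100 random states;
in practice the two routes agree to ~10⁻¹³.

Two consequences of the closed form drive everything downstream:

* for a vertical moment the average is an odd function of $y_B$, so a
  transit across the short axis produces a **bipolar** pulse with its zero
  crossing at the centerline;
* the point-dipole field decays as $1/h^3$, so height and bead load are
  confounded: a 1-bead object at 1 µm and a 100-bead object at ~4.6 µm are
  indistinguishable by amplitude.

Composite objects: aggregates are modeled as $N$ co-located vertical
dipoles at the operating moment (their spatial extent has negligible effect
at these scales), making their signal exactly $N$ times a single bead's.
Cells are spheres (6 µm default, the NS1 average) with beads placed
uniformly at random on the surface; each bead carries the saturation moment
(2.1 × 10⁻¹¹ emu) tilted by a random angle. The measured ensemble moment at
90 mT is 1.6 × 10⁻¹¹ emu per bead, and we enforce it *in expectation*: the
tilt is uniform on $[0, \theta_{max}]$ with $\theta_{max}$ solving
$\sin\theta_{max}/\theta_{max} = 1.6/2.1$. Whether the real constraint holds
per cell or per ensemble is not known; enforcing it per bead-population is
the weakest assumption that reproduces the measured magnetization.

## Synthetic samples

The generator encodes the measured composition of the reference assay:

| parameter | default | why |
|---|---|---|
| bead concentration | 2 × 10⁷ /mL | fixed labeling concentration of the assay |
| aggregate sizes | zero-truncated geometric, $p = 1 - 0.07^{1/6} \approx 0.358$ | calibrated so P(n < 7) = 0.93; the second measured anchor P(n < 15) ≈ 0.99 then follows |
| beads per cell | negative binomial, mean 50, dispersion calibrated | anchors: mean ≈ 50 beads/cell and P(n > 7) = 0.98 |
| channel | 25 µm × 100 µm, 6 µm spacer | chip geometry; transit heights uniform on [spacer, spacer + height] |
| flow | 1/30 mL/min | 1 mL in 30 min; plug-flow speed ≈ 0.22 m/s |

The two-parameter families are the simplest ones that can hit both printed
anchors of each distribution; both are exposed, so other bead chemistries
can be described by re-anchoring. Arrivals are Poisson per object class
with rate concentration × volume rate; cells drawing zero beads are dropped
(an unlabeled cell is magnetically invisible). Free beads enter as
aggregates of sampled size — the suspension's own clustering — rather than
as singlets. What the generator deliberately does **not** emulate: binding
kinetics over the 2 h incubation, Poiseuille velocity profiles (constant
transit speed at the mean flow velocity), magnetophoretic forces, day-to-day
chip variability, and drift or telegraph noise in the electronics. Passing
tests on these samples therefore validate the pipeline's counting logic,
not the biological variability of real runs.

## Trace synthesis and noise

`simulate_trace()` evaluates each object's signal along its transit,
converts field to volts through the chain
$V = V_{bias}\, s\, B\, G_1 G_2$ (1 V bias, 2.5 %/mT, gains 500 × 20 — so
2.2 µT ↦ 0.55 V), superposes all events at 200 kHz, applies a 4th-order
Butterworth low-pass at 15 kHz, and adds Gaussian noise. Two numerical
choices deserve a note:

* the filter is applied zero-phase (forward–backward), because a causal
  4th-order filter's group delay would skew the pulse and bias the symmetry
  statistic that the detector uses against telegraph noise; the real
  instrument's analog filter is unspecified, and zero-phase is the neutral
  stand-in;
* `noise_rms_field` is defined as the **measured, in-band** RMS noise of
  the recording (default: detectivity/3, i.e. 2.2 µT is three times the
  noise), and is therefore injected after the filter. The instrument's
  separately printed spectral density, broadband voltage noise and
  threshold cannot be reconciled under a single white-noise model, so the
  one number that the detection threshold actually references is the one
  the simulator controls.

## Pulse detection

`detect_events()` reimplements the rule-based detector. Every sample with
$|V| > V_{thr}$ (either polarity — pulses are bipolar) seeds a window of
±20 samples that grows by 15 samples per side until both the window maximum
and minimum sit at least 20 samples inside its edges. Searches that reach
4× the maximum accepted width, or are pinned to the trace boundaries, are
abandoned as unterminated — this is what happens on slow drifts. A candidate
$(i_{min}, V_{min}, i_{max}, V_{max})$ is then accepted iff, in order:

1. **bipolarity**: $V_{max} > 0 > V_{min}$ and both magnitudes exceed
   $V_{thr}/3$;
2. **orientation**: $k\,(i_{max} - i_{min}) < 0$ for the user's lobe order
   $k = \pm 1$;
3. **width**: 25 µs ≤ $|i_{max} - i_{min}|/f_s$ ≤ 2.5 ms (compatible with
   the flow speed);
4. **symmetry**: $|V_{max} + V_{min}| / |V_{max} - V_{min}| < 0.4$. The
   printed form of this criterion is typographically ambiguous; this
   reading is the one that accepts the near-antisymmetric pulses the
   physics produces (the inverse reading rejects them all).

Because every super-threshold sample seeds a search, one pulse yields many
identical or overlapping candidates. Candidates whose extremum intervals
overlap by at least half the shorter interval are merged, keeping the larger
peak-to-peak amplitude; accepted and rejected candidates are merged
separately so that an overlapping artifact cannot displace a validated
transit — the practical guarantee that raising $V_{thr}$ never increases
the accepted count. Window initialization, the growth cap and the merge
rule are not documented for the original software; they are recorded here
as this package's choices.

## Spacer-layer design analysis

`detectable_height(n)` bisects the peak transit amplitude of an $n$-bead
object against the sensor detectivity (0.05 µm tolerance);
`min_beads_detectable(h)` inverts it exactly, since aggregate amplitude is
linear in $n$. With the calibrated size distributions,
`discrimination_fractions()` averages, over each population, the fraction
of the transit-height range that is detectable. This reproduces the design
logic of the reference chip: at 2.2 µT detectivity a 7-bead object is
detectable only below ≈ 7 µm (this model's value; the published figure is
6 µm, and the ±1 µm gap is consistent with modeling the yoke-shaped element
as its bounding rectangle, which concentrates the average over a smaller
area), while 98% of cells but only 7% of aggregates carry more than 7
beads — hence a ~6 µm spacer floor removes most nonspecific signals at a
modest cost in cell counts. Cells are inverted with the co-located
worst-case geometry; the decorated-sphere Monte Carlo in `object_signal()`
remains available for verification at leisure.

## Counting statistics

Counts are normalized to 1 mL. The sample-level decision rule is
`detection_count_threshold()`: mean of the worst negative control's
replicate counts plus three times their standard deviation. **Population**
SD (divisor $n$) is used everywhere in the package: on the packaged count
matrix it is the only convention that reproduces the published summary
column (e.g. 1.1 × 10³ ± 8.2 × 10² for beads-only controls, threshold
3.6 × 10³), which is an empirical rather than textual resolution of an
ambiguity. `classify_and_bracket_lod()` compares row means to the
threshold and brackets the limit of detection between the highest negative
and lowest positive concentration — (10⁴, 3 × 10⁴) cells/mL on the packaged
matrix. `blank_based_lod_loq()` provides the plate-assay blank + 3 SD /
+ 10 SD conventions for comparison studies.

## Validation scale

The test suite exercises the full pipeline at sizes chosen to probe each
property without waste: oracle agreement on 100 random dipole states;
distribution calibrations at 10⁴ draws (Kolmogorov distance < 0.02);
arrival statistics over 20 seeded 1 mL-equivalent streams; and an
end-to-end titration of 10³–10⁵ cells/mL over 5–50 µL equivalent volumes
per point, run noise-free and without the free-bead background. That last
choice isolates what the titration is meant to test — that detected
counts/mL are monotone and linear in cell concentration through the whole
generate → trace → detect → normalize chain; absolute per-concentration
counts of the real instrument depend on day effects, bead batches and
chip-to-chip geometry that the simulator deliberately does not model, and
the aggregate background only adds a concentration-independent offset
(simulating its ~10⁷ objects/mL faithfully is available via
`amplitude_floor` pruning in `run_campaign()` when the offset itself is of
interest).

## Known limitations

* The yoke-shaped sensing element is modeled as its 120 µm × 4 µm bounding
  rectangle; the arms are ignored. This overestimates the sensor-averaged
  field somewhat, visible as the +1 µm bias in the 7-bead detectable
  height.
* Out-of-plane sensitivity is taken as exactly zero; transits are at
  constant speed and default to the channel centerline (lateral jitter is
  available but off).
* The electronics model is gain + low-pass only: no 1/f noise, no 50 Hz
  pickup, and telegraph noise only through the symmetry criterion it was
  designed to reject.
* Negative samples are bead-only compositions; nonspecific binding of
  beads to off-target cells is not modeled.
* When the detection threshold sits at exactly three times the Gaussian
  noise RMS, the rule set accepts a nonzero rate of pure-noise windows
  (both lobes only need to reach threshold/3). The reference instrument
  pooled its analysis at an amplitude cutoff above most days' noise; use
  `acquisition_config(noise_rms_field = )` accordingly when absolute
  background rates matter.
* The simulated nonspecific background (detectable aggregates per mL) is
  higher than the reference instrument's measured one — the geometric
  size tail and the bounding-rectangle sensor both overestimate aggregate
  visibility. Comparisons across conditions are meaningful; absolute
  background counts are not calibrated.
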