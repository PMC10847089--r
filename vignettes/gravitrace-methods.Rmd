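---
title: "Calcium activity of neuronal networks across gravity phases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium activity of neuronal networks across gravity phases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gravitrace)
```

# The problem

During one parabola of a parabolic flight, an aircraft produces roughly 30 s
of hypergravity (1.8 g), 22 s of microgravity (~0 g), and a second
hypergravity pull-out. Immature 2D hippocampal networks loaded with a
fluorescent calcium indicator (Fluo4-AM) show spontaneous, non-synchronized
calcium oscillations with periods of a few seconds, so each gravity phase is
long enough to measure a per-neuron oscillation period and ask how gravity
modulates it. `gravitrace` implements the full measurement chain for such
recordings — movie stabilization, ROI and DF/F extraction, transient (spike)
detection, per-phase period statistics, network classification — plus a
synthetic-movie generator with exact ground truth, so that every stage is
verifiable by parameter recovery rather than by eye.

Two facts shape the whole design. First, recordings are short: an 82 s
movie at 2.5 Hz (100 ms exposure every 400 ms) spans a 10 s baseline at
1 g, the first hypergravity phase, the microgravity phase and an unstable
second hypergravity phase. Second, the aircraft vibrates: the sample
jitters by about a micron, which at 1 µm/px is enough to corrupt
pixel-level statistics unless corrected.

# The gravity timeline

`build_timeline()` lays phase segments end to end and assigns every frame to
the half-open interval `[start, end)` containing its timestamp. The default
configuration is PRE_1G 10 s, HYPER_1 30 s, MICRO_0G 22 s, HYPER_2 20 s.
The stated phase durations and the "ended 12 s after the parabola" recipe
do not sum to the 82 s recording length that the protocol also states; we
resolve the discrepancy in favour of the explicit 82 s total by defaulting
the second hypergravity phase to 20 s, and make every duration
config-overridable (JSON or YAML).

Frames within `blur_halfwidth` (default 2 s) of any boundary between
segments are masked: phase transitions blur the images. No number for this
half-width is available from the recordings themselves; 2 s (five frames on
each side) covers the visible blur band without consuming the short 1 g
baseline. The second hypergravity phase is flagged unstable — the aircraft
is adjusting its trajectory — and is excluded from all period statistics;
it is still simulated and analyzed frame-wise so that indexing never
changes.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions, and the acceptance checks run against them.

**Campaign structure (flight preset).** 29 fields of view: 5 constitutive
networks (active already at 1 g), 14 triggered networks (first activity
during hypergravity), 10 inactive. Active neurons per field are drawn from
a Poisson(6) conditioned to [2, 13]. The laboratory preset instead uses a
single 82 s 1 g phase and 12–27 active neurons per field, matching
ground-control fields of view.

**Periods.** Per-neuron, per-phase oscillation periods are truncated-normal
draws with a floor of 0.8 s (two frame intervals, below which a period is
meaningless at this cadence). The preset means/sds are the measured
statistics: 2.9 s (sd 1.54) at 1 g and 4.8 s (sd 2.09) at 1.8 g; the lab
preset uses mean 5 s, sd 1.5 s (range ≈ 2–8 s). Because those numbers are
*measured means*, the sampler solves for the truncated normal's location
so that its realized mean equals the preset mean; parameterizing the
pre-truncation location instead would inflate every generative mean by the
truncation shift (≈ +0.26 s at 1 g) and make parameter recovery
systematically compare against the wrong target.

**Microgravity structure.** The per-phase pooled statistics alone do not
pin down the joint structure across phases, but the directional claims do:
constitutive networks slow down from 1 g to 1.8 g and to 0 g
(α₁→₁.₈g > 1, α₁→₀g > 1), while triggered networks run *faster* in 0 g
than in 1.8 g (α₁.₈→₀g < 1). Independent per-phase draws cannot produce
the last effect, so the preset is class-conditional: constitutive neurons
draw a 0 g period from mean 6.5 s (sd 1.5), and each triggered neuron's
0 g period is its own 1.8 g period times a ratio drawn around 0.9
(sd 0.08). With the planted 5/14 class mix this leaves the pooled 0 g
mean at ≈ 5 s, the printed value, while reproducing all three directions.

**Spike trains.** Inter-spike intervals are Gamma with mean equal to the
period and coefficient of variation 0.2 (a quasi-periodic oscillator;
CV 0 would be metronomic, CV ≫ 0.3 Poisson-like, and the observed traces
are visibly rhythmic). The first spike in a window is offset by
Uniform(0, period) — a random oscillator phase. Spike trains are drawn
per phase segment with that phase's period.

**Movie formation.** Somata are isotropic Gaussians (radius 7 px ≈ 15 µm
soma at the default 1 µm/px; no pixel pitch is published, and 1 µm/px
makes the "one micron" jitter equal one pixel). A neuron's brightness is
`amplitude × (baseline_frac + Σ kernel(t − t_spike))` with the transient
kernel `(1 − e^{−t/0.2}) e^{−t/1.0}` (sharp rise, ~1 s decay; no measured
time constants are available for these recordings, so generic Fluo4
values are used and remain configurable). Amplitudes (420–560 counts over
a 100-count background, baseline fraction 0.25) put single-transient
DF/F near 1.1–1.5, the scale of strong Fluo4 transients; the peak
detector's default prominence (0.3 DF/F) presumes transients of roughly
this contrast, so dimmer settings would change what "default SNR"
means for every recovery check. Frames receive Poisson
shot noise and Gaussian read noise (σ = 2 counts) and are quantized to
integer counts.

**Jitter.** A Gaussian-smoothed random walk (not white noise — measured
displacements drift slowly), anchored at zero on frame 1 and rescaled to
RMS 1 px for flight (0.2 px for lab). The exact trajectory is stored as
ground truth.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: astrocyte calcium waves,
network synchronization and bursting, optical PSF blur, non-rigid
deformation of the chip, photobleaching (off by default; an exponential
bleach factor can be enabled for robustness checks), and focus changes.
Real segmentation also faces overlapping somata and neuropil
contamination that the well-separated synthetic somata largely avoid.

# Stabilization

The correction follows the classic sparse Lucas–Kanade recipe:
Shi–Tomasi features (minimum eigenvalue of the windowed structure
tensor), iterative LK solution of the 2×2 normal equations per feature,
and a robust global translation per frame. Design choices that the
recordings leave open, made explicit here:

* **Rigid translation only.** The correction subtracts a measured
  displacement; no rotation/affine component is estimated.
* **Median aggregation** across features, because features sitting on
  blinking neurons produce outlier displacements.
* **Reference-frame tracking with warm starts.** Chaining consecutive
  frame pairs accumulates per-pair errors as a random walk
  (√204 × per-pair error would dominate the error budget); tracking each
  frame against a reference anchored at frame 1, warm-started at the
  previous frame's shift so the per-iteration motion stays small,
  removes the accumulation. The reference refreshes every 50 frames.
* **Per-window z-normalization.** Calcium transients change a soma's
  brightness several-fold between a reference and a later frame,
  violating intensity constancy and making plain LK run away on active
  neurons. Normalizing each window to zero mean and unit variance makes
  the match invariant to per-window gain and offset. On identical
  windows the normalized residual is still exactly zero, so noiseless
  integer shifts are still recovered to machine precision.
* **Presmoothing (σ = 2 px) for detection and tracking only.** At
  realistic photon counts, shot noise carries per-pixel gradient energy
  comparable to a dim soma's rim, so unsmoothed Shi–Tomasi scores peak
  on noise and LK windows lock onto the reference frame's noise
  pattern. Smoothing suppresses the spatially uncorrelated noise
  gradients far more than the blob gradients. The corrected movie is
  always resampled from the *raw* frames.
* **Bilinear resampling with constant-edge padding** for the subpixel
  correction: monotone, ringing-free at soma edges, and cheap. The
  border band that padding invalidates is excluded from the activity
  map (8 px margin).
* **Single-level LK, no pyramid.** Displacements are ~1 px; the
  small-motion assumption holds, and the tests document how a 10 px
  shift breaks it.

With six dim somata and default noise, per-frame localization is
information-limited near 0.02–0.08 px; the residual against ground-truth
jitter stays below 0.2 px RMS, i.e. well below the 1 µm scale being
corrected.

# ROIs and DF/F

Active neurons are found from the temporal standard deviation of each
pixel over unmasked frames (smoothed with a σ = 2 px Gaussian):
anatomical segmentation is deliberately not attempted, since only active
neurons enter the statistics. The threshold is the 0.95 quantile of the
nonzero map values, bounded below by `median + 6·MAD` — in an inactive
field the quantile alone would sit inside the noise distribution and
segment noise clusters. Components are 8-connected; those outside
[20, 400] px are discarded, except that an oversized component whose
watershed contains a single object is one bright soma, not a merger, and
is kept. Oversized components with multiple watershed objects are split.

The fluorescence normalization is `DF/F = (F − F_m)/F_m`, with `F` the
ROI's mean intensity and `F_m` the mean intensity of the *whole field of
view at that frame*. A per-frame `F_m` is the only reading that keeps
DF/F well defined under slow global drift; a scalar (time-averaged) mode
is available behind a switch for sensitivity checks. Note a property of
this normalization that tests rely on: it is exactly invariant under
multiplying the entire stack by a constant, but it is *not* a
background-subtracted fraction — a bright soma has positive baseline
DF/F.

# Peaks and periods

Peaks are local maxima of the DF/F trace smoothed by a 0.8 s moving
average (two frames), kept when their topographic prominence reaches
0.3 DF/F units, thinned to a minimum separation of 1.2 s (strongest
first), and rejected on masked frames. These defaults resolve the 2–8 s
periods of interest at 2.5 Hz without splitting single transients;
periods below ~1.5 s are at the resolution limit of a 1 s-decay
indicator sampled at 2.5 Hz, and neurons that fast are partly merged or
dropped — a genuine limitation of the measurement, not of the
implementation, and visible in the recovery tests as a small upward bias
of the pooled 1 g mean.

The per-neuron period is the arithmetic mean inter-spike interval within
a phase window, defined only when at least two peaks (one ISI) survive;
with only a handful of cycles per phase, spectral estimators are not
meaningful. ISIs spanning a masked transition gap are discarded, never
interpolated.

# Per-phase statistics

Field-level phase periods are means over the field's defined per-neuron
periods. The period ratios are computed from field-level periods
(α₁→₁.₈g = T₁.₈g/T₁g, α₁→₀g = T₀g/T₁g, α₁.₈→₀g = T₀g/T₁.₈g), each defined
only when both operands are; a per-neuron ratio mode exists behind a
flag. Undefined operands propagate — a triggered network has no 1 g
period and therefore no α₁→·, and a zero denominator yields an undefined
ratio, never infinity.

Classification is purely temporal: a field is CONSTITUTIVE if any
unmasked peak occurs during PRE_1G, else TRIGGERED if any peak occurs
later, else INACTIVE. "Reacted to gravity" is operationalized as a
maximum pairwise relative period change above 20% across phases
(configurable; no published criterion exists). Campaign summaries pool
per-neuron mean periods per phase (pooling raw ISIs instead would weight
fast neurons more; the per-neuron-mean convention matches per-neuron
violin plots), and report Sarle's bimodality coefficient
(skew² + 1)/(kurtosis + small-sample term) per phase with the uniform
benchmark 5/9 ≈ 0.555 as the flag threshold — a closed-form descriptive
flag, deliberately not a hypothesis test. Formal between-phase testing
and mixed-effects modeling of neuron-within-field nesting are out of
scope.

# Viability and cell typing

The module consumes nuclei label masks (segmentation itself, a learned
segmenter in practice, is out of scope; the synthetic generator provides
masks with truth). A nucleus is called dead only when *all three* cues
agree — at most one nucleolus, condensed area, and high DAPI intensity —
because the published rule lists the cues without combination logic, and
the conjunction is the only monotone choice (adding nucleoli can never
kill a cell). Thresholds default to Otsu over the per-nucleus values.
Nucleoli are strict local DAPI maxima at least 0.15 above the nucleus
median. Since MAP2/GFAP labeling is somatic, marker intensity is
measured on a ring ROI: the nucleus dilated by a Euclidean disk
(default 4 px ≈ a 4 µm somatic shell; no published radius) minus the
nucleus, with neighbouring nuclei excluded from the ring. Cell types are
assigned by Otsu-thresholded ring means; ties fall to OTHER.

The nuclei simulator plants 65% alive cells and a 2:1 neuron:astrocyte
ratio by default (the published sorting result) on a jittered grid with
guaranteed non-overlap; recovery within ±5 percentage points and ±20% of
the ratio is part of the test suite.

# Numerical choices and degenerate inputs

* Truncated normals are drawn by rejection; the location solve uses
  `uniroot` at 1e-8 tolerance.
* LK iterations stop when the update norm falls below `tol`
  (5e-3 px in the pipeline; tests use 1e-10 to demonstrate exactness)
  or after `max_iter`; near-singular structure tensors (relative
  minimum-eigenvalue test) invalidate a feature rather than producing a
  wild solve.
* A frame where tracking fails entirely inherits the previous shift and
  is flagged in the trajectory; frames are never dropped.
* Peak thinning breaks ties by smoothed height, then earlier time.
* An all-masked stack, an empty nucleus mask, a zero-intensity field
  (`F_m = 0`) and an empty period set are errors; an inactive field
  (no ROIs, no peaks) is a valid result, not an error.
* Problem sizes in the test suite: the full-scale flight campaign
  (29 fields of 205 frames at 256×256) and lab campaign (10 fields) run
  once each; unit tests use analytic scenes and small rendered fields.

# Reproducibility

A campaign is a pure function of (preset, seed): the global seed fans
out to per-field substreams through a fixed affine map, so field k is
bit-identical whether 5 or 50 fields are generated, and
`simulate_and_analyze()` (the streaming route, bounded memory) matches
`simulate_campaign()` + `analyze_campaign()` exactly.

# Known limitations

* Periods under ~1.5 s are unresolvable at 2.5 Hz with a 1 s-decay
  indicator; the pooled 1 g mean carries a small (+0.2–0.4 s) upward
  bias from losing the fastest neurons.
* The 1 g phase offers at most 8 unmasked seconds, so per-neuron 1 g
  estimates rest on 1–3 ISIs and the pooled 1 g mean on ~15–25 neurons;
  its seed-to-seed spread (±0.2–0.3 s) is inherent to the design, not
  reducible by the analysis.
* Rigid translation cannot correct non-rigid chip deformation.
* DF/F with a field-mean normalizer mixes a neuron's signal with global
  activity; with few, sparse, non-synchronized neurons the effect is
  negligible, but it would bias dense synchronized preparations.
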