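# gravitrace

Analysis of spontaneous calcium activity in 2D neuronal networks imaged
during parabolic-flight gravity changes — and a synthetic-movie generator
that makes the whole pipeline verifiable by parameter recovery.

## The problem

A parabolic flight exposes a sample to ~30 s of hypergravity (1.8 g),
~22 s of microgravity (0 g), and a second hypergravity phase. Immature
hippocampal networks loaded with the calcium indicator Fluo4-AM show
spontaneous calcium oscillations with periods of a few seconds, so an
82 s recording at 2.5 Hz (100 ms exposure every 400 ms) captures a few
oscillation cycles per gravity phase. The scientific questions are
quantitative: does the oscillation period *T* change with gravity, and
are silent networks activated by hypergravity?

`gravitrace` implements the measurement chain for time-lapse movies of
such recordings:

1. **timeline** — map every frame to its gravity phase
   (1 g / 1.8 g / 0 g), masking blurred transition frames;
2. **stabilize** — remove micron-scale rigid jitter with Shi–Tomasi
   features + iterative Lucas–Kanade tracking, median-aggregated into a
   global per-frame translation;
3. **traces** — segment active-neuron ROIs from the temporal-variance
   map and extract normalized traces
   `DF/F = (F − F_m)/F_m`, where `F` is the ROI mean intensity and
   `F_m` the mean intensity of the field of view at that frame;
4. **spikes** — detect calcium transients as prominence-filtered local
   maxima and estimate each neuron's period as its mean inter-spike
   interval (ISI) per phase;
5. **gravstats** — field-level mean periods `T(g)`, period ratios
   `α₁→₁.₈g = T₁.₈g/T₁g`, `α₁→₀g = T₀g/T₁g`, `α₁.₈→₀g = T₀g/T₁.₈g`,
   constitutive/triggered/inactive network classification, campaign
   summaries and bimodality flags;
6. **viability** — live/dead nuclei calls (polynucleolated ⇒ alive;
   mononucleolated + condensed + DAPI-bright ⇒ dead) and
   neuron/astrocyte typing from ring-shaped somatic ROIs
   (dilated nucleus minus nucleus) on MAP2/GFAP channels;
7. **simulate** — synthetic campaigns (TIFF movies + ground-truth CSVs)
   with planted per-phase periods, triggered activation, jitter and
   noise, so that 1–6 are tested by recovering what 7 planted.

## Worked example

Simulate one flight-like field of view, analyze it, and look at the
recovered statistics:

```r
library(gravitrace)

fields <- simulate_campaign(
  n_fields = 3, preset = flight_preset(),
  class_counts = c(CONSTITUTIVE = 1, TRIGGERED = 1, INACTIVE = 1),
  seed = 7)

an <- analyze_field(fields[[1]]$stack, fields[[1]]$timeline, field_id = 1)
an$stats
#>   field_id     class T_1g    T_18g     T_0g n_active n_active_1g n_active_18g n_active_0g alpha_1_18 alpha_1_0 alpha_18_0
#> 1        1 TRIGGERED   NA 5.130101 5.061905       10           0           10          10         NA        NA  0.9867066

fields[[1]]$truth$field_class
#> [1] "TRIGGERED"
colMeans(fields[[1]]$truth$neurons[, c("period_HYPER_1", "period_MICRO_0G")])
#>  period_HYPER_1 period_MICRO_0G
#>        4.834117        4.422699
```

Reading the output: the field was planted as a hypergravity-triggered
network — no activity at 1 g (`T_1g = NA`, so the 1 g-referenced α are
undefined), ten active neurons from the 1.8 g phase on. The recovered
field-level mean periods (5.13 s at 1.8 g, 5.06 s at 0 g) track the
generative ones (4.83 s, 4.42 s), and `alpha_18_0 < 1` says this
triggered network ran *faster* in microgravity than in hypergravity —
the signature the per-class flight preset plants.

The same machinery scales to a campaign (memory-bounded, one field at a
time):

```r
res <- simulate_and_analyze(preset = flight_preset(), seed = 7)
res$summary$phase$T_1g$mean    # pooled 1 g period, ~2.9-3.1 s
res$summary$class_counts       # CONSTITUTIVE 5, TRIGGERED 14, INACTIVE 10
res$summary$median_alpha       # alpha_1_18 > 1, alpha_18_0 < 1
```

A thin command-line front end over these functions ships in
`inst/scripts/gravitrace`
(`simulate`, `stabilize`, `analyze`, `viability`, `all`).

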