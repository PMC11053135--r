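---
title: "Mapping lower-urinary-tract responses to epidural spinal stimulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lower-urinary-tract responses to epidural spinal stimulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eesmap)
```

## The problem

Epidural electrical stimulation (EES) of the spinal cord is mapped by
delivering low-frequency pulse trains at different spinal segments while
recording muscle EMG and bladder pressure. Two questions drive the analysis:

1. **Site specificity of recruitment.** Which stimulation sites most
   effectively recruit the detrusor (Detr, bladder smooth muscle) and bladder
   pressure (CYST) versus the external urethral sphincter (EUS, striated
   muscle)? This is answered by building, for every (site, channel) pair, a
   *recruitment curve* — evoked-response amplitude as a function of
   stimulation current — fitting the slope of its rising part by linear
   regression, normalizing slopes per animal and channel to the best site,
   and comparing rostral (lower thoracic / upper lumbar) against caudal
   (lower lumbar / sacral) site groups.
2. **Sustained responses to burst stimulation.** During a 5 Hz train, how
   much does each channel's activity rise relative to the pre-stimulation
   background (%BG)? The rostral/caudal contrast of these percentages is
   tested per animal with paired exact Wilcoxon signed-rank tests.

No raw recordings are distributed with the package, so every downstream stage
is exercised against a synthetic-recording generator whose ground truth is
known exactly. The generator is first-class, tested code: its parameters are
recovered by the very measurement chain that would run on real data.

## The synthetic-recording generator

`generate_session()` lays out one contiguous block per stimulation site. In
each block a current ladder (default 10–800 µA in 10 µA steps, 10 pulses per
step at 1 Hz, 0.3 ms pulse width, digitized at 20 kHz) is delivered; each
pulse adds, per channel:

* a single-sample **stimulus artifact** (default 100 units) at the pulse
  time, so that artifact blanking is exercised downstream;
* the channel's **waveform template**, scaled by the recruitment function and
  the site's gain multiplier, and aligned so that the template's first
  prominent peak falls `latency + jitter` milliseconds after the pulse;
* white Gaussian **background noise** with channel-specific SD.

Templates come in three shapes (`waveform_template()`), all scaled so the
peak-to-peak amplitude equals the commanded amplitude exactly:

* **fast** (EUS, TA): three Gaussian lobes of alternating sign with
  amplitudes (1, −1.35, 0.35), total duration 20 ms — a multiphasic
  short-latency EMG wave that integrates to approximately zero;
* **slow** (Detr): a positive raised-cosine lobe over the first quarter of
  the duration followed by an area-matched shallow negative lobe, total
  duration 225 ms — a slow biphasic wave, zero net area;
* **pressure** (CYST): a monophasic lobe rising over the first 15% of the
  duration and decaying over the rest (pressure transients do not integrate
  to zero).

The slow and pressure shapes rise quickly after onset on purpose: the
generator aligns the first peak at the configured latency, so the internal
peak offset must be smaller than the latency or the response would begin
before its own stimulus. `generate_session()` enforces this causality
constraint and rejects violating configurations.

The recruitment function (`recruitment_gain()`) is piecewise linear: zero at
or below a threshold current, linear with slope `gain` above it, constant
above a saturation current. This phenomenological form deliberately avoids
any biophysical model of current spread; it exists to give the slope-fitting
stage a known ground truth.

Latency jitter is drawn per pulse from a normal distribution clamped at
±3 SD, which keeps the ordering of first peaks stable. Determinism is strict:
a session is a pure function of (inputs, seed). Each site uses the substream
`seed + site_index`, so appending a site never perturbs the sites already
generated.

`generate_burst_session()` prepends a noise-only background segment (default
5 s) to a constant-current train (default taken at the ladder maximum). At
5 Hz the 225 ms slow templates outlast the 200 ms inter-pulse interval,
producing the sustained elevation that the %BG analysis quantifies.

### Preset conditions

`preset_feline_lut()` encodes the emulated study conditions: four channels
and five sites (T13, L1 rostral; L6, L7, S1 caudal). Channel latencies are
the reported group means — Detr 38.01/38.07 ms (rostral/caudal sites), EUS
13.72/7.41 ms, TA 14.61/8.96 ms. Gain multipliers make Detr/CYST recruitment
rostral-dominant (caudal multipliers 4–7× smaller) and EUS recruitment
caudal-dominant, with TA recruited broadly. CYST latency is not reported for
the original recordings; the preset uses 40 ms (a slow wave similar to the
detrusor) and CYST is conventionally excluded from latency summaries.
Background-noise SDs (0.2 for EMG channels, 0.05 for pressure) and the
recruitment thresholds/saturations (20 µA / 600 µA) are likewise not reported
for the original recordings; they are package choices giving moderate
signal-to-noise at mid-ladder currents, and they stay configurable in
`channel_model()`.

## Evoked-potential extraction

`epoch_and_average()` cuts `[-pre, +post]` windows (defaults 50/400 ms)
around each pulse and averages them pointwise. Samples in `[0, blank]`
(default 2 ms) are excluded from all measurement — this removes the stimulus
artifact; no artifact-exclusion window is reported for the original
recordings, so the value is a package default. Baseline statistics are taken
on `[-20, 0)` ms.

Two baseline SDs are kept:

* `baseline_sd` — SD of the averaged epoch's baseline. This is the quantity
  that shrinks as σ/√n with the number of sweeps (verified by a Monte Carlo
  test).
* `baseline_sd_sweep` — pooled SD of the single-sweep baselines, i.e. the
  background-noise scale of the recording itself.

**Presence criterion.** A response is *present* if some post-blanking local
extremum of the averaged epoch deviates from the baseline mean by more than
`k` × `baseline_sd_sweep` (default `k = 3`), in the direction of the
extremum (maxima above, minima below). Thresholding against the *sweep-level*
SD is deliberate: averaging n sweeps reduces the averaged noise by 1/√n
below the threshold, which is precisely why averaging buys detection power.
Thresholding against the averaged epoch's own baseline SD would flag nearly
every pure-noise epoch as a response (some extremum of a several-thousand-
sample noise window always exceeds 3 of its own SDs); with the sweep-level
criterion the false-presence rate on pure noise is near zero (tested at
≤ 5/100). When the background SD is exactly zero (noise-free synthetic
data) any nonzero extremum qualifies.

**First-peak latency** (`measure_latency()`) is the time from pulse onset to
the first qualifying extremum of either polarity. A *sustained-peak* rule
disambiguates noisy flanks: a candidate extremum counts only if it is also
the most extreme value over the following `peak_window_ms` (default 50 ms).
Without it, small noise wiggles riding on the rising edge of slow waves are
taken for the first peak and the latency collapses toward the blanking edge.
The window trades temporal resolution for robustness — responses with
distinct true peaks closer together than the window cannot be separated — and
is configurable. Ties are broken toward the earlier sample ("first peak"
semantics).

**Peak-to-peak amplitude** (`measure_p2p()`) is, by default, the value at
the first qualifying peak minus the value at the immediately following
opposite-polarity sustained extremum within the window; for a monophasic
response, the absolute deviation of the peak from the baseline mean; 0 when
the response is absent. The alternative reading of "peak-to-peak" —
max-minus-min over the post-blanking window — is available as
`p2p_mode = "window_range"`.

Rectification is available in the epoching configuration but is off for
latency/amplitude measurement (it destroys first-peak polarity); the
rectify-then-smooth conditioning is instead the default for the burst
metric, where a magnitude envelope is wanted.

On noise-free preset sessions the chain is exact: measured latencies equal
configured latencies to within one sample period, and measured amplitudes
equal the inserted template amplitudes to better than 1e-6 relative.

## Recruitment mapping

`build_recruitment_curve()` sorts measurements by current, averages repeats,
and keeps absent responses as zero-amplitude points. `fit_slope()` regresses
amplitude on current by ordinary least squares *from the lowest current
through the first current at which the maximum amplitude is attained*;
saturation and post-maximum decline are excluded by construction, so adding
post-maximum points never changes the slope. "First attainment" resolves
repeated maxima (a plateau) to the start of the plateau. The intercept is
free — the fit is a generic linear regression, not forced through zero. A
curve whose maximum sits at its first point has no rising part; its slope is
undefined, flagged, and excluded from normalization. A constant curve has
slope 0.

`normalize_slopes()` expresses each slope as a percentage of the maximum
over sites, separately per animal and per channel, clamping negative slopes
to zero first; an all-zero vector is flagged degenerate. Normalizing per
channel (rather than across all channels jointly) makes each channel's map
span [0, 100], which is what a per-channel color scale displays; the
alternative reading would only rescale columns jointly and cannot change
which site is best.

`build_segment_map()` averages the normalized percentages across animals
into a sites × channels map (mean ± SE per cell) and aggregates sites into
rostral/caudal group scores per animal. The default group score is the
*maximum* over the animal's sites in the group — the region's best
recruitment — with `"mean"` available; the per-animal group scores feed
paired rostral-vs-caudal Wilcoxon tests.

## Burst (%BG) analysis

`percent_of_background()` computes the same metric on the pre-stimulation
background interval and on the stimulation interval and reports
`100 × stim / background` percent. The default conditioning is full-wave
rectification followed by a 50 ms moving-average envelope, and the default
metric is RMS; both are configurable and recorded in the result, since only
"amplitude as a percentage of background" is specified for the original
analysis. Samples within 2 ms after each pulse are zeroed before
conditioning so the stimulus artifact does not inflate the stimulation
metric. The ratio is invariant to uniform gain on the whole trace, and a
zero background metric is a degenerate-background error rather than an
infinite percentage.

The package ships the per-animal %BG table of the emulated experiment
(`load_burst_percent()`: CYST, Detr, EUS × rostral/caudal × five cats).
These 30 values are the inputs of the site-specificity tests below.

## Exact nonparametric statistics

The sample sizes here (n = 5 animals) make asymptotic p-values meaningless,
so the tests are implemented with exact null distributions rather than
wrapped from approximations:

* `wilcoxon_exact()` — paired signed-rank test. Zero differences are
  dropped; tied absolute differences get midranks. The null distribution of
  W (sum of positive-difference ranks) is built over all 2^m sign
  assignments via a count-generating recursion on doubled midranks
  (mathematically identical to full enumeration, exact in double precision
  for the whole supported range m ≤ 25).
* `mannwhitney_exact()` — unpaired rank-sum test; the null distribution of
  the rank sum is built over all `choose(n1+n2, n1)` labelings (midranks
  under ties). Exact whenever min(n1, n2) ≤ 25.
* Two-sided p-values use the doubling convention `min(1, 2 × min(lower,
  upper))`. Under complete separation this reproduces the analytic limits
  2/126 ≈ 0.0159 for group sizes (4, 5) and 2/56 ≈ 0.0357 for (3, 5).
* Sidedness is never inferred from the data; callers must state it. The
  five-pair %BG comparisons are one-sided by design (the direction is the
  hypothesis under test), and with five concordant pairs the one-sided exact
  p is 1/32 = 0.03125, which prints as 0.0313. The same value could also be
  a halved two-sided report; both readings are exposed through the
  `alternative` argument.
* `kruskal_wallis()` — H on pooled midranks with tie correction; p from the
  chi-square approximation with k−1 df (standard practice), with a full
  permutation-enumeration p behind `exact = TRUE` for pooled sizes ≤ 10.
* `dunn_posthoc()` — pairwise z from mean-rank differences with
  tie-corrected pooled variance; multiplicity adjustment defaults to none
  (reported post-hoc p-values cannot be attributed to a specific
  correction), with Bonferroni and Holm available.
* Larger samples fall back to normal approximations with tie and continuity
  corrections, flagged as non-exact in the result.

Printed p-values round half away from zero (1/32 → 0.0313); base `round()`
rounds half to even and would print 0.0312.

## Pipeline, container format, determinism

`run_pipeline()` composes the stages over a simulated cohort (default 5
animals) and writes `evoked.csv`, `slopes.csv`, `segment_map.csv`,
`group_stats.csv`, `burst.csv` and `stats.csv`. All outputs are plain
delimited text with numeric fields at 6 significant digits, stamped with an
MD5 hash of the analysis configuration (the output path is excluded from the
hash). Given a configuration and seed the outputs are byte-identical across
runs; animal a uses seed substream `seed + 1000(a−1)`. A channel that never
responds flows through as absent everywhere — zero slopes, degenerate
normalization, an NA test — rather than an error.

Sessions round-trip through a plain-text container (`write_session()` /
`read_session()`): `metadata.json`, one full-precision text file per
channel, `events.csv` (absolute seconds), and `ground_truth.json` for
synthetic sessions. Reading validates trace lengths and strictly increasing
in-range event times, naming the offending file. Times are seconds in
containers and stimulus-relative milliseconds in evoked outputs.

## Problem sizes used by the test suite

The preset protocol keeps the full study conditions, but simulation-based
tests run reduced versions of it, chosen as the smallest sizes that still
separate signal from noise cleanly: noise-free exactness checks use 2 pulses
per current over a 30–60 µA ladder at 20 kHz; noisy cohort checks use 50
seeded cohorts of 5 animals each, a 30–80 µA ladder with 2 pulses per
current at 1 kHz; Monte Carlo detection checks use 100 seeds with 10-sweep
averages. With these sizes the whole suite runs in a few minutes on one CPU.

## What passing tests do and do not show

The generator emulates the structure of stimulation-locked recordings —
stimulus-locked templates, recruitment growth, latency jitter, stationary
Gaussian noise, a clean pre-train background. Real recordings violate most
of these idealizations: noise is non-stationary and often line-contaminated,
stimulus artifacts span multiple samples and ring, evoked shapes vary
between pulses, movement and cystometric drift corrupt baselines, and
electrode impedance changes over a session. Passing the closed-loop tests
therefore shows that the measurement chain is *correct* (it recovers known
truth under its stated model), not that its defaults are *optimal* for any
particular real recording. The configuration surface (blanking, presence
threshold, sustained-peak window, smoothing, metric) exists precisely
because those choices must be re-examined against real data.

## Known limitations

* The recruitment model is phenomenological; no volume-conductor or cable
  modeling, so absolute slope values carry no biophysical meaning — only
  their site ordering does.
* The sustained-peak window (50 ms default) limits latency resolution for
  multi-component responses with peaks closer than the window.
* The measured peak-to-peak amplitude of noisy responses carries a positive
  noise bias (extrema of noisy signals are biased outward); recruitment
  slopes inherit a milder version of it. Noise-free closed loops are exact.
* Kruskal–Wallis p-values use the chi-square approximation by default,
  which is anticonservative for very small groups; the exact permutation
  option is limited to pooled sizes ≤ 10.
* The burst analysis assumes a stationary background immediately preceding
  the train; slow pressure drift would bias %BG for the CYST channel.
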