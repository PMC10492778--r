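---
title: "Quantifying trans-neuronal aggregate transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trans-neuronal aggregate transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synspread)
```

## The experimental system and the quantity of interest

synspread analyses data from compartmentalized microfluidic neuron cultures
in which a presynaptic population connects to a postsynaptic population
exclusively through axons growing one way through asymmetric microchannels
("axon valves"). When fluorescently tagged alpha-synuclein (aSyn) assemblies
— fibrils (hFib/mFib) or oligomers (hOlig) — are spiked into the presynaptic
compartment, the fluorescence that later appears on postsynaptic somas
measures anterograde trans-neuronal transfer.

All fluorescence is quantified as ROI means and normalized by untreated
control devices imaged in the same microscopy session, so the control level
maps to 1 and detector gain cancels. The central statistic is the
**Transmitted Excess Signal**:

$$\mathrm{TES}_{\mathrm{presyn}\to\mathrm{postsyn}}
  = \frac{S_{\mathrm{postsyn}} - S_{\mathrm{background}}}
         {\tfrac1n \sum_{i=1}^{n} \left(S_{\mathrm{presyn},i} -
          S_{\mathrm{background}}\right)},$$

with $S_{\mathrm{background}} = 1$ (controls cluster at 1 after
normalization), the numerator the experiment's mean excess in the target
compartment, and the denominator the mean excess over the $n$ experiments of
the same condition and culture age (DIV) in which the source compartment was
measured. The presyn→axons and axons→postsyn variants replace numerator or
denominator accordingly. TES is reported per experiment and aggregated as
mean ± SEM over experiments.

Design choices around TES that the formula itself leaves open:

* **Negative values are kept.** Sub-background postsynaptic signal gives a
  negative excess; clipping at zero would bias control distributions upward,
  so `compute_tes()` never truncates.
* **Denominator floor.** When the source excess is at or below `epsilon`
  (default 0.05, i.e. a 5 % excess), TES would amplify noise rather than
  measure transfer; `compute_tes()` raises an error instead. For tables with
  no usable source arm (control-only runs) an explicit `denominator_excess`
  can be supplied; the control identity — TES centred on 0 — holds for any
  fixed positive denominator.
* **Condition-matched denominators.** The $1/n\sum$ spans experiments of the
  same treatment and DIV only; this is the only grouping under which the
  per-condition profiles are interpretable.

## The rate model

Transfer efficiencies translate into exposure terms under explicitly liberal
assumptions: a linear relation between bath concentration and bound
fluorescence, a constant transfer rate over the window, and no fluorescence
loss to transport, secondary transfer, or bleaching. `rate_estimate()`
carries these assumptions in its output; they are not optional metadata.

* `equivalent_dose(spike_nM, tes_fraction)` = the bath concentration that
  would produce the observed postsynaptic increase by direct exposure
  (500 nM × 0.5 % = 2.5 nM).
* `per_axon_rate(dose, n_axons = 100, window_days = 2)` spreads that dose
  over the ~100 axons innervating the postsynaptic compartment and the
  transfer window. The 2-day default reflects the protocol — 24 h exposure,
  rinse, readout 3 days after introduction, hence about two days of
  post-uptake transfer — and is the only value consistent with the published
  bracket arithmetic (1–10 nM ↔ 5–50 pM/day); it is configurable.
* `dose_from_calibration()` inverts a user-supplied monotone dose→excess
  calibration by linear interpolation, returning the bracketing calibration
  interval alongside the point estimate and refusing to extrapolate outside
  the calibrated range (flagged endpoint instead).

## The synthetic-microscopy generator

No imaging data are deposited for this kind of experiment, so every stage is
validated against a seeded generator (`gen_soma_field()`, `gen_axon_field()`,
`gen_timelapse()`, `gen_synapse_field()`, `gen_signal_table()`) that emulates
the data-generating process with known ground truth.

What it emulates, and what it deliberately does not:

* **Per-soma fluorescence** is log-normal — right-skewed and strictly
  positive, matching the unimodal, right-skewed pooled histograms of real
  per-soma measurements — with mean `baseline × fold` and a coefficient of
  variation `soma_cv`. The condition folds default to the experiment-level
  means of the emulated study (`condition_defaults()`): presynaptic uptake
  21× / 29× (hFib at DIV14/21), 4.5× / 7.3× (hOlig), axonal +60–95 %,
  postsynaptic +3.2–10 %. The mFib presynaptic and axonal folds are not
  reported for that arm and reuse the hFib DIV14 values as fibril-like
  placeholders.
* **`soma_cv` calibration.** The default of 0.3 was chosen as follows:
  per-device means average over the somas measured in that device, and the
  reported device- and experiment-level reproducibility (postsynaptic
  excesses of 3–10 % detected as significant over ~5 experiments, with "up
  to several hundred" somas measured per culture) implies an effective
  per-experiment noise of roughly 2 %. With ~120–240 somas measured per
  device this corresponds to a per-soma CV near 0.3, which is therefore the
  default. The CV is a calibration knob of the generator, not a biological
  claim; the distribution-shape diagnostics do not depend on it.
* **Phase rendering** is minimal: dark soma bodies with a bright halo on a
  mid-gray background plus Gaussian noise — sufficient contrast for a
  classical segmenter, with no attempt to model true phase optics or a PSF.
  Somatic autofluorescence of untreated cultures is emulated as bright
  puncta carrying a fraction (`autofluorescence_level`) of each soma's
  integrated signal; this changes texture, not per-soma means, so
  fold-recovery is unaffected.
* **Transport stacks** place particles in a microchannel (default 500 µm ≈
  769 px at 0.65 µm/px, 5 s frames, 60 frames = 5 min); a set fraction move
  at normal-law speeds, interrupted by geometric-duration pauses
  (`pause_prob` per frame, mean `pause_mean_frames`); stationary particles
  jitter within a pixel. Initial positions keep ≥ 10 px separation: two
  particles inside one PSF are not resolvable as two objects by any method,
  manual or automated. Moving particles leave the channel and their tracks
  truncate, as in real recordings.
* **Synapse fields** scatter Bassoon-like foci within 1.5 µm of a folded
  dendrite trace at a set linear density, with a 0.7 µm minimum separation
  (synapses are discrete, resolvable structures at the 0.24 µm/px confocal
  sampling emulated); aSyn-positive foci carry a clearly separated aSyn
  intensity.
* **Determinism.** Every generator derives a local substream from a single
  integer seed via stable string hashing (`substream_seed()`), so adding one
  scene to a study never reshuffles another, and identical seed + spec is
  bit-identical. The global RNG state is never touched.

Because the generator omits optics, debris, uneven illumination and
morphological variability, passing tests demonstrate the correctness of the
measurement and statistics chain on data with known truth — not segmentation
robustness on arbitrary real micrographs.

## Segmentation

`detect_somas()` replaces the interactive/learned detection used on real
data with a classical pipeline with the same output contract: Gaussian
smoothing (σ = 1.5 px), Otsu binarization of the inverted phase image, hole
filling, a plausible-area filter (25–250 µm²), and distance-transform
watershed declumping of components too large to be one soma. A noise guard
(foreground/background separation must exceed 3 image MADs) returns an empty
set on blank fields instead of segmenting noise. On synthetic fields at the
default SNR it reaches recall ≥ 0.9 at mean IoU ≥ 0.7 against ground truth.

`segment_foci()` follows the published recipe: rolling-ball-style
background subtraction (morphological white top-hat, radius 5 px for the
synaptic marker; 20 px for the aSyn channel in `classify_foci()`),
binarization by Otsu over the corridor pixels (the published pipeline says
only "binarized"), connected components restricted to the 3 µm dilated
dendrite corridor, and the particles-larger-than-one-pixel rule
(`min_area_px = 2`). The aSyn± threshold is Otsu on the focus mean
intensities by default — the original threshold was an arbitrary manual
choice, so the rule is always recorded in the output metadata and a fixed
value can be substituted; a dip-test check warns when the intensities do not
actually separate into two classes.

## Transport analysis

`build_kymograph()` samples each time-lapse frame along the microchannel ROI
(maximum over a 3 px transverse width), giving the standard time × position
image. `detect_tracks()` automates manual path counting in two passes:

1. **Stationary particles** are time-persistent vertical lines: positions
   holding a peak in ≥ 50 % of frames are claimed as stationary tracks
   (their peaks are claimed generously, ±5 px, so a blob formed by a passing
   particle merging with a stationary one is attributed to the line rather
   than poisoning the moving pool).
2. **Moving particles** are linked frame-to-frame by globally greedy
   nearest-prediction assignment with a robust (median-of-steps) velocity
   estimate, bounded coasting through crossings, and collinear fragment
   merging that also bridges pauses (positional continuity).

Motion classification uses the net displacement between trimmed-median
endpoints of median-smoothed positions (threshold 3 px), which is robust to
transient centroid pulls at crossings. Speeds ignore pausing, as in the
published analysis: runs of per-frame displacement below 0.5 px spanning at
least two frames are excised before the displacement average; the estimate
matches a brute-force least-squares slope within 1 % on straight-line
fixtures. The published analysis traced paths manually; no pause criterion
or line detector is stated there, so the 0.5 px / 2-frame rule and the
tracker above are this package's explicit operationalisation.

## Quality control and aggregation

`qc_device()` applies the study's inclusion minima, closed at the stated
bounds: ≥ 40 somas from ≥ 4 fields per soma device, ≥ 10 axons per axon
device, ≥ 650 µm of dendrite from ≥ 4 fields per synapse device. Devices
failing QC are flagged with explicit reasons and excluded from downstream
statistics by `run_pipeline()`, never silently dropped. Device means
aggregate to experiment means before any statistic, mirroring the study's
unit of replication; whether the session control mean should pool per soma
or per device is not stated in the source protocol — per device is used, to
match device-level data points.

Statistics follow the published decision tree: Shapiro–Wilk gates each group
(α = 0.05); normal groups get the one-sample t against 1 (for normalized
conditions vs control) or Welch's t; non-normal routes to Mann–Whitney.
Multi-group machinery (two-way ANOVA + Tukey, Kruskal–Wallis) is delegated
to the standard implementations behind thin tidy wrappers.

## The unimodality diagnostic

The pooled per-soma distributions (500 sampled somas, 100 bins, seeded
sampling without replacement in `signal_histogram()`) are checked for
unimodality with a dip-type statistic: the exact sup-norm distance from the
empirical CDF (midpoint convention, ties collapsed) to the nearest CDF that
is convex below and concave above a mode, computed by scanning all candidate
modes with lower/upper convex-hull deviations (Rcpp, O(n²)). Calibration is
Monte-Carlo against the uniform null — the classical least-favourable
reference for dip statistics — with the null sample cached per sample size.
This is an exact implementation of the stated geometric definition, verified
in the test suite against an independent brute-force chord construction; it
is not claimed to be numerically identical to the historical dip algorithm.

## Problem sizes and reproducibility

The validation suite runs everything end to end at sizes chosen so the full
suite completes in well under half an hour on one core: the TES-recovery
study uses 5 experiments × (4 treated + 4 control) devices with 120
postsynaptic and 60 presynaptic somas per device, one rendered field per
device-compartment (splitting the same somas over several fields is
statistically identical and only changes rendering cost), over 100 seeds;
transport recovery uses 25 channels × 20 particles. At these sizes the
a-priori error budget puts the per-seed TES estimate at a relative SD of
about 10 %, so recovery within 20 % of the implied value is expected in
~95 % of seeds. `run_pipeline()` defaults are smaller still and exist to
exercise the orchestration, not to produce publishable precision.

## Known limitations

* The soma segmenter is tuned to the generator's rendering; real phase
  micrographs (uneven illumination, debris, touching clusters beyond pairs)
  would need parameter adjustment or a learned detector behind the same
  `soma_rois` contract.
* The tracker resolves crossings statistically, not perfectly; two particles
  within one PSF are intrinsically one blob, and counts inherit that limit
  (the generator enforces resolvable separations for exactly this reason).
* The rate model is an order-of-magnitude translation, not a mechanistic
  transport model; every output carries its assumption list.
* `dose_from_calibration()` is only as good as the supplied calibration;
  without one, dose estimates reduce to spike × TES linearity.
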