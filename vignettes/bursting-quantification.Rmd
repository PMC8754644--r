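---
title: "Quantifying transcriptional bursting from MS2/MCP movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursting from MS2/MCP movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msburst)
```

# The measurement problem

In nuclear cycle 14 of the *Drosophila* embryo, a reporter carrying MS2
stem-loops bound by MCP-GFP makes nascent transcription visible as one
bright dot per nucleus. A two-channel time-lapse (histone marker + MCP,
z-stacks every 16.8 s or 12.8 s) therefore contains, implicitly, a per-nucleus
time series of transcriptional activity. `msburst` extracts those series and
reduces them to bursting parameters — amplitude, duration, frequency, total
output, onset time, induction rate — that can be compared across promoter
variants.

This vignette documents the models and the numerical choices behind each
stage, what the synthetic data generator does and does not emulate, and the
problem sizes used by the test suite.

# The telegraph signal model

The generator simulates each promoter as a two-state telegraph process in
continuous time:

* OFF → ON switching with rate `k_on` (1/min), so OFF dwell times are
  exponential — the signature of a single rate-limiting activation step;
* ON → OFF switching through `off_steps` sequential exponential steps of
  rate `k_off` each. At the default `off_steps = 1` ON dwell times are
  exponential; `off_steps = 3` gives Erlang ON durations, the multi-step
  shut-off alternative used to show that the duration-distribution test can
  reject single-step kinetics;
* while ON, Pol II initiates as a Poisson process at `r_load` (1/min);
* each initiated transcript contributes `unit_intensity` fluorescence for
  exactly `dwell` minutes (boxcar dwell kernel) — the residence time of the
  nascent transcript at the locus. A triangular elongation ramp would be
  more literal; the boxcar is sufficient to exercise every downstream stage
  and is isolated behind the simulator so it could be swapped.
* frames sample the transcript count every `frame_interval` seconds, plus
  additive Gaussian noise clipped at zero (emulating background-subtracted
  shot noise without a camera model).

Switching is simulated event-driven (exact exponential waiting times), not
per-frame Bernoulli, so dwell-time distributions are exact. With a fixed
seed the simulation is bit-reproducible.

The `variant_presets()` table encodes only ordinal relations between the
core-promoter variants (the TATA mutant trades away amplitude and frequency;
Inr/MTE/DPE mutants mainly lose frequency and delay onset, MTE mildest;
the Zelda variant activates early): no absolute kinetic rates are published
for these constructs, so the absolute preset values are package choices and
should never be read as measurements.

## The rendered movie

`render_movie()` draws non-overlapping textured disks (radius ~7 px) for the
histone channel and places one isotropic Gaussian dot per transcribing
nucleus in the MS2 channel, with integrated intensity equal to the true
trajectory value at that frame, at a fixed per-nucleus z-plane (neighboring
planes carry Gaussian-attenuated copies, so brightest-z selection is
exercised). Nuclei jitter around anchored positions (mean-reverting with
stationary sd `drift_sd`, default 0.3 px/frame) while the whole field shares
a slow random-walk drift — interphase nuclei are anchored in the embryo, and
independent random walks would let disks interpenetrate over a few hundred
frames, which no segmentation could (or should) untangle. The histone
channel is rendered as a single plane, i.e. as its own maximum projection.

What the generator does **not** emulate: photon/camera statistics, optical
PSF anisotropy, nuclear shape change, mitosis, photobleaching, or
out-of-focus drift. Passing the round-trip tests therefore shows the
pipeline is internally consistent and recovers known ground truth under
realistic geometry and noise — not that it is robust to every pathology of
real microscopy, which is what the manual mask override hook is for.

# Segmentation

Both methods operate on the max-projected, cropped histone frame (default
crops mirror the 512→430×430 and 512→300×430 field reductions and scale with
input size).

**Method 1**: Gaussian blur (σ = 2 px) → white top-hat (disc radius 15 px,
removing background larger than a nucleus) → CLAHE (8×8 tiles; the image is
edge-padded to a tile multiple and cropped back) → Otsu threshold →
marker-based watershed. Markers are local maxima of the distance transform
at least `seed_min_sep` apart (default 4 px ≈ half the nucleus radius;
deeper maximum wins) and at least `seed_min_depth` (2 px) deep, propagated
over the foreground. A depth-tolerance watershed was tried first and merged
touching nuclei whose distance-map saddle is shallow; the marker form is
what the separation rule actually describes.

**Method 2**: blur → clip near-saturated pixels (above 95% of the global
maximum, emulating chromocenter removal) to the local 3×3 median → scan ~40
candidate thresholds over the intensity quantiles, scoring each by (i)
closeness of the component count to the expected nucleus count (previous
frame's count, or the Otsu blob count on the first frame), (ii) the fraction
of components outside [0.3, 3]× the Otsu-reference median area, and (iii)
deviation of the median component area from that reference; lowest score
wins, ties to the lower threshold. The exact scoring function is not
specified anywhere authoritative, so it is isolated in one place and
documented here. MS2 pixels above 2× the channel mean are transcription
dots; a dot outside all nuclei pulls the boundary of the nucleus with the
nearest centroid until covered. Labels are finally clipped to the Voronoi
cells of the component centroids (guaranteeing disjoint labels); any dot
pixel orphaned by clipping is recovered by growing its cell's owner within
the cell, so the spot-coverage guarantee and label disjointness hold
simultaneously.

# Tracking

Frame-to-frame lineage linking accepts candidate (track, label) pairs
greedily in ascending centroid distance — the nearest-neighbour rule — with
ties broken deterministically (lower track id, then lower label) and a hard
gate `max_disp` (default = nucleus radius; some gate is required to stop
lineages teleporting when a nucleus vanishes). Greedy ascending matching is
symmetric between the two frames, so forward and backward passes agree by
construction. Tracks absent for up to 2 frames are bridged and flagged
(acquisition pauses produce short gaps); longer absences split the lineage.

# Spot quantification

Per nucleus and timepoint the brightest voxel over the label's projected
footprint (all z) seeds a 2D Gaussian fit in an 11×11 px window at that
z-plane:

$$I(x,y) = \alpha + I_0\,
  e^{-\left(\frac{(x-x_0)^2}{2\sigma_x^2}+\frac{(y-y_0)^2}{2\sigma_y^2}\right)}$$

solved by Levenberg–Marquardt with starts α = window-border median,
I₀ = center − α, σ = 1.5 px, and bounds 0.3 ≤ σ ≤ 8 px, I₀ ≥ 0 (numerical
stability only; results are insensitive to the start values on rendered
dots). The spot intensity is the closed-form background-subtracted integral
2π σₓ σᵧ I₀ — an identity maintained bit-exactly. Three guards matter:

* a fit whose estimated dot exceeds the window (2σ > window/2 on either
  axis, the operational reading of "larger than the fitted region") is
  invalid, and the nucleus's whole timepoint is excluded; excluded frames
  are linearly interpolated so smoothing and burst continuity survive, but
  stay flagged and never enter totals as measured values;
* a near-flat window converges to I₀ ≈ 0 and stays valid with integral ≈ 0
  (a silent nucleus is a measurement of zero, not a failure);
* a fit whose center lands outside the nucleus footprint (1 px margin) has
  locked onto a neighbouring nucleus's dot bleeding across the boundary and
  counts as no dot here — a transcription site must lie inside its nucleus.

Per-trajectory minima are then subtracted so every baseline is zero.

# Burst calling

On the 5-frame moving-average smoothed trace (truncated windows at the
edges): a burst opens at the first frame strictly above the threshold,
tracks its running local peak (the only causal reading of "local peak" in a
left-to-right scan), and closes at the first frame strictly below 55% of
that peak (ties at exactly 55% do not close; the closing frame is excluded
and rescanned, since it may open a new burst). The interval then shifts 2
frames later (clamped at the trace end; a burst pushed entirely off the end
is dropped; shifted bursts that come to overlap merge). Bursts shorter than
5 frames after the shift are detection noise and are dropped — verified not
to distort the duration distribution of surviving bursts. A burst opening at
the very first frame on a strictly decreasing 5-frame run is a trace caught
mid-decay and is dropped.

The burst-start threshold is not published; the default reuses the one
threshold rule that is stated — 10% of the group maximum (of the smoothed
trace) — one value per experiment set, overridable. An independent
brute-force implementation of these rules lives in the test suite and the
caller must match it burst-for-burst on hundreds of random traces.

Statistics per nucleus: amplitude = mean smoothed peak over bursts; duration
= mean burst length; total output = rectangle-rule area under the **raw**
trajectory over the whole analysis window (the trajectory, not the bursts,
is what is integrated); `t_first` = start of the first surviving burst;
induction rate = bursts per minute between `t_first` and the trace end.

# Population metrics

Activity uses the raw trajectories: a nucleus is instantaneously active
above 10% of the group maximum; the cumulative fraction counts ever-active
nuclei and is monotone by construction. OFF/ON duration distributions are
fit by maximum likelihood (exponential rate = 1/mean) with a
Kolmogorov–Smirnov test against the fitted law.

Autocorrelation: smooth (window 5) → first difference (removes the slow
nc14 trend) → biased sample autocorrelation on the frame-interval lag grid,
normalized to 1 at the smallest lag of that grid — lag 0. Normalizing at
lag 1 of the derivative series was considered and rejected: for a
temporally unstructured trace the derivative of a 5-frame moving average has
zero lag-1 autocovariance, so that normalization divides by noise. The
shuffled null permutes the trend-removed derivative sequence per nucleus;
permuting the raw trace and re-filtering would simply reproduce the
smoothing filter's own autocorrelation (−0.5 at the window lag for any
unstructured input) rather than a flat reference. The first periodicity peak
is the largest value after the curve's first turning point.

# Expression reconstitution

Each frame's raw intensity is a production-rate proxy; the cohort produced
at time *t* decays until the end of the analysis. "Linear degradation with a
half-life" is self-contradictory, so the default is standard first-order
kinetics, `2^(-age/half_life)` with `half_life = 7` min, and a literal
linear-cohort alternative (each cohort decays to zero over two half-lives)
sits behind `model = "linear"`; both retain exactly half a cohort after one
half-life, and at `half_life → ∞` the exponential model reduces to the plain
time integral (= total output). Decay is compounded per frame; at a 16.8-s
frame interval the difference from continuous compounding is under 0.2%.
Final-frame nuclei are then false-colored proportionally to their remaining
mRNA and overlaid on the histone projection.

# Test problem sizes and regimes

The suite validates every stage against generator ground truth. Sizes were
chosen so each property is measured where it is statistically decidable:

* dwell-time distributional checks use ~10⁴ simulated intervals (closed-form
  MLE oracle, 5% tolerance);
* the imaging round-trip uses a 100-nucleus, 200-frame, 300×300 px movie:
  noiseless for per-frame trajectory recovery (≤1% of the intensity scale),
  generator-default noise for segmentation recall (IoU ≥ 0.7) and lineage
  accuracy;
* the frequency/amplitude dissociation (halving `k_on` vs halving `r_load`,
  300 nuclei per condition) runs in a burst-resolvable regime — `k_on` =
  0.06/min, `k_off` = 0.4/min, `r_load` = 40/min, dwell = 2 min, 400 frames —
  where mean OFF time (~17 min) far exceeds the ON + dwell envelope, so
  called events track the switching process; in dense WT-like regimes
  (OFF gaps comparable to the signal envelope) merging makes called
  frequency sublinear in `k_on`, which is a property of threshold-based
  calling itself, not an implementation artifact. Within one experiment set
  (the `k_on` pair, identical intensity scale) a single threshold is used;
  the halved-`r_load` condition is its own set with its own threshold.
* called OFF durations are KS-tested on ~150–200 gaps: calls are quantized
  to the 16.8-s frame grid and short gaps are censored by merging, and these
  known artifacts must stay below the KS detection limit for the test to
  probe the exponential shape rather than the grid;
* periodicity uses 400 nuclei of period-20 square-wave bursting against the
  shuffled null.

# Known limitations

* Single-allele assumption: one dot per nucleus; sister-chromatid or
  two-allele resolution is out of scope.
* 2D Gaussian fits at one z-plane; no 3D PSF model.
* The threshold-based burst caller merges events whose gaps are shorter
  than the signal decay envelope (dwell-limited resolution) — inherent to
  this class of method; HMM/change-point inference is deliberately not
  implemented.
* Method-2's threshold scoring function is a documented package choice;
  alternatives plug in at one site.
* The generator's absolute kinetic presets are illustrative; only their
  ordinal structure is meaningful.
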