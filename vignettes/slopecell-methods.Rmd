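---
title: "Place-cell analysis on a tiltable linear track: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-cell analysis on a tiltable linear track: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`slopecell` re-implements, as a tested pipeline, the analysis of dorsal-CA1
place-cell activity recorded while rats shuttle on a linear track that can
be tilted from flat (0°) to 15° and 25°. The scientific questions the
pipeline serves are (i) whether standard place-cell metrics degrade on
sloped terrain, (ii) how cells remap when only the tilt of an otherwise
unchanged environment is manipulated, and (iii) whether theta-timescale
temporal coding (phase precession) changes with slope. The recordings
behind the original study are not publicly deposited, so the package pairs
the analysis stages with a ground-truthed synthetic session generator;
every stage is validated against planted parameters, closed-form oracles,
or the published contingency tables.

## Geometry, trials and inclusion rules

The apparatus is a 120 × 24 cm shuttle box. The two reward endzones occupy
8.5 cm at each end; the 103 cm between their boundaries is the running
region of interest (ROI), and all spatial analysis is restricted to it.
Coordinates are centimetres with the origin at the ground-level (pivot)
corner; "north" is x = 120 and "south" x = 0.

A *trial* is one end-to-end run: from the first position sample beyond an
endzone boundary to the first sample beyond the opposite boundary
(half-open in time). Excursions that return to their origin endzone are
excluded as incomplete; trials slower than the 7 s criterion
(mean speed below about 15 cm/s over the 103 cm ROI) are excluded as slow.
Mean trial speed is defined as ROI length over duration — consistent with
the equivalence of the 7 s and 15 cm/s thresholds — rather than as an
integrated path length. Slope direction is assigned from the departure
end: trials leaving the ground-level end run uphill. For flat blocks the
same geometric convention is applied using the block's recorded elevated
end, so "uphill" on the flat denotes the equivalent running direction.
Whether the speed filter runs before or after direction labelling does
not change any output; the package labels first and filters second.

## Rate maps, fields, and the metric battery

Maps live on a 2.5 cm square grid anchored at the ROI origin with
half-open bins. Because 103/2.5 = 41.2 and 24/2.5 = 9.6, the grid is
41 × 9 bins with the residual sliver folded into the last bin of each
axis. Occupancy accumulates each position sample's forward inter-sample
interval (capped at five times the median, to survive tracking gaps) into
the bin the sample falls in; bins under 100 ms of dwell are removed from
all further computation. Rate maps are elementwise spike counts over
dwell. Spikes that land in removed bins are excluded from the map but
still count toward the 100-spike criterion.

Field detection runs on a smoothed copy of the map: a Gaussian kernel
with σ of one bin (2.5 cm), truncated at 3σ, with unvisited bins excluded
from the kernel and the remaining mass renormalised (zero-filling would
deflate rates along the track edges; the cost is that smoothing is not
exactly mass-preserving in edge bins). Bins at or above 15% of the
smoothed-map peak that have at least seven of their eight neighbours also
above threshold survive; 8-connected components of survivors are fields,
measured by bin count and bounding-box length/width, with the largest
component the main field. Edge bins have at most five neighbours and so
can never survive the neighbour rule themselves — an accepted consequence
of reading "seven neighbouring bins" literally on an 8-neighbourhood.

The metric battery is computed on the *unsmoothed* map: Skaggs spatial
information `I = Σ p_i (λ_i/λ) log2(λ_i/λ)` (terms with zero rate
contribute zero, the x·log x limit), sparsity
`S = (Σ p_i λ_i)² / Σ p_i λ_i²`, and spatial coherence — the Pearson
correlation across visited bins between each bin's rate and the mean of
its visited 8-neighbours, Fisher z-transformed. The place-cell criterion
applies the coherence threshold 0.5 to the z value: reported coherences
in this paradigm exceed 1, which is impossible for a raw correlation, so
the z scale is the only consistent reading. A unit counts as a place cell
in a condition when it fired ≥ 100 in-ROI spikes there, kept a mean rate
of ≥ 0.1 Hz (in-ROI spikes over included-trial time; the endzone-count
alternative is not used because the analysis is ROI-restricted
throughout), conveyed ≥ 1 bit/spike, and had coherence z > 0.5.

## Remapping classification

Remapping is assessed per cell for each ordered tilt pair within a slope
direction (0→15, 0→25, 15→25). Cells active (by the criteria above) in
neither condition are *inactive*; in only the steeper, *turn on*; in only
the shallower, *turn off*. For cells active in both, the peaks of the 1D
place-field maps (field-masked smoothed maps averaged across the short
axis) are compared: separation ≥ 20 cm — the boundary value included — is
a *field remap*; otherwise a two-sided Wilcoxon rank-sum test on per-trial
firing rates decides *rate remap* (p < 0.05) against *stable*. The calls
are mutually exclusive and exhaustive by construction.

Spatial correlations between conditions use the bins occupied in all
three tilts of a direction; a pair is only evaluated when at least three
common bins have non-zero rate in both maps (the stricter reading of
"common-occupied bins with non-zero firing rates", guarding against
spurious two-point correlations). The shuffle null permutes the bin
locations of the steeper condition's map over the common bins 10,000
times — permuting one map is distributionally equivalent to permuting
both and twice as fast — and reports the mean null correlation; all
shuffles consume an explicit seed recorded in the output.

The elevation-half analysis splits the ROI at its midpoint (51.5 cm) into
the half nearer the elevated end ("top") and the pivot half ("bottom"),
assigns 0°-active cells by their 1D place-field peak (an exact-midpoint
tie goes to bottom — a measure-zero, deterministic rule), and tabulates
remap calls of the 0→15 and 0→25 pairs by half. The split-half control
re-classifies cells between the first and second ten included trials of a
block (within) and across consecutive block boundaries (between),
distinguishing tilt-driven remapping from drift over time.

Contingency statistics are Pearson chi-squared without continuity
correction — validated by exact agreement with the published statistics
(1.635, 2.89, 23.5, 16.6, 6.81) on the published tables, which the
package carries as `reference_remap_counts()`. The within/between test
excludes the inactive category, the only choice consistent with its
published four degrees of freedom. The published per-tilt active counts
(78/70/74) do not reproduce their quoted X²(2) = 0.27 under any
goodness-of-fit reading (the oracle gives 0.43); the underlying table is
not printed, and that statistic is deliberately not recomputed.

## Phase precession

The LFP is band-pass filtered at 7–9 Hz with a 4th-order Butterworth
applied forward–backward (zero phase distortion in the passband; only the
band itself is prescribed, the filter family is the package's choice),
and the analytic signal provides instantaneous phase and amplitude
envelope. Phase is re-referenced so 0° falls at the trough of the
filtered signal.

The precession field is detected on a coarse 4 × 20 grid over the ROI
(bins ≈ 6 × 5.15 cm; reward areas excluded by construction): bins firing
above the map mean over visited coarse bins — "above average" is read as
the map mean; the unit-mean alternative is nearly identical on these
data — with at least two qualifying neighbours are clustered, and the
largest cluster is analysed. Only uphill travel (and the equivalent flat
direction) is used. Spikes inside the field during included trials are
kept when the envelope at spike time exceeds its mean over the analysed
condition's in-ROI samples (the averaging window is otherwise
unspecified; the condition-restricted mean matches the rest of the
pipeline's conditioning); cells with fewer than 50 qualifying spikes are
skipped. Each spike is mapped to its normalised position in the field —
0 at the entry edge per the running direction, 1 at the exit — so that
the slope bound of two theta cycles is expressed per field traverse.

The circular–linear fit maximises the mean resultant length
`R(a) = |n⁻¹ Σ exp(i(φ_j − a·x_j))|` over a 1°-per-traverse grid on
[−720°, 720°] with local refinement; the grid is verified against dense
brute-force maximisation. The phase offset is the circular mean of
`φ_j − a·x_j` (the phase at field entry). The correlation is the
circular–circular correlation between measured phases and fitted
positions-on-the-circle, with the asymptotic normal p-value. Estimates at
the bound are clipped to ±720° and flagged rather than rejected — the
flag preserves the information that the bound was active. Because the
slope is selected to maximise the resultant before the correlation is
computed, the p-value is mildly anticonservative on unstructured data
(measured false-positive rate ≈ 14% at n = 200 rather than 5%); this is
inherent to the procedure, not a defect of the implementation. Rayleigh
(uniformity) and Watson–Williams (equality of circular means, with the
standard concentration correction and a warning when the pooled resultant
falls below 0.45) tests accompany the fits; group comparisons of offsets
use Watson–Williams, which is the appropriate test for that question.

## The synthetic session generator

The generator emulates the study conditions and is the source of every
test fixture. Its defaults are fixed study parameters, not tuning knobs:
three blocks (0°, 15°, 25°, north end elevated), 20 laps per block,
per-tilt and per-direction mean speeds set to the published group means
(32.7/33.4 uphill/downhill on the flat, 33.4/31.5 at 15°, 30.0/26.6 at
25°), 8 Hz theta. Values the study does not state were chosen once for
realism: 50 Hz position sampling (a typical camera rate), 3 s endzone
dwells (irrelevant to ROI-restricted analysis), a mean-reverting lateral
wander with 2.5 cm stationary SD (paths several bins wide, as the
published occupancy counts imply), 250 Hz LFP sampling, and per-run speed
jitter of 5%.

Trajectories are piecewise constant-velocity runs with raised-cosine
acceleration confined to the endzones, so trial mean speed equals the
drawn cruise speed. Spike trains are inhomogeneous Poisson via thinning:
rate = baseline + a Gaussian spatial tuning curve (centre, σ, peak),
gated by slope-direction preference, multiplied inside the field by a von
Mises factor concentrated on the programmed precession line
`φ(x) = φ0 + s·x_norm` (normalised so its phase average is one, keeping
the spatial profile Poisson-thinnable). With zero phase noise
(`kappa = Inf`) spikes are instead placed exactly at the crossings of the
theta phase with the programmed line, thinned by the spatial envelope, so
phases sit exactly on the line — at most one spike per theta cycle, a
deliberate property of that mode. The LFP is a theta-frequency sinusoid
(trough at phase zero) plus white noise.

Default ensemble tuning follows the published metric battery rather than
minimal thresholds: peak rates uniform on 15–35 Hz, 1 Hz baseline — the
battery's peak (~33 Hz), mean (~3.5 Hz) and out-field (~1.1 Hz) rates are
only jointly consistent with that regime. A deliberately marginal cell
(10:1 peak:baseline with σ = 6 cm on this track) carries almost exactly
1 bit/spike, i.e. it sits *on* the information criterion; tests of the
criteria therefore use a battery-matched cell, while field-localisation
tests keep the marginal 10:1 cell, whose detection does not depend on the
flag. Programmed remapping transforms the 0° tuning per tilt: rate
scaling, centre shifts, silencing (turn off; the baseline is retained),
or activation only on tilt (turn on). The generator returns the session
together with its ground truth (per-tilt tuning and the implied remap
call for every ordered pair).

What the generator does **not** emulate: broadband LFP structure beyond a
noisy sinusoid (the filtering stage is exercised, but not challenged by
1/f backgrounds or harmonics), tracking dropouts, gait or speed-coupled
theta-frequency changes, inter-neuron correlations, and within-block
nonstationarity. Passing tests therefore demonstrate correctness of the
analysis on data that satisfy the model's assumptions, not robustness of
the science to every property of real recordings.

## Numerical choices and degenerate inputs

Bins are half-open; the exact ROI midpoint belongs to the bottom half;
the 20 cm field-remap boundary triggers the remap; filters are truncated
at 3σ; the Wilcoxon test is exact below 21 combined observations without
ties and a tie-corrected normal approximation otherwise; chi-squared
tests raise errors naming any all-zero margin; a constant map has
undefined coherence (reported not-computable, failing the criterion); a
zero-rate map has undefined information and sparsity; an all-excluded
condition is reported unanalyzable rather than erroring. All stochastic
stages take explicit seeds and identical seeds reproduce byte-identical
outputs.

## Problem sizes

The test and acceptance runs use the study-sized sessions (20 laps per
condition, three blocks) with ensembles of 1–30 units; recovery rates are
estimated over 10–50 seeded replicates per claim, sizes chosen to make
the binomial uncertainty on each rate small relative to its margin.

## Known limitations

Field length/width are bounding-box extents (no better definition is
prescribed); the coarse-grid field's entry edge quantises the precession
offset at the single-cell level (ensemble comparisons are the supported
use); the information criterion is structurally marginal for low-SNR
cells; and the chi-squared tests on small expected counts inherit the
usual asymptotic caveats (the published statistics are reproduced
exactly, which is the point of carrying them).
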