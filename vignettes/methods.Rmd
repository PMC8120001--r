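---
title: "Methods: models, parameters and validation in lesionscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation in lesionscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionscope)
```

`lesionscope` measures how neutrophils and macrophages behave around skin
lesions (wounds, pre-neoplastic clones) in calibrated 2-D time-lapse
movies. This vignette records the models the package implements, the
assumptions behind them, the defaults and why they were chosen, and what
the synthetic validation does — and does not — establish. It states no
empirical result that the test suite does not itself compute.

## Coordinate and calibration conventions

Pixels are 0-based, origin top-left, y downward; physical coordinates are
`index × pixel_size` (µm), times are `frame × frame_interval` (minutes).
Calibration is always user-supplied configuration: confocal export metadata
is unreliable, so a metadata mismatch only warns. The pixel size of the
original 20× acquisitions is not published, which is why calibration is a
mandatory input rather than a default; the simulator uses 1 µm/px as a
round, realistic value for a 20× air/glycerol objective. Z-stacks are
reduced by maximum-intensity projection before analysis — the workflow is
2-D by design.

## Detection

**Neutrophils (cytoplasmic signal).** Optional Gaussian pre-smoothing, one
global threshold (a fixed, empirically derived intensity, or Otsu's method
as the automatic default), 8-connected component labelling, then an
inclusive area filter. 8-connectivity matches common Fiji blob-labelling
behaviour and is fixed so tests can be exact. Defaults: 30–800 µm² for
neutrophils — generous bounds around the tens-of-µm² scale of larval
neutrophil cross-sections; the original analysis used empirical values it
did not print, so these are engineering defaults, configurable per run.

**Macrophages (nuclear signal).** The macrophage cytoplasmic margin is too
poorly defined to threshold, so the nuclear reporter is segmented instead
via trainable pixel classification: a logistic model over a feature bank of
raw intensity plus Gaussian smoothing, gradient magnitude and Laplacian at
scales σ = 1 and 2 px (two scales, sized to ~4 µm nuclei at 1 µm/px). The
probability map is binarised at a fixed probability (default 0.5) and
labelled as above (default filter 10–300 µm²). Training is deterministic
given the seed (used only to subsample oversized label sets). The classifier
family is a package choice — the contract only requires a deterministic
probabilistic pixel classifier over this feature bank.

A practical lesson encoded in `sample_training_labels()`: background labels
drawn uniformly almost never hit the one-pixel halo around nuclei, where
smoothed features still look object-like; a classifier trained that way
dilates every object by roughly its smoothing radius. The helper therefore
stratifies half of the background labels into a 3-px ring around the
foreground, which is exactly what experienced users of trainable
segmentation tools do by hand (label the borders).

**Manual corrections.** Touching or overlaying cells are not split
automatically (no watershed); they are handled by directives — delete,
merge (union must stay 8-connected), split along a polyline (cut pixels are
reassigned to the nearest resulting part), add a polygon. Object ids are
reassigned deterministically (raster order of each object's
topmost-leftmost pixel) after all directives.

## Tracking

Per consecutive frame pair the package solves a minimum-cost one-to-one
assignment on centroid Euclidean distance, with links above
`max_link_distance_um` (default 30 µm) forbidden; the padded square LAP
formulation first maximises the number of feasible links, then minimises
their summed distance. Track ends are then joined across gaps of up to
`max_gap_frames` (default 2) missing frames, cheapest candidate first,
under the same distance rule. This is frame-to-frame LAP linking in the
TrackMate tradition; merging and splitting are deliberately excluded
because segmented immune cells are tracked as indivisible objects.

Metrics per track (≥ 2 detections): path length = Σ consecutive centroid
distances, with gap segments contributing their straight-line distance; net
displacement = ‖last − first‖; duration = (last − first frame) ×
frame interval; **mean speed** = path length / duration — one consistent
estimator rather than a mean of instantaneous speeds across gaps; and
**directionality ratio** = net displacement / path length, the standard
migration-analysis definition (1 = perfectly straight, undefined for a
zero-length path). A lesion-directed chemotaxis index would be a different
statistic; the standard ratio was chosen because the source workflow names
"directionality ratio" without further definition.

## Lesion geometry and distances

Lesion outlines are manual, time-keyed polygons. Frame *f* uses the latest
keyframe at or before *f* (hold-last): outlines are *replaced* when
redrawn, not morphed, because iterated manual annotation replaces shapes —
interpolation would invent geometry nobody drew. Polygons are rasterised by
the pixel-centre-inside rule (even-odd, half-open on edges), which makes an
axis-aligned n×n square exactly n² pixels and every test exact.

The signed Euclidean distance field gives each pixel its distance (µm) to
the nearest *boundary pixel* of the mask — positive outside, negative
strictly inside, zero on the boundary (boundary = mask pixel with a
4-neighbour outside). Distances are measured between pixel centres with no
half-pixel offsets; contact semantics live downstream. The transform is the
exact two-pass lower-envelope algorithm, verified against an all-pairs
brute force to 1e-9 µm. Note one subtlety: the *unsigned* field is
1-Lipschitz (8-adjacent values differ by ≤ √2 px), but the *signed* field
obeys that bound only under 4-adjacency — an interior pixel can touch an
exterior pixel diagonally, flipping sign without passing through zero.

Multiple lesions are independent interaction targets; overlapping clones
are not merged, since each clone is analysed as an independently acting
lesion.

## Interaction events

Per (track, lesion, frame-with-detection): distance = max(0, min over the
detection's boundary pixels of the signed field), with an overlap flag when
the raw minimum is ≤ 0. The measured surface is the cytoplasmic margin for
neutrophils and the nuclear margin for macrophages.

An **event** is a maximal run of consecutive frames with distance strictly
below the lineage threshold: neutrophil < 20 µm, macrophage < 50 µm
(nuclear margin; the extra 30 µm reflects the average macrophage radius,
so nuclear proximity approximates cytoplasmic proximity). The strict `<`
follows the "<20 µm or <50 µm" classification notation, reading "20 µm as
a maximum" as an exclusive bound. Runs are broken by frames at/above the
threshold and by track gaps (no interpolation across gaps). A run
containing any overlap frame is classed `contact` — contact is surface
overlap/touch, not a small-µm band, since "direct contact" is never defined
numerically — and contact dominates the run rather than splitting it, so
one sustained encounter counts as one interaction. Duration of an n-frame
run is **n × frame_interval**: each sampled frame represents one sampling
interval, so a single qualifying frame at 2 min/frame is a 2-min event
(the alternative (n−1) convention would assign it zero duration, which
contradicts counting it as an interaction).

A mathematical caveat the tests document: the total event *duration* and
the number of interacting track–lesion pairs are non-decreasing in the
threshold, but the event *count* is not a monotone function of the
threshold in general — raising it can merge two events separated by a
near-threshold excursion (distances [5, 25, 5] µm: threshold 10 → two
events; threshold 30 → one). On approach-shaped profiles, such as the
simulator's biased walks, counts do increase monotonically.

The field-of-view count (e.g. the 660 µm × 310 µm counting region) uses a
half-open rectangle on centroids, so an object sliding across the boundary
is counted exactly once at any instant.

## Statistics

Cell-level values are averaged per fish before testing (fish are the
independent units; the per-cell cloud is still reported). Normality
routing: D'Agostino–Pearson omnibus for n ≥ 8 (its minimum reliable n),
Shapiro–Wilk below; the parametric route requires *all* groups to pass at
α = 0.05 — a conservative reading of "when the data was normally
distributed", which names both tests without saying when each applied.
Two groups → Student's unpaired two-tailed t-test or Mann–Whitney; more →
one-way ANOVA + Tukey or Kruskal–Wallis + Dunn. Dunn's z statistics use
pooled tied ranks and Bonferroni adjustment over the k(k−1)/2 pairs (the
adjustment inside Dunn's is unstated in the source; Bonferroni is the
common, conservative choice). Fisher's exact test (two-tailed) handles 2×2
tables. Identical constant groups are flagged degenerate and produce no
p-value. Significance labels: `n.s.` (p > 0.05), `*` < 0.05, `**` < 0.01,
`***` < 0.001, `****` < 0.0001. The routed two-group procedure holds its
type-I error ≤ 0.07 at nominal 0.05 under null-normal simulation (n = 10
per group, 2,000 replicates) — verified in the acceptance suite, not
assumed.

## The synthetic world

The simulator emulates the stated acquisition conditions: 2 min/frame,
1.5–2 h (default 60 frames), 512×512 px at 1 µm/px, bright cytoplasmic
neutrophil discs (radius 7–9 µm) and small macrophage nuclei (3–5 µm;
macrophage cytoplasm deliberately unrendered), one lesion polygon
(optionally deforming), background 20 / foreground 200 with Gaussian noise
SD 18 (SNR ≈ 10). Motion is a persistent random walk: fixed step length
`speed × frame_interval`, direction ∝ `persistence · previous + bias ·
(unit vector to lesion centroid) + (1−persistence)(1−bias) · random`,
reflective boundaries. Motility defaults (5 µm/min, persistence 0.6, bias
0.3) are *testing placeholders*, not biological claims — the source
workflow publishes no motility parameters.

Two generator choices deserve their reasoning on record:

* **Sharp discs, not anti-aliased.** With anti-aliased edges, rim pixels sit
  at ~50% coverage — exactly at the binarisation threshold — and imaging
  noise flips them with probability ≈ 0.5 per frame, making exact
  ground-truth recovery impossible *by construction*. Rendering by the
  pixel-centre rule gives every pixel a 5σ intensity margin at default SNR,
  so the rendered support of a cell equals its analytic raster disc with
  overwhelming probability. Anti-aliasing is available off the default
  path but is incompatible with bit-exact validation.
* **Minimum separation 12 µm between same-lineage cells.** The validation
  world is "non-overlapping cells", which for an automated pipeline means
  two things: *resolvable* — surface gaps larger than the classifier's
  feature support (~6 px), otherwise probability maps bridge and objects
  merge — and *trackable* — centre spacing above the per-frame displacement
  (10 µm at default speed), otherwise identity is genuinely ambiguous and
  any optimal linker may swap labels. Cells closer than this are exactly
  the touching/overlaying cases the real workflow routes to manual
  correction. Steps violating the separation are resampled, then refused
  (the cell waits a frame).

**Ground truth.** True tracks are the analytic centroid paths; true events
are computed from the *rasterised* true discs against the annotated
lesion's distance field — noiseless analytic geometry pushed through the
same raster surface metric and the same run/threshold rules as the
measurement stage, but with no rendering, noise, segmentation or linking
involved. The raster metric (rather than continuous centre-minus-radius
distance) is deliberate: any pixel-based measurement differs from the
continuous distance by up to ~1 px, so demanding exact event agreement
forces a single well-defined surface metric; that metric is itself
validated against brute-force oracles.

**What a green end-to-end test establishes** — that segmentation,
tracking, distance measurement and event extraction are internally exact
on resolvable, trackable cells at SNR ≈ 10. **What it does not** — realism
of cell morphology (discs, constant radius), photobleaching, drift,
z-motion, division, swarming, uneven illumination, or segmentation
performance on marginal SNR; and it says nothing about the biological
parameter values themselves.

## Numerical and degenerate-input choices

Blank frames segment to empty lists (not errors); an empty lesion mask or
an annotation starting after the first analysed frame is an error. Area
filters are inclusive on both ends. Assignment ties are broken by the
solver's deterministic order; gap-closing candidates by (distance, lower
track id). Tracks with < 2 detections carry no metrics; zero-length paths
have undefined directionality (NA, flagged). The whole pipeline is
bit-reproducible given config + seed; the simulator restores the caller's
RNG state.

## Known limitations

No 3-D analysis, no automatic lesion segmentation, no merge/split
tracking, no deep-learning detection, no multiple-testing control across
measurement families, and no modelling of swarming dynamics. The TIFF
codec intentionally covers the uncompressed grayscale subset used by
ImageJ/Fiji and tifffile defaults; compressed or tiled files are rejected
with a clear message rather than half-read.
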