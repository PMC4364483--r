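---
title: "Methods: binned colocalization profiles, AMI/BMI and the permutation null"
author: "regioncoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned colocalization profiles, AMI/BMI and the permutation null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regioncoloc)
```

## The model

`regioncoloc` measures the spatial association between a user's regions
of interest (ROIs) and a reference feature track, both given as BED3
intervals (0-based, half-open). The unit of analysis is a window of `w`
bp (default `w = 20000`) around each ROI center, divided into 100 bins
of `w/100` bp. All coordinates are binned against genome-anchored bins
(bin `i` of a chromosome covers `[i*b, (i+1)*b)` with `b = w/100`), so a
window is *snapped*: output bin `i` is genome bin
`floor((center - w/2)/b) + i`. Snapping keeps every lookup O(1) against
a per-chromosome occupancy array and costs at most one bin of positional
blur, which is why downstream checks are stated to ±1 bin.

Counting is per feature and binary per bin: a feature overlapping `k`
bins increments each of those `k` bins by 1, whether the overlap is
partial or complete, and co-occurring features accumulate. The ROI
center is `floor((start + end)/2)`; window bins before position 0, past
the end of the indexed chromosome, or on an unknown chromosome
contribute 0.

The **density matrix** stacks these window lookups: ROIs are sorted by
(chromosome, start, end) and partitioned into 100 consecutive rank
blocks (row `r`, 0-based, takes ranks `[floor(r*n/100),
floor((r+1)*n/100))`), and each ROI's 100 window counts are added into
its row. Genomic-order rows make the image reproducible run to run. The
**colocation histogram** is the vector of column sums `v_b`, normalized
twice:

$$v_b^{norm} = v_b \cdot \frac{10{,}000}{n_{ROI}} \cdot
  \frac{10{,}000}{n_{bins}^{feat}}$$

where `n_bins^feat` is the number of distinct genome bins the indexed
track occupies at the current bin size (each bin counted once regardless
of multiplicity). Per-10,000-ROI scaling removes dependence on the size
of the submitted set; per-10,000-feature-bin scaling removes dependence
on the abundance and width of the feature, which is what makes AMIs
comparable across features and samples. All downstream statistics are
computed on the normalized histogram; since both factors are fixed
positive scalars this changes none of the threshold memberships, and the
permutation p-value is provably identical either way (a property the
test suite asserts).

## Background model and integral statistics

The background level is the mean of the 51 bins furthest from the
center (1-based bins 1–25 and 75–100):

$$L_b = \frac{1}{|S_b|}\sum_{v_b \in S_b} v_b, \qquad
  S_b = \{v_b : b \le 25 \ \text{or}\ b \ge 75\}.$$

The asymmetric 25 + 26 edge set follows the defining inequalities as
printed; the one-bin asymmetry moves `L_b` by well under the noise scale
on any histogram we generate.

The variance proxy `V` is the 75th-percentile *oscillation distance*:
take the 99 absolute consecutive differences `|v[i+1] - v[i]|`, sort
ascending, and take the nearest-rank 75th percentile (rank
`ceiling(0.75 * 99) = 75`). Nearest-rank (not interpolated) keeps `V` an
actually observed oscillation and is the simplest reading of a
percentile over an ordered list of traversal distances. `V` is a robust
noise scale: a single sharp colocalization peak contributes only a
handful of large differences, which land above rank 75 and leave `V`
untouched, while `V` tracks the bin-to-bin jitter of the background.
Adding a constant to every bin shifts `L_b` but leaves `V` unchanged
(asserted as a property test).

Thresholds and statistics:

$$L_h = L_b + V, \qquad L_l = \max(L_b - V,\ 0)$$
$$H = \max\{v_b > L_h\},\quad AMI = \sum\{v_b : v_b > L_h\},\quad
  BMI = \sum\{v_b : v_b < L_l\}$$

with empty sets giving 0. Two deliberate choices here:

* **The lower threshold.** The symmetric form `L_l = L_b − V` (clamped
  at 0) is the default. An alternative form `L_l = V − L_b` is exposed
  via `estimate_background(..., lower_literal = TRUE)`; it is negative
  whenever the background exceeds its own noise scale — the common case —
  which empties `S_l` and makes BMI identically zero, defeating the
  purpose of an anti-colocalization score and contradicting the idea of
  a lower variance line under the background. The symmetric counterpart
  of `L_h` is the form consistent with that purpose, so it is the
  default; the alternative is kept only for comparability.
* **Integrals sum full bin values**, not the excess over the threshold.
  This follows the set-builder definitions above. A consequence worth
  knowing: BMI rewards bins that are *low but nonzero*. A trough
  depleted all the way to zero contributes nothing to a sum of values,
  so BMI is largest for partial depletion and blind to complete
  exclusion (the `anticolocated` fixture tests are designed in that
  partial-depletion regime). H and AMI have no analogous pathology
  because large values are their own evidence.

## The permutation p-value

The null hypothesis is that the feature has no positional preference
within the window. The observed histogram total `T = Σ raw v_b` is
redistributed by giving each of the `T` feature-bin units an independent
uniform bin — a `Multinomial(T, 1/100)` draw — after which the
randomized histogram is normalized with the same constants, its
background re-estimated, and its AMI recomputed. The p-value is the
fraction of `n_perms` randomizations (default 1,000) with
`AMI ≥ AMI_observed`; ties count against significance, and a degenerate
`T = 0` histogram returns p = 1 with a warning. The plain fraction is
reported by default; `correct = TRUE` gives the `(r+1)/(n+1)`
small-sample variant for users who want a never-zero estimate.

Re-estimating the background inside every permutation matters: both the
threshold `L_h` and the exceedance set are random under the null, and
freezing the observed background would understate the null AMI.

**Assumptions.** Unit-level redistribution treats the `T` feature-bin
units as exchangeable and independent. That is exact for features no
wider than one bin (each feature contributes one unit at one position)
and approximate for wider features, which occupy adjacent bins jointly:
the observed histogram then has positive short-range autocorrelation
that the null does not model, and the p-value becomes anti-conservative
roughly in proportion to the fraction of features spanning bin
boundaries. With the default 200 bp bins this is negligible for summit
tracks and modest for peak-width features; for feature tracks much wider
than a bin (e.g. broad domains), p-values should be read as enrichment
rankings rather than calibrated probabilities. The same reasoning drove
the synthetic generator's default of point features (below).

## Input contract

ROI files are filtered before analysis: regions wider than `w/4` are
discarded (at `w` = 20 kb: 5,000 bp) — wider regions would smear their
own span across the profile; at least 1,000 valid regions must remain or
the run aborts; and at most 200,000 are analyzed, a seeded uniform
subsample being taken above that. Malformed BED lines (non-integer
coordinates, `end ≤ start`, missing fields) are rejected individually
and counted in a warning rather than aborting the file. In
feature-centered mode these filters still apply to the *user's* file
only; the centered track is used whole, with a warning when its mean
width exceeds `w/4`.

## Feature-centered mode and determinism

Feature-centered analysis swaps the roles of the (already filtered) ROI
set and the feature track: the matrix is centered on features, the ROIs
are indexed, and the normalization uses the occupied bins of the indexed
track. Aside from the swap, processing is identical, so a
feature-centered run of (X, Y) and an ROI-centered run of (Y, X) agree
*exactly* whenever Y passes the ROI filters unchanged — including the
p-value, because each track pair's permutation stream is seeded from the
run seed plus a hash of the *unordered* label pair. Seeding per pair
(rather than per run position) also means adding or reordering feature
tracks never changes any single track's results.

All randomness — ROI subsampling, fixture generation, permutations —
derives from explicit integer seeds, and identical inputs plus an
identical seed reproduce byte-identical output files (numeric columns
are serialized at fixed precision).

## The synthetic fixture generator

`fixture_spec()`/`generate_pair()` produce seeded ROI/feature BED pairs
on a synthetic genome of five 10 Mb chromosomes — small enough that the
full test suite runs in seconds, large enough that 20 kb windows rarely
collide. ROIs (default 1,000 × 200 bp, a typical peak width) are placed
uniformly, keeping a 20 kb margin from chromosome ends so windows stay
on-chromosome. Features follow the requested geometry: `centered` at
ROI centers, `offset` displaced by a signed constant, `bifurcated` half
at −offset and half at +offset (flanking accumulation with central
exclusion), `anticolocated` uniform outside an exclusion radius around
every ROI center, `null` uniform and independent; Normal jitter
(default SD 100 bp, half a bin, truncated to the chromosome) and a
uniform background fraction (`colocated_fraction`) overlay realistic
noise. Colocated features are assigned to host ROIs in balanced
round-robin fashion so a fully colocated fixture covers every ROI.

Features default to 1 bp point intervals — the summit convention of
peak callers — because sub-bin features are the regime in which the
permutation null is exact (see above); the measured false-positive rate
at p ≤ 0.05 across 200 null fixtures is then statistically
indistinguishable from 0.05. What the generator does **not** emulate:
wide/broad features (and hence the anti-conservativeness they induce),
chromosome-scale density gradients, clustered or mappability-biased
backgrounds, and inter-feature spacing constraints of real annotation
tracks. Passing fixture tests therefore demonstrates correctness of the
machinery and calibration under the stated null, not calibration on
arbitrary real tracks.

## Problem sizes and numerical choices in the test suite

The suite exercises: window lookups and density matrices against
brute-force interval-overlap oracles (500+ random cases at a 2 kb
window); conservation of histogram mass and exact linearity of the
normalization; hand-computed background/AMI/BMI examples evaluated
symbolically (e.g. `L_b = 154/51`); recovery of an imposed +2,000 bp
offset at histogram bin 60 ± 1 and of ±1,000 bp bifurcation at bins
45/55 ± 1 across 50 replicates each; p-value calibration on 200 null
fixtures of 1,000 ROIs × 1,000 features at 200 permutations; the ROI
filter contract including a 250,000 → 200,000 subsample; and exact
feature-centered/ROI-centered inversion symmetry. These sizes keep the
whole suite under a minute on one CPU while leaving each check's
sampling error far below its assertion margin.

## Known limitations

* AMI has no analytic null; inference is purely permutation-based, and
  its calibration degrades for features much wider than a bin.
* BMI cannot see complete exclusion (sum-of-values definition, above).
* No multiple-testing correction is applied across feature tracks;
  users screening large libraries should adjust the p-values
  themselves (e.g. `p.adjust`).
* Windows extending past chromosome ends read zeros rather than being
  clipped; ROIs within half a window of an end are slightly diluted.
* The quarter-window width filter uses `end − start`; strand and all
  BED columns beyond the third are ignored.
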