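# regioncoloc

Colocalization analysis of genomic region sets.

`regioncoloc` answers a question bench biologists ask of every new
ChIP-seq experiment: *which known genomic features pile up around my
regions, how strongly, and is it more than chance?* Given a BED file of
regions of interest (ROIs — typically peaks from a peak caller) and one
or more feature tracks (transcription-factor binding sites, histone
marks, CpG islands, replication origins, ...), it profiles each feature
in a fixed window around the ROI centers and reports graphical and
numerical measures of colocalization that are directly comparable across
features and samples.

## Method

For a window of `w` bp (default 20,000) split into 100 bins of `w/100`
bp, each chromosome of a feature track is loaded into a binned occupancy
array for O(1) lookups. The analysis then builds:

* **Density matrix** — a 100 × 100 grid: rows are consecutive blocks of
  1/100th of the ROIs (in genomic order), columns are positions relative
  to the ROI center; each ROI adds the feature counts of the 100 bins
  around its center into its row. Rendered as a grayscale image (dark =
  dense).
* **Colocation histogram** — the column sums `v_b`, doubly normalized to
  totals *per 10,000 ROIs* and *per 10,000 feature bins* (the number of
  genome bins the feature occupies), so histograms are comparable across
  features and samples.
* **Background model** — the background level is estimated from the 51
  bins furthest from the center, `L_b = mean(v_b : b ≤ 25 or b ≥ 75)`,
  and the noise scale `V` as the 75th-percentile (nearest-rank) of the 99
  absolute consecutive bin differences. Thresholds: `L_h = L_b + V`,
  `L_l = max(L_b − V, 0)`.
* **Statistics** — peak height `H = max{v_b > L_h}`; the
  **Above-Mean Integral** `AMI = Σ{v_b : v_b > L_h}` (colocalization
  strength); the **Below-Mean Integral** `BMI = Σ{v_b : v_b < L_l}`
  (anti-colocalization); the percentage of ROIs with at least one
  feature in their window; and an empirical p-value: the total histogram
  count is redistributed uniformly over the 100 bins (each unit
  independently), the AMI recomputed with a re-estimated background, and
  the p-value is the fraction of randomized histograms with
  `AMI ≥ AMI_observed`.

A feature-centered mode inverts the roles: the matrix is centered on
each feature and the ROIs are profiled around them; processing is
otherwise identical.

## Worked example

The package ships a seeded generator of synthetic ROI/feature pairs with
known geometry (see `?fixture_spec`). Here one ROI set is profiled
against a co-centered summit track, a track flanking the ROIs at
±1,000 bp, and an unrelated uniform track:

```r
library(regioncoloc)

cen <- generate_pair(fixture_spec(n_rois = 2000, n_features = 2000,
                                  pattern = "centered", seed = 101))
bif <- generate_pair(fixture_spec(n_rois = 2000, n_features = 2000,
                                  pattern = "bifurcated", offset = 1000,
                                  seed = 101))$features   # same seed -> same ROIs
nul <- generate_pair(fixture_spec(n_rois = 2000, n_features = 2000,
                                  pattern = "null", seed = 103))$features
cen$features$label <- "cofactor_summits"
bif$label <- "flanking_marks"; nul$label <- "random_track"

cfg <- coloc_config(window = 20000, n_perms = 1000, seed = 7,
                    output_dir = "demo_out")
res <- run_analysis(cen$rois, list(nul, bif, cen$features), cfg)
results_table(res)
```

```
          feature n_features occupied_bins pct_near_feature peak_height   AMI   BMI p_value
   flanking_marks       2000          1990           100.00     15879.4 55528 175.9    0.00
 cofactor_summits       2000          1991           100.00     30512.3 54420 175.8    0.00
     random_track       2000          1992            54.65       652.6  2435 602.4    0.78
```

Results are sorted by descending AMI. Both structured tracks have every
ROI near a feature, AMIs two orders of magnitude above the background
track and permutation p-values of 0 at 1,000 permutations; the unrelated
track sits at chance (about half the ROIs have some feature within
±10 kb by luck, AMI near the null scale, p = 0.78).
`write_results(res, cfg)` writes `summary.csv`, a per-feature histogram
TSV, density-matrix TSV and PNG. A shell driver with the same behavior
is installed at `inst/scripts/colocalize`:

```sh
colocalize run --roi peaks.bed --features tracks/ --window 20000 \
  --permutations 1000 --seed 17 --out results
```

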