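#' Specification for a synthetic ROI/feature fixture pair
#'
#' Describes a seeded pair of BED-style region sets with a controlled
#' spatial relationship, used to exercise every statistic of the package
#' without external data. ROIs are placed uniformly at random on a small
#' synthetic genome; features are placed relative to them according to
#' `pattern`:
#'
#' * `centered` — at the ROI center plus Normal(0, `jitter_sd`) noise;
#' * `offset` — at the ROI center plus `offset` plus jitter;
#' * `bifurcated` — half at center − `offset`, half at center + `offset`
#'   (plus jitter), emulating flanking accumulation with central
#'   exclusion;
#' * `anticolocated` — uniform, but excluding `offset` bp around every ROI
#'   center (a depleted trough);
#' * `null` — uniform and independent of the ROIs.
#'
#' Only `colocated_fraction` of the features follow the pattern; the rest
#' are uniform background. Default widths model ChIP-seq data: 200 bp ROI
#' peaks and 1 bp point features (peak summits). Point features keep each
#' feature within a single histogram bin at the default 200 bp bin size,
#' the regime in which the unit-level permutation null is exact; wider
#' features are available via `feature_width`.
#'
#' @param n_rois,n_features Region counts.
#' @param chrom_lengths Named vector of chromosome lengths (bp); default 5
#'   synthetic chromosomes of 10 Mb.
#' @param pattern One of `centered`, `offset`, `bifurcated`,
#'   `anticolocated`, `null`.
#' @param offset Signed displacement (bp) for `offset`/`bifurcated`;
#'   exclusion radius for `anticolocated`.
#' @param jitter_sd Normal jitter SD (bp) around the pattern position.
#' @param colocated_fraction Fraction of features following the pattern,
#'   in `[0, 1]`.
#' @param roi_width,feature_width Interval widths (bp).
#' @param margin Distance (bp) kept between ROI centers and chromosome
#'   ends so that a default 20 kb analysis window always lies
#'   on-chromosome.
#' @param seed Integer seed; the generated pair is fully deterministic
#'   given the spec. ROIs are drawn before any pattern-specific draw, so
#'   specs differing only in `pattern`/`offset` but sharing a seed produce
#'   identical ROI sets — convenient for profiling several feature
#'   geometries against one ROI set.
#' @return A `FixtureSpec` (classed list).
#' @export
fixture_spec <- function(n_rois = 1000L, n_features = 1000L,
                         chrom_lengths = stats::setNames(rep(1e7, 5), paste0("chr", 1:5)),
                         pattern = c("centered", "offset", "bifurcated",
                                     "anticolocated", "null"),
                         offset = 0L, jitter_sd = 100, colocated_fraction = 1,
                         roi_width = 200L, feature_width = 1L,
                         margin = 20000L, seed = 1L) {
  pattern <- match.arg(pattern)
  if (roi_width <= 0 || feature_width <= 0)
    stop_validation("widths must be positive")
  if (colocated_fraction < 0 || colocated_fraction > 1)
    stop_validation("colocated_fraction must be in [0, 1]")
  if (any(chrom_lengths <= 2 * margin + roi_width))
    stop_validation("chromosomes too small for the requested margin and widths")
  structure(list(n_rois = as.integer(n_rois),
                 n_features = as.integer(n_features),
                 chrom_lengths = chrom_lengths, pattern = pattern,
                 offset = as.integer(offset), jitter_sd = jitter_sd,
                 colocated_fraction = colocated_fraction,
                 roi_width = as.integer(roi_width),
                 feature_width = as.integer(feature_width),
                 margin = as.integer(margin), seed = as.integer(seed)),
            class = "FixtureSpec")
}

# uniform integer draw in [lo, hi], vectorized over n
runif_int <- function(n, lo, hi) {
  sample.int(hi - lo + 1L, n, replace = TRUE) + lo - 1L
}

# uniform genome positions: chromosome weighted by length, position in
# [0, len - width]
uniform_positions <- function(n, chrom_lengths, width) {
  chroms <- names(chrom_lengths)
  ci <- sample.int(length(chroms), n, replace = TRUE,
                   prob = chrom_lengths / sum(chrom_lengths))
  len <- unname(chrom_lengths[ci])
  start <- vapply(len, function(l) runif_int(1L, 0L, as.integer(l) - width), 0L)
  data.frame(chrom = chroms[ci], start = start, stringsAsFactors = FALSE)
}

#' Generate a seeded ROI/feature pair
#'
#' @param spec A `FixtureSpec`.
#' @return A list with `rois` and `features` (both `RegionSet`, labels
#'   `"rois"` and `"<pattern>_features"`) and the `spec` itself.
#' @seealso [fixture_spec()], [write_fixture_pair()]
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    chroms <- names(spec$chrom_lengths)
    # ROIs: uniform centers, kept `margin` away from chromosome ends
    ci <- sample.int(length(chroms), spec$n_rois, replace = TRUE,
                     prob = spec$chrom_lengths / sum(spec$chrom_lengths))
    lens <- as.integer(unname(spec$chrom_lengths[ci]))
    centers <- vapply(lens, function(l)
      runif_int(1L, spec$margin, l - spec$margin), 0L)
    roi_start <- centers - spec$roi_width %/% 2L
    roi_chrom <- chroms[ci]
    rois <- region_set(roi_chrom, roi_start, roi_start + spec$roi_width,
                       label = "rois", source_path = "<synthetic>")

    n_coloc <- if (spec$pattern == "null") 0L else
      as.integer(round(spec$colocated_fraction * spec$n_features))
    n_bg <- spec$n_features - n_coloc
    fw <- spec$feature_width

    feat <- NULL
    if (n_coloc > 0L) {
      if (spec$pattern %in% c("centered", "offset", "bifurcated")) {
        # balanced assignment: each ROI hosts floor or ceiling of
        # n_coloc/n_rois features, pairing randomized
        host <- sample(rep_len(seq_len(spec$n_rois), n_coloc))
        shift <- switch(spec$pattern,
          centered = rep(0L, n_coloc),
          offset = rep(spec$offset, n_coloc),
          bifurcated = {
            s <- rep(c(-spec$offset, spec$offset), length.out = n_coloc)
            sample(s)   # decouple sign from host assignment order
          })
        pos <- round(centers[host] + shift + stats::rnorm(n_coloc, 0, spec$jitter_sd))
        chr <- roi_chrom[host]
        maxs <- as.integer(spec$chrom_lengths[chr]) - fw
        start <- pmin(pmax(as.integer(pos) - fw %/% 2L, 0L), maxs)
        feat <- data.frame(chrom = chr, start = start, stringsAsFactors = FALSE)
      } else if (spec$pattern == "anticolocated") {
        # sorted ROI centers per chromosome, rejection-sample outside the
        # exclusion zones
        by_chr <- split(centers, roi_chrom)
        by_chr <- lapply(by_chr, sort)
        got <- list(); n_got <- 0L; tries <- 0L
        while (n_got < n_coloc) {
          tries <- tries + 1L
          if (tries > 1000L)
            stop_validation("cannot place anticolocated features: exclusion zones cover the genome")
          cand <- uniform_positions(2L * (n_coloc - n_got),
                                    spec$chrom_lengths, fw)
          mid <- cand$start + fw %/% 2L
          ok <- vapply(seq_len(nrow(cand)), function(i) {
            cs <- by_chr[[cand$chrom[i]]]
            if (is.null(cs)) return(TRUE)
            j <- findInterval(mid[i], cs)
            d <- Inf
            if (j >= 1L) d <- min(d, mid[i] - cs[j])
            if (j < length(cs)) d <- min(d, cs[j + 1L] - mid[i])
            d > spec$offset
          }, NA)
          keep <- cand[ok, , drop = FALSE]
          if (nrow(keep) > 0L) {
            need <- n_coloc - n_got
            got[[length(got) + 1L]] <- utils::head(keep, need)
            n_got <- n_got + min(nrow(keep), need)
          }
        }
        feat <- do.call(rbind, got)
      }
    }
    if (n_bg > 0L || spec$pattern == "null") {
      n_unif <- if (spec$pattern == "null") spec$n_features else n_bg
      bg <- uniform_positions(n_unif, spec$chrom_lengths, fw)
      feat <- rbind(feat, bg)
    }
    features <- region_set(feat$chrom, feat$start, feat$start + fw,
                           label = paste0(spec$pattern, "_features"),
                           source_path = "<synthetic>")
    list(rois = rois, features = features, spec = spec)
  })
}

#' Write a fixture pair as BED files plus a JSON sidecar
#'
#' Emits `rois.bed`, `features.bed` and `fixture_spec.json` (the full
#' generating spec, for provenance) into `dir`.
#'
#' @param pair Result of [generate_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rois = file.path(dir, "rois.bed"),
             features = file.path(dir, "features.bed"),
             spec = file.path(dir, "fixture_spec.json"))
  write_bed(pair$rois, paths[["rois"]])
  write_bed(pair$features, paths[["features"]])
  spec <- pair$spec
  spec$chrom_lengths <- as.list(spec$chrom_lengths)
  jsonlite::write_json(unclass(spec), paths[["spec"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Histogram bin where a fixture's peak is expected
#'
#' For patterned fixtures, the colocation histogram argmax is expected at
#' bin `50 + round(offset / (window/100))` (0-based bin index, bin 50
#' starting at the ROI center); `bifurcated` fixtures have one expected
#' peak per side.
#'
#' @param spec A `FixtureSpec` with pattern `centered`, `offset` or
#'   `bifurcated`.
#' @param window Analysis window (bp).
#' @return Integer bin index (length 2 for `bifurcated`).
#' @export
expected_peak_bin <- function(spec, window) {
  bin <- window / 100
  k <- as.integer(round(spec$offset / bin))
  switch(spec$pattern,
         centered = 50L,
         offset = 50L + k,
         bifurcated = c(50L - k, 50L + k),
         stop_validation(sprintf(
           "expected peak bin is undefined for pattern '%s'", spec$pattern)))
}
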