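#' Binned per-chromosome feature occupancy index
#'
#' Builds, for each chromosome, an integer array whose entry `i` counts the
#' features overlapping genome bin `[i*bin_size, (i+1)*bin_size)` (0-based
#' bin numbering, bins anchored at coordinate 0). A feature spanning `k`
#' bins adds 1 to each of those `k` bins, so overlapping features
#' accumulate. The index supports constant-time lookups of the 100 bins
#' around any genomic position.
#'
#' @param track A `RegionSet` (canonically sorted).
#' @param bin_size Bin width in bp (`window / 100` for an analysis window).
#' @return An object of class `BinnedFeatureIndex`: a list with `bin_size`,
#'   `per_chrom` (named list of integer count vectors) and
#'   `total_occupied_bins` (number of bins with a positive count across all
#'   chromosomes).
#' @export
build_index <- function(track, bin_size) {
  if (bin_size <= 0) stop_config("bin_size must be positive")
  bin_size <- as.integer(bin_size)
  df <- track$regions
  per_chrom <- list()
  occupied <- 0L
  if (nrow(df) > 0L) {
    for (chr in unique(df$chrom)) {
      sel <- df$chrom == chr
      b0 <- df$start[sel] %/% bin_size
      b1 <- (df$end[sel] - 1L) %/% bin_size
      # enumerate every (feature, bin) incidence, then tally per bin
      hits <- sequence(b1 - b0 + 1L, from = b0 + 1L)
      counts <- tabulate(hits, nbins = max(b1) + 1L)
      per_chrom[[chr]] <- as.integer(counts)
      occupied <- occupied + sum(counts > 0L)
    }
  }
  structure(list(bin_size = bin_size, per_chrom = per_chrom,
                 total_occupied_bins = occupied),
            class = "BinnedFeatureIndex")
}

#' @export
print.BinnedFeatureIndex <- function(x, ...) {
  cat(sprintf("BinnedFeatureIndex: bin %d bp, %d chromosome(s), %d occupied bin(s)\n",
              x$bin_size, length(x$per_chrom), x$total_occupied_bins))
  invisible(x)
}

#' Look up the 100-bin window around a genomic position
#'
#' Returns feature counts for the 100 genome bins whose union covers
#' `[center - window/2, center + window/2)`, left to right. Because genome
#' bins are anchored at 0, the window is snapped: output bin `i` is genome
#' bin `floor((center - window/2)/bin_size) + i`. Bins before position 0,
#' past the indexed end of the chromosome, or on a chromosome absent from
#' the index contribute 0.
#'
#' @param index A `BinnedFeatureIndex`.
#' @param chrom Chromosome name.
#' @param center Lookup position (bp).
#' @param window Window span in bp; must equal `100 * index$bin_size`.
#' @return Integer vector of 100 counts.
#' @export
query_window <- function(index, chrom, center, window) {
  m <- window_counts(index, chrom, center, window)
  as.integer(m[1L, ])
}

# Vectorized window lookup: one row of 100 counts per center.
# All centers must be on the same chromosome.
window_counts <- function(index, chrom, centers, window) {
  if (window %% 100 != 0 || window %/% 100L != index$bin_size)
    stop_config(sprintf(
      "window %d implies bin size %s but index was built at bin size %d",
      window, format(window / 100), index$bin_size))
  half <- as.integer(window) %/% 2L
  n <- length(centers)
  arr <- index$per_chrom[[chrom]]
  if (is.null(arr)) return(matrix(0L, n, 100L))
  first_bin <- (as.integer(centers) - half) %/% index$bin_size
  pos <- outer(first_bin, 0:99, `+`) + 1L   # 1-based into arr
  pos[pos < 1L | pos > length(arr)] <- NA_integer_
  out <- arr[pos]
  out[is.na(out)] <- 0L
  dim(out) <- c(n, 100L)
  out
}

# Window counts for a RegionSet's centers, preserving canonical order.
roi_window_counts <- function(rois, index, window) {
  df <- rois$regions
  centers <- region_centers(rois)
  out <- matrix(0L, nrow(df), 100L)
  for (chr in unique(df$chrom)) {
    sel <- df$chrom == chr
    out[sel, ] <- window_counts(index, chr, centers[sel], window)
  }
  out
}
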