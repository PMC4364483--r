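#' Feature density matrix around region centers
#'
#' Partitions the canonically ordered ROIs into 100 consecutive blocks (row
#' `r`, 0-based, holds ROIs with rank in `[floor(r*n/100),
#' floor((r+1)*n/100))`) and accumulates, for each ROI, the 100-bin window
#' lookup at its center into its row. Column 50 sits immediately right of
#' the ROI center, so the center of each row represents the center of the
#' ROIs it summarizes. With 5,000 ROIs each row aggregates 50 of them.
#'
#' @param rois A `RegionSet` that has passed [filter_rois()]; at least 100
#'   regions.
#' @param index A `BinnedFeatureIndex` built at `bin_size = window/100`.
#' @param window Analysis window (bp).
#' @param mode Label recorded on the matrix: `"roi-centered"` or
#'   `"feature-centered"`.
#' @return An object of class `DensityMatrix`: a list with `values`
#'   (100 x 100 integer matrix), `window`, `n_rois` and `mode`.
#' @export
build_density_matrix <- function(rois, index, window, mode = "roi-centered") {
  n <- n_regions(rois)
  if (n < 100L)
    stop_validation(sprintf("need at least 100 regions to form 100 rows, got %d", n))
  counts <- roi_window_counts(rois, index, window)
  boundaries <- floor((0:100) * n / 100)
  row_id <- findInterval(0:(n - 1L), boundaries)   # 1..100
  values <- rowsum(counts, row_id)
  dimnames(values) <- NULL
  structure(list(values = values, window = as.integer(window),
                 n_rois = n, mode = mode),
            class = "DensityMatrix")
}

#' @export
print.DensityMatrix <- function(x, ...) {
  cat(sprintf("DensityMatrix (%s): %d ROIs, window %d bp, total mass %d\n",
              x$mode, x$n_rois, x$window, sum(x$values)))
  invisible(x)
}

#' Colocation histogram: column sums with dual normalization
#'
#' Sums the density matrix columns into the 100-bin colocation histogram
#' and applies the dual normalization that makes histograms comparable
#' across features and samples: totals are expressed per 10,000 user
#' regions and per 10,000 feature bins (the number of genome bins the
#' feature occupies), i.e.
#' `normalized[j] = raw[j] * (10000 / n_rois) * (10000 / feature_bins)`.
#'
#' @param matrix A `DensityMatrix`.
#' @param n_rois Number of regions profiled (defaults to the matrix's).
#' @param feature_bins Occupied genome bins of the feature track at the
#'   current bin size. A zero (empty track) yields an all-zero histogram
#'   with a warning.
#' @return An object of class `ColocationHistogram`: list with `raw`
#'   (integer, length 100), `normalized` (double, length 100), `window`,
#'   `n_rois`, `feature_bins`.
#' @export
histogram_from_matrix <- function(matrix, n_rois = matrix$n_rois, feature_bins) {
  raw <- as.integer(colSums(matrix$values))
  if (feature_bins == 0) {
    warning("empty feature track: histogram is identically zero", call. = FALSE)
    normalized <- rep(0, 100L)
  } else {
    normalized <- raw * (10000 / n_rois) * (10000 / feature_bins)
  }
  structure(list(raw = raw, normalized = normalized,
                 window = matrix$window, n_rois = as.integer(n_rois),
                 feature_bins = as.integer(feature_bins)),
            class = "ColocationHistogram")
}

#' @export
print.ColocationHistogram <- function(x, ...) {
  cat(sprintf("ColocationHistogram: window %d bp, %d ROIs, %d feature bins, total raw %d\n",
              x$window, x$n_rois, x$feature_bins, sum(x$raw)))
  invisible(x)
}

#' Percentage of regions with a co-located feature
#'
#' The fraction (as a percentage) of ROIs whose 100-bin window contains at
#' least one feature-occupied bin.
#'
#' @inheritParams build_density_matrix
#' @return A percentage in `[0, 100]`.
#' @export
percent_near_feature <- function(rois, index, window) {
  counts <- roi_window_counts(rois, index, window)
  100 * mean(rowSums(counts > 0L) > 0L)
}

#' Render a density matrix as a grayscale image
#'
#' Maps cell values linearly from `[0, max]` to `[white, black]`, so dark
#' pixels mark a high density of features. An all-zero matrix renders all
#' white.
#'
#' @param matrix A `DensityMatrix`.
#' @return A 100 x 100 numeric matrix of grayscale intensities in `[0, 1]`
#'   (1 = white, 0 = black), suitable for [png::writePNG()].
#' @export
render_density_image <- function(matrix) {
  v <- matrix$values
  mx <- max(v)
  if (mx == 0) return(array(1, dim(v)))
  1 - v / mx
}

#' Write the density image to a PNG file
#'
#' @param matrix A `DensityMatrix`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_density_png <- function(matrix, path) {
  png::writePNG(render_density_image(matrix), target = path)
  invisible(path)
}
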