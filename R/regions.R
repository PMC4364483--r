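#' Region sets: validated genomic intervals grouped by chromosome
#'
#' A `RegionSet` holds half-open, 0-based genomic intervals (BED convention:
#' `start` inclusive, `end` exclusive) in canonical order, together with a
#' track label and the path they came from. It is the container for both the
#' user's regions of interest (ROIs) and reference feature tracks.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end` for every region.
#' @param label Track name; defaults to `"regions"`.
#' @param source_path Origin of the data, recorded for provenance.
#' @param n_rejected Count of input lines rejected during parsing.
#' @return An object of class `RegionSet`: a list with a `regions`
#'   data.frame (`chrom`, `start`, `end`), `label`, `source_path` and
#'   `n_rejected`, sorted by (chrom, start, end).
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       label = "regions", source_path = NA_character_,
                       n_rejected = 0L) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop_validation("chrom, start and end must have equal length")
  if (any(start < 0L) || any(end <= start))
    stop_validation("regions must satisfy start >= 0 and end > start")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(regions = df, label = label, source_path = source_path,
                 n_rejected = as.integer(n_rejected)),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d regions", x$label, n_regions(x)))
  if (!is.na(x$source_path)) cat(sprintf(" [%s]", x$source_path))
  if (x$n_rejected > 0L) cat(sprintf(" (%d lines rejected)", x$n_rejected))
  cat("\n")
  invisible(x)
}

#' Number of regions in a RegionSet
#' @param x A `RegionSet`.
#' @return Integer count.
#' @export
n_regions <- function(x) nrow(x$regions)

#' Region widths in base pairs
#' @param x A `RegionSet`.
#' @return Integer vector of `end - start`.
#' @export
region_widths <- function(x) x$regions$end - x$regions$start

#' Region centers (bp)
#'
#' The center of a region is `floor((start + end) / 2)` in 0-based
#' coordinates.
#' @param x A `RegionSet`.
#' @return Integer vector of center positions.
#' @export
region_centers <- function(x) (x$regions$start + x$regions$end) %/% 2L

#' Read a BED3+ file into a RegionSet
#'
#' Reads a tab-delimited BED file using only its first three fields
#' (chromosome, start, stop). `track`, `browser` and `#` comment lines are
#' skipped. Lines with fewer than three fields, non-integer coordinates,
#' negative starts, or `end <= start` are rejected individually; the count
#' of rejected lines is reported in a warning and stored on the result.
#'
#' @param path Path to a BED file.
#' @param label Track label; defaults to the file name without extension.
#' @param chrom_sizes Optional named numeric vector (chromosome -> length,
#'   bp). When given, regions whose `end` exceeds the chromosome length
#'   (or whose chromosome is unknown) are rejected too.
#' @return A `RegionSet`, canonically sorted.
#' @export
read_bed <- function(path, label = NULL, chrom_sizes = NULL) {
  if (!file.exists(path)) stop_io(sprintf("cannot read BED file '%s'", path))
  label <- label %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skip <- grepl("^(track\\b|browser\\b|#)", lines)
  lines <- lines[!skip]
  if (length(lines) == 0L)
    return(region_set(label = label, source_path = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  chrom <- vapply(fields, function(f) f[[1]], "")
  s_raw <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", "")
  e_raw <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "", "")
  int_re <- "^[0-9]+$"
  ok <- nf >= 3L & grepl(int_re, s_raw) & grepl(int_re, e_raw)
  start <- suppressWarnings(as.integer(s_raw))
  end <- suppressWarnings(as.integer(e_raw))
  ok <- ok & !is.na(start) & !is.na(end) & end > start
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[chrom])
    ok <- ok & !is.na(len) & end <= len
  }
  n_rej <- sum(!ok)
  if (n_rej > 0L)
    warning(sprintf("%s: rejected %d malformed line(s) of %d",
                    basename(path), n_rej, length(lines)), call. = FALSE)
  region_set(chrom[ok], start[ok], end[ok], label = label,
             source_path = path, n_rejected = n_rej)
}

#' Write a RegionSet as BED3
#'
#' @param x A `RegionSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- x$regions
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), con = path)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a tab- or space-delimited file with columns
#'   chromosome and length (bp).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read chrom sizes '%s'", path))
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

#' Apply the ROI admission filters
#'
#' Enforces the input contract for regions of interest: regions wider than a
#' quarter of the analysis window are discarded; if more than `max_regions`
#' survive, a seeded uniform subsample of exactly `max_regions` is kept; if
#' fewer than `min_regions` survive, the analysis cannot proceed and a
#' validation error is raised.
#'
#' @param rois A `RegionSet`.
#' @param window Analysis window in bp; must be positive and divisible
#'   by 100.
#' @param max_regions Upper bound on regions analyzed (default 200,000).
#' @param min_regions Minimum surviving regions required (default 1,000).
#' @param seed Integer seed for the subsampling draw.
#' @return A `RegionSet` with at most `max_regions` regions, all of width
#'   `<= window/4`, canonically sorted.
#' @export
filter_rois <- function(rois, window, max_regions = 200000L,
                        min_regions = 1000L, seed = 17L) {
  if (window <= 0 || window %% 100 != 0)
    stop_config("window must be positive and divisible by 100")
  df <- rois$regions
  keep <- (df$end - df$start) <= window / 4
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < min_regions)
    stop_validation(sprintf(
      "only %d region(s) of width <= window/4 remain (%d dropped); at least %d required",
      nrow(df), n_dropped, min_regions))
  if (nrow(df) > max_regions) {
    idx <- with_seed(seed, sample.int(nrow(df), max_regions))
    df <- df[sort(idx), , drop = FALSE]
  }
  region_set(df$chrom, df$start, df$end, label = rois$label,
             source_path = rois$source_path, n_rejected = rois$n_rejected)
}

#' Summary statistics for a feature track
#'
#' @param track A `RegionSet`.
#' @param bin_size Genome bin width in bp; bins are anchored at coordinate 0
#'   on each chromosome.
#' @return A list with `n_features`, `mean_width` (0 for an empty track) and
#'   `occupied_bins`, the number of distinct genome bins overlapped by at
#'   least one feature.
#' @export
summarize_features <- function(track, bin_size) {
  if (bin_size <= 0) stop_config("bin_size must be positive")
  n <- n_regions(track)
  if (n == 0L)
    return(list(n_features = 0L, mean_width = 0, occupied_bins = 0L))
  idx <- build_index(track, bin_size)
  list(n_features = n,
       mean_width = mean(region_widths(track)),
       occupied_bins = idx$total_occupied_bins)
}
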