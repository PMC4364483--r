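# Brute-force oracles, deliberately independent of the vectorized
# implementation paths: plain loops over interval/bin intersections.

# Counts for the 100 window bins around `center`, by intersecting each
# genome-anchored bin with every feature interval on the chromosome.
# Bins before position 0 contribute 0 by contract.
brute_window_counts <- function(track_df, chrom, center, window) {
  bin <- window / 100
  first <- floor((center - window / 2) / bin)
  feats <- track_df[track_df$chrom == chrom, , drop = FALSE]
  out <- integer(100)
  for (j in 0:99) {
    bs <- (first + j) * bin
    be <- bs + bin
    if (bs < 0) next
    out[j + 1] <- sum(feats$start < be & feats$end > bs)
  }
  out
}

# Distinct genome bins overlapped by at least one feature, enumerated
# feature by feature.
brute_occupied_bins <- function(track_df, bin_size) {
  bins <- character(0)
  for (i in seq_len(nrow(track_df))) {
    b0 <- track_df$start[i] %/% bin_size
    b1 <- (track_df$end[i] - 1) %/% bin_size
    bins <- union(bins, paste(track_df$chrom[i], b0:b1))
  }
  length(bins)
}

# H/AMI/BMI re-evaluated directly from the set-builder definitions.
brute_stats <- function(hist, L_h, L_l) {
  S_h <- c(); S_l <- c()
  for (v in hist) {
    if (v > L_h) S_h <- c(S_h, v)
    if (v < L_l) S_l <- c(S_l, v)
  }
  list(H = if (length(S_h)) max(S_h) else 0,
       AMI = if (length(S_h)) sum(S_h) else 0,
       BMI = if (length(S_l)) sum(S_l) else 0)
}

# Small random track on one or two chromosomes, as a plain data.frame.
random_track_df <- function(n, chroms = c("chrA", "chrB"), max_pos = 20000,
                            max_width = 600) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

as_region_set <- function(df, label = "track") {
  region_set(df$chrom, df$start, df$end, label = label)
}

write_bed_lines <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# Shared analysis shorthand for fixture-based tests.
analyze_pair <- function(pair, window = 20000L) {
  idx <- build_index(pair$features, window %/% 100L)
  m <- build_density_matrix(pair$rois, idx, window)
  h <- histogram_from_matrix(m, feature_bins = idx$total_occupied_bins)
  bg <- estimate_background(h$normalized)
  list(index = idx, matrix = m, hist = h, bg = bg,
       stats = compute_stats(h$normalized, bg))
}
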