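#' Analysis configuration
#'
#' @param window Analysis window in bp (default 20,000: 100 bins of
#'   200 bp). Must be positive and divisible by 100. Larger windows zoom
#'   out; they are also more likely to overlap neighboring ROIs.
#' @param mode `"roi-centered"` (default) profiles features around ROI
#'   centers; `"feature-centered"` inverts the roles, centering the matrix
#'   on each feature and profiling the user regions around it.
#' @param max_regions Cap on analyzed ROIs (default 200,000; a seeded
#'   uniform subsample is taken above it).
#' @param min_regions Minimum valid ROIs required (default 1,000).
#' @param n_perms Permutations for the empirical p-value (default 1,000).
#' @param seed Integer seed; every random draw in the run derives from it.
#' @param output_dir Directory for [write_results()].
#' @return An `AnalysisConfig` (classed list).
#' @export
coloc_config <- function(window = 20000L, mode = c("roi-centered", "feature-centered"),
                         max_regions = 200000L, min_regions = 1000L,
                         n_perms = 1000L, seed = 17L,
                         output_dir = "coloc_results") {
  mode <- match.arg(mode)
  if (window <= 0 || window %% 100 != 0)
    stop_config("window must be positive and divisible by 100")
  if (!(max_regions >= min_regions && min_regions >= 100))
    stop_config("need max_regions >= min_regions >= 100")
  structure(list(window = as.integer(window), mode = mode,
                 max_regions = as.integer(max_regions),
                 min_regions = as.integer(min_regions),
                 n_perms = as.integer(n_perms), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "AnalysisConfig")
}

resolve_track <- function(x, label = NULL) {
  if (inherits(x, "RegionSet")) return(x)
  read_bed(x, label = label)
}

# Analyze one feature track against the filtered ROI set.
analyze_feature <- function(rois, track, config) {
  window <- config$window
  bin_size <- window %/% 100L
  if (config$mode == "feature-centered") {
    centers <- track
    indexed <- rois
    if (n_regions(track) > 0 && mean(region_widths(track)) > window / 4)
      warning(sprintf(
        "track '%s': mean width %.0f bp exceeds window/4; feature-centered profiles work best with fine-grained features",
        track$label, mean(region_widths(track))), call. = FALSE)
  } else {
    centers <- rois
    indexed <- track
  }
  index <- build_index(indexed, bin_size)
  feat_summary <- summarize_features(track, bin_size)
  matrix <- build_density_matrix(centers, index, window, mode = config$mode)
  hist <- histogram_from_matrix(matrix, n_rois = n_regions(centers),
                                feature_bins = index$total_occupied_bins)
  bg <- estimate_background(hist$normalized)
  st <- compute_stats(hist$normalized, bg)
  pct <- percent_near_feature(centers, index, window)
  pseed <- derive_seed(config$seed, c(rois$label, track$label))
  p <- empirical_pvalue(hist$raw, n_rois = hist$n_rois,
                        feature_bins = max(hist$feature_bins, 1L),
                        n_perms = config$n_perms, seed = pseed)
  structure(list(feature_label = track$label,
                 n_features = feat_summary$n_features,
                 mean_width = feat_summary$mean_width,
                 occupied_bins = feat_summary$occupied_bins,
                 stats = list(H = st$H, AMI = st$AMI, BMI = st$BMI,
                              pct_near = pct, p_value = p),
                 background = bg, histogram = hist, matrix = matrix,
                 window = window, mode = config$mode),
            class = "FeatureResult")
}

#' @export
print.FeatureResult <- function(x, ...) {
  cat(sprintf("FeatureResult '%s': AMI %.3f, H %.3f, BMI %.3f, %.1f%% near, p %.4g\n",
              x$feature_label, x$stats$AMI, x$stats$H, x$stats$BMI,
              x$stats$pct_near, x$stats$p_value))
  invisible(x)
}

#' Run the colocalization analysis over a set of feature tracks
#'
#' Reads and filters the ROI set once ([filter_rois()]: quarter-window
#' width limit, subsampling cap, minimum-count check), then analyzes each
#' feature track: a binned index is built at `window/100` resolution, the
#' density matrix, colocation histogram, background model, H/AMI/BMI,
#' percent-near-feature and permutation p-value are computed. Results are
#' returned sorted by descending AMI. In feature-centered mode the roles
#' of the (already filtered) ROI set and each feature track are swapped;
#' processing is otherwise identical.
#'
#' An invalid ROI file aborts the run; a feature track that fails to load
#' or analyze is skipped with a warning while the remaining tracks are
#' still processed.
#'
#' @param roi Path to a BED file, or a `RegionSet`.
#' @param features Character vector of BED paths, a directory containing
#'   `.bed` files, or a (possibly named) list of `RegionSet` objects.
#' @param config An `AnalysisConfig` from [coloc_config()].
#' @return List of `FeatureResult`, AMI-descending.
#' @export
run_analysis <- function(roi, features, config = coloc_config()) {
  rois <- resolve_track(roi)
  rois <- filter_rois(rois, window = config$window,
                      max_regions = config$max_regions,
                      min_regions = config$min_regions, seed = config$seed)
  if (is.character(features) && length(features) == 1L && dir.exists(features))
    features <- list.files(features, pattern = "\\.bed$", full.names = TRUE)
  if (length(features) == 0L) {
    warning("no feature tracks to analyze", call. = FALSE)
    return(list())
  }
  if (!is.list(features)) features <- as.list(features)
  results <- list()
  for (f in features) {
    res <- tryCatch(
      analyze_feature(rois, resolve_track(f), config),
      error = function(e) {
        lbl <- if (inherits(f, "RegionSet")) f$label else as.character(f)
        warning(sprintf("skipping feature '%s': %s", lbl, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  ami <- vapply(results, function(r) r$stats$AMI, 0)
  results[order(-ami)]
}

#' Tabulate results as the summary data frame
#'
#' One row per feature in AMI-descending order, with the fixed column set
#' `feature, n_features, mean_width_bp, occupied_bins, pct_near_feature,
#' peak_height, AMI, BMI, p_value, window_bp, mode`.
#'
#' @param results List of `FeatureResult` from [run_analysis()].
#' @return A data.frame.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(feature = r$feature_label,
               n_features = r$n_features,
               mean_width_bp = r$mean_width,
               occupied_bins = r$occupied_bins,
               pct_near_feature = r$stats$pct_near,
               peak_height = r$stats$H,
               AMI = r$stats$AMI,
               BMI = r$stats$BMI,
               p_value = r$stats$p_value,
               window_bp = r$window,
               mode = r$mode,
               stringsAsFactors = FALSE)))
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Write the result bundle to disk
#'
#' Writes `summary.csv` (AMI-descending, fixed header and numeric
#' formatting so identical runs are byte-identical), a per-feature
#' histogram TSV (`bin_index` 0-99, `genomic_offset_bp` from −window/2,
#' `raw`, `normalized`), a per-feature density-matrix TSV and grayscale
#' PNG, and optionally a zip archive of the bundle (requires a `zip`
#' utility on the PATH; a warning is emitted when none is found).
#'
#' @param results Nonempty list of `FeatureResult`.
#' @param config The `AnalysisConfig` used (provides `output_dir`).
#' @param zip Also produce `results.zip` (default `FALSE`).
#' @param png Also write density-matrix PNGs (default `TRUE`).
#' @return Invisibly, a list with `files` (paths written, relative to
#'   `output_dir`) and `zip` (archive path or `NA`).
#' @export
write_results <- function(results, config, zip = FALSE, png = TRUE) {
  if (length(results) == 0L) stop_validation("no results to write")
  dir <- config$output_dir
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create output dir '%s'", dir))
  tab <- results_table(results)
  files <- character()

  header <- paste(colnames(tab), collapse = ",")
  rows <- sprintf("%s,%d,%.2f,%d,%.4f,%.6f,%.6f,%.6f,%.6f,%d,%s",
                  tab$feature, tab$n_features, tab$mean_width_bp,
                  tab$occupied_bins, tab$pct_near_feature, tab$peak_height,
                  tab$AMI, tab$BMI, tab$p_value, tab$window_bp, tab$mode)
  writeLines(c(header, rows), file.path(dir, "summary.csv"))
  files <- c(files, "summary.csv")

  for (r in results) {
    base <- sanitize_label(r$feature_label)
    bin_size <- r$window %/% 100L
    hfile <- paste0(base, "_histogram.tsv")
    offs <- -r$window %/% 2L + (0:99) * bin_size
    writeLines(c("bin_index\tgenomic_offset_bp\traw\tnormalized",
                 sprintf("%d\t%d\t%d\t%.6f", 0:99, offs,
                         r$histogram$raw, r$histogram$normalized)),
               file.path(dir, hfile))
    mfile <- paste0(base, "_matrix.tsv")
    writeLines(apply(r$matrix$values, 1L, paste, collapse = "\t"),
               file.path(dir, mfile))
    files <- c(files, hfile, mfile)
    if (png) {
      pfile <- paste0(base, "_matrix.png")
      write_density_png(r$matrix, file.path(dir, pfile))
      files <- c(files, pfile)
    }
  }

  zip_path <- NA_character_
  if (zip) {
    if (nzchar(Sys.which("zip"))) {
      zip_path <- file.path(dir, "results.zip")
      old <- setwd(dir); on.exit(setwd(old), add = TRUE)
      utils::zip("results.zip", files, flags = "-q9X")
      setwd(old)
    } else {
      warning("no 'zip' utility on PATH; bundle left unarchived", call. = FALSE)
    }
  }
  invisible(list(files = files, zip = zip_path))
}
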