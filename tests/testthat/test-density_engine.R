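# ROIs on one chromosome, spaced farther apart than the window so each
# window sees only its own feature.
isolated_rois <- function(n, spacing = 25000, width = 200) {
  start <- spacing * seq_len(n)
  region_set(rep("chr1", n), start, start + width)
}

test_that("density matrix places a lone feature in the right row and column", {
  rois <- isolated_rois(1000)
  centers <- region_centers(rois)
  feat <- region_set("chr1", centers[1], centers[1] + 1)
  idx <- build_index(feat, 200)
  m <- build_density_matrix(rois, idx, 20000)
  nz <- which(m$values != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(unname(nz[1, "row"]), 1L)      # ROI rank 0 -> first row block
  expect_equal(unname(nz[1, "col"]), 51L)     # 0-based column 50
  expect_equal(sum(m$values), 1L)
})

test_that("rows partition ROIs into 100 consecutive rank blocks", {
  rois <- isolated_rois(5000)
  centers <- region_centers(rois)
  # one feature at the center of ROI rank 137 (0-based): row floor(137/50)
  feat <- region_set("chr1", centers[138], centers[138] + 1)
  m <- build_density_matrix(rois, build_index(feat, 200), 20000)
  expect_equal(which(rowSums(m$values) != 0), 3L)

  # a feature at every ROI center: each row aggregates exactly 50 ROIs
  feats <- region_set(rep("chr1", 5000), centers, centers + 1)
  m2 <- build_density_matrix(rois, build_index(feats, 200), 20000)
  expect_equal(unname(rowSums(m2$values)), rep(50, 100))

  expect_error(build_density_matrix(isolated_rois(80),
                                    build_index(feat, 200), 20000),
               class = "coloc_validation_error")
})

test_that("zero-feature index yields an all-zero matrix and flagged histogram", {
  rois <- isolated_rois(150)
  idx <- build_index(region_set(), 200)
  m <- build_density_matrix(rois, idx, 20000)
  expect_true(all(m$values == 0))
  expect_warning(h <- histogram_from_matrix(m, feature_bins = 0), "zero")
  expect_equal(h$raw, rep(0L, 100))
  expect_equal(h$normalized, rep(0, 100))
})

test_that("histogram raw values are the matrix column sums (conservation)", {
  set.seed(31)
  rois <- isolated_rois(200, spacing = 4000)   # overlapping windows allowed
  df <- random_track_df(300, chroms = "chr1", max_pos = 900000)
  idx <- build_index(as_region_set(df), 200)
  m <- build_density_matrix(rois, idx, 20000)
  h <- histogram_from_matrix(m, feature_bins = idx$total_occupied_bins)
  expect_identical(h$raw, as.integer(colSums(m$values)))
  # no mass lost across the row partitioning
  per_roi <- sum(vapply(region_centers(rois), function(cc)
    sum(query_window(idx, "chr1", cc, 20000)), 0L))
  expect_equal(sum(m$values), per_roi)
})

test_that("dual normalization follows the per-10,000 constants and is linear", {
  mk <- function(vals) structure(list(values = vals, window = 20000L,
                                      n_rois = 5000L, mode = "roi-centered"),
                                 class = "DensityMatrix")
  v <- matrix(0L, 100, 100); v[1, 51] <- 40L
  h <- histogram_from_matrix(mk(v), n_rois = 5000, feature_bins = 20000)
  expect_equal(h$normalized[51], 40 * 2 * 0.5)

  # both scale factors 1
  h1 <- histogram_from_matrix(mk(v), n_rois = 10000, feature_bins = 10000)
  expect_equal(h1$normalized, as.numeric(h1$raw))

  # doubling every raw count doubles every normalized value
  set.seed(8)
  v2 <- matrix(rpois(10000, 2), 100, 100)
  ha <- histogram_from_matrix(mk(v2), n_rois = 3000, feature_bins = 7000)
  hb <- histogram_from_matrix(mk(2L * v2), n_rois = 3000, feature_bins = 7000)
  expect_equal(hb$normalized, 2 * ha$normalized)
})

test_that("mirrored input produces the reversed histogram", {
  set.seed(17)
  n <- 120
  starts <- 200 * sample(100:4000, n) + 100   # centers on bin boundaries
  rois <- region_set(rep("chr1", n), starts, starts + 200)
  centers <- region_centers(rois)
  fpos <- sample(centers, 400, replace = TRUE) +
    sample(-9000:9000, 400, replace = TRUE)
  fw <- sample(1:400, 400, replace = TRUE)
  feats <- region_set(rep("chr1", 400), fpos, fpos + fw)

  M <- 200 * 5200                            # reflection point, bin-aligned
  refl <- function(rs) region_set(rs$regions$chrom, M - rs$regions$end,
                                  M - rs$regions$start)
  h <- analyze_pair(list(rois = rois, features = feats))$hist
  hm <- analyze_pair(list(rois = refl(rois), features = refl(feats)))$hist
  expect_identical(hm$raw, rev(h$raw))
  expect_equal(hm$normalized, rev(h$normalized))
})

test_that("percent_near_feature matches a per-ROI brute-force overlap check", {
  set.seed(13)
  df <- random_track_df(60, chroms = "chr1", max_pos = 500000)
  starts <- sample.int(480000, 250)
  rois <- region_set(rep("chr1", 250), starts, starts + 200)
  idx <- build_index(as_region_set(df), 200)
  got <- percent_near_feature(rois, idx, 20000)
  near <- vapply(region_centers(rois), function(cc)
    sum(brute_window_counts(df, "chr1", cc, 20000)) > 0, NA)
  expect_equal(got, 100 * mean(near))

  expect_equal(percent_near_feature(rois, build_index(region_set(), 200),
                                    20000), 0)
})

test_that("density image maps [0, max] linearly onto [white, black]", {
  mk <- function(vals) structure(list(values = vals, window = 20000L,
                                      n_rois = 100L, mode = "roi-centered"),
                                 class = "DensityMatrix")
  zero <- mk(matrix(0L, 100, 100))
  expect_true(all(render_density_image(zero) == 1))

  v <- matrix(0L, 100, 100); v[10, 20] <- 8L; v[30, 40] <- 4L
  img <- render_density_image(mk(v))
  expect_equal(img[10, 20], 0)     # max cell -> black
  expect_equal(img[30, 40], 0.5)   # half of max -> mid-gray
  expect_equal(img[1, 1], 1)       # zero -> white

  path <- tempfile(fileext = ".png")
  write_density_png(mk(v), path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
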