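test_that("fixture generation is byte-deterministic given the spec", {
  spec <- fixture_spec(n_rois = 300, n_features = 300, pattern = "offset",
                       offset = 1500, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixture_pair(generate_pair(spec), d1)
  p2 <- write_fixture_pair(generate_pair(spec), d2)
  for (k in c("rois", "features", "spec"))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  # sidecar records the generating parameters
  side <- jsonlite::read_json(p1[["spec"]])
  expect_equal(side$pattern, "offset")
  expect_equal(side$offset, 1500)
  expect_equal(side$seed, 77)
})

test_that("fixture specs reject infeasible geometry", {
  expect_error(fixture_spec(chrom_lengths = c(chrA = 30000), margin = 20000),
               class = "coloc_validation_error")
  expect_error(fixture_spec(colocated_fraction = 1.2),
               class = "coloc_validation_error")
  # exclusion zones covering the whole genome cannot be satisfied
  spec <- fixture_spec(n_rois = 50, n_features = 20,
                       chrom_lengths = c(chrA = 2e5), margin = 5000,
                       pattern = "anticolocated", offset = 2e5, seed = 1)
  expect_error(generate_pair(spec), class = "coloc_validation_error")
})

test_that("expected_peak_bin converts offsets to bin indices", {
  expect_equal(expected_peak_bin(fixture_spec(pattern = "centered"), 20000),
               50L)
  expect_equal(expected_peak_bin(fixture_spec(pattern = "offset",
                                              offset = 2000), 20000), 60L)
  expect_equal(expected_peak_bin(fixture_spec(pattern = "bifurcated",
                                              offset = 1000), 20000),
               c(45L, 55L))
  expect_error(expected_peak_bin(fixture_spec(pattern = "null"), 20000),
               class = "coloc_validation_error")
})

test_that("a co-centered noiseless fixture concentrates all mass at the center", {
  spec <- fixture_spec(n_rois = 1000, n_features = 1000, pattern = "centered",
                       jitter_sd = 0, colocated_fraction = 1, seed = 5)
  pair <- generate_pair(spec)
  a <- analyze_pair(pair)
  # every ROI's own feature lands in bin 50 exactly; the remaining mass is
  # other ROIs' features falling elsewhere in overlapping windows
  expect_equal(which.max(a$hist$raw) - 1L, 50L)
  center_mass <- sum(a$hist$raw[50:52]) / sum(a$hist$raw)
  expect_gte(center_mass, 0.5)
  expect_gte(a$hist$raw[51], 1000L)   # one hit per ROI at minimum
  p <- empirical_pvalue(a$hist$raw, a$hist$n_rois, a$hist$feature_bins,
                        n_perms = 1000, seed = 6)
  expect_lte(p, 0.01)
  expect_gte(percent_near_feature(pair$rois, a$index, 20000), 99)
})

test_that("null fixtures hit the closed-form uniform overlap expectation", {
  genome <- 5e7
  for (seed in c(2, 12)) {
    pair <- generate_pair(fixture_spec(pattern = "null", seed = seed))
    idx <- build_index(pair$features, 200)
    got <- percent_near_feature(pair$rois, idx, 20000)
    expected <- 100 * (1 - (1 - 20000 / genome)^1000)
    expect_lt(abs(got - expected), 5)
  }
})

test_that("colocated fixtures dominate null fixtures on AMI", {
  wins <- vapply(1:10, function(i) {
    ac <- analyze_pair(generate_pair(fixture_spec(
      n_rois = 2000, n_features = 2000, pattern = "centered",
      seed = 4000 + i)))$stats$AMI
    an <- analyze_pair(generate_pair(fixture_spec(
      n_rois = 2000, n_features = 2000, pattern = "null",
      seed = 6000 + i)))$stats$AMI
    ac > an
  }, NA)
  expect_true(all(wins))
})

test_that("partially depleted troughs raise BMI above the null level", {
  # Full depletion zeroes the trough bins, and bins of value 0 add nothing
  # to a sum of values; the statistic responds to partial depletion, so the
  # fixture keeps half the features as uniform background.
  wins <- vapply(1:20, function(i) {
    ba <- analyze_pair(generate_pair(fixture_spec(
      n_rois = 2000, n_features = 4000, pattern = "anticolocated",
      offset = 4000, colocated_fraction = 0.5, seed = 500 + i)))$stats$BMI
    bn <- analyze_pair(generate_pair(fixture_spec(
      n_rois = 2000, n_features = 4000, pattern = "null",
      seed = 700 + i)))$stats$BMI
    ba > bn
  }, NA)
  expect_gt(mean(wins), 0.5)
})
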