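#' Background model estimated from the histogram edges
#'
#' The background feature-density level `L_b` is the mean of the histogram
#' values furthest from the region center: bins up to and including the
#' 25th, and from the 75th up (1-based), 51 bins in all. The background
#' variance proxy `V` is the 75th-percentile (nearest-rank) oscillation
#' distance: sort the 99 absolute consecutive differences
#' `|v[i+1] - v[i]|` ascending and take rank `ceiling(0.75 * 99) = 75`.
#' The upper threshold is `L_h = L_b + V`. The default lower threshold is
#' the symmetric counterpart `L_l = max(L_b - V, 0)`; setting
#' `lower_literal = TRUE` uses `L_l = V - L_b` instead, which can be
#' negative (it then never captures any bin).
#'
#' @param hist Numeric vector of exactly 100 finite, non-negative histogram
#'   values (normally the `normalized` slot of a `ColocationHistogram`).
#' @param lower_literal Use the alternative lower-threshold form
#'   `V - L_b` (default `FALSE`).
#' @return An object of class `BackgroundModel`: list with `L_b`, `V`,
#'   `L_h`, `L_l` and `S_b_indices` (the 51 edge-bin indices, 1-based).
#' @export
estimate_background <- function(hist, lower_literal = FALSE) {
  if (length(hist) != 100L || !all(is.finite(hist)) || any(hist < 0))
    stop_validation("hist must be 100 finite non-negative values")
  edges <- c(1:25, 75:100)
  L_b <- mean(hist[edges])
  d <- sort(abs(diff(hist)))
  V <- d[ceiling(0.75 * length(d))]
  L_l <- if (lower_literal) V - L_b else max(L_b - V, 0)
  structure(list(L_b = L_b, V = V, L_h = L_b + V, L_l = L_l,
                 S_b_indices = edges),
            class = "BackgroundModel")
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat(sprintf("BackgroundModel: L_b %.4g, V %.4g, L_h %.4g, L_l %.4g\n",
              x$L_b, x$V, x$L_h, x$L_l))
  invisible(x)
}

#' Peak height, AMI and BMI from a histogram and its background
#'
#' `S_h` is the set of histogram values strictly above the upper threshold
#' `L_h`, `S_l` the set strictly below the lower threshold `L_l`. The
#' colocation peak height `H` is the maximum of `S_h`; the Above-Mean
#' Integral (AMI) is the sum of `S_h`, the score of colocalization
#' strength; the Below-Mean Integral (BMI) is the sum of `S_l`,
#' quantifying anti-colocation. Empty sets yield 0. The full bin values
#' are summed, not the excess over the threshold.
#'
#' @param hist Numeric vector of 100 histogram values.
#' @param bg A `BackgroundModel` derived from `hist`
#'   (see [estimate_background()]).
#' @return List with `H`, `AMI`, `BMI`.
#' @export
compute_stats <- function(hist, bg) {
  S_h <- hist[hist > bg$L_h]
  S_l <- hist[hist < bg$L_l]
  list(H = if (length(S_h)) max(S_h) else 0,
       AMI = sum(S_h),
       BMI = sum(S_l))
}

# AMI for each column of a 100 x k histogram matrix (used for permutations).
ami_columns <- function(m, lower_literal = FALSE) {
  edges <- c(1:25, 75:100)
  L_b <- colMeans(m[edges, , drop = FALSE])
  D <- abs(m[-1L, , drop = FALSE] - m[-100L, , drop = FALSE])
  rank75 <- ceiling(0.75 * (nrow(m) - 1L))
  V <- apply(D, 2L, function(x) sort.int(x, method = "quick")[rank75])
  L_h <- L_b + V
  above <- m > rep(L_h, each = 100L)
  colSums(m * above)
}

#' Empirical permutation p-value for the AMI
#'
#' Randomizes feature placement within the histogram: the total raw count
#' `T` is redistributed by assigning each of its `T` units an independent
#' uniform random bin (a multinomial draw over the 100 bins, preserving
#' the total). Each randomized histogram is normalized with the same
#' constants as the observed one, its background re-estimated, and its AMI
#' computed. The p-value is the fraction of randomized histograms with an
#' AMI greater than or equal to the observed AMI.
#'
#' Because the normalization constants are fixed positive scalars, AMI and
#' its thresholds scale together, so the p-value is identical whether
#' computed on raw or normalized histograms.
#'
#' @param raw_hist Integer vector of 100 non-negative raw column totals.
#' @param n_rois,feature_bins Normalization constants (see
#'   [histogram_from_matrix()]).
#' @param n_perms Number of randomizations (default 1,000).
#' @param seed Integer seed for the randomization stream.
#' @param correct Apply the `(r + 1) / (n + 1)` small-sample correction
#'   (default `FALSE`, matching the plain percentage definition).
#' @param lower_literal Passed through to background estimation.
#' @return A probability in `[0, 1]`. A histogram with total count 0 is
#'   degenerate and returns 1 with a warning.
#' @export
empirical_pvalue <- function(raw_hist, n_rois, feature_bins, n_perms = 1000L,
                             seed = 17L, correct = FALSE,
                             lower_literal = FALSE) {
  if (n_perms < 1L) stop_config("n_perms must be at least 1")
  if (length(raw_hist) != 100L || any(raw_hist < 0))
    stop_validation("raw_hist must be 100 non-negative counts")
  total <- sum(raw_hist)
  if (total == 0) {
    warning("histogram total is 0; p-value is degenerate", call. = FALSE)
    return(1)
  }
  scale <- (10000 / n_rois) * (10000 / feature_bins)
  obs <- estimate_background(raw_hist * scale, lower_literal = lower_literal)
  ami_obs <- compute_stats(raw_hist * scale, obs)$AMI
  perm <- with_seed(seed,
    stats::rmultinom(n_perms, size = total, prob = rep(1 / 100, 100L)))
  ami_perm <- ami_columns(perm * scale, lower_literal = lower_literal)
  r <- sum(ami_perm >= ami_obs)
  if (correct) (r + 1) / (n_perms + 1) else r / n_perms
}
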