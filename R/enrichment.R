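#' Per-pixel z-score field over the specimen mask
#'
#' Standardizes one channel over the traced specimen: each mask pixel's
#' z-score is its intensity minus the mean intensity of the whole mask,
#' divided by the standard deviation of intensities within the whole mask.
#' The population convention (divide by `N`) is used for the standard
#' deviation, so the z-scores sum to zero over the mask exactly (up to
#' floating point).
#'
#' @param sample An [oriented_sample()].
#' @param channel Channel name or index.
#' @return A `zscore_field`: list with `z` (matrix, `NA` outside the
#'   mask), `mask`, `mu`, `sigma`, `channel`, `ap_bounds`, `sample_id`.
#' @examples
#' s <- oriented_sample(matrix(c(1, 3), 1), matrix(TRUE, 1, 2))
#' zscore_field(s, 1)$z  # -1, +1
#' @export
zscore_field <- function(sample, channel) {
  stopifnot(inherits(sample, "oriented_sample"))
  img <- channel_matrix(sample, channel)
  vals <- img[sample$mask]
  if (length(vals) < 2L) stop("mask must contain at least 2 pixels")
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  if (sigma == 0) {
    stop("degenerate input: channel is constant over the mask (sd = 0)")
  }
  z <- matrix(NA_real_, nrow(img), ncol(img))
  z[sample$mask] <- (vals - mu) / sigma
  structure(
    list(z = z, mask = sample$mask, mu = mu, sigma = sigma,
         channel = if (is.character(channel)) channel else
           sample$channel_names[channel],
         ap_bounds = sample$ap_bounds, sample_id = sample$sample_id),
    class = "zscore_field")
}

#' @export
print.zscore_field <- function(x, ...) {
  cat(sprintf(
    "<zscore_field> %s/%s: %d mask px, mu = %.4g, sigma = %.4g\n",
    x$sample_id, x$channel, sum(x$mask), x$mu, x$sigma))
  invisible(x)
}

#' Anterior integrated enrichment
#'
#' The headline per-sample statistic: the sum of per-pixel z-scores over
#' the anterior region (by default the anterior-most 15\% of mask
#' pixels). Because z-scores sum to zero over the whole mask, positive
#' values indicate anterior-enriched signal and the statistic over the
#' anterior set equals minus the statistic over its complement.
#'
#' @param zfield A [zscore_field()].
#' @param region A [pixel_set()] contained in the mask, typically from
#'   [anterior_region()].
#' @return An `enrichment_result`: list with `value`, `n_pixels`,
#'   `fraction`, `mode`, `channel`, `sample_id`.
#' @export
anterior_integrated_enrichment <- function(zfield, region) {
  stopifnot(inherits(zfield, "zscore_field"), inherits(region, "pixel_set"))
  if (nrow(region) == 0L) stop("`region` is empty")
  z <- zfield$z[cbind(region$y, region$x)]
  if (anyNA(z)) stop("`region` contains pixels outside the mask")
  structure(
    list(value = sum(z), n_pixels = nrow(region),
         fraction = attr(region, "fraction"),
         mode = attr(region, "mode"),
         channel = zfield$channel, sample_id = zfield$sample_id),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s/%s: sum z = %.4f over %d anterior px\n",
    x$sample_id, x$channel, x$value, x$n_pixels))
  invisible(x)
}

#' Standardized anteroposterior z-score profile
#'
#' Reduces a z-score field to one value per mask column (the mean z-score
#' of mask pixels in that column), maps column positions linearly from
#' the mask's AP extent onto `[0, 1]` (0 = anterior), and linearly
#' interpolates onto `n_points` equally spaced standard positions so
#' samples of different sizes and shapes can be compared and aggregated.
#' Interior columns with no mask pixels are bridged linearly from their
#' neighbours.
#'
#' @param zfield A [zscore_field()].
#' @param n_points Number of standard positions (default 300).
#' @return An `ap_profile`: list with `positions` (length `n_points`,
#'   increasing on `[0, 1]`), `values`, `n_points`, `channel`,
#'   `sample_id`.
#' @export
ap_profile <- function(zfield, n_points = 300L) {
  stopifnot(inherits(zfield, "zscore_field"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be at least 2")
  counts <- colSums(zfield$mask)
  cols <- which(counts > 0)
  if (length(cols) < 2L) {
    stop("mask must span at least 2 distinct columns for a profile")
  }
  colmean <- colSums(zfield$z * zfield$mask, na.rm = TRUE)[cols] / counts[cols]
  pos <- (cols - cols[1]) / (cols[length(cols)] - cols[1])
  std <- seq(0, 1, length.out = n_points)
  vals <- approx(pos, colmean, xout = std, method = "linear")$y
  structure(
    list(positions = std, values = vals, n_points = n_points,
         channel = zfield$channel, sample_id = zfield$sample_id),
    class = "ap_profile")
}

#' Aggregate AP profiles across samples of a group
#'
#' Pointwise mean across samples with a 95\% confidence band, mean
#' +/- 1.96 standard errors of the mean (sample standard deviation,
#' `n - 1`). A single profile yields a zero-width band.
#'
#' @param profiles List of [ap_profile()] objects with equal `n_points`.
#' @return A `profile_ensemble`: list with `positions`, `mean`, `ci_low`,
#'   `ci_high`, `sem`, `n_samples`, `n_points`, `channel`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) stop("need at least 1 profile")
  stopifnot(all(vapply(profiles, inherits, logical(1), "ap_profile")))
  np <- vapply(profiles, function(p) p$n_points, integer(1))
  if (length(unique(np)) != 1L) stop("profiles have mixed n_points")
  m <- vapply(profiles, function(p) p$values, numeric(np[1]))
  m <- matrix(m, nrow = np[1])
  mu <- rowMeans(m)
  n <- ncol(m)
  sem <- if (n > 1) apply(m, 1, sd) / sqrt(n) else rep(0, np[1])
  structure(
    list(positions = profiles[[1]]$positions, mean = mu,
         ci_low = mu - 1.96 * sem, ci_high = mu + 1.96 * sem,
         sem = sem, n_samples = n, n_points = np[1],
         channel = profiles[[1]]$channel),
    class = "profile_ensemble")
}

#' @export
print.profile_ensemble <- function(x, ...) {
  cat(sprintf(
    "<profile_ensemble> %s: %d samples, %d points, mean z in [%.3f, %.3f]\n",
    x$channel, x$n_samples, x$n_points, min(x$mean), max(x$mean)))
  invisible(x)
}

#' Plot a profile ensemble
#'
#' Mean z-score along the normalized AP axis with the 95\% confidence
#' band, in the style of the per-genotype enrichment profile figures.
#'
#' @param x A `profile_ensemble`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.profile_ensemble <- function(x, ...) {
  graphics::plot(x$positions, x$mean, type = "n",
                 ylim = range(x$ci_low, x$ci_high),
                 xlab = "normalized AP position (0 = anterior)",
                 ylab = "z-score", ...)
  graphics::polygon(c(x$positions, rev(x$positions)),
                    c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::lines(x$positions, x$mean, lwd = 2)
  invisible(x)
}
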