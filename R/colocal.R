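#' Settings for HA-anchored colocalization
#'
#' Two threshold modes select the "high-HA" pixels within the anterior
#' region: `"mean_plus_2sd"` keeps pixels strictly above the region mean
#' plus two (population) standard deviations of the anchor channel;
#' `"top_fraction"` keeps the `round(top_fraction * n)` brightest anchor
#' pixels (default fraction 0.175, i.e. the 17.5\% highest values).
#'
#' @param threshold_mode `"mean_plus_2sd"` (default) or `"top_fraction"`.
#' @param top_fraction Fraction of region pixels kept in
#'   `"top_fraction"` mode; in `(0, 1]`.
#' @param gaussian_sigma Standard deviation (pixels) of the Gaussian
#'   filter applied to both channels before correlating; 0 disables.
#' @param min_pixels Minimum number of selected pixels for a defined
#'   Pearson coefficient (default 2).
#' @return A `coloc_settings` list.
#' @export
coloc_settings <- function(threshold_mode = c("mean_plus_2sd", "top_fraction"),
                           top_fraction = 0.175, gaussian_sigma = 1,
                           min_pixels = 2L) {
  threshold_mode <- match.arg(threshold_mode)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must be in (0, 1]")
  }
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0")
  list(threshold_mode = threshold_mode, top_fraction = top_fraction,
       gaussian_sigma = gaussian_sigma, min_pixels = as.integer(min_pixels))
}

#' Select high-anchor-signal pixels within a region
#'
#' @param sample An [oriented_sample()].
#' @param region A [pixel_set()], typically the anterior region.
#' @param settings A [coloc_settings()].
#' @param anchor_channel Channel the threshold is computed on
#'   (default `"HA"`).
#' @return A [pixel_set()] with provenance `"HA-high"`; may be empty in
#'   `"mean_plus_2sd"` mode (e.g. a constant anchor leaves nothing
#'   strictly above the threshold).
#' @export
ha_high_mask <- function(sample, region, settings = coloc_settings(),
                         anchor_channel = "HA") {
  stopifnot(inherits(sample, "oriented_sample"), inherits(region, "pixel_set"))
  if (nrow(region) == 0L) stop("`region` is empty")
  anchor <- channel_matrix(sample, anchor_channel)
  vals <- anchor[cbind(region$y, region$x)]
  if (settings$threshold_mode == "mean_plus_2sd") {
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2))
    keep <- which(vals > mu + 2 * sigma)
  } else {
    k <- round_half_up(settings$top_fraction * length(vals))
    ord <- order(-vals, region$x, region$y)
    keep <- ord[seq_len(min(k, length(vals)))]
    if (k < 1L) keep <- integer(0)
  }
  pixel_set(region$y[keep], region$x[keep], provenance = "HA-high",
            threshold_mode = settings$threshold_mode)
}

#' Gaussian-filter one channel of a sample
#'
#' Separable 2-D Gaussian convolution with reflecting boundary; the
#' kernel is truncated at 4 sigma and normalized, so a constant image is
#' preserved and total intensity is conserved. `sigma = 0` returns the
#' channel unchanged.
#'
#' @param sample An [oriented_sample()].
#' @param channel Channel name or index.
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return The filtered channel as a matrix.
#' @export
gaussian_filter_channel <- function(sample, channel, sigma = 1) {
  gaussian_blur(channel_matrix(sample, channel), sigma)
}

gaussian_blur <- function(m, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single number >= 0")
  }
  if (sigma == 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_pad_conv <- function(v) {
    n <- length(v)
    # reflect boundary: d c b a | a b c d | d c b a (indices clamped when
    # the kernel radius exceeds the image extent)
    pre <- v[pmin(n, pmax(1L, r:1))]
    post <- v[pmin(n, pmax(1L, n:(n - r + 1L)))]
    padded <- c(pre, v, post)
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  out <- m
  for (j in seq_len(ncol(out))) out[, j] <- reflect_pad_conv(out[, j])
  for (i in seq_len(nrow(out))) out[i, ] <- reflect_pad_conv(out[i, ])
  out
}

#' HA-anchored thresholded Pearson colocalization
#'
#' Builds the high-anchor pixel mask on the unfiltered anchor channel,
#' Gaussian-filters both channels, and computes the Pearson correlation
#' between the filtered anchor and target values on the selected pixels.
#' If fewer than `min_pixels` pixels are selected, or either channel is
#' constant on the selection, the result is marked undefined rather than
#' raising an error; such samples are excluded from group summaries.
#'
#' @param sample An [oriented_sample()].
#' @param target_channel Channel correlated against the anchor.
#' @param region A [pixel_set()], typically from [anterior_region()].
#' @param settings A [coloc_settings()].
#' @param anchor_channel Anchor (thresholding) channel, default `"HA"`.
#' @return A `coloc_result`: list with `r` (`NA` if undefined),
#'   `defined`, `n_pixels`, `channel_pair`, `threshold_mode`, `sigma`,
#'   `sample_id`.
#' @export
colocalization <- function(sample, target_channel, region,
                           settings = coloc_settings(),
                           anchor_channel = "HA") {
  sel <- ha_high_mask(sample, region, settings, anchor_channel)
  a <- gaussian_blur(channel_matrix(sample, anchor_channel),
                     settings$gaussian_sigma)
  b <- gaussian_blur(channel_matrix(sample, target_channel),
                     settings$gaussian_sigma)
  res <- list(r = NA_real_, defined = FALSE, n_pixels = nrow(sel),
              channel_pair = c(anchor = anchor_channel,
                               target = target_channel),
              threshold_mode = settings$threshold_mode,
              sigma = settings$gaussian_sigma,
              sample_id = sample$sample_id)
  if (nrow(sel) >= settings$min_pixels) {
    av <- a[cbind(sel$y, sel$x)]
    bv <- b[cbind(sel$y, sel$x)]
    if (var(av) > 0 && var(bv) > 0) {
      res$r <- pearson_r(av, bv)
      res$defined <- TRUE
    }
  }
  structure(res, class = "coloc_result")
}

# cov/sqrt(var*var) rather than cor(): exact 1 for identical vectors
pearson_r <- function(x, y) {
  r <- stats::cov(x, y) / sqrt(var(x) * var(y))
  min(1, max(-1, r))
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %s %s~%s: %s (n = %d px, %s, sigma = %g)\n",
    x$sample_id, x$channel_pair[["anchor"]], x$channel_pair[["target"]],
    if (x$defined) sprintf("r = %.4f", x$r) else "undefined",
    x$n_pixels, x$threshold_mode, x$sigma))
  invisible(x)
}
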