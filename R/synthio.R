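#' Parameters for the synthetic-micrograph generator
#'
#' The generator emulates the structure the quantification pipeline
#' expects from a real micrograph: an elliptical specimen on a dark
#' background, an anchor channel (`"HA"`) whose signal decays
#' exponentially from the anterior pole, a target channel linearly mixed
#' against the anchor, and additive Gaussian noise. Defaults give a
#' specimen of ~7,000 mask pixels with an anterior signal of twice the
#' noise standard deviation.
#'
#' @param height,width Frame size in pixels.
#' @param ellipse_axes Semi-axes `(a, b)` of the specimen ellipse in
#'   pixels, `a` along the (horizontal) AP axis. The ellipse must fit
#'   inside the frame.
#' @param amplitude Anterior signal amplitude `A >= 0`, in intensity
#'   units above baseline at the anterior pole.
#' @param decay_length Decay length `lambda > 0` of the anterior signal,
#'   as a fraction of the AP extent.
#' @param baseline Background intensity inside the specimen, `>= 0`.
#' @param noise_sd Standard deviation of the additive Gaussian noise,
#'   `>= 0` (intensities are truncated at 0 after adding noise).
#' @param mixing Mixing coefficient `alpha` in `[0, 1]` of the target
#'   channel against the noise-free anchor signal: `alpha = 1` makes the
#'   channels identical up to noise, `alpha = 0` makes them independent.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical images.
#' @return A validated `image_sim_params` list.
#' @export
image_sim_params <- function(height = 96L, width = 128L,
                             ellipse_axes = c(56, 40),
                             amplitude = 1, decay_length = 0.2,
                             baseline = 10, noise_sd = 0.5,
                             mixing = 0.5, seed = NULL) {
  stopifnot(height >= 3, width >= 3, length(ellipse_axes) == 2)
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (decay_length <= 0) stop("`decay_length` must be > 0")
  if (baseline < 0) stop("`baseline` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (mixing < 0 || mixing > 1) stop("`mixing` must be in [0, 1]")
  if (2 * ellipse_axes[1] >= width || 2 * ellipse_axes[2] >= height) {
    stop("ellipse exceeds the image frame")
  }
  list(height = as.integer(height), width = as.integer(width),
       ellipse_axes = as.numeric(ellipse_axes),
       amplitude = amplitude, decay_length = decay_length,
       baseline = baseline, noise_sd = noise_sd, mixing = mixing,
       seed = seed)
}

#' Generate a synthetic two-channel micrograph with known ground truth
#'
#' Inside an axis-aligned elliptical mask, channel `"HA"` is
#' `baseline + A * exp(-xhat / lambda) + N(0, noise_sd^2)` where `xhat`
#' is the normalized AP coordinate (0 at the anterior, left); channel
#' `"target"` is `baseline + alpha * (noise-free anterior signal) +
#' (1 - alpha) * independent noise`. Intensities are truncated at 0 and
#' pixels outside the mask are 0.
#'
#' @param params An [image_sim_params()].
#' @return A `labeled_micrograph`: list with `sample` (an
#'   [oriented_sample()] with channels `HA`, `target`) and
#'   `ground_truth` (list of `amplitude`, `decay_length`, `mixing`,
#'   `noise_sd`, `seed`).
#' @export
generate_sample_image <- function(params = image_sim_params()) {
  run <- function() {
    h <- params$height; w <- params$width
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    a <- params$ellipse_axes[1]; b <- params$ellipse_axes[2]
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
    cols <- which(colSums(mask) > 0)
    xhat <- (xx - min(cols)) / (max(cols) - min(cols))
    clean <- params$amplitude * exp(-xhat / params$decay_length)
    n_px <- h * w
    noise1 <- matrix(rnorm(n_px, 0, params$noise_sd), h, w)
    noise2 <- matrix(rnorm(n_px, 0, params$noise_sd), h, w)
    ch1 <- pmax(params$baseline + clean + noise1, 0)
    ch2 <- pmax(params$baseline + params$mixing * clean +
                  (1 - params$mixing) * noise2, 0)
    ch1[!mask] <- 0
    ch2[!mask] <- 0
    img <- array(c(ch1, ch2), dim = c(h, w, 2L))
    sample <- oriented_sample(img, mask,
                              channel_names = c("HA", "target"),
                              orientation_applied = TRUE)
    structure(
      list(sample = sample,
           ground_truth = list(amplitude = params$amplitude,
                               decay_length = params$decay_length,
                               mixing = params$mixing,
                               noise_sd = params$noise_sd,
                               seed = params$seed)),
      class = "labeled_micrograph")
  }
  if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
}

#' Parameters for the synthetic pole-cell score-table generator
#'
#' Emulates per-embryo scoring of a genotype cohort: each embryo is
#' scored `negative`, `attempt` (pole-bud initiation without completed
#' pole cells), or `anterior_pole_cells`, and pole cells are counted at
#' both poles. Defaults reproduce the conditions reported for wild-type
#' anteriorly targeted Oskar: 15.1\% penetrance, a mean of 20.5 anterior
#' pole cells among positive embryos, and 24.3 posterior pole cells.
#'
#' @param n_embryos Number of embryos in the cohort.
#' @param penetrance Probability `p` an embryo forms anterior pole cells.
#' @param attempt_rate Probability of the `attempt` phenotype;
#'   `p + attempt_rate <= 1`.
#' @param count_mean_anterior Poisson mean of anterior pole-cell counts
#'   for positive embryos (truncated to `>= 1`).
#' @param count_mean_posterior Poisson mean of posterior pole-cell
#'   counts, all embryos.
#' @param seed Integer seed for reproducibility.
#' @return A validated `score_sim_params` list.
#' @export
score_sim_params <- function(n_embryos = 300L, penetrance = 0.151,
                             attempt_rate = 0.05,
                             count_mean_anterior = 20.5,
                             count_mean_posterior = 24.3, seed = NULL) {
  if (n_embryos < 0) stop("`n_embryos` must be >= 0")
  if (penetrance < 0 || penetrance > 1) stop("`penetrance` must be in [0, 1]")
  if (attempt_rate < 0 || attempt_rate > 1) {
    stop("`attempt_rate` must be in [0, 1]")
  }
  if (penetrance + attempt_rate > 1) {
    stop("`penetrance + attempt_rate` must be <= 1")
  }
  if (count_mean_anterior < 0 || count_mean_posterior < 0) {
    stop("count means must be >= 0")
  }
  list(n_embryos = as.integer(n_embryos), penetrance = penetrance,
       attempt_rate = attempt_rate,
       count_mean_anterior = count_mean_anterior,
       count_mean_posterior = count_mean_posterior, seed = seed)
}

#' Generate a synthetic per-embryo score table
#'
#' Each embryo draws exactly one phenotype category; embryos scored
#' `anterior_pole_cells` draw an anterior count from a zero-truncated
#' Poisson (so the category is consistent with a count of at least 1),
#' and every embryo draws a posterior count from a Poisson.
#'
#' @param params A [score_sim_params()].
#' @param genotype Genotype label stored in the table.
#' @return An embryo score table: data.frame with columns `embryo_id`,
#'   `genotype`, `category`, `n_anterior`, `n_posterior`. Zero embryos
#'   yield an empty table.
#' @export
generate_score_table <- function(params = score_sim_params(),
                                 genotype = "WT") {
  run <- function() {
    n <- params$n_embryos
    cats <- c("negative", "attempt", "anterior_pole_cells")
    if (n == 0L) {
      return(data.frame(embryo_id = character(0), genotype = character(0),
                        category = character(0), n_anterior = integer(0),
                        n_posterior = integer(0)))
    }
    category <- sample(cats, n, replace = TRUE,
                       prob = c(1 - params$penetrance - params$attempt_rate,
                                params$attempt_rate, params$penetrance))
    n_anterior <- integer(n)
    pos <- which(category == "anterior_pole_cells")
    if (length(pos)) {
      n_anterior[pos] <- rtruncpois(length(pos), params$count_mean_anterior)
    }
    n_posterior <- rpois(n, params$count_mean_posterior)
    data.frame(
      embryo_id = sprintf("%s_e%04d", genotype, seq_len(n)),
      genotype = genotype, category = category,
      n_anterior = n_anterior, n_posterior = n_posterior,
      stringsAsFactors = FALSE)
  }
  if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
}

# zero-truncated Poisson via the inverse-CDF restricted above P(X = 0);
# the lambda -> 0 limit is a point mass at 1
rtruncpois <- function(n, lambda) {
  if (lambda == 0) return(rep(1L, n))
  u <- runif(n, ppois(0, lambda), 1)
  pmax(1L, qpois(u, lambda))
}
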