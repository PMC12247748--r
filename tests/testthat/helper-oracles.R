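# Independent brute-force oracles and small fixture builders. These are
# deliberately written from first principles (explicit loops, direct
# formulas) so they share no code path with the package implementation.

# random masked sample: random intensities on a random rectangular-ish
# mask inside an n x n frame, guaranteed to span >= 2 columns
random_masked_sample <- function(n = 32, seed = 1, channels = 1) {
  withr::with_seed(seed, {
    mask <- matrix(FALSE, n, n)
    y0 <- sample.int(n - 4, 1); x0 <- sample.int(n - 4, 1)
    y1 <- y0 + sample(3:(n - y0), 1); x1 <- x0 + sample(3:(n - x0), 1)
    mask[y0:y1, x0:x1] <- TRUE
    # poke random holes, but keep every column inhabited
    holes <- which(mask)
    drop <- sample(holes, length(holes) %/% 4)
    mask[drop] <- FALSE
    for (x in x0:x1) if (!any(mask[, x])) mask[y0, x] <- TRUE
    img <- array(runif(n * n * channels, 0, 100), dim = c(n, n, channels))
    oriented_sample(img, mask, sample_id = paste0("rnd", seed))
  })
}

# direct z-score computation from the definition, no package code
oracle_zscores <- function(img, mask) {
  v <- img[mask]
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / length(v))
  (img - mu) / sigma
}

# sort-and-sum anterior enrichment oracle: rank mask pixels and sum
# z-scores over the selected anterior set
oracle_enrichment <- function(img, mask, fraction, mode) {
  z <- oracle_zscores(img, mask)
  coords <- which(mask, arr.ind = TRUE)
  coords <- coords[order(coords[, "col"], coords[, "row"]), , drop = FALSE]
  if (mode == "pixels") {
    k <- floor(fraction * nrow(coords) + 0.5)
    sel <- coords[seq_len(k), , drop = FALSE]
  } else {
    xs <- coords[, "col"]
    if (fraction >= 1) sel <- coords
    else sel <- coords[xs < min(xs) + fraction * (max(xs) - min(xs)), ,
                       drop = FALSE]
  }
  total <- 0
  for (i in seq_len(nrow(sel))) total <- total + z[sel[i, 1], sel[i, 2]]
  total
}

# exhaustive fixed-margin enumeration of the one-sided Fisher p-value
oracle_fisher_less <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  tmin <- max(0, k - m2); tmax <- min(k, m1)
  probs <- vapply(tmin:tmax, function(t) {
    choose(m1, t) * choose(m2, k - t) / choose(m1 + m2, k)
  }, numeric(1))
  sum(probs[(tmin:tmax) <= a])
}

# direct O(n^2 k^2) Gaussian convolution with reflect boundary
oracle_gaussian <- function(m, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  reflect <- function(i, n) {
    # d c b a | a b c d | d c b a
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- m * 0
  for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + kern[dy + r + 1, dx + r + 1] *
        m[reflect(y + dy, nrow(m)), reflect(x + dx, ncol(m))]
    }
    out[y, x] <- acc
  }
  out
}
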