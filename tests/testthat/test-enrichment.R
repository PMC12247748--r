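test_that("z-scores match hand arithmetic and use the population SD", {
  s2 <- oriented_sample(matrix(c(1, 3), 1), matrix(TRUE, 1, 2))
  z2 <- zscore_field(s2, 1)
  expect_equal(z2$mu, 2)
  expect_equal(z2$sigma, 1)
  expect_equal(as.numeric(z2$z), c(-1, 1))

  s4 <- oriented_sample(matrix(c(2, 4, 6, 8), 1), matrix(TRUE, 1, 4))
  z4 <- zscore_field(s4, 1)
  expect_equal(z4$sigma, sqrt(5))
  expect_equal(as.numeric(z4$z),
               c(-3, -1, 1, 3) / sqrt(5), tolerance = 1e-12)

  expect_error(zscore_field(
    oriented_sample(matrix(7, 2, 2), matrix(TRUE, 2, 2)), 1), "constant")
})

test_that("z-scores sum to zero over the mask and enrichment is conservative", {
  for (seed in 1:10) {
    s <- random_masked_sample(32, seed = seed)
    zf <- zscore_field(s, 1)
    N <- sum(s$mask)
    expect_lt(abs(sum(zf$z[s$mask])), 1e-6 * N)
    # anterior set enrichment = -(complement enrichment)
    ant <- anterior_region(s, 0.15, "pixels")
    all_px <- which(s$mask, arr.ind = TRUE)
    key <- paste(all_px[, 1], all_px[, 2])
    comp <- !key %in% paste(ant$y, ant$x)
    e_ant <- anterior_integrated_enrichment(zf, ant)$value
    e_comp <- sum(zf$z[all_px[comp, , drop = FALSE]])
    expect_equal(e_ant, -e_comp, tolerance = 1e-9 * N)
  }
})

test_that("anterior enrichment reproduces the hand-computed step-mask case", {
  # 10-pixel row (10 x5, 0 x5): mu = 5, sigma = 5, anterior z = +1 each
  s <- oriented_sample(matrix(c(10, 10, 10, 10, 10, 0, 0, 0, 0, 0), 1),
                       matrix(TRUE, 1, 10))
  zf <- zscore_field(s, 1)
  e <- anterior_integrated_enrichment(zf, anterior_region(s, 0.15))
  expect_equal(e$value, 2)
  expect_equal(e$n_pixels, 2L)
  # whole mask sums to zero
  whole <- anterior_integrated_enrichment(zf, anterior_region(s, 1))
  expect_lt(abs(whole$value), 1e-6 * 10)
})

test_that("enrichment equals the sort-and-sum oracle on random samples", {
  for (seed in 1:20) {
    s <- random_masked_sample(32, seed = seed)
    zf <- zscore_field(s, 1)
    img <- s$image[, , 1]
    for (mode in c("pixels", "length")) {
      got <- anterior_integrated_enrichment(
        zf, anterior_region(s, 0.15, mode))$value
      expect_equal(got, oracle_enrichment(img, s$mask, 0.15, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("z-field, enrichment and profile are invariant under I -> aI + b", {
  s <- random_masked_sample(32, seed = 3)
  s_aff <- oriented_sample(3 * s$image + 7, s$mask)
  z1 <- zscore_field(s, 1); z2 <- zscore_field(s_aff, 1)
  expect_equal(z1$z, z2$z, tolerance = 1e-10)
  r <- anterior_region(s, 0.15)
  expect_equal(anterior_integrated_enrichment(z1, r)$value,
               anterior_integrated_enrichment(z2, r)$value,
               tolerance = 1e-10)
  expect_equal(ap_profile(z1)$values, ap_profile(z2)$values,
               tolerance = 1e-10)
})

test_that("AP profiles have the stated length, endpoints and monotonicity", {
  # 300-column ramp: profile must be strictly increasing
  ramp <- matrix(seq_len(300), 1, 300, byrow = TRUE)
  ramp <- rbind(ramp, ramp)
  s <- oriented_sample(ramp, matrix(TRUE, 2, 300))
  pr <- ap_profile(zscore_field(s, 1))
  expect_length(pr$values, 300)
  expect_true(all(diff(pr$values) > 0))
  expect_true(all(diff(pr$positions) > 0))

  # endpoints equal the first/last column means
  s2 <- random_masked_sample(24, seed = 6)
  zf <- zscore_field(s2, 1)
  pr2 <- ap_profile(zf)
  cols <- which(colSums(s2$mask) > 0)
  first_mean <- mean(zf$z[s2$mask[, cols[1]], cols[1]])
  last_mean <- mean(zf$z[s2$mask[, cols[length(cols)]], cols[length(cols)]])
  expect_equal(pr2$values[1], first_mean)
  expect_equal(pr2$values[300], last_mean)

  expect_error(ap_profile(zscore_field(
    oriented_sample(matrix(c(1, 2), 2, 1), matrix(TRUE, 2, 1)), 1)),
    "2 distinct columns")
})

test_that("interior mask gaps are bridged linearly", {
  m <- matrix(TRUE, 1, 5); m[1, 3] <- FALSE
  img <- matrix(c(0, 1, 99, 3, 4), 1)  # col 3 masked out
  s <- oriented_sample(img, m)
  zf <- zscore_field(s, 1)
  pr <- ap_profile(zf, n_points = 5)
  # standard position 0.5 falls exactly on the missing column: the value
  # must be the average of its neighbours
  expect_equal(pr$values[3], (pr$values[2] + pr$values[4]) / 2)
})

test_that("profile aggregation matches a direct recomputation", {
  single <- ap_profile(zscore_field(random_masked_sample(24, 1), 1))
  ens1 <- aggregate_profiles(list(single))
  expect_equal(ens1$mean, single$values)
  expect_equal(ens1$ci_low, ens1$mean)
  expect_equal(ens1$ci_high, ens1$mean)

  neg <- single; neg$values <- -single$values
  ens2 <- aggregate_profiles(list(single, neg))
  expect_equal(ens2$mean, rep(0, 300))
  expect_equal(ens2$ci_low, -ens2$ci_high)

  profs <- lapply(1:10, function(i) {
    ap_profile(zscore_field(random_masked_sample(24, seed = 100 + i), 1))
  })
  ens <- aggregate_profiles(profs)
  m <- sapply(profs, `[[`, "values")
  mu <- apply(m, 1, mean)
  sem <- apply(m, 1, sd) / sqrt(10)
  expect_equal(ens$mean, mu)
  expect_equal(ens$ci_low, mu - 1.96 * sem)
  expect_equal(ens$ci_high, mu + 1.96 * sem)
  expect_true(all(ens$ci_low <= ens$mean & ens$mean <= ens$ci_high))

  short <- ap_profile(zscore_field(random_masked_sample(24, 2), 1),
                      n_points = 100)
  expect_error(aggregate_profiles(list(single, short)), "mixed")
})
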