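test_that("group summaries reproduce known counts", {
  # 2 positives out of 355 embryos: penetrance 2/355 ~ 0.005634
  tab <- data.frame(
    embryo_id = sprintf("e%03d", 1:355), genotype = "S210P",
    category = c(rep("anterior_pole_cells", 2), rep("negative", 353)),
    n_anterior = c(3L, 5L, rep(0L, 353)),
    n_posterior = 20L, stringsAsFactors = FALSE)
  s <- summarize_scores(tab, "S210P")
  expect_equal(s$n_embryos, 355)
  expect_equal(s$n_positive, 2)
  expect_equal(s$penetrance, 2 / 355, tolerance = 1e-12)
  expect_equal(s$mean_anterior_count, 4)

  allneg <- tab; allneg$category <- "negative"; allneg$n_anterior <- 0L
  s0 <- summarize_scores(allneg, "S210P")
  expect_equal(s0$penetrance, 0)
  expect_true(is.na(s0$mean_anterior_count))

  expect_error(summarize_scores(tab, "nope"), "not in table")
})

test_that("summaries agree with the generator's own bookkeeping", {
  tab <- generate_score_table(
    score_sim_params(n_embryos = 500, penetrance = 0.2,
                     attempt_rate = 0.1, seed = 11), "G")
  s <- summarize_scores(tab, "G")
  expect_equal(s$n_embryos, 500)
  expect_equal(s$n_positive, sum(tab$category == "anterior_pole_cells"))
  expect_equal(s$n_attempts, sum(tab$category == "attempt"))
  expect_equal(s$mean_posterior_count, mean(tab$n_posterior))
})

test_that("score-table validation catches malformed rows", {
  bad <- data.frame(embryo_id = "e1", genotype = "G", category = "weird",
                    n_anterior = 0L, n_posterior = 1L)
  expect_error(validate_score_table(bad), "unknown category")
  bad2 <- data.frame(embryo_id = "e1", genotype = "G",
                     category = "anterior_pole_cells",
                     n_anterior = 0L, n_posterior = 1L)
  expect_error(validate_score_table(bad2), "n_anterior >= 1")
})

test_that("bootstrap handles degenerate, enumerable and symmetric cases", {
  r0 <- bootstrap_diff_means(5, 5, B = 100, seed = 1)
  expect_equal(r0$observed_diff, 0)
  expect_equal(r0$p_value, 1)

  # exactly enumerable pooled-resampling probability: 2 * (1/2)^3 * (1/2)^3
  rb <- bootstrap_diff_means(c(0, 0, 0), c(100, 100, 100),
                             B = 10000, seed = 7)
  p_exact <- 0.03125
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(rb$p_value - p_exact), 3 * mc_se)

  # determinism and x/y swap symmetry of the two-sided statistic
  rb2 <- bootstrap_diff_means(c(0, 0, 0), c(100, 100, 100),
                              B = 10000, seed = 7)
  expect_identical(rb$p_value, rb2$p_value)
  swap <- bootstrap_diff_means(c(100, 100, 100), c(0, 0, 0),
                               B = 10000, seed = 7)
  expect_identical(swap$p_value, rb$p_value)

  expect_error(bootstrap_diff_means(numeric(0), 1), "non-empty")
  # optional small-sample correction keeps p off zero
  rp <- bootstrap_diff_means(c(0, 0, 0, 0, 0, 0), c(9, 9, 9, 9, 9, 9),
                             B = 50, seed = 2, plus_one = TRUE)
  expect_gte(rp$p_value, 1 / 51)
})

test_that("bootstrap RNG use does not disturb the caller's stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(bootstrap_diff_means(1:5, 2:6, B = 200, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("one-sided Fisher p equals the enumeration oracle", {
  # C(5,0) C(5,5) / C(10,5) = 1/252
  expect_equal(fisher_one_sided(rbind(c(0, 5), c(5, 0))), 1 / 252,
               tolerance = 1e-12)
  # no phenotype anywhere: only one attainable table
  expect_equal(fisher_one_sided(rbind(c(0, 5), c(0, 7))), 1)

  for (total in c(4, 6, 8)) {
    for (a in 0:total) for (b in 0:(total - a)) {
      for (cc in 0:(total - a - b)) {
        d <- total - a - b - cc
        tab <- rbind(c(a, b), c(cc, d))
        if (sum(tab) == 0) next
        expect_equal(fisher_one_sided(tab, "less"),
                     oracle_fisher_less(a, b, cc, d), tolerance = 1e-9)
        expect_equal(fisher_one_sided(tab, "greater"),
                     oracle_fisher_less(b, a, d, cc), tolerance = 1e-9)
      }
    }
  }
  expect_error(fisher_one_sided(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("penetrance comparison flags lower-penetrance variants", {
  tab <- rbind(
    generate_score_table(score_sim_params(500, penetrance = 0.151,
                                          seed = 1), "WT"),
    generate_score_table(score_sim_params(500, penetrance = 0.001,
                                          seed = 2), "dLOTUS"))
  s_wt <- summarize_scores(tab, "WT")
  s_mut <- summarize_scores(tab, "dLOTUS")
  cmp <- compare_penetrance(s_mut, s_wt)
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$significant)
  expect_equal(unname(cmp$table[1, 1]), s_mut$n_positive)

  # identical groups are never significant
  same <- compare_penetrance(s_wt, s_wt)
  expect_gte(same$p_value, 0.5)
  expect_false(same$significant)
})

test_that("penetrance comparison has power and holds its size", {
  # power: control p = 0.15 (n = 400) vs variant p = 0.001 (n = 1000)
  rejected <- vapply(seq_len(200), function(i) {
    tab <- rbind(
      generate_score_table(score_sim_params(400, penetrance = 0.15,
                                            seed = 2 * i), "WT"),
      generate_score_table(score_sim_params(1000, penetrance = 0.001,
                                            seed = 2 * i + 1), "V"))
    compare_penetrance(summarize_scores(tab, "V"),
                       summarize_scores(tab, "WT"))$significant
  }, logical(1))
  expect_gt(mean(rejected), 0.95)

  # size: equal true penetrance, one-sided exact test is conservative
  false_pos <- vapply(seq_len(500), function(i) {
    tab <- rbind(
      generate_score_table(score_sim_params(200, penetrance = 0.1,
                                            seed = 7000 + 2 * i), "WT"),
      generate_score_table(score_sim_params(200, penetrance = 0.1,
                                            seed = 7001 + 2 * i), "V"))
    compare_penetrance(summarize_scores(tab, "V"),
                       summarize_scores(tab, "WT"))$significant
  }, logical(1))
  expect_lte(mean(false_pos), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})
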