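#' Pipeline run configuration
#'
#' Bundles the tunable constants of the quantification pipeline. The
#' defaults are the study constants: anterior fraction 0.15, 300-point
#' profiles, 10,000 bootstrap iterations, significance level 0.05.
#'
#' @param anterior_fraction Anterior fraction for enrichment (0.15).
#' @param anterior_mode `"pixels"` or `"length"`; see
#'   [anterior_region()].
#' @param coloc A [coloc_settings()].
#' @param n_profile_points Standard AP profile length (300).
#' @param bootstrap_iters Bootstrap iterations for group comparisons.
#' @param alpha Significance level.
#' @param control_genotype Genotype every other genotype is compared to.
#' @param anchor_channel Colocalization anchor channel (`"HA"`).
#' @param seed Integer seed driving every stochastic step of a run.
#' @return A `run_config` list.
#' @export
run_config <- function(anterior_fraction = 0.15,
                       anterior_mode = "pixels",
                       coloc = coloc_settings(),
                       n_profile_points = 300L,
                       bootstrap_iters = 10000L,
                       alpha = 0.05,
                       control_genotype = "WT",
                       anchor_channel = "HA",
                       seed = 1L) {
  list(anterior_fraction = anterior_fraction,
       anterior_mode = anterior_mode,
       coloc = coloc,
       n_profile_points = as.integer(n_profile_points),
       bootstrap_iters = as.integer(bootstrap_iters),
       alpha = alpha,
       control_genotype = control_genotype,
       anchor_channel = anchor_channel,
       seed = as.integer(seed))
}

#' Simulate a multi-genotype imaging cohort on disk
#'
#' Generates synthetic micrographs for each genotype, writes them as
#' TIFF image/mask pairs with a JSON ground-truth sidecar, and writes
#' the orientation manifest the pipeline consumes. Each genotype can
#' carry its own anterior amplitude (emulating variants with different
#' degrees of germ-plasm enrichment).
#'
#' @param out_dir Output directory (created if needed).
#' @param genotypes Character vector of genotype labels.
#' @param n_per_genotype Samples per genotype.
#' @param amplitudes Named numeric vector of anterior amplitudes, one
#'   per genotype; defaults to the base parameter's amplitude for all.
#' @param base_params An [image_sim_params()] supplying all other
#'   generator parameters.
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @return The manifest path, invisibly.
#' @export
simulate_cohort <- function(out_dir, genotypes = c("WT", "variant"),
                            n_per_genotype = 10L, amplitudes = NULL,
                            base_params = image_sim_params(),
                            seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(amplitudes)) {
    amplitudes <- stats::setNames(rep(base_params$amplitude,
                                      length(genotypes)), genotypes)
  }
  rows <- list()
  counter <- 0L
  for (g in genotypes) {
    for (i in seq_len(n_per_genotype)) {
      counter <- counter + 1L
      p <- base_params
      p$amplitude <- unname(amplitudes[[g]])
      p$seed <- seed * 10000L + counter
      lm_ <- generate_sample_image(p)
      sid <- sprintf("%s_s%03d", g, i)
      img <- file.path(out_dir, paste0(sid, ".tif"))
      msk <- file.path(out_dir, paste0(sid, "_mask.tif"))
      write_micrograph(lm_$sample, img, msk)
      jsonlite::write_json(lm_$ground_truth,
                           file.path(out_dir, paste0(sid, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
      rows[[counter]] <- data.frame(
        sample_id = sid, genotype = g, stage = "synthetic",
        image_path = basename(img), mask_path = basename(msk),
        rotation_deg = 0, flip_lr = FALSE, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Run the enrichment/profile/colocalization pipeline over a cohort
#'
#' For every manifest row: read the image and mask, apply the recorded
#' orientation, compute the per-channel z-score field, the anterior
#' integrated enrichment, the standardized AP profile, and the
#' HA-anchored colocalization against every non-anchor channel. Per
#' genotype and channel, profiles are aggregated into mean/95\%-CI
#' ensembles and enrichment values are compared to the control genotype
#' with the pooled bootstrap. Row-level failures are collected, not
#' fatal; the run reports them at the end.
#'
#' @param manifest Manifest data.frame or CSV path (see
#'   [read_manifest()]).
#' @param out_dir Optional output directory; when given, writes
#'   `enrichment.csv`, `coloc.csv`, `profiles.csv`, `comparisons.csv`
#'   and `errors.csv`.
#' @param config A [run_config()].
#' @param channel_names Channel labels for the image TIFF directories,
#'   anchor first by convention (default `c("HA", "target")`).
#' @return Invisibly, a list with data.frames `enrichment`, `coloc`,
#'   `profiles`, `comparisons`, `errors` and the integer `status`
#'   (0 if every row succeeded).
#' @export
run_enrichment_pipeline <- function(manifest, out_dir = NULL,
                                    config = run_config(),
                                    channel_names = c("HA", "target")) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  enr <- list(); col <- list(); prof_objs <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      raw <- read_micrograph(row$image_path, row$mask_path,
                             channel_names = channel_names,
                             sample_id = row$sample_id)
      s <- orient_sample(raw$image, raw$mask,
                         rotation_deg = row$rotation_deg,
                         flip_lr = row$flip_lr,
                         channel_names = channel_names,
                         sample_id = row$sample_id)
      region <- anterior_region(s, config$anterior_fraction,
                                config$anterior_mode)
      for (ch in s$channel_names) {
        zf <- zscore_field(s, ch)
        e <- anterior_integrated_enrichment(zf, region)
        enr[[length(enr) + 1L]] <- data.frame(
          sample_id = row$sample_id, genotype = row$genotype,
          channel = ch, enrichment_value = e$value,
          n_pixels = e$n_pixels, fraction = e$fraction, mode = e$mode,
          stringsAsFactors = FALSE)
        pr <- ap_profile(zf, config$n_profile_points)
        prof_objs[[length(prof_objs) + 1L]] <- list(
          genotype = row$genotype, channel = ch, profile = pr)
      }
      for (ch in setdiff(s$channel_names, config$anchor_channel)) {
        cc <- colocalization(s, ch, region, config$coloc,
                             anchor_channel = config$anchor_channel)
        col[[length(col) + 1L]] <- data.frame(
          sample_id = row$sample_id, genotype = row$genotype,
          pair = paste(config$anchor_channel, ch, sep = "~"),
          threshold_mode = cc$threshold_mode, sigma = cc$sigma,
          n_pixels = cc$n_pixels, r = cc$r, defined = cc$defined,
          stringsAsFactors = FALSE)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errs[[length(errs) + 1L]] <- data.frame(
        sample_id = row$sample_id, message = res, stringsAsFactors = FALSE)
    }
  }
  enrichment <- if (length(enr)) do.call(rbind, enr) else
    data.frame(sample_id = character(0), genotype = character(0),
               channel = character(0), enrichment_value = numeric(0),
               n_pixels = integer(0), fraction = numeric(0),
               mode = character(0))
  coloc <- if (length(col)) do.call(rbind, col) else
    data.frame(sample_id = character(0), genotype = character(0),
               pair = character(0), threshold_mode = character(0),
               sigma = numeric(0), n_pixels = integer(0), r = numeric(0),
               defined = logical(0))
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(sample_id = character(0), message = character(0))

  profiles <- aggregate_profile_table(prof_objs)
  comparisons <- enrichment_comparisons(enrichment, config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(enrichment, file.path(out_dir, "enrichment.csv"),
              row.names = FALSE)
    write.csv(coloc, file.path(out_dir, "coloc.csv"), row.names = FALSE)
    write.csv(profiles, file.path(out_dir, "profiles.csv"),
              row.names = FALSE)
    write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
    write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  }
  invisible(list(enrichment = enrichment, coloc = coloc,
                 profiles = profiles, comparisons = comparisons,
                 errors = errors,
                 status = if (nrow(errors)) 1L else 0L))
}

aggregate_profile_table <- function(prof_objs) {
  empty <- data.frame(genotype = character(0), channel = character(0),
                      position = numeric(0), mean = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      n = integer(0))
  if (!length(prof_objs)) return(empty)
  keys <- vapply(prof_objs, function(p) paste(p$genotype, p$channel,
                                              sep = "\r"), character(1))
  out <- lapply(unique(keys), function(k) {
    grp <- prof_objs[keys == k]
    ens <- aggregate_profiles(lapply(grp, `[[`, "profile"))
    data.frame(genotype = grp[[1]]$genotype, channel = grp[[1]]$channel,
               position = ens$positions, mean = ens$mean,
               ci_low = ens$ci_low, ci_high = ens$ci_high,
               n = ens$n_samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

enrichment_comparisons <- function(enrichment, config) {
  empty <- data.frame(genotype = character(0), channel = character(0),
                      observed_diff = numeric(0), p_value = numeric(0),
                      significant = logical(0), n_test = integer(0),
                      n_control = integer(0))
  ctrl <- enrichment[enrichment$genotype == config$control_genotype, ]
  others <- setdiff(unique(enrichment$genotype), config$control_genotype)
  if (!nrow(ctrl) || !length(others)) return(empty)
  out <- list()
  for (g in others) {
    for (ch in unique(enrichment$channel)) {
      x <- enrichment$enrichment_value[enrichment$genotype == g &
                                         enrichment$channel == ch]
      y <- ctrl$enrichment_value[ctrl$channel == ch]
      if (!length(x) || !length(y)) next
      bt <- bootstrap_diff_means(x, y, B = config$bootstrap_iters,
                                 seed = config$seed)
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, channel = ch, observed_diff = bt$observed_diff,
        p_value = bt$p_value, significant = bt$p_value < config$alpha,
        n_test = length(x), n_control = length(y),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Summaries and hypothesis tests for a pole-cell score table
#'
#' Summarizes every genotype and compares each non-control genotype to
#' the control: penetrance with the one-sided Fisher exact test (is the
#' variant's penetrance lower?) and anterior/posterior pole-cell counts
#' with the pooled bootstrap. Count comparisons on anterior counts use
#' positive embryos only and are skipped (NA) when either group has
#' none.
#'
#' @param table An embryo score table (data.frame or CSV path).
#' @param config A [run_config()]; supplies the control genotype,
#'   bootstrap iterations, alpha and seed.
#' @param out_dir Optional directory; writes `summaries.csv` and
#'   `tests.json`.
#' @return Invisibly, a list with `summaries` (data.frame) and `tests`
#'   (data.frame; zero rows for a single-genotype table).
#' @export
run_polestats <- function(table, config = run_config(), out_dir = NULL) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  validate_score_table(table)
  genotypes <- unique(table$genotype)
  sums <- lapply(genotypes, function(g) summarize_scores(table, g))
  names(sums) <- genotypes
  summaries <- do.call(rbind, lapply(sums, function(s) {
    data.frame(genotype = s$genotype, n_embryos = s$n_embryos,
               n_attempts = s$n_attempts, n_positive = s$n_positive,
               penetrance = s$penetrance,
               mean_anterior_count = s$mean_anterior_count,
               mean_posterior_count = s$mean_posterior_count,
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL

  tests <- data.frame(genotype = character(0), test = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      significant = logical(0))
  ctrl <- config$control_genotype
  if (ctrl %in% genotypes && length(genotypes) > 1L) {
    rows <- list()
    for (g in setdiff(genotypes, ctrl)) {
      cmp <- compare_penetrance(sums[[g]], sums[[ctrl]],
                                alpha = config$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, test = "fisher_penetrance",
        statistic = sums[[g]]$penetrance - sums[[ctrl]]$penetrance,
        p_value = cmp$p_value, significant = cmp$significant,
        stringsAsFactors = FALSE)
      xa <- table$n_anterior[table$genotype == g &
                               table$category == "anterior_pole_cells"]
      ya <- table$n_anterior[table$genotype == ctrl &
                               table$category == "anterior_pole_cells"]
      if (length(xa) && length(ya)) {
        bt <- bootstrap_diff_means(xa, ya, B = config$bootstrap_iters,
                                   seed = config$seed)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, test = "bootstrap_anterior_count",
          statistic = bt$observed_diff, p_value = bt$p_value,
          significant = bt$p_value < config$alpha,
          stringsAsFactors = FALSE)
      }
      xp <- table$n_posterior[table$genotype == g]
      yp <- table$n_posterior[table$genotype == ctrl]
      bt <- bootstrap_diff_means(xp, yp, B = config$bootstrap_iters,
                                 seed = config$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, test = "bootstrap_posterior_count",
        statistic = bt$observed_diff, p_value = bt$p_value,
        significant = bt$p_value < config$alpha,
        stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, rows)
  } else if (length(genotypes) > 1L) {
    stop(sprintf("control genotype '%s' not present in table", ctrl))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summaries, file.path(out_dir, "summaries.csv"),
              row.names = FALSE)
    jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(summaries = summaries, tests = tests))
}
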