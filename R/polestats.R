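#' Validate an embryo score table
#'
#' Checks the column contract and invariants of a per-embryo score table:
#' known categories, non-negative counts, and anterior count at least 1
#' whenever the category is `anterior_pole_cells`.
#'
#' @param table Data.frame with columns `embryo_id`, `genotype`,
#'   `category` (`negative` | `attempt` | `anterior_pole_cells`),
#'   `n_anterior`, `n_posterior`.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_score_table <- function(table) {
  need <- c("embryo_id", "genotype", "category", "n_anterior", "n_posterior")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("score table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad_cat <- !table$category %in% c("negative", "attempt",
                                    "anterior_pole_cells")
  if (any(bad_cat)) {
    stop("unknown category in rows: ",
         paste(utils::head(which(bad_cat), 5), collapse = ", "))
  }
  if (any(table$n_anterior < 0) || any(table$n_posterior < 0)) {
    stop("pole-cell counts must be >= 0")
  }
  inconsistent <- table$category == "anterior_pole_cells" &
    table$n_anterior < 1
  if (any(inconsistent)) {
    stop("category 'anterior_pole_cells' requires n_anterior >= 1; rows: ",
         paste(utils::head(which(inconsistent), 5), collapse = ", "))
  }
  invisible(table)
}

#' Summarize pole-cell scoring for one genotype
#'
#' Counts embryos per phenotype category and computes the penetrance
#' (fraction of embryos with anterior pole cells), the mean anterior
#' pole-cell count among positive embryos, and the mean posterior count
#' over all embryos.
#'
#' @param table A validated embryo score table (see
#'   [validate_score_table()]).
#' @param genotype Genotype to summarize; must be present in the table.
#' @return A `group_summary`: list with `genotype`, `n_embryos`,
#'   `n_attempts`, `n_positive`, `penetrance`, `mean_anterior_count`
#'   (`NA` when no embryo is positive), `mean_posterior_count`.
#' @export
summarize_scores <- function(table, genotype) {
  validate_score_table(table)
  rows <- table[table$genotype == genotype, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("genotype '%s' not in table", genotype))
  pos <- rows$category == "anterior_pole_cells"
  structure(
    list(genotype = genotype,
         n_embryos = nrow(rows),
         n_attempts = sum(rows$category == "attempt"),
         n_positive = sum(pos),
         penetrance = sum(pos) / nrow(rows),
         mean_anterior_count = if (any(pos)) mean(rows$n_anterior[pos])
                               else NA_real_,
         mean_posterior_count = mean(rows$n_posterior)),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> %s: %d embryos, %d attempts, %d positive (penetrance %.3f)\n",
    x$genotype, x$n_embryos, x$n_attempts, x$n_positive, x$penetrance))
  cat(sprintf("  mean anterior count (positives): %s; mean posterior count: %.2f\n",
              if (is.na(x$mean_anterior_count)) "undefined" else
                sprintf("%.2f", x$mean_anterior_count),
              x$mean_posterior_count))
  invisible(x)
}

#' Pooled-bootstrap test for a difference in means
#'
#' The observed statistic is `mean(x) - mean(y)`. The null distribution
#' is built by pooling the two samples and, in each of `B` iterations,
#' resampling `length(x)` and `length(y)` values with replacement from
#' the pool and recomputing the difference in means. The p-value is the
#' proportion of null statistics equal to or more extreme than the
#' observed value (two-sided by absolute value, by default).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param B Number of bootstrap iterations (default 10,000).
#' @param seed Optional integer seed; given a seed the p-value is
#'   deterministic, and the caller's RNG state is left untouched.
#' @param alternative `"two.sided"` (default), `"greater"`
#'   (`mean(x) > mean(y)`) or `"less"`.
#' @param plus_one Apply the `(k + 1) / (B + 1)` small-sample correction
#'   so p can never be exactly 0? Off by default, matching the plain
#'   proportion formula.
#' @return A `bootstrap_result`: list with `observed_diff`, `p_value`,
#'   `n_iterations`, `alternative`, `seed`, `n_x`, `n_y`.
#' @export
bootstrap_diff_means <- function(x, y, B = 10000L, seed = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 plus_one = FALSE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  B <- as.integer(B)
  observed <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x); ny <- length(y)
  run <- function() {
    draws <- matrix(pool[sample.int(length(pool), (nx + ny) * B,
                                    replace = TRUE)],
                    nrow = nx + ny)
    colMeans(draws[seq_len(nx), , drop = FALSE]) -
      colMeans(draws[nx + seq_len(ny), , drop = FALSE])
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  k <- switch(alternative,
              two.sided = sum(abs(null) >= abs(observed)),
              greater = sum(null >= observed),
              less = sum(null <= observed))
  p <- if (plus_one) (k + 1) / (B + 1) else k / B
  structure(
    list(observed_diff = observed, p_value = p, n_iterations = B,
         alternative = alternative, seed = seed, n_x = nx, n_y = ny),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> diff in means = %.4g, p = %.4g (%s, B = %d)\n",
    x$observed_diff, x$p_value, x$alternative, x$n_iterations))
  invisible(x)
}

#' One-sided Fisher exact test on a 2x2 contingency table
#'
#' Exact hypergeometric tail probability for a table
#' `rbind(c(a, b), c(c, d))` of (group x with/without phenotype) counts.
#' `direction = "less"` tests whether the first group's phenotype
#' proportion is lower than the second's (odds ratio < 1), the direction
#' used when asking whether a variant has lower penetrance than control.
#'
#' @param table 2x2 numeric matrix of non-negative counts, rows = groups,
#'   column 1 = embryos with the phenotype. At least one entry positive.
#' @param direction `"less"` (default) or `"greater"`.
#' @return The one-sided p-value.
#' @examples
#' fisher_one_sided(rbind(c(0, 5), c(5, 0)))  # 1/252
#' @export
fisher_one_sided <- function(table, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0) || any(!is.finite(table))) {
    stop("`table` entries must be non-negative counts")
  }
  if (sum(table) == 0) stop("`table` must have at least one positive margin")
  fisher.test(table, alternative = direction)$p.value
}

#' Compare penetrance between two genotype summaries
#'
#' Builds the 2x2 contingency table of embryos with and without the
#' anterior-pole-cell phenotype in each group and applies the one-sided
#' Fisher exact test, flagging significance at `alpha`.
#'
#' @param summary_test,summary_control `group_summary` objects from
#'   [summarize_scores()]; the default direction asks whether the test
#'   group's penetrance is *lower* than the control's.
#' @param direction Passed to [fisher_one_sided()].
#' @param alpha Significance level (default 0.05).
#' @return A `penetrance_comparison`: list with `table`, `p_value`,
#'   `significant`, `direction`, `alpha`, `genotypes`.
#' @export
compare_penetrance <- function(summary_test, summary_control,
                               direction = "less", alpha = 0.05) {
  stopifnot(inherits(summary_test, "group_summary"),
            inherits(summary_control, "group_summary"))
  if (summary_test$n_embryos == 0L || summary_control$n_embryos == 0L) {
    stop("both groups must contain embryos")
  }
  tab <- rbind(
    c(summary_test$n_positive,
      summary_test$n_embryos - summary_test$n_positive),
    c(summary_control$n_positive,
      summary_control$n_embryos - summary_control$n_positive))
  dimnames(tab) <- list(c(summary_test$genotype, summary_control$genotype),
                        c("with_phenotype", "without_phenotype"))
  p <- fisher_one_sided(tab, direction = direction)
  structure(
    list(table = tab, p_value = p, significant = p < alpha,
         direction = direction, alpha = alpha,
         genotypes = c(test = summary_test$genotype,
                       control = summary_control$genotype)),
    class = "penetrance_comparison")
}

#' @export
print.penetrance_comparison <- function(x, ...) {
  cat(sprintf(
    "<penetrance_comparison> %s vs %s: one-sided Fisher p = %.3g%s\n",
    x$genotypes[["test"]], x$genotypes[["control"]], x$p_value,
    if (x$significant) " *" else ""))
  print(x$table)
  invisible(x)
}
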