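#' Analytical SEC column constants
#'
#' Void and total volumes of the gel-filtration column. Defaults are the
#' constants of a Superose 6 PC 3.2/30 column: void volume 0.86 mL,
#' total volume 2.4 mL.
#'
#' @param v0 Void volume in mL.
#' @param vt Total column volume in mL; must exceed `v0`.
#' @return A `sec_column` list.
#' @export
sec_column <- function(v0 = 0.86, vt = 2.4) {
  if (!(v0 > 0)) stop("`v0` must be > 0")
  if (vt <= v0) stop("`vt` must exceed `v0`")
  structure(list(v0 = v0, vt = vt), class = "sec_column")
}

#' Gel-filtration partition coefficient
#'
#' `Kav = (Ve - Vo) / (Vt - Vo)`: the extent to which a protein
#' penetrates the gel-filtration matrix, 0 at the void volume and 1 at
#' the total column volume. Values outside `[0, 1]` indicate anomalous
#' elution (aggregation, matrix interaction) and trigger a warning, not
#' an error.
#'
#' @param ve Elution (retention) volume(s) in mL; vectorized.
#' @param column A [sec_column()].
#' @return Numeric partition coefficient(s).
#' @examples
#' kav(1.63)  # 0.5 on the default column
#' @export
kav <- function(ve, column = sec_column()) {
  stopifnot(inherits(column, "sec_column"))
  k <- (ve - column$v0) / (column$vt - column$v0)
  if (any(k < 0 | k > 1)) {
    warning("Kav outside [0, 1]: anomalous elution volume(s)")
  }
  k
}

#' Fit a log-molecular-weight calibration curve
#'
#' Ordinary least-squares fit of `log10(MW [kDa])` against `Kav` for a
#' set of gel-filtration standards, one curve per running buffer. The
#' linear relationship assumes the standards and samples share surface
#' chemistry and overall geometry.
#'
#' @param ve Elution volumes of the standards (mL).
#' @param mw Known molecular weights of the standards (kDa).
#' @param column A [sec_column()].
#' @return A `calibration_curve`: list with `slope`, `intercept`
#'   (of `log10(MW)` on `Kav`), `r_squared`, `n_standards`, `column`.
#' @export
fit_calibration <- function(ve, mw, column = sec_column()) {
  if (length(ve) != length(mw)) stop("`ve` and `mw` lengths differ")
  if (length(ve) < 2L) stop("need at least 2 standards")
  if (any(mw <= 0)) stop("molecular weights must be positive")
  k <- kav(ve, column)
  if (length(unique(k)) < 2L) stop("standards have identical Kav values")
  fit <- lm(log10(mw) ~ k)
  # r^2 from the definition: summary.lm() warns on exact-line standards
  tss <- sum((log10(mw) - mean(log10(mw)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2,
         n_standards = length(ve), column = column),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> log10(MW) = %.4f + %.4f * Kav (r^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n_standards))
  invisible(x)
}

#' Apparent molecular weight from a calibration curve
#'
#' Evaluates `10 ^ (intercept + slope * Kav(ve))` on the curve's column.
#'
#' @param curve A [calibration_curve][fit_calibration()].
#' @param ve Sample elution volume(s) in mL; vectorized.
#' @return Apparent molecular weight(s) in kDa.
#' @export
apparent_mw <- function(curve, ve) {
  stopifnot(inherits(curve, "calibration_curve"))
  10^(curve$intercept + curve$slope * kav(ve, curve$column))
}

#' Call the oligomeric state from an apparent molecular weight
#'
#' Rounds the apparent-to-monomer mass ratio to the nearest integer
#' multiple: below `cutpoints[1]` (default 1.5) is a monomer, between
#' the cutpoints a dimer, above `cutpoints[2]` (default 2.5) a higher
#' oligomer. The published judgement is qualitative ("close to that of a
#' dimer"); the cutpoints make it reproducible and are configurable.
#'
#' @param apparent Apparent molecular weight (kDa), `> 0`.
#' @param monomer Monomer molecular weight (kDa), `> 0`.
#' @param cutpoints Ratio cut-points `(monomer/dimer, dimer/higher)`.
#' @return An `oligomer_call`: list with `apparent_mw`, `monomer_mw`,
#'   `ratio`, `state` (`"monomer"`, `"dimer"` or `"higher"`).
#' @examples
#' call_oligomer(21.55, 12.3)$state  # "dimer"
#' call_oligomer(10.03, 10.5)$state  # "monomer"
#' @export
call_oligomer <- function(apparent, monomer, cutpoints = c(1.5, 2.5)) {
  if (!(apparent > 0) || !(monomer > 0)) stop("masses must be positive")
  stopifnot(length(cutpoints) == 2L, cutpoints[1] < cutpoints[2])
  ratio <- apparent / monomer
  state <- if (ratio < cutpoints[1]) "monomer"
           else if (ratio < cutpoints[2]) "dimer"
           else "higher"
  structure(
    list(apparent_mw = apparent, monomer_mw = monomer, ratio = ratio,
         state = state),
    class = "oligomer_call")
}

#' @export
print.oligomer_call <- function(x, ...) {
  cat(sprintf(
    "<oligomer_call> apparent %.2f kDa / monomer %.2f kDa = %.2f -> %s\n",
    x$apparent_mw, x$monomer_mw, x$ratio, x$state))
  invisible(x)
}
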