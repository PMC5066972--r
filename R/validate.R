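# Analytical method-validation statistics: calibration with LOD/LOQ,
# matrix effect, CV, S/N flags and the two-group comparison.

#' Fit a calibration curve with LOD/LOQ
#'
#' Ordinary least squares of response on concentration. The residual
#' standard error `se = sqrt(SSE / (n - 2))` drives the detection and
#' quantitation limits: `LOD = 3 se / slope`, `LOQ = 10 se / slope` (so
#' `LOQ / LOD = 10/3` exactly); the working range runs from the LOQ to the
#' highest calibrated concentration. When replicate responses are given
#' per concentration the fit uses the mean response per concentration
#' (`use = "means"`, the default, which matches how validation tables are
#' conventionally computed) or all replicates (`use = "all"`).
#'
#' @param concentrations mg/mL (>= 3 points, >= 2 distinct; include a 0
#'   blank row if measured).
#' @param responses responses (same length), or a matrix with one row per
#'   concentration and one column per replicate.
#' @param use `"means"` or `"all"` (replicate matrices only).
#' @return object of class `calibration_result`: `slope`, `se`,
#'   `intercept`, `r_squared`, `lod`, `loq`, `working_range`, `n_points`.
#' @export
fit_calibration <- function(concentrations, responses,
                            use = c("means", "all")) {
  use <- match.arg(use)
  if (is.matrix(responses)) {
    if (nrow(responses) != length(concentrations))
      stop("response matrix must have one row per concentration")
    if (use == "means") {
      responses <- rowMeans(responses)
    } else {
      concentrations <- rep(concentrations, ncol(responses))
      responses <- as.vector(responses)
    }
  }
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length")
  if (length(concentrations) < 3 || length(unique(concentrations)) < 2)
    stop("need >= 3 points over >= 2 distinct concentrations")
  fit <- stats::lm(responses ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope: uninformative assay")
  s <- suppressWarnings(summary(fit))  # noise-free fits warn harmlessly
  se <- s$sigma
  structure(list(
    slope = slope,
    se = se,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    lod = 3 * se / slope,
    loq = 10 * se / slope,
    working_range = c(10 * se / slope, max(concentrations)),
    n_points = length(concentrations),
    fit = fit
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration> slope ", signif(x$slope, 6), ", intercept ",
      signif(x$intercept, 6), ", SE ", signif(x$se, 6),
      ", R2 ", round(x$r_squared, 4), "\n  LOD ", signif(x$lod, 4),
      ", LOQ ", signif(x$loq, 4), " mg/mL; working range ",
      signif(x$working_range[1], 3), "-", signif(x$working_range[2], 3),
      " mg/mL (n = ", x$n_points, ")\n", sep = "")
  invisible(x)
}

#' Matrix effect (percent)
#'
#' Relative change of the internal standard's response in a biological
#' matrix versus the clean-solvent control:
#' `(response_matrix - response_control) / response_control x 100`;
#' negative values signal ion suppression.
#'
#' @param response_matrix IS response in the matrix.
#' @param response_control IS response in clean solvent (> 0).
#' @return percent.
#' @export
matrix_effect <- function(response_matrix, response_control) {
  if (any(response_control <= 0)) stop("control response must be > 0")
  (response_matrix - response_control) / response_control * 100
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 denominator) over the mean, in
#' percent.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(values) / m * 100
}

#' Signal-to-noise ratio with LOQ flag
#'
#' `apex / noise`, with a logical flag marking ratios below the standard
#' LOQ threshold of 10.
#'
#' @param signal_apex apex intensity.
#' @param blank_noise noise level from blank runs (> 0).
#' @return list with `s_n` and `below_loq`.
#' @export
snr <- function(signal_apex, blank_noise) {
  if (any(blank_noise <= 0)) stop("blank noise must be > 0")
  s <- signal_apex / blank_noise
  list(s_n = s, below_loq = s < 10)
}

#' Two-group comparison of normalised responses
#'
#' Two-sided two-sample t test, pooled-variance Student by default (Welch
#' optional), with significance tiers at p < 0.1 (`*`), p < 0.01 (`**`)
#' and p < 0.001 (`***`). The degenerate case (both groups constant and
#' equal) returns p = 1.
#'
#' @param group_a,group_b numeric responses (>= 2 each).
#' @param welch use Welch's unequal-variance test.
#' @param code optional proteoform code carried into the result.
#' @return object of class `group_comparison`: `mean_a`, `mean_b`,
#'   `cv_a`, `cv_b`, `t`, `p_value`, `significance`.
#' @export
compare_groups <- function(group_a, group_b, welch = FALSE,
                           code = NA_character_) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 values per group")
  degenerate <- stats::sd(group_a) == 0 && stats::sd(group_b) == 0
  if (degenerate && mean(group_a) == mean(group_b)) {
    t <- 0; p <- 1
  } else if (degenerate) {
    t <- Inf * sign(mean(group_a) - mean(group_b)); p <- 0
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = !welch)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.1) "*" else "n.s."
  structure(list(
    protein_code = code,
    mean_a = mean(group_a), mean_b = mean(group_b),
    cv_a = if (mean(group_a) != 0) stats::sd(group_a) / mean(group_a) * 100
           else NA_real_,
    cv_b = if (mean(group_b) != 0) stats::sd(group_b) / mean(group_b) * 100
           else NA_real_,
    t = t, p_value = p, significance = tier
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group comparison>", if (!is.na(x$protein_code)) x$protein_code,
      " mean A ", signif(x$mean_a, 5), " vs B ", signif(x$mean_b, 5),
      "; t = ", signif(x$t, 4), ", p = ", signif(x$p_value, 3), " ",
      x$significance, "\n", sep = "")
  invisible(x)
}
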