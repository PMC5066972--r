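# Extracted ion chromatograms, RT-window peak integration, internal
# standard normalisation and response ranking.

#' Extract an ion chromatogram over a proteoform's ion series
#'
#' Per scan, sums the intensities of all data points lying within the
#' series tolerance of any series ion m/z (each point contributes once even
#' when adjacent charge-state windows overlap). Extraction windows are
#' centred on the most-abundant-isotope (apex) ions by default, which is
#' how charge-state ion lists are reported for intact proteins; set
#' `target = "mono"` to centre on the monoisotopic ions.
#'
#' @param run a `spectra_run`.
#' @param series an [ion_series()].
#' @param target `"apex"` (default) or `"mono"`.
#' @return an object of class `eic_trace` with fields `rt`, `intensity`,
#'   and attributes recording the series and tolerance used.
#' @export
extract_eic <- function(run, series, target = c("apex", "mono")) {
  stopifnot(inherits(run, "spectra_run"), inherits(series, "ion_series"))
  target <- match.arg(target)
  tol <- attr(series, "tolerance")
  centers <- if (target == "apex") series$mz_apex else series$mz
  rng <- run$metadata$mz_range
  if (!is.null(rng)) {
    centers <- centers[centers >= rng[1] - tol & centers <= rng[2] + tol]
  }
  if (!length(centers))
    stop("all ions of '", attr(series, "proteoform_code"),
         "' fall outside the run's m/z range")
  sel <- logical(length(run$mz))
  for (ctr in centers) {
    lo <- findInterval(ctr - tol, run$mz) + 1L
    hi <- findInterval(ctr + tol, run$mz)
    if (hi >= lo) sel[lo:hi] <- TRUE
  }
  idx <- which(sel)
  intensity <- if (length(idx))
    colSums(run$intensity[idx, , drop = FALSE]) else
    numeric(length(run$rt))
  structure(list(rt = run$rt, intensity = intensity),
            proteoform_code = attr(series, "proteoform_code"),
            tolerance = tol, target = target, n_ions = length(centers),
            class = "eic_trace")
}

#' @export
print.eic_trace <- function(x, ...) {
  cat("<EIC> ", attr(x, "proteoform_code"), ": ", length(x$rt),
      " scans, ", attr(x, "n_ions"), " ions at +/-",
      attr(x, "tolerance"), " Th\n", sep = "")
  invisible(x)
}

#' Fraction of a proteoform's signal captured by its EIC windows
#'
#' Generator-side ground truth for EIC recovery: the fraction of a
#' proteoform's total generated ion count that falls inside the +/-
#' tolerance windows of its ion series (summing isotope abundances per
#' charge, weighted by the charge envelope used in `design`).
#'
#' @param design a [run_design()] containing the proteoform.
#' @param code proteoform code.
#' @param tolerance extraction half-width in Th.
#' @param target `"apex"` or `"mono"` window centres.
#' @return fraction in `[0, 1]`.
#' @export
eic_capture_fraction <- function(design, code, tolerance = 0.1,
                                 target = c("apex", "mono")) {
  target <- match.arg(target)
  e <- design$mix[[code]]
  if (is.null(e)) stop("no proteoform '", code, "' in the design")
  p <- e$proteoform
  pat <- p$isotope_pattern
  z <- p$charges
  cw <- stats::dnorm(z, e$charge_mean, e$charge_sigma)
  cw <- cw / sum(cw)
  cap <- 0
  for (j in seq_along(z)) {
    mz_k <- (pat$mass + z[j] * PROTON_MASS) / z[j]
    inside <- mz_k >= design$mz_range[1] & mz_k <= design$mz_range[2]
    ctr_mass <- if (target == "apex")
      p$mono_mass + p$apex_offset * NEUTRON_SPACING else p$mono_mass
    ctr <- (ctr_mass + z[j] * PROTON_MASS) / z[j]
    hit <- inside & abs(mz_k - ctr) <= tolerance
    cap <- cap + cw[j] * sum(pat$abundance[hit])
  }
  cap
}

#' Integrate an EIC peak over a retention-time window
#'
#' Trapezoidal area (intensity x minutes) over the closed window
#' `rt_center +/- window/2` with no baseline subtraction; the apex is the
#' scan of maximal intensity inside the window. Signal-to-noise uses the
#' median absolute intensity of blank traces over the same window when
#' blanks are supplied, otherwise it falls back (with a warning) to the
#' 10th percentile of the full trace.
#'
#' @param trace an `eic_trace`.
#' @param rt_center window centre in minutes.
#' @param window full window width in minutes (default 4).
#' @param blank_traces optional list of `eic_trace`s from analyte-free
#'   blank runs, used to estimate noise.
#' @return a list with `area`, `rt_apex`, `s_n`, `apex_intensity`, `noise`.
#' @export
integrate_peak <- function(trace, rt_center, window = 4.0,
                           blank_traces = NULL) {
  stopifnot(inherits(trace, "eic_trace"))
  if (window <= 0) stop("window must be > 0")
  lo <- rt_center - window / 2; hi <- rt_center + window / 2
  idx <- which(trace$rt >= lo & trace$rt <= hi)
  if (length(idx) == 0)
    stop("integration window [", lo, ", ", hi,
         "] does not overlap the trace")
  rt <- trace$rt[idx]; y <- trace$intensity[idx]
  area <- if (length(idx) > 1)
    sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) else 0
  apex_i <- which.max(y)
  noise <- NA_real_
  if (!is.null(blank_traces)) {
    bvals <- unlist(lapply(blank_traces, function(b) {
      bi <- which(b$rt >= lo & b$rt <= hi)
      b$intensity[bi]
    }))
    noise <- stats::median(abs(bvals))
    if (!is.finite(noise) || noise == 0) noise <- mean(abs(bvals))
  } else if (any(trace$intensity > 0)) {
    warning("no blank traces supplied; noise from the trace's ",
            "10th intensity percentile")
    noise <- stats::quantile(trace$intensity, 0.1, names = FALSE)
  }
  s_n <- if (is.finite(noise) && noise > 0) y[apex_i] / noise else NA_real_
  list(area = area, rt_apex = rt[apex_i], s_n = s_n,
       apex_intensity = y[apex_i], noise = noise)
}

#' Quantify all registry proteoforms in a run
#'
#' Builds each proteoform's ion series, extracts its EIC, and integrates at
#' the expected retention time, producing one quantitation row per
#' proteoform (the per-run analogue of a response table).
#'
#' @param run a `spectra_run`.
#' @param registry a `proteoform_registry`.
#' @param rt_window integration window in minutes (default 4).
#' @param tolerance EIC half-width in Th; default from the registry.
#' @param blank_runs optional list of blank `spectra_run`s for noise.
#' @param normalize if `TRUE` (default) and the registry declares an
#'   internal standard present in the run, adds IS-normalised responses.
#' @return a data frame (class `quant_table`) with columns
#'   `protein_code`, `rt_apex`, `area`, `s_n`, `normalized_response`.
#' @export
quantify_run <- function(run, registry, rt_window = 4.0, tolerance = NULL,
                         blank_runs = NULL, normalize = TRUE) {
  stopifnot(inherits(registry, "proteoform_registry"))
  tol <- tolerance %||% attr(registry, "tolerance") %||% 0.1
  is_code <- attr(registry, "internal_standard")
  rows <- lapply(registry, function(p) {
    ser <- ion_series(p, mz_window = run$metadata$mz_range %||% c(0, Inf),
                      tolerance = tol)
    if (attr(ser, "empty")) return(NULL)
    tr <- extract_eic(run, ser)
    blanks <- if (!is.null(blank_runs))
      lapply(blank_runs, extract_eic, series = ser) else NULL
    pk <- suppressWarnings(
      integrate_peak(tr, p$expected_rt, rt_window, blanks))
    data.frame(protein_code = p$protein_code, rt_apex = pk$rt_apex,
               area = pk$area, s_n = pk$s_n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$normalized_response <- NA_real_
  if (normalize && !is.null(is_code) && is_code %in% out$protein_code)
    out <- normalize_to_is(out, out[out$protein_code == is_code, ])
  class(out) <- c("quant_table", "data.frame")
  attr(out, "internal_standard") <- is_code
  out
}

#' Sum variant responses into a standard-level response
#'
#' The response of a commercial standard is the sum of the peak areas of
#' its individual protein variants.
#'
#' @param rows a data frame of quantitation rows (must have `area`).
#' @return summed area.
#' @export
summed_response <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0)
    stop("summed_response() needs at least one quantitation row")
  sum(rows$area)
}

#' Normalise responses to the internal standard
#'
#' Divides each row's area by the IS area; errors when the IS area is
#' absent or non-positive (a failed spike must not silently pass).
#'
#' @param rows data frame of quantitation rows.
#' @param is_row single row for the internal standard.
#' @return `rows` with `normalized_response = area / IS area`.
#' @export
normalize_to_is <- function(rows, is_row) {
  if (is.null(is_row) || nrow(is_row) != 1 || !is.finite(is_row$area) ||
      is_row$area <= 0)
    stop("internal-standard area is missing or non-positive ",
         "(failed spike?)")
  rows$normalized_response <- rows$area / is_row$area
  rows
}

#' Rank proteoforms by response
#'
#' Orders codes by descending response; responses within `tie_tol` relative
#' difference of the previous ranked response are reported as ties (the
#' "=" notation of ionisation-efficiency rankings). Inputs must be at equal
#' concentration for the ranking to mean ionisation efficiency.
#'
#' @param rows data frame with `protein_code` and a response column.
#' @param response_col column to rank on (default `"area"`).
#' @param tie_tol relative tie tolerance (default 0.02).
#' @return data frame with `protein_code`, `response`, `rank` (tied rows
#'   share a rank).
#' @export
rank_by_response <- function(rows, response_col = "area", tie_tol = 0.02) {
  stopifnot(nrow(rows) >= 1)
  ord <- order(-rows[[response_col]])
  resp <- rows[[response_col]][ord]
  rank <- integer(length(resp)); rank[1] <- 1L
  for (i in seq_along(resp)[-1]) {
    tied <- resp[i - 1] > 0 && (resp[i - 1] - resp[i]) / resp[i - 1] <= tie_tol
    rank[i] <- if (tied) rank[i - 1] else i
  }
  data.frame(protein_code = rows$protein_code[ord], response = resp,
             rank = rank)
}

#' Replicate summary of quantitation tables
#'
#' Combines per-run quantitation rows across replicates into mean, SD and
#' CV (%) per proteoform for both raw areas and IS-normalised responses.
#'
#' @param tables list of `quant_table`s from replicate runs.
#' @return data frame with per-proteoform replicate statistics.
#' @export
replicate_summary <- function(tables) {
  stopifnot(length(tables) >= 1)
  codes <- tables[[1]]$protein_code
  get <- function(col) vapply(tables, function(t)
    t[[col]][match(codes, t$protein_code)], numeric(length(codes)))
  a <- matrix(get("area"), nrow = length(codes))
  n <- matrix(get("normalized_response"), nrow = length(codes))
  r <- matrix(get("rt_apex"), nrow = length(codes))
  data.frame(
    protein_code = codes,
    rt_mean = rowMeans(r), rt_sd = apply(r, 1, stats::sd),
    area_mean = rowMeans(a), area_sd = apply(a, 1, stats::sd),
    area_cv = apply(a, 1, stats::sd) / rowMeans(a) * 100,
    norm_mean = rowMeans(n), norm_sd = apply(n, 1, stats::sd),
    norm_cv = apply(n, 1, stats::sd) / rowMeans(n) * 100
  )
}
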