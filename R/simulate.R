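# Synthetic LC-ESI-Q-TOF run generator.
#
# Emulates the acquisition regime the quantitation pipeline assumes:
# Gaussian elution profiles sampled every few seconds, intensity split over
# a discretized-Gaussian charge envelope, each charge state rendered as its
# isotope pattern convolved with a Gaussian analyzer peak shape at fixed
# resolving power, multiplicative lognormal replicate noise on peak area,
# multiplicative matrix suppression, and additive uniform detector noise.
#
# Intensity bookkeeping: every isotope peak is rendered so that the SUM of
# its profile (or centroid) point intensities equals its ion count. The
# total generated ion current of a proteoform therefore equals
# concentration x response_factor x (1 - suppression) exactly (noise-free,
# envelope fully inside the m/z window), and chromatographic "area" is a
# count sum rather than a density integral.

#' Describe a synthetic LC-MS run
#'
#' Captures acquisition settings and the proteoform mix. Per-proteoform
#' concentration/response-factor/retention parameters default to the values
#' stored in the supplied proteoforms.
#'
#' @param proteoforms a `proteoform_registry` or list of `proteoform`s to
#'   include as analytes.
#' @param concentrations numeric vector (recycled) of analyte
#'   concentrations in mg/mL.
#' @param is_code optional code of the internal-standard proteoform within
#'   `proteoforms` (spiked at `is_concentration`, not scaled by dilution).
#' @param is_concentration IS spike level in mg/mL (default 0.2).
#' @param response_factors per-analyte EIC response per mg/mL; defaults to
#'   each proteoform's `response_factor`.
#' @param rt_centers elution apexes in minutes; default `expected_rt`.
#' @param rt_sigma chromatographic peak SD in minutes (default 0.3 min,
#'   i.e. a ~1.2-min 4-sigma base width giving >= 20 scans per peak at a
#'   3-s scan period).
#' @param charge_mean,charge_sigma charge-envelope centre and SD over
#'   integer charge states; `charge_mean` defaults to mass/1200 which
#'   concentrates signal around 900-1800 m/z.
#' @param duration acquired analytical window in minutes (default 37.5).
#' @param rt_start retention time of the first scan in minutes (default
#'   2.5; the initial segment of a run is diverted to waste).
#' @param scan_period seconds between scans (default 3.0).
#' @param mz_range acquisition window in Th (default `c(600, 3000)`).
#' @param resolving_power analyzer m/dm at FWHM (default 60000).
#' @param suppression_factor multiplicative matrix ion-suppression in
#'   `[0, 1]` (0 = clean solvent).
#' @param replicate_cv lognormal replicate CV of peak area (fraction).
#' @param rt_jitter_sd between-run retention-time jitter SD in minutes
#'   (default 0).
#' @param noise_floor additive uniform noise ceiling per data point
#'   (counts; 0 disables noise).
#' @param mode `"profile"` (isotopes convolved with the analyzer peak
#'   shape, ~4 samples per FWHM) or `"centroid"` (one stick per isotope).
#' @param seed integer seed making the run reproducible.
#' @return an object of class `run_design`.
#' @export
run_design <- function(proteoforms, concentrations = 1, is_code = NULL,
                       is_concentration = 0.2, response_factors = NULL,
                       rt_centers = NULL, rt_sigma = 0.3,
                       charge_mean = NULL, charge_sigma = 3,
                       duration = 37.5, rt_start = 2.5, scan_period = 3.0,
                       mz_range = c(600, 3000), resolving_power = 60000,
                       suppression_factor = 0, replicate_cv = 0,
                       rt_jitter_sd = 0, noise_floor = 0,
                       mode = c("profile", "centroid"), seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(proteoforms, "proteoform")) proteoforms <- list(proteoforms)
  forms <- unclass(proteoforms)
  forms <- forms[vapply(forms, inherits, TRUE, "proteoform")]
  if (!length(forms)) stop("no proteoforms supplied")
  codes <- vapply(forms, `[[`, "", "protein_code")
  names(forms) <- codes
  n <- length(forms)
  conc <- rep_len(concentrations, n)
  rf <- if (is.null(response_factors))
    vapply(forms, `[[`, 0, "response_factor") else rep_len(response_factors, n)
  rtc <- if (is.null(rt_centers))
    vapply(forms, `[[`, 0, "expected_rt") else rep_len(rt_centers, n)
  if (anyNA(rf)) stop("missing response_factor for: ",
                      paste(codes[is.na(rf)], collapse = ", "))
  if (anyNA(rtc)) stop("missing rt_center for: ",
                       paste(codes[is.na(rtc)], collapse = ", "))
  cmean <- if (is.null(charge_mean))
    vapply(forms, function(p) p$mono_mass / 1200, 0) else
    rep_len(charge_mean, n)
  mix <- lapply(seq_len(n), function(i) list(
    proteoform = forms[[i]], concentration = conc[i],
    response_factor = rf[i], rt_center = rtc[i],
    rt_sigma = rep_len(rt_sigma, n)[i],
    charge_mean = cmean[i], charge_sigma = rep_len(charge_sigma, n)[i],
    is_spike = FALSE))
  names(mix) <- codes
  if (!is.null(is_code)) {
    if (!is_code %in% codes)
      stop("internal standard '", is_code, "' not in the supplied proteoforms")
    mix[[is_code]]$concentration <- is_concentration
    mix[[is_code]]$is_spike <- TRUE
  }
  if (scan_period <= 0 || duration <= 0) stop("invalid time settings")
  structure(list(
    mix = mix, duration = duration, rt_start = rt_start,
    scan_period = scan_period, mz_range = mz_range,
    resolving_power = resolving_power,
    suppression_factor = suppression_factor, replicate_cv = replicate_cv,
    rt_jitter_sd = rt_jitter_sd, noise_floor = noise_floor,
    mode = mode, seed = as.integer(seed)
  ), class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("<run design> ", length(x$mix), " proteoforms; ",
      floor(x$duration * 60 / x$scan_period), " scans every ",
      x$scan_period, " s; m/z ", x$mz_range[1], "-", x$mz_range[2],
      "; R = ", x$resolving_power, "; mode ", x$mode, "\n", sep = "")
  invisible(x)
}

# per-charge rendering template for one proteoform: grid positions and the
# unit-intensity profile (sums to 1 over the charge's points)
charge_template <- function(p, z, mz_range, resolving_power, mode) {
  pat <- p$isotope_pattern
  mz_k <- (pat$mass + z * PROTON_MASS) / z
  inside <- mz_k >= mz_range[1] & mz_k <= mz_range[2]
  if (!any(inside)) return(NULL)
  frac_inside <- sum(pat$abundance[inside])
  if (mode == "centroid") {
    return(list(mz = mz_k[inside],
                unit = pat$abundance[inside],
                frac_inside = frac_inside))
  }
  sigma <- fwhm_to_sigma(peak_fwhm(mean(mz_k), resolving_power))
  step <- peak_fwhm(mean(mz_k), resolving_power) / 4
  lo <- max(min(mz_k[inside]) - 4 * sigma, mz_range[1])
  hi <- min(max(mz_k[inside]) + 4 * sigma, mz_range[2])
  grid <- seq(lo, hi, by = step)
  unit <- numeric(length(grid))
  for (k in which(inside)) {
    g <- stats::dnorm(grid, mz_k[k], sigma)
    s <- sum(g)
    if (s > 0) unit <- unit + pat$abundance[k] * g / s
  }
  list(mz = grid, unit = unit, frac_inside = frac_inside)
}

#' Simulate one LC-MS run
#'
#' Renders each proteoform of the design as a Gaussian elution profile
#' whose total ion count is `concentration x response_factor x
#' (1 - suppression_factor) x lognormal(1, replicate_cv)`, split over the
#' charge envelope and isotope pattern. Deterministic for a given seed.
#'
#' @param design a [run_design()].
#' @param seed optional seed overriding `design$seed` (used by the
#'   replicate drivers).
#' @return an object of class `spectra_run` with fields `rt` (minutes,
#'   strictly increasing), `mz` (shared, sorted m/z grid in Th),
#'   `intensity` (matrix, points x scans), `metadata` (acquisition
#'   settings, seed, rendering mode, dropped-charge log) and
#'   `ground_truth` (per-proteoform generated ion counts and capture
#'   fractions).
#' @export
simulate_run <- function(design, seed = NULL) {
  stopifnot(inherits(design, "run_design"))
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  set.seed(seed)
  n_scans <- floor(design$duration * 60 / design$scan_period)
  if (n_scans < 1) stop("design yields no scans")
  dt_min <- design$scan_period / 60
  rt <- design$rt_start + (seq_len(n_scans) - 1) * dt_min

  templates <- list(); log <- character(); truth <- list()
  for (e in design$mix) {
    p <- e$proteoform
    z <- e$proteoform$charges
    cw <- stats::dnorm(z, e$charge_mean, e$charge_sigma)
    if (sum(cw) == 0) cw <- rep(1, length(z))
    cw <- cw / sum(cw)
    tpl <- list(); keep_w <- numeric()
    for (j in seq_along(z)) {
      t <- charge_template(p, z[j], design$mz_range,
                           design$resolving_power, design$mode)
      if (is.null(t)) {
        log <- c(log, sprintf("dropped %s z=%d (outside m/z window)",
                              p$protein_code, z[j]))
        next
      }
      t$weight <- cw[j] * t$frac_inside
      if (t$frac_inside < 1 - 1e-9)
        log <- c(log, sprintf(
          "clipped %s z=%d (%.1f%% of isotopes outside window)",
          p$protein_code, z[j], 100 * (1 - t$frac_inside)))
      tpl[[length(tpl) + 1]] <- t
      keep_w <- c(keep_w, t$weight)
    }
    if (!length(tpl)) {
      warning("proteoform '", p$protein_code,
              "' fully outside the m/z window; omitted")
      log <- c(log, sprintf("omitted %s (envelope outside window)",
                            p$protein_code))
      next
    }
    templates[[p$protein_code]] <- list(entry = e, charges = tpl)
  }

  # assemble the shared m/z grid
  seg_mz <- unlist(lapply(templates, function(t)
    unlist(lapply(t$charges, `[[`, "mz"))))
  if (is.null(seg_mz)) seg_mz <- numeric(0)
  ord <- order(seg_mz)
  mz <- unname(seg_mz[ord])
  inv <- integer(length(ord)); inv[ord] <- seq_along(ord)

  intensity <- matrix(0, nrow = length(mz), ncol = n_scans)
  offset <- 0L
  for (t in templates) {
    e <- t$entry
    total <- e$concentration * e$response_factor *
      (1 - design$suppression_factor)
    if (design$replicate_cv > 0 && total > 0) {
      sdlog <- sqrt(log(1 + design$replicate_cv^2))
      total <- total * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
    rtc <- e$rt_center +
      if (design$rt_jitter_sd > 0) stats::rnorm(1, 0, design$rt_jitter_sd)
      else 0
    w <- stats::dnorm(rt, rtc, e$rt_sigma)
    if (sum(w) > 0) w <- w / sum(w)
    profile <- unlist(lapply(t$charges, function(ch) ch$weight * ch$unit))
    npts <- length(profile)
    idx <- inv[offset + seq_len(npts)]
    if (total > 0 && sum(w) > 0)
      intensity[idx, ] <- intensity[idx, ] + total * (profile %o% w)
    truth[[e$proteoform$protein_code]] <- list(
      total_counts = if (sum(w) > 0) total else 0,
      rt_center = rtc,
      envelope_fraction = sum(vapply(t$charges, `[[`, 0, "weight")))
    offset <- offset + npts
  }
  if (design$noise_floor > 0 && length(mz))
    intensity <- intensity +
      matrix(stats::runif(length(mz) * n_scans, 0, design$noise_floor),
             nrow = length(mz))

  structure(list(
    rt = rt, mz = mz, intensity = intensity,
    metadata = list(seed = seed, mode = design$mode,
                    scan_period = design$scan_period,
                    rt_start = design$rt_start,
                    mz_range = design$mz_range,
                    resolving_power = design$resolving_power,
                    centroided = design$mode == "centroid",
                    log = log),
    ground_truth = truth
  ), class = "spectra_run")
}

#' @export
print.spectra_run <- function(x, ...) {
  cat("<spectra run> ", length(x$rt), " scans, RT ",
      round(min(x$rt), 2), "-", round(max(x$rt), 2), " min, ",
      length(x$mz), " m/z points (",
      if (isTRUE(x$metadata$centroided)) "centroid" else "profile",
      ")\n", sep = "")
  invisible(x)
}

#' Total generated ion current of a spectra run
#'
#' Sum of all data-point intensities over all scans (a count, because of
#' the generator's sum-normalised rendering).
#' @param run a `spectra_run`.
#' @export
total_ion_current <- function(run) sum(run$intensity)

#' Simulate a dilution series
#'
#' One run per concentration and replicate. Analyte concentrations in the
#' design are scaled by each series concentration (a 0 mg/mL blank yields
#' noise-only signal for the analytes); an IS spike, if present, stays at
#' its fixed level. Per-run seeds derive deterministically from the design
#' seed.
#'
#' @param design a [run_design()] describing the standard at 1 mg/mL.
#' @param concentrations numeric vector of nominal concentrations (mg/mL).
#' @param replicates runs per concentration (>= 1).
#' @return a list of `spectra_run`s with attributes `concentration` and
#'   `replicate` (parallel vectors).
#' @export
simulate_dilution_series <- function(design, concentrations,
                                     replicates = 2L) {
  stopifnot(inherits(design, "run_design"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  runs <- list(); conc_v <- numeric(); rep_v <- integer()
  k <- 0L
  for (ci in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      d <- design
      for (code in names(d$mix)) {
        if (!d$mix[[code]]$is_spike)
          d$mix[[code]]$concentration <-
            design$mix[[code]]$concentration * concentrations[ci]
      }
      runs[[k]] <- simulate_run(d, seed = design$seed + 131L * ci + r)
      conc_v[k] <- concentrations[ci]; rep_v[k] <- r
    }
  }
  structure(runs, concentration = conc_v, replicate = rep_v)
}

#' Simulate a two-group (breed-contrast) study
#'
#' Replicate runs for two designs sharing acquisition settings but
#' differing in proteoform concentrations, each spiked with the same IS.
#'
#' @param design_a,design_b [run_design()]s for the two groups.
#' @param replicates runs per group (>= 1).
#' @return `list(a = runs, b = runs)`.
#' @export
simulate_two_group_study <- function(design_a, design_b, replicates = 3L) {
  stopifnot(inherits(design_a, "run_design"),
            inherits(design_b, "run_design"))
  if (replicates < 1) stop("replicates must be >= 1")
  shared <- c("duration", "scan_period", "mz_range", "resolving_power",
              "rt_start", "mode")
  for (f in shared)
    if (!identical(design_a[[f]], design_b[[f]]))
      stop("group designs must share acquisition setting '", f, "'")
  list(
    a = lapply(seq_len(replicates), function(r)
      simulate_run(design_a, seed = design_a$seed + r)),
    b = lapply(seq_len(replicates), function(r)
      simulate_run(design_b, seed = design_b$seed + 7919L + r))
  )
}

#' Draw replicate responses from the generator's area-level model
#'
#' The run generator's peak areas follow, by construction,
#' `concentration x response_factor x (1 - suppression) x multiplicative
#' lognormal(mean 1, CV = replicate_cv)` noise. This fast path samples that
#' distributional contract directly (no spectra), for large resampling
#' studies of downstream statistics; a test verifies that full-run EIC
#' areas follow the same law.
#'
#' @param design a [run_design()].
#' @param replicates number of replicate draws.
#' @param seed RNG seed.
#' @return matrix (replicates x proteoforms) of response draws.
#' @export
simulate_responses <- function(design, replicates, seed = design$seed) {
  stopifnot(inherits(design, "run_design"))
  set.seed(seed)
  sdlog <- sqrt(log(1 + design$replicate_cv^2))
  means <- vapply(design$mix, function(e)
    e$concentration * e$response_factor * (1 - design$suppression_factor), 0)
  out <- vapply(means, function(m) {
    if (design$replicate_cv > 0)
      m * stats::rlnorm(replicates, -sdlog^2 / 2, sdlog)
    else rep(m, replicates)
  }, numeric(replicates))
  if (replicates == 1) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, names(design$mix)))
  out
}
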