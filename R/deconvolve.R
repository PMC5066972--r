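# Charge-envelope deconvolution to neutral monoisotopic mass.
#
# A deliberately transparent replacement for vendor maximum-entropy
# deconvolution: average spectra over an RT range, pick profile peaks,
# group them into isotope clusters, infer the charge from the isotope
# spacing, convert the tallest isotope to a neutral mass, correct it to the
# monoisotopic species through the averagine most-abundant-offset (so the
# step stays independent of any registry identity), and pool estimates
# across charge states. Isotope-unresolved species (the serum-albumin
# case) fall back to a charge-ladder average-mass estimate, flagged.

#' Average spectra over a retention-time range
#'
#' Mean intensity per m/z grid point across the scans whose RT falls in
#' `rt_range` (profile runs share one grid; centroid runs merge identical
#' stick positions).
#'
#' @param run a `spectra_run`.
#' @param rt_range numeric length-2 in minutes.
#' @return a list with `mz`, `intensity` and a `centroided` flag, class
#'   `spectrum`.
#' @export
average_spectra <- function(run, rt_range = range(run$rt)) {
  stopifnot(inherits(run, "spectra_run"))
  idx <- which(run$rt >= rt_range[1] & run$rt <= rt_range[2])
  if (!length(idx))
    stop("rt_range [", rt_range[1], ", ", rt_range[2],
         "] selects no scans")
  structure(list(mz = run$mz,
                 intensity = rowMeans(run$intensity[, idx, drop = FALSE]),
                 centroided = isTRUE(run$metadata$centroided)),
            class = "spectrum")
}

#' Pick centroided peaks from a profile spectrum
#'
#' Local maxima above `min_snr` times the spectrum noise (median absolute
#' deviation of intensity scaled by 1.4826), centroided by a 3-point
#' parabola on log intensity (exact for Gaussian peaks), with a per-peak
#' FWHM estimate from the parabola curvature. Centroid input is passed
#' through (above threshold).
#'
#' @param spectrum a `spectrum` (see [average_spectra()]).
#' @param min_snr minimal S/N for a peak (default 5).
#' @return data frame with `mz`, `intensity`, `fwhm`, `s_n` (possibly
#'   empty).
#' @export
pick_peaks <- function(spectrum, min_snr = 5) {
  if (min_snr <= 0) stop("min_snr must be > 0")
  mz <- spectrum$mz; y <- spectrum$intensity
  empty <- data.frame(mz = numeric(), intensity = numeric(),
                      fwhm = numeric(), s_n = numeric(),
                      prominence = numeric())
  if (length(y) < 3) return(empty)
  noise <- stats::mad(y, constant = 1.4826)
  if (noise == 0) noise <- max(mean(y) * 1e-6, .Machine$double.eps)
  if (isTRUE(spectrum$centroided)) {
    keep <- y > min_snr * noise
    return(data.frame(mz = mz[keep], intensity = y[keep],
                      fwhm = NA_real_, s_n = y[keep] / noise,
                      prominence = 1))
  }
  i <- 2:(length(y) - 1)
  is_max <- y[i] >= y[i - 1] & y[i] > y[i + 1] & y[i] > min_snr * noise
  apex <- i[is_max]
  if (!length(apex)) return(empty)
  # prominence: fractional dip to the higher of the two valleys separating
  # an apex from its neighbours; ~1 for baseline-resolved peaks, ~0 for
  # ripple riding on an unresolved envelope
  valleys <- vapply(seq_along(apex), function(k) {
    left <- if (k == 1) min(y[1:apex[1]]) else
      min(y[apex[k - 1]:apex[k]])
    right <- if (k == length(apex)) min(y[apex[k]:length(y)]) else
      min(y[apex[k]:apex[k + 1]])
    max(left, right)
  }, 0)
  prominence <- 1 - valleys / y[apex]
  out <- lapply(seq_along(apex), function(kk) {
    j <- apex[kk]
    y3 <- y[(j - 1):(j + 1)]; x3 <- mz[(j - 1):(j + 1)]
    if (any(y3 <= 0)) {
      return(data.frame(mz = mz[j], intensity = y[j], fwhm = NA_real_,
                        s_n = y[j] / noise, prominence = prominence[kk]))
    }
    ly <- log(y3)
    d <- (x3[3] - x3[1]) / 2
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom >= 0) {
      return(data.frame(mz = mz[j], intensity = y[j], fwhm = NA_real_,
                        s_n = y[j] / noise, prominence = prominence[kk]))
    }
    shift <- 0.5 * (ly[1] - ly[3]) / denom * d
    sigma <- sqrt(-d^2 / denom)
    data.frame(mz = mz[j] + shift,
               intensity = exp(ly[2] - (ly[1] - ly[3])^2 / (8 * denom)),
               fwhm = 2 * sqrt(2 * log(2)) * sigma,
               s_n = y[j] / noise, prominence = prominence[kk])
  })
  out <- do.call(rbind, out)
  out[order(out$mz), , drop = FALSE]
}

#' Infer charge from isotope spacing
#'
#' `z = round(s_n / median adjacent spacing)` with the averagine neutron
#' spacing `s_n = 1.00235` Da; requires at least three centroids. When the
#' spacing dispersion (median absolute relative deviation) exceeds 20% the
#' cluster is reported unresolved, triggering the average-mass path.
#'
#' @param mz sorted centroid m/z values of one isotope cluster.
#' @return list with `z` (integer or `NA`), `resolved` flag, `dispersion`.
#' @export
infer_charge <- function(mz) {
  mz <- sort(mz)
  if (length(mz) < 3)
    return(list(z = NA_integer_, resolved = FALSE, dispersion = NA_real_))
  sp <- diff(mz)
  med <- stats::median(sp)
  disp <- stats::median(abs(sp - med)) / med
  z <- as.integer(round(NEUTRON_SPACING / med))
  if (!is.finite(disp) || disp > 0.2 || is.na(z) || z < 1 || z > 60)
    return(list(z = NA_integer_, resolved = FALSE, dispersion = disp))
  list(z = z, resolved = TRUE, dispersion = disp)
}

# Monoisotopic anchor for one charge-resolved isotope cluster.
#
# A plain "tallest isotope minus averagine most-abundant offset" rule is
# off by one neutron for compositions that deviate from averagine (milk
# caseins carry up to 14 phosphates: P and O add mass with almost no
# isotope spread, sulfur-rich whey proteins add extra spread). The
# envelope's variance encodes that deviation, so the correction scales the
# averagine mean offset by the observed/predicted variance ratio
# (moment-matched averagine), then snaps the tallest isotope onto the
# neutron comb. Moments on both sides use the same relative-intensity
# cutoff so peak-picking truncation cancels.
cluster_mono_mass <- function(m, intensity, rel_cutoff = 0.05) {
  keep <- intensity >= rel_cutoff * max(intensity)
  m <- m[keep]; intensity <- intensity[keep]
  w <- intensity / sum(intensity)
  m_wm <- sum(w * m)
  v_obs <- sum(w * (m - m_wm)^2)
  mom <- averagine_moments(m_wm, rel_cutoff)
  mu <- if (mom$var > 0 && v_obs > 0)
    mom$mean * (v_obs / mom$var) else mom$mean
  mono0 <- m_wm - mu
  m_tallest <- m[which.max(intensity)]
  k <- round((m_tallest - mono0) / NEUTRON_SPACING)
  m_tallest - k * NEUTRON_SPACING
}

# truncation-matched first/second moments (about the monoisotopic species)
# of the averagine isotope pattern at mass M, cached on a 50-Da grid
averagine_moments <- local({
  cache <- new.env(parent = emptyenv())
  function(M, rel_cutoff) {
    key <- paste0(round(M / 50), "_", rel_cutoff)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    comp <- averagine_composition(round(M / 50) * 50)
    pat <- isotope_distribution(comp, prune = 1e-6)
    keep <- pat$abundance >= rel_cutoff * max(pat$abundance)
    ab <- pat$abundance[keep] / sum(pat$abundance[keep])
    mass <- pat$mass[keep]
    mwm <- sum(ab * mass)
    out <- list(mean = mwm - monoisotopic_mass(comp),
                var = sum(ab * (mass - mwm)^2))
    cache[[key]] <- out
    out
  }
})

# split sorted centroids into isotope clusters: a gap larger than
# `gap` Th (isotope spacings never exceed ~1.003) starts a new cluster
split_clusters <- function(peaks, gap = 1.1) {
  if (nrow(peaks) == 0) return(list())
  breaks <- c(0, which(diff(peaks$mz) > gap), nrow(peaks))
  lapply(seq_len(length(breaks) - 1), function(i)
    peaks[(breaks[i] + 1):breaks[i + 1], , drop = FALSE])
}

#' Deconvolute a spectrum to neutral masses
#'
#' Pipeline: pick peaks, split into isotope clusters, infer each cluster's
#' charge from its isotope spacing, convert the cluster's tallest isotope
#' to a neutral mass, subtract `most_abundant_offset x 1.00235` of the
#' averagine composition at that mass to reach the monoisotopic species,
#' and pool estimates from different charge states agreeing within
#' `mass_tol_ppm` into intensity-weighted means. Unresolved clusters are
#' combined through a charge-ladder fit into a flagged average-mass result.
#'
#' @param spectrum a `spectrum`.
#' @param charge_range admissible charges (default `c(1, 60)`).
#' @param mass_tol_ppm cross-charge clustering tolerance (default 20 ppm).
#' @param min_snr peak-picking threshold (default 5).
#' @param min_charges minimum supporting charge states to report a mass
#'   (default 2).
#' @return data frame of class `neutral_mass_peaks`: `mass` (monoisotopic,
#'   or average when `average_only`), `intensity`, `s_n`, `fwhm` (Da),
#'   `resolution` (mass/FWHM), `n_charges`, `charges`, `average_only`.
#' @export
deconvolute <- function(spectrum, charge_range = c(1, 60),
                        mass_tol_ppm = 20, min_snr = 5, min_charges = 2) {
  peaks <- pick_peaks(spectrum, min_snr)
  empty <- data.frame(mass = numeric(), intensity = numeric(),
                      s_n = numeric(), fwhm = numeric(),
                      resolution = numeric(), n_charges = integer(),
                      charges = character(), average_only = logical())
  class(empty) <- c("neutral_mass_peaks", "data.frame")
  if (nrow(peaks) < 1) return(empty)
  clusters <- split_clusters(peaks)
  est <- list(); unresolved <- list()
  for (cl in clusters) {
    ic <- infer_charge(cl$mz)
    med_prom <- stats::median(cl$prominence, na.rm = TRUE)
    modulated <- !is.finite(med_prom) || med_prom > 0.3
    if (!ic$resolved || !modulated ||
        ic$z < charge_range[1] || ic$z > charge_range[2]) {
      # keep the cluster's intensity-weighted centroid for the
      # average-mass ladder
      unresolved[[length(unresolved) + 1]] <- data.frame(
        mz = sum(cl$mz * cl$intensity) / sum(cl$intensity),
        intensity = sum(cl$intensity), s_n = max(cl$s_n),
        fwhm = stats::median(cl$fwhm, na.rm = TRUE))
      next
    }
    tallest <- which.max(cl$intensity)
    est[[length(est) + 1]] <- data.frame(
      mass = cluster_mono_mass(neutral_mass(cl$mz, ic$z), cl$intensity),
      intensity = sum(cl$intensity), z = ic$z, s_n = max(cl$s_n),
      fwhm_mz = cl$fwhm[tallest])
  }
  out <- list()
  if (length(est)) {
    est <- do.call(rbind, est)
    est <- est[order(est$mass), , drop = FALSE]
    grp <- cumsum(c(1, diff(est$mass) / est$mass[-1] > mass_tol_ppm * 1e-6))
    groups <- lapply(unique(grp), function(g)
      est[grp == g, , drop = FALSE])
    # merge integer-neutron offset artifacts: short clusters at the
    # envelope edges occasionally mis-anchor by a neutron or few; fold
    # weaker groups lying on a stronger group's comb into it. A genuine
    # minor species off the comb is never swallowed; one sitting exactly
    # an integer number of neutrons away within tolerance is a documented
    # blind spot of registry-free deconvolution.
    gi <- vapply(groups, function(e) sum(e$intensity), 0)
    ord <- order(-gi)
    owner <- seq_along(groups)
    for (i in ord) {
      if (owner[i] != i) next
      mi <- sum(groups[[i]]$mass * groups[[i]]$intensity) / gi[i]
      for (j in seq_along(groups)) {
        if (j == i || owner[j] != j) next
        mj <- sum(groups[[j]]$mass * groups[[j]]$intensity) / gi[j]
        if (abs(mj - mi) > 8 || gi[j] >= gi[i]) next
        k <- round((mj - mi) / NEUTRON_SPACING)
        if (abs(mj - k * NEUTRON_SPACING - mi) / mi <= mass_tol_ppm * 1e-6) {
          shifted <- groups[[j]]
          shifted$mass <- shifted$mass - k * NEUTRON_SPACING
          groups[[i]] <- rbind(groups[[i]], shifted)
          owner[j] <- i
        }
      }
    }
    for (g in which(owner == seq_along(groups))) {
      e <- groups[[g]]
      if (length(unique(e$z)) < min_charges) next
      w <- e$intensity / sum(e$intensity)
      mass <- sum(e$mass * w)
      fwhm_da <- stats::median(e$fwhm_mz * e$z, na.rm = TRUE)
      out[[length(out) + 1]] <- data.frame(
        mass = mass, intensity = sum(e$intensity), s_n = max(e$s_n),
        fwhm = fwhm_da,
        resolution = if (is.finite(fwhm_da) && fwhm_da > 0)
          mass / fwhm_da else NA_real_,
        n_charges = length(unique(e$z)),
        charges = paste(sort(unique(e$z)), collapse = ";"),
        average_only = FALSE)
    }
  }
  if (length(unresolved) >= 3) {
    un <- do.call(rbind, unresolved)
    un <- un[order(-un$mz), , drop = FALSE]  # descending m/z = ascending z
    lad <- list()
    for (i in seq_len(nrow(un) - 1)) {
      m1 <- un$mz[i]; m2 <- un$mz[i + 1]
      if (m1 - m2 <= 0) next
      z2 <- round((m1 - PROTON_MASS) / (m1 - m2))
      if (z2 < charge_range[1] + 1 || z2 > charge_range[2]) next
      lad[[length(lad) + 1]] <- data.frame(
        mass = neutral_mass(m2, z2), z = z2,
        intensity = un$intensity[i + 1], fwhm_mz = un$fwhm[i + 1],
        s_n = un$s_n[i + 1])
    }
    if (length(lad) >= 2) {
      lad <- do.call(rbind, lad)
      med <- stats::median(lad$mass)
      keep <- abs(lad$mass - med) / med < 1e-3
      lad <- lad[keep, , drop = FALSE]
      if (nrow(lad) >= 2) {
        w <- lad$intensity / sum(lad$intensity)
        mass <- sum(lad$mass * w)
        fwhm_da <- stats::median(lad$fwhm_mz * lad$z, na.rm = TRUE)
        out[[length(out) + 1]] <- data.frame(
          mass = mass, intensity = sum(lad$intensity), s_n = max(lad$s_n),
          fwhm = fwhm_da,
          resolution = if (is.finite(fwhm_da) && fwhm_da > 0)
            mass / fwhm_da else NA_real_,
          n_charges = length(unique(lad$z)),
          charges = paste(sort(unique(lad$z)), collapse = ";"),
          average_only = TRUE)
      }
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neutral_mass_peaks", "data.frame")
  out
}

#' Match deconvoluted masses to registry identities
#'
#' Nearest-theoretical-mass assignment within `max_ppm`; average-only
#' results are matched against average masses. Candidate ties within 1 ppm
#' are reported ambiguous. Unmatched peaks are returned unassigned.
#'
#' @param peaks a `neutral_mass_peaks` data frame.
#' @param registry a `proteoform_registry`.
#' @param max_ppm assignment tolerance (default 60 ppm, covering the worst
#'   curated-mass discrepancy of the milk panel).
#' @return data frame of class `identifications` with `protein_code`
#'   (`NA` when unassigned), `observed_mass`, `theoretical_mass`,
#'   `mass_difference` (theoretical - observed), `error_ppm`, `ambiguous`.
#' @export
match_identities <- function(peaks, registry, max_ppm = 60) {
  stopifnot(inherits(registry, "proteoform_registry"))
  if (!length(registry)) stop("empty registry")
  # curated masses are monoisotopic except for average-only entries, where
  # the curated value is itself an average mass
  th_mono <- vapply(registry, function(p)
    if (is.na(p$curated_mass)) p$mono_mass else p$curated_mass, 0)
  avg_only <- vapply(registry, `[[`, TRUE, "average_only")
  codes <- vapply(registry, `[[`, "", "protein_code")
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    obs <- peaks$mass[i]
    use_avg <- isTRUE(peaks$average_only[i])
    cand <- which(avg_only == use_avg)
    if (!length(cand))
      return(data.frame(protein_code = NA_character_, observed_mass = obs,
                        theoretical_mass = NA_real_,
                        mass_difference = NA_real_, error_ppm = NA_real_,
                        ambiguous = FALSE))
    ppm <- abs(ppm_error(th_mono[cand], obs))
    best <- which.min(ppm)
    if (ppm[best] > max_ppm)
      return(data.frame(protein_code = NA_character_, observed_mass = obs,
                        theoretical_mass = NA_real_,
                        mass_difference = NA_real_, error_ppm = NA_real_,
                        ambiguous = FALSE))
    amb <- sum(ppm <= ppm[best] + 1) > 1
    j <- cand[best]
    data.frame(protein_code = codes[j], observed_mass = obs,
               theoretical_mass = th_mono[j],
               mass_difference = th_mono[j] - obs,
               error_ppm = ppm_error(th_mono[j], obs), ambiguous = amb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("identifications", "data.frame")
  out
}
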