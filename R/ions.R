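# Charge-state m/z arithmetic and ion series.

#' m/z of a multiply protonated ion
#'
#' Standard positive-mode ESI relation `(M + z * m_p) / z` with the proton
#' mass `m_p = 1.007276466` Da.
#'
#' @param M neutral mass in Daltons (> 0).
#' @param z charge (number of protons, integer >= 1); vectorised.
#' @return m/z in Thomson.
#' @export
ion_mz <- function(M, z) {
  if (any(M <= 0)) stop("M must be > 0")
  if (any(z < 1) || any(z != round(z))) stop("z must be an integer >= 1")
  (M + z * PROTON_MASS) / z
}

#' Neutral mass from an observed m/z and charge
#' @param mz observed m/z (Th).
#' @param z charge.
#' @return neutral mass in Daltons.
#' @export
neutral_mass <- function(mz, z) (mz - PROTON_MASS) * z

#' Parts-per-million mass error
#'
#' Signed as `(theoretical - observed) / theoretical * 1e6`: positive when
#' the observed mass is lighter than the theoretical one (the convention of
#' deconvolution report tables).
#'
#' @param theoretical theoretical mass in Daltons (> 0).
#' @param observed observed mass in Daltons.
#' @return error in ppm.
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  (theoretical - observed) / theoretical * 1e6
}

#' Mass difference `m2 - m1`
#'
#' Convenience for modification deltas between proteoforms (e.g. one
#' phosphate, one O-glycan).
#'
#' @param m1,m2 masses in Daltons.
#' @export
mass_delta <- function(m1, m2) m2 - m1

#' Charge-state ion series of a proteoform
#'
#' Computes, for every charge in `p$charges`, the monoisotopic ion m/z and
#' the most-abundant-isotope (apex) ion m/z, keeping entries whose apex m/z
#' lies inside the acquisition window. Extraction tolerances are a symmetric
#' half-width in Thomson.
#'
#' @param p a `proteoform` (see [proteoform()]).
#' @param mz_window numeric length-2 acquisition window `(lo, hi)` in Th.
#' @param tolerance extraction half-width in Th (default 0.1).
#' @return a data frame of class `ion_series` with columns `z`, `mz`
#'   (monoisotopic), `mz_apex`; attributes `proteoform_code`, `tolerance`,
#'   and `empty` flag. m/z decreases strictly with z.
#' @export
ion_series <- function(p, mz_window = c(600, 3000), tolerance = 0.1) {
  stopifnot(inherits(p, "proteoform"))
  z <- sort(unique(as.integer(p$charges)))
  if (!length(z)) stop("proteoform '", p$protein_code, "' has no charges")
  mz <- ion_mz(p$mono_mass, z)
  apex_shift <- p$apex_offset * NEUTRON_SPACING
  mz_apex <- ion_mz(p$mono_mass + apex_shift, z)
  keep <- mz_apex >= mz_window[1] & mz_apex <= mz_window[2]
  out <- data.frame(z = z[keep], mz = mz[keep], mz_apex = mz_apex[keep])
  out <- out[order(out$z), , drop = FALSE]
  empty <- nrow(out) == 0
  if (empty)
    warning("no ion of '", p$protein_code, "' falls inside the m/z window [",
            mz_window[1], ", ", mz_window[2], "]")
  structure(out,
            proteoform_code = p$protein_code,
            tolerance = tolerance,
            empty = empty,
            class = c("ion_series", "data.frame"))
}
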