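# Isotope-pattern computation (nominal-offset convolution) and the
# Gaussian analyzer peak-shape model.
#
# Patterns are coarse-grained over nominal neutron offsets k = 0, 1, 2, ...
# above the monoisotopic species; each offset carries the abundance-weighted
# exact mass of the isotopologues that fall on it. Fine isotopic structure
# is irrelevant at a resolving power of 60,000 for 14-70 kDa proteins.

# convolve two (abundance, mass-by-offset) patterns; both are lists with
# integer offsets starting at 0 and aligned vectors `ab`, `mass`
pattern_convolve <- function(a, b) {
  na <- length(a$ab); nb <- length(b$ab)
  n <- na + nb - 1
  ab <- numeric(n); wm <- numeric(n)
  for (i in seq_len(na)) {
    idx <- i:(i + nb - 1)
    contrib <- a$ab[i] * b$ab
    ab[idx] <- ab[idx] + contrib
    wm[idx] <- wm[idx] + contrib * (a$mass[i] + b$mass)
  }
  mass <- ifelse(ab > 0, wm / pmax(ab, .Machine$double.xmin), 0)
  list(ab = ab, mass = mass)
}

pattern_trim <- function(p, floor = 1e-12) {
  keep <- which(p$ab > floor)
  if (!length(keep)) return(list(ab = 1, mass = p$mass[1]))
  last <- max(keep)
  list(ab = p$ab[1:last], mass = p$mass[1:last])
}

# n-fold self-convolution by binary exponentiation
pattern_power <- function(p, n) {
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1)
      result <- if (is.null(result)) p else pattern_trim(pattern_convolve(result, p))
    n <- n %/% 2
    if (n > 0) p <- pattern_trim(pattern_convolve(p, p))
  }
  if (is.null(result)) list(ab = 1, mass = 0) else result
}

element_pattern <- function(el) {
  iso <- ISOTOPES[[el]]
  n <- max(iso$offset) + 1L
  ab <- numeric(n); mass <- numeric(n)
  ab[iso$offset + 1L] <- iso$abundance
  # masses relative to the lightest isotope so convolution sums deltas
  mass[iso$offset + 1L] <- iso$mass - iso$mass[1]
  list(ab = ab, mass = mass)
}

#' Isotope distribution of an elemental composition
#'
#' Computes the aggregated (nominal-offset) isotope distribution by iterated
#' convolution of the per-element isotope vectors, using the embedded
#' abundance table. Offsets with relative abundance below `prune` (relative
#' to the most abundant offset) are removed and the remainder renormalised.
#'
#' @param comp an `elemental_composition`.
#' @param prune relative-abundance pruning threshold in `[0, 1)`;
#'   default `1e-6`.
#' @return a data frame of class `isotope_pattern` with columns `offset`
#'   (integer neutron offset, 0 = monoisotopic), `mass` (exact
#'   abundance-weighted mass in Da) and `abundance` (fractions summing
#'   to 1 after renormalisation).
#' @export
isotope_distribution <- function(comp, prune = 1e-6) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (prune < 0 || prune >= 1) stop("prune must be in [0, 1)")
  counts <- unclass(comp)
  acc <- NULL
  for (el in ELEMENTS) {
    n <- counts[[el]]
    if (n == 0) next
    pe <- pattern_power(element_pattern(el), n)
    acc <- if (is.null(acc)) pe else pattern_trim(pattern_convolve(acc, pe))
  }
  if (is.null(acc)) acc <- list(ab = 1, mass = 0)
  mono <- monoisotopic_mass(comp)
  ab <- acc$ab
  keep <- ab >= prune * max(ab) & ab > 0
  offset <- which(keep) - 1L
  ab <- ab[keep] / sum(ab[keep])
  mass <- mono + acc$mass[keep]
  structure(
    data.frame(offset = offset, mass = mass, abundance = ab),
    class = c("isotope_pattern", "data.frame")
  )
}

#' Most abundant isotope offset of a pattern
#'
#' The nominal neutron offset carrying maximal abundance; ties break toward
#' the smaller offset. This maps the tallest isotope peak back to the
#' monoisotopic species during deconvolution.
#'
#' @param p an `isotope_pattern`.
#' @return integer offset (0 for light molecules).
#' @export
most_abundant_offset <- function(p) {
  stopifnot(inherits(p, "isotope_pattern"), nrow(p) > 0)
  p$offset[which.max(p$abundance)]
}

#' Averagine composition for a target mass
#'
#' Scales the average-residue ("averagine") model
#' C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da to the target
#' monoisotopic mass, rounds to integer atom counts and pads with hydrogens
#' so the monoisotopic mass matches within half a Dalton. Used for proteins
#' whose sequence is not available (mass-backed registry entries, and the
#' registry-free offset correction inside the deconvolver).
#'
#' @param M target monoisotopic mass in Daltons (> 0).
#' @return an `elemental_composition`.
#' @export
averagine_composition <- function(M) {
  if (length(M) != 1 || M <= 0) stop("M must be a single mass > 0")
  units <- M / AVERAGINE_MASS
  counts <- round(AVERAGINE_UNIT * units)
  counts["H"] <- max(counts[["H"]], 1)
  comp <- as_composition(counts)
  dh <- round((M - monoisotopic_mass(comp)) / MONO_MASS[["H"]])
  counts["H"] <- max(counts[["H"]] + dh, 0)
  as_composition(counts)
}

#' Analyzer peak width at a given m/z
#'
#' Gaussian peak-shape model of the TOF analyzer: the full width at half
#' maximum grows linearly with m/z at fixed resolving power,
#' `FWHM = mz / resolving_power`.
#'
#' @param mz position in Th.
#' @param resolving_power m/dm at FWHM (default 60000).
#' @return FWHM in Th.
#' @export
peak_fwhm <- function(mz, resolving_power = 60000) {
  if (any(resolving_power <= 0)) stop("resolving_power must be > 0")
  mz / resolving_power
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
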