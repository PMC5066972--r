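# Physical constants and embedded element / residue tables.
#
# All masses are in Daltons (unified atomic mass units). Element values are
# the IUPAC 2013 monoisotopic masses and representative isotopic abundances;
# they are embedded constants, not a live lookup, so results are stable
# across environments.

#' @name constants
#' @title Embedded physico-chemical constants
#' @description
#' `PROTON_MASS` is the mass of a proton (charge carrier in positive-mode
#' ESI). `NEUTRON_SPACING` is the average spacing between adjacent isotope
#' peaks of a peptide/protein ("averagine" mean neutron mass increment),
#' used for charge inference from isotope spacing and for
#' most-abundant-offset corrections.
#' @keywords internal
NULL

PROTON_MASS    <- 1.007276466
NEUTRON_SPACING <- 1.00235

ELEMENTS <- c("C", "H", "N", "O", "S", "P")

# monoisotopic masses of the lightest isotope
MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

# abundance-weighted (average) atomic masses
AVG_MASS <- c(
  C = 12.0107,
  H = 1.00794,
  N = 14.0067,
  O = 15.9994,
  S = 32.065,
  P = 30.973762
)

# isotope table: per element, exact masses and relative abundances ordered
# by increasing nominal mass; offsets are nominal neutron increments over
# the lightest isotope
ISOTOPES <- list(
  C = list(offset = c(0L, 1L),
           mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(offset = c(0L, 1L),
           mass = c(1.0078250319, 2.0141017780),
           abundance = c(0.999885, 0.000115)),
  N = list(offset = c(0L, 1L),
           mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99636, 0.00364)),
  O = list(offset = c(0L, 1L, 2L),
           mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(offset = c(0L, 1L, 2L, 4L),
           mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(offset = 0L,
           mass = 30.97376151,
           abundance = 1.0)
)

# residue (dehydrated) elemental compositions of the 20 standard amino
# acids, one-letter codes; a peptide is sum(residues) + H2O
AA_RESIDUES <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0, P = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0, P = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0, P = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0, P = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0, P = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0, P = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1, P = 0),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0, P = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0, P = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0, P = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0, P = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0, P = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0, P = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0, P = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1, P = 0),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0, P = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0, P = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0, P = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0, P = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0, P = 0)
)

H2O  <- c(C = 0, H = 2, N = 0, O = 1, S = 0, P = 0)
# phosphate adduct on Ser/Thr: +HPO3
HPO3 <- c(C = 0, H = 1, N = 0, O = 3, S = 0, P = 1)

# glycan residue (dehydrated monosaccharide) compositions
GLYCAN_RESIDUES <- list(
  Hex    = c(C = 6,  H = 10, N = 0, O = 5, S = 0, P = 0),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5, S = 0, P = 0),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8, S = 0, P = 0),
  Fuc    = c(C = 6,  H = 10, N = 0, O = 4, S = 0, P = 0)
)

# averagine model unit (Senko-style average residue) used to approximate
# the elemental composition of a protein of known mass but unknown sequence
AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                    S = 0.0417, P = 0)
AVERAGINE_MASS <- 111.1254
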