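# Elemental compositions and proteoform mass arithmetic.

#' Create an elemental composition
#'
#' An elemental composition is a named vector of non-negative integer atom
#' counts over the elements C, H, N, O, S, P (the elements occurring in
#' unmodified and phospho/glyco-modified proteins).
#'
#' @param ... atom counts by element symbol, e.g. `composition(C = 2, H = 5,
#'   N = 1, O = 2)`. Omitted elements default to zero.
#' @return an object of class `elemental_composition`.
#' @examples
#' composition(H = 2, O = 1)   # water
#' @export
composition <- function(...) {
  x <- c(...)
  if (length(x) == 0) return(as_composition(numeric(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("composition() arguments must be named by element symbol")
  as_composition(x)
}

as_composition <- function(x) {
  out <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  if (length(x)) {
    bad <- setdiff(names(x), ELEMENTS)
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- out[names(x)] + as.numeric(x)
  }
  if (any(out < 0)) stop("negative atom count in composition")
  if (any(out != round(out))) stop("atom counts must be integers")
  structure(out, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  f <- if (length(nz)) paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
       else "(empty)"
  cat("<elemental composition> ", f, "\n",
      "  monoisotopic ", format(monoisotopic_mass(x), nsmall = 5),
      " Da, average ", format(average_mass(x), nsmall = 4), " Da\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  as_composition(unclass(e1) + unclass(e2))
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  d <- unclass(e1) - unclass(e2)
  if (any(d < 0))
    stop("composition subtraction would give a negative count for: ",
         paste(names(d)[d < 0], collapse = ", "))
  as_composition(d)
}

comp_scale <- function(comp, n) {
  as_composition(unclass(comp) * n)
}

#' Elemental composition of a mature protein sequence
#'
#' Sums the residue compositions of the one-letter amino-acid sequence plus
#' one water (for the termini). By default the protein is treated as fully
#' reduced (free cysteines), matching samples prepared in a DTT-containing
#' denaturation buffer; set `n_disulfides` to subtract two hydrogens per
#' disulfide bridge for unreduced species.
#'
#' @param sequence mature amino-acid sequence (signal peptide removed),
#'   standard one-letter codes only.
#' @param cys_reduced logical; if `FALSE`, `n_disulfides` must give the
#'   number of disulfide bridges to subtract.
#' @param n_disulfides number of disulfide bridges (only used when
#'   `cys_reduced = FALSE`).
#' @return an `elemental_composition`.
#' @examples
#' composition_from_sequence("G")       # free glycine, C2H5NO2
#' @export
composition_from_sequence <- function(sequence, cys_reduced = TRUE,
                                      n_disulfides = 0L) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  known <- aa %in% names(AA_RESIDUES)
  if (!all(known))
    stop("unknown residue '", aa[which(!known)[1]], "' at position ",
         which(!known)[1])
  counts <- Reduce(`+`, AA_RESIDUES[aa]) + H2O
  if (!cys_reduced) {
    if (n_disulfides < 0) stop("n_disulfides must be >= 0")
    n_cys <- sum(aa == "C")
    if (2 * n_disulfides > n_cys)
      stop("more disulfides than cysteine pairs")
    counts["H"] <- counts["H"] - 2 * n_disulfides
  }
  as_composition(counts)
}

#' Apply phosphorylation and O-glycosylation to a composition
#'
#' Adds `n_phospho` HPO3 groups and the residue composition of each
#' monosaccharide in `glycan` (counts of Hex, HexNAc, NeuAc, Fuc).
#'
#' @param base an `elemental_composition` (the unmodified backbone).
#' @param n_phospho number of phosphate groups (>= 0).
#' @param glycan named numeric vector of monosaccharide counts, e.g.
#'   `c(Hex = 1, HexNAc = 1, NeuAc = 1)`; `NULL` for none.
#' @return the modified `elemental_composition`.
#' @export
apply_modifications <- function(base, n_phospho = 0L, glycan = NULL) {
  stopifnot(inherits(base, "elemental_composition"))
  if (length(n_phospho) != 1 || is.na(n_phospho) || n_phospho < 0 ||
      n_phospho != round(n_phospho))
    stop("n_phospho must be a single non-negative integer")
  out <- unclass(base) + n_phospho * HPO3
  if (!is.null(glycan) && length(glycan)) {
    bad <- setdiff(names(glycan), names(GLYCAN_RESIDUES))
    if (length(bad))
      stop("unknown monosaccharide(s): ", paste(bad, collapse = ", "))
    if (any(glycan < 0)) stop("glycan counts must be >= 0")
    for (g in names(glycan))
      out <- out + glycan[[g]] * GLYCAN_RESIDUES[[g]]
  }
  as_composition(out)
}

#' Monoisotopic and average mass of a composition
#'
#' Dot product of the atom counts with the monoisotopic (resp.
#' abundance-weighted average) element masses.
#'
#' @param comp an `elemental_composition`.
#' @return mass in Daltons.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(unclass(comp) * MONO_MASS[ELEMENTS])
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(unclass(comp) * AVG_MASS[ELEMENTS])
}
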