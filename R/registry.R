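# Proteoform registry: data-driven construction of proteoform objects from
# a FASTA of mature sequences plus a YAML modification/variant config.

#' Construct a proteoform
#'
#' A proteoform is one allelic protein backbone plus a defined modification
#' state (number of phosphates, O-glycan composition). When a mature
#' sequence is supplied the elemental composition and masses are derived
#' from it (exact chemistry, fully reduced by default); otherwise a curated
#' mass must be given and an averagine composition of that mass serves as a
#' stand-in for isotope-pattern purposes.
#'
#' @param protein_code unique code, e.g. `"kCN B-1P"`.
#' @param sequence mature amino-acid sequence, or `NULL` for mass-backed
#'   entries.
#' @param n_phospho number of phosphate groups.
#' @param glycan named monosaccharide counts (Hex, HexNAc, NeuAc, Fuc) or
#'   `NULL`.
#' @param curated_mass curated neutral mass in Da (required when `sequence`
#'   is `NULL`; monoisotopic, or average if `average_only`).
#' @param average_only logical; `TRUE` for species too heavy for isotope
#'   resolution, reported by average mass (the serum-albumin case).
#' @param expected_rt expected elution apex in minutes.
#' @param charges integer vector of charge states for the ion series.
#' @param response_factor EIC response per mg/mL (ionisation efficiency
#'   scale) used by the run simulator.
#' @param cys_reduced treat cysteines as free thiols (default `TRUE`).
#' @param n_disulfides disulfide count when `cys_reduced = FALSE`.
#' @return an object of class `proteoform`.
#' @export
proteoform <- function(protein_code, sequence = NULL, n_phospho = 0L,
                       glycan = NULL, curated_mass = NULL,
                       average_only = FALSE, expected_rt = NA_real_,
                       charges = integer(), response_factor = NA_real_,
                       cys_reduced = TRUE, n_disulfides = 0L) {
  stopifnot(is.character(protein_code), nzchar(protein_code))
  if (is.null(sequence) && is.null(curated_mass))
    stop("proteoform '", protein_code,
         "' needs a sequence or a curated mass")
  if (!is.null(glycan)) glycan <- glycan[unlist(glycan) > 0]
  if (!is.null(glycan) && !length(glycan)) glycan <- NULL
  if (!is.null(sequence)) {
    base <- composition_from_sequence(sequence, cys_reduced, n_disulfides)
    comp <- apply_modifications(base, n_phospho, unlist(glycan))
    mono <- monoisotopic_mass(comp)
    avg  <- average_mass(comp)
    sequence_backed <- TRUE
  } else {
    mono <- curated_mass
    if (isTRUE(average_only)) {
      # curated value is an average mass; back out an approximate
      # monoisotopic anchor through the averagine mass defect
      mono <- curated_mass
      comp <- averagine_composition(curated_mass * 0.9986)
      # refine so the average mass matches the curated value
      for (i in 1:4) {
        delta <- curated_mass - average_mass(comp)
        if (abs(delta) < 0.05) break
        comp <- averagine_composition(monoisotopic_mass(comp) + delta)
      }
      mono <- monoisotopic_mass(comp)
      avg  <- average_mass(comp)
    } else {
      comp <- averagine_composition(mono)
      avg  <- average_mass(comp)
    }
    sequence_backed <- FALSE
  }
  pat <- isotope_distribution(comp, prune = 1e-4)
  if (!sequence_backed) {
    # the averagine stand-in's integer atom counts quantise its mass; shift
    # the pattern (and masses) by a constant so the rendered species sits
    # exactly at the curated mass (abundances are unaffected)
    shift <- if (isTRUE(average_only)) curated_mass - avg
      else curated_mass - monoisotopic_mass(comp)
    pat$mass <- pat$mass + shift
    mono <- monoisotopic_mass(comp) + shift
    avg <- avg + shift
  }
  structure(list(
    protein_code = protein_code,
    mature_sequence = sequence,
    n_phospho = as.integer(n_phospho),
    glycan = glycan,
    cys_reduced = cys_reduced,
    composition = comp,
    mono_mass = mono,
    avg_mass = avg,
    curated_mass = if (is.null(curated_mass)) NA_real_ else curated_mass,
    average_only = isTRUE(average_only),
    sequence_backed = sequence_backed,
    expected_rt = expected_rt,
    charges = as.integer(charges),
    response_factor = response_factor,
    isotope_pattern = pat,
    apex_offset = most_abundant_offset(pat)
  ), class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", x$protein_code,
      if (x$sequence_backed) "  [sequence-backed]" else "  [mass-backed]",
      "\n  monoisotopic ", format(x$mono_mass, nsmall = 4),
      " Da; average ", format(x$avg_mass, nsmall = 3), " Da",
      if (x$average_only) " (average-only)", "\n", sep = "")
  if (x$n_phospho > 0) cat("  phosphates:", x$n_phospho, "\n")
  if (!is.null(x$glycan))
    cat("  glycan:", paste(names(x$glycan), unlist(x$glycan),
                           sep = "x", collapse = " "), "\n")
  if (length(x$charges))
    cat("  charges ", min(x$charges), "-", max(x$charges),
        "; expected RT ", x$expected_rt, " min\n", sep = "")
  invisible(x)
}

#' Read a proteoform registry from FASTA + YAML
#'
#' The YAML lists one entry per proteoform (`protein_code`, `fasta_id`,
#' `n_phospho`, `glycan`, `curated_mass`, `average_only`,
#' `expected_rt_min`, `charges`, `response_factor`), the EIC `tolerance`,
#' the `internal_standard` code and the `standard_groups` used to sum
#' variant responses per commercial standard.
#'
#' @param yaml_path path to the registry YAML.
#' @param fasta_path path to the mature-sequence FASTA; entries whose
#'   `fasta_id` is absent/`NULL` are mass-backed via their `curated_mass`.
#' @return an object of class `proteoform_registry`: a named list of
#'   `proteoform`s with attributes `tolerance`, `internal_standard` and
#'   `standard_groups`.
#' @export
read_registry <- function(yaml_path, fasta_path = NULL) {
  cfg <- yaml::read_yaml(yaml_path)
  seqs <- character()
  if (!is.null(fasta_path)) {
    aa <- Biostrings::readAAStringSet(fasta_path)
    seqs <- stats::setNames(as.character(aa),
                            vapply(strsplit(names(aa), "\\s+"), `[`, "", 1))
  }
  forms <- lapply(cfg$proteoforms, function(e) {
    seq <- NULL
    if (!is.null(e$fasta_id) && !is.na(e$fasta_id) && nzchar(e$fasta_id)) {
      if (!e$fasta_id %in% names(seqs))
        stop("fasta_id '", e$fasta_id, "' not found in ", fasta_path)
      seq <- seqs[[e$fasta_id]]
    }
    ch <- e$charges
    proteoform(
      protein_code = e$protein_code,
      sequence = seq,
      n_phospho = e$n_phospho %||% 0L,
      glycan = e$glycan,
      curated_mass = e$curated_mass,
      average_only = isTRUE(e$average_only),
      expected_rt = e$expected_rt_min %||% NA_real_,
      charges = if (is.null(ch)) integer() else unlist(ch),
      response_factor = e$response_factor %||% NA_real_
    )
  })
  codes <- vapply(forms, `[[`, "", "protein_code")
  if (anyDuplicated(codes))
    stop("duplicate protein_code in registry: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  structure(stats::setNames(forms, codes),
            tolerance = cfg$tolerance %||% 0.1,
            internal_standard = cfg$internal_standard,
            standard_groups = cfg$standard_groups,
            class = "proteoform_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged bovine milk proteoform registry
#'
#' Loads the fixture registry shipped with the package: the milk
#' casein/whey panel (23 proteoforms) plus the horse-myoglobin internal
#' standard, with curated masses, expected retention times, charge lists
#' and response factors.
#'
#' @return a `proteoform_registry`.
#' @export
milk_registry <- function() {
  read_registry(
    system.file("extdata", "milk_registry.yaml", package = "lactoquant"),
    system.file("extdata", "milk_sequences.fasta", package = "lactoquant")
  )
}

#' @export
print.proteoform_registry <- function(x, ...) {
  cat("<proteoform registry> ", length(x), " proteoforms; IS: ",
      attr(x, "internal_standard") %||% "(none)", "\n", sep = "")
  for (p in x)
    cat(sprintf("  %-14s %10.3f Da%s\n", p$protein_code, p$mono_mass,
                if (p$average_only) " (avg)" else ""))
  invisible(x)
}

#' Printed-table fixtures
#'
#' Accessors for the small CSV fixtures shipped with the package: the
#' external-standard calibration responses (per-standard mean/SD over a
#' 0.25-10 mg/mL dilution series), the internal-standard matrix-effect
#' panel (solution A vs two milk matrices), the deconvolution report
#' (observed masses, resolution, S/N, FWHM per proteoform), and the
#' triplicate reproducibility panel.
#'
#' @param which one of `"calibration"`, `"is_matrix"`, `"deconvolution"`,
#'   `"reproducibility"`.
#' @return a data frame.
#' @export
milk_fixture_table <- function(which = c("calibration", "is_matrix",
                                         "deconvolution",
                                         "reproducibility")) {
  which <- match.arg(which)
  file <- switch(which,
    calibration    = "table_calibration_standards.csv",
    is_matrix      = "table_is_matrix.csv",
    deconvolution  = "table_deconvolution_report.csv",
    reproducibility = "table_reproducibility.csv")
  utils::read.csv(system.file("extdata", file, package = "lactoquant"),
                  check.names = FALSE)
}
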