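Package: lactoquant
Title: Quantitation and Identification of Intact Milk Proteoforms from
    LC-ESI-Q-TOF Runs
Version: 0.1.0
Authors@R:
    person("Delia", "Verran", email = "delia.verran@example.org",
           role = c("aut", "cre"))
Description: Identification and quantitation of intact bovine milk
    proteoforms (casein and whey protein allelic variants with their
    phosphorylation and O-glycosylation states) from liquid
    chromatography electrospray quadrupole time-of-flight mass
    spectrometry runs. Provides proteoform mass arithmetic from mature
    sequences and modification compositions, isotope-pattern computation,
    charge-state ion series and extracted ion chromatograms with
    retention-time-window peak integration, charge-envelope deconvolution
    to neutral monoisotopic mass, internal-standard normalisation, and
    analytical method-validation statistics (calibration with LOD/LOQ,
    matrix effect, coefficients of variation, signal-to-noise, two-group
    comparison). Includes a synthetic LC-MS run generator emulating the
    acquisition regime of a high-resolution Q-TOF instrument, a minimal
    MS1 mzML reader/writer, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
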