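# Minimal MS1 mzML reader/writer.
#
# Supports exactly what the pipeline needs: positive-mode MS1 scans with
# retention time in minutes, uncompressed 64-bit little-endian m/z and
# intensity arrays, and a profile/centroid flag. MSn spectra are skipped
# on read with a logged count. This is intentionally a narrow subset of
# the mzML vocabulary, not a general-purpose reader.

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

decode_doubles <- function(txt) {
  readBin(jsonlite::base64_dec(gsub("\\s", "", txt)), "double",
          n = nchar(txt), size = 8, endian = "little")
}

#' Write a spectra run to mzML
#'
#' @param run a `spectra_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "spectra_run"))
  centroided <- isTRUE(run$metadata$centroided)
  spec_mode_acc <- if (centroided) "MS:1000127" else "MS:1000128"
  spec_mode_name <- if (centroided) "centroid spectrum" else
    "profile spectrum"
  n <- length(run$rt)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <cvList count="1">')
  w('    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  w('  </cvList>')
  w('  <fileDescription><fileContent>')
  w('    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>')
  w('  </fileContent></fileDescription>')
  seed <- run$metadata$seed
  w('  <run id="run1"', if (!is.null(seed))
      paste0(' startTimeStamp="seed:', seed, '"') else '', '>')
  w('    <spectrumList count="', n, '">')
  for (i in seq_len(n)) {
    mz <- run$mz
    int <- run$intensity[, i]
    b_mz <- encode_doubles(mz)
    b_int <- encode_doubles(int)
    w('      <spectrum index="', i - 1, '" id="scan=', i,
      '" defaultArrayLength="', length(mz), '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>')
    w('        <cvParam cvRef="MS" accession="', spec_mode_acc,
      '" name="', spec_mode_name, '"/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      format(run$rt[i], digits = 12), '" unitName="minute"/>')
    w('        </scan></scanList>')
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="', nchar(b_mz), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
    w('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>')
    w('            <binary>', b_mz, '</binary>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="', nchar(b_int), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>')
    w('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>')
    w('            <binary>', b_int, '</binary>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

#' Read an mzML file into a spectra run
#'
#' Reads MS1 spectra (retention time, m/z and intensity arrays, polarity,
#' profile/centroid flag); non-MS1 spectra are skipped and counted in the
#' metadata log. Scans are resampled onto the union m/z grid (scans from
#' the package's own writer share one grid, so this is lossless for the
#' round trip).
#'
#' @param path mzML file path.
#' @return a `spectra_run`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty mzML file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed mzML (XML parse failure): ", conditionMessage(e)))
  ns <- c(m = xml2::xml_ns(doc)[[1]])
  specs <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  if (!length(specs)) stop("mzML contains no spectra: ", path)
  rt <- numeric(); mz_l <- list(); int_l <- list()
  centroided <- FALSE; skipped <- 0L
  for (sp in specs) {
    params <- xml2::xml_find_all(sp, "./m:cvParam", ns)
    acc <- xml2::xml_attr(params, "accession")
    lvl <- xml2::xml_attr(params[acc == "MS:1000511"], "value")
    if (length(lvl) && lvl != "1") { skipped <- skipped + 1L; next }
    if ("MS:1000127" %in% acc) centroided <- TRUE
    stime <- xml2::xml_find_first(
      sp, ".//m:scan/m:cvParam[@accession='MS:1000016']", ns)
    if (is.na(xml2::xml_attr(stime, "value")))
      stop("spectrum ", xml2::xml_attr(sp, "index"),
           ": missing scan start time")
    this_rt <- as.numeric(xml2::xml_attr(stime, "value"))
    if (identical(xml2::xml_attr(stime, "unitName"), "second"))
      this_rt <- this_rt / 60
    arrays <- xml2::xml_find_all(sp, ".//m:binaryDataArray", ns)
    vals <- list(mz = NULL, int = NULL)
    for (arr in arrays) {
      aacc <- xml2::xml_attr(
        xml2::xml_find_all(arr, "./m:cvParam", ns), "accession")
      bin <- xml2::xml_text(xml2::xml_find_first(arr, "./m:binary", ns))
      v <- decode_doubles(bin)
      if ("MS:1000514" %in% aacc) vals$mz <- v
      if ("MS:1000515" %in% aacc) vals$int <- v
    }
    if (is.null(vals$mz) || is.null(vals$int))
      stop("spectrum ", xml2::xml_attr(sp, "index"),
           ": missing m/z or intensity array")
    rt <- c(rt, this_rt)
    mz_l[[length(mz_l) + 1]] <- vals$mz
    int_l[[length(int_l) + 1]] <- vals$int
  }
  if (!length(rt)) stop("no MS1 spectra in ", path)
  grid <- sort(unique(unlist(mz_l)))
  intensity <- matrix(0, nrow = length(grid), ncol = length(rt))
  for (i in seq_along(rt)) {
    idx <- match(mz_l[[i]], grid)
    intensity[idx, i] <- int_l[[i]]
  }
  seed <- NA_integer_
  runnode <- xml2::xml_find_first(doc, ".//m:run", ns)
  st <- xml2::xml_attr(runnode, "startTimeStamp")
  if (!is.na(st) && grepl("^seed:", st))
    seed <- as.integer(sub("^seed:", "", st))
  structure(list(
    rt = rt, mz = grid, intensity = intensity,
    metadata = list(seed = seed, centroided = centroided,
                    mz_range = if (length(grid)) range(grid) else NULL,
                    log = if (skipped)
                      sprintf("skipped %d non-MS1 spectra", skipped)
                    else character())
  ), class = "spectra_run")
}
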