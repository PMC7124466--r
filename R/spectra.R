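#' Construct an MS2 spectrum
#'
#' Peaks are sorted by m/z; total ion current and base peak statistics are
#' computed when not supplied.
#'
#' @param scanId integer scan number.
#' @param precursorMz precursor ion m/z.
#' @param precursorCharge precursor charge state.
#' @param rt retention time (minutes).
#' @param mz,intensity numeric peak arrays.
#' @return an \code{\linkS4class{Ms2Spectrum}}.
#' @export
ms2Spectrum <- function(scanId, precursorMz, precursorCharge, rt, mz,
                        intensity) {
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  tic <- sum(intensity)
  bp <- if (length(intensity)) which.max(intensity) else NA_integer_
  new("Ms2Spectrum", scanId = as.integer(scanId),
      precursorMz = precursorMz, precursorCharge = as.integer(precursorCharge),
      rt = rt, mz = mz, intensity = intensity, tic = tic,
      basePeakMz = if (is.na(bp)) 0 else mz[bp],
      basePeakIntensity = if (is.na(bp)) 0 else intensity[bp])
}

#' Neutral precursor mass of a spectrum
#'
#' @param spectrum an \code{\linkS4class{Ms2Spectrum}}.
#' @return \code{precursorMz * z - z * 1.007276}.
#' @export
precursorNeutralMass <- function(spectrum) {
  z <- spectrum@precursorCharge
  spectrum@precursorMz * z - z * PROTON_MASS
}

#' Write spectra to a binary-free JSON container
#'
#' A fast, text-only alternative to mzML for tests and synthetic data.
#'
#' @param spectra list of \code{\linkS4class{Ms2Spectrum}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSpectraJSON <- function(spectra, path) {
  payload <- lapply(spectra, function(s) list(
    scanId = s@scanId, precursorMz = s@precursorMz,
    precursorCharge = s@precursorCharge, rt = s@rt,
    mz = s@mz, intensity = s@intensity))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read spectra from the JSON container
#'
#' @param path file written by \code{\link{writeSpectraJSON}}.
#' @return list of \code{\linkS4class{Ms2Spectrum}}.
#' @export
readSpectraJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p)
    ms2Spectrum(p$scanId, p$precursorMz, p$precursorCharge, p$rt,
                as.numeric(p$mz), as.numeric(p$intensity)))
}

.encodeDoubles <- function(x, size) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = size,
                                endian = "little"))
}

.decodeDoubles <- function(b64, size) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  readBin(raw, what = "numeric", n = length(raw) %/% size, size = size,
          endian = "little")
}

#' Write centroided MS2 spectra to a minimal mzML file
#'
#' Emits a small but schema-conformant mzML document: centroid spectra with
#' 64-bit m/z and 32-bit intensity arrays (uncompressed, little-endian
#' base64), MS level, retention time, and precursor isolation with selected
#' ion m/z and charge.
#'
#' @param spectra list of \code{\linkS4class{Ms2Spectrum}}.
#' @param path output mzML path.
#' @return the path, invisibly.
#' @export
writeMzML <- function(spectra, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>')
  w('  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>')
  w('  <softwareList count="1"><software id="xlmspipe" version="0.9"/></softwareList>')
  w('  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>')
  w('  <dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="xlmspipe"/></dataProcessing></dataProcessingList>')
  w('  <run id="run1" defaultInstrumentConfigurationRef="IC1">')
  w('    <spectrumList count="%d" defaultDataProcessingRef="DP1">', length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    mzB <- .encodeDoubles(s@mz, 8L)
    inB <- .encodeDoubles(s@intensity, 4L)
    w('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, s@scanId, length(s@mz))
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
    w('        <scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitName="minute"/></scan></scanList>',
      s@rt)
    w('        <precursorList count="1"><precursor><isolationWindow><cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f"/></isolationWindow><selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/><cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/></selectedIon></selectedIonList><activation><cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/></activation></precursor></precursorList>',
      s@precursorMz, s@precursorMz, s@precursorCharge)
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitName="m/z"/><binary>%s</binary></binaryDataArray>',
      nchar(mzB), esc(mzB))
    w('          <binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>',
      nchar(inB), esc(inB))
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

#' Read MS2 spectra from an mzML file
#'
#' Supports uncompressed 32/64-bit little-endian binary arrays (the encoding
#' \code{\link{writeMzML}} emits). Spectra without precursor information
#' (MS1 scans) are skipped.
#'
#' @param path mzML file.
#' @return list of \code{\linkS4class{Ms2Spectrum}}.
#' @export
readMzML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(m = xml2::xml_ns(doc)[[1]])
  specs <- xml2::xml_find_all(doc, ".//m:spectrum", ns = ns)
  out <- list()
  for (sp in specs) {
    ion <- xml2::xml_find_first(sp, ".//m:selectedIon", ns = ns)
    if (inherits(ion, "xml_missing")) next
    cv <- function(node, acc) {
      p <- xml2::xml_find_first(
        node, sprintf(".//m:cvParam[@accession='%s']", acc), ns = ns)
      if (inherits(p, "xml_missing")) NA_character_
      else xml2::xml_attr(p, "value")
    }
    premz <- as.numeric(cv(ion, "MS:1000744"))
    z <- as.integer(cv(ion, "MS:1000041"))
    rt <- as.numeric(cv(sp, "MS:1000016"))
    scanId <- sub(".*scan=(\\d+).*", "\\1", xml2::xml_attr(sp, "id"))
    arrays <- xml2::xml_find_all(sp, ".//m:binaryDataArray", ns = ns)
    mz <- numeric(); inten <- numeric()
    for (arr in arrays) {
      has <- function(acc) !inherits(xml2::xml_find_first(
        arr, sprintf(".//m:cvParam[@accession='%s']", acc), ns = ns),
        "xml_missing")
      if (!has("MS:1000576"))
        stop("compressed binary arrays are not supported by this reader")
      size <- if (has("MS:1000523")) 8L else 4L
      vals <- .decodeDoubles(
        xml2::xml_text(xml2::xml_find_first(arr, ".//m:binary", ns = ns)),
        size)
      if (has("MS:1000514")) mz <- vals
      if (has("MS:1000515")) inten <- vals
    }
    out[[length(out) + 1L]] <-
      ms2Spectrum(as.integer(scanId), premz, z, rt, mz, inten)
  }
  out
}
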