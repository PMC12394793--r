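## mzML input/output. Reading goes through mzR (proteowizard backend);
## the dissociation-method CV terms are not surfaced by mzR's header, so
## they are picked up from the same file with xml2. Writing a minimal
## centroid mzML 1.1 document is done directly (fixture generation only).

.ACTIVATION_CV <- data.frame(
  accession = c("MS:1000133", "MS:1000422", "MS:1000598"),
  name = c("collision-induced dissociation",
           "beam-type collision-induced dissociation",
           "electron transfer dissociation"),
  activation = c("CID", "HCD", "ETD"),
  stringsAsFactors = FALSE)

## activation string per spectrum element, NA when no precursor/activation
.mzmlActivations <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  vapply(nodes, function(sp) {
    acc <- xml2::xml_attr(
      xml2::xml_find_all(sp, ".//activation/cvParam"), "accession")
    hit <- .ACTIVATION_CV$activation[.ACTIVATION_CV$accession %in% acc]
    if (!length(hit)) return(NA_character_)
    if (all(c("ETD", "HCD") %in% hit)) return("EThcD")
    hit[1]
  }, character(1))
}

#' Read an mzML file
#'
#' Reads centroided MS1/MS2 scans via mzR, extracting precursor isolation
#' m/z and charge, activation type (from the dissociation CV terms),
#' and retention time (normalized to seconds). Profile-mode spectra are
#' rejected rather than silently centroided.
#'
#' @param path mzML file path.
#' @param msLevel Optional integer filter (1 or 2).
#' @return List of [MsSpectrum-class] objects.
#' @export
readMzml <- function(path, msLevel = NULL) {
  if (!file.exists(path)) stop(sprintf("mzML file not found: %s", path))
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop(sprintf(
                       "failed to parse mzML '%s': %s", path,
                       conditionMessage(e))))
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  if (!nrow(hd)) {
    warning(sprintf("no spectra in %s", path))
    return(list())
  }
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop(sprintf(
      "%s contains profile-mode spectra; centroid the data first", path))
  acts <- tryCatch(.mzmlActivations(path), error = function(e)
    rep(NA_character_, nrow(hd)))
  if (length(acts) != nrow(hd)) acts <- rep(NA_character_, nrow(hd))
  keep <- seq_len(nrow(hd))
  if (!is.null(msLevel)) keep <- which(hd$msLevel %in% msLevel)
  if (!is.null(msLevel) && all(msLevel == 2L) && !length(keep))
    warning(sprintf("no MS2 spectra in %s", path))
  warned <- FALSE
  out <- lapply(keep, function(i) {
    pk <- mzR::peaks(handle, i)
    lvl <- hd$msLevel[i]
    act <- if (lvl >= 2L) acts[i] else NA_character_
    if (lvl >= 2L && is.na(act)) {
      if (!warned) {
        warning(sprintf(
          "%s: spectrum without dissociation CV term; assuming HCD", path))
        warned <<- TRUE
      }
      act <- "HCD"
    }
    msSpectrum(pk[, 1], pk[, 2],
               scanId = as.character(hd$spectrumId[i]), msLevel = lvl,
               precursorMz = if (lvl >= 2L) hd$precursorMZ[i] else NA_real_,
               precursorCharge = if (lvl >= 2L && hd$precursorCharge[i] > 0L)
                 as.integer(hd$precursorCharge[i]) else NA_integer_,
               activation = act, rtime = hd$retentionTime[i])
  })
  out
}

.b64doubles <- function(x) {
  raw <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
  ## base64 encoding without extra dependencies
  if (requireNamespace("jsonlite", quietly = TRUE))
    return(gsub("[\r\n]", "", jsonlite::base64_enc(raw)))
  chars <- c(LETTERS, letters, 0:9, "+", "/")
  n <- length(raw)
  pad <- (3L - n %% 3L) %% 3L
  raw <- c(raw, as.raw(rep(0L, pad)))
  m <- matrix(as.integer(raw), nrow = 3L)
  b1 <- m[1, ] %/% 4L
  b2 <- (m[1, ] %% 4L) * 16L + m[2, ] %/% 16L
  b3 <- (m[2, ] %% 16L) * 4L + m[3, ] %/% 64L
  b4 <- m[3, ] %% 64L
  s <- paste(chars[rbind(b1, b2, b3, b4) + 1L], collapse = "")
  if (pad > 0L) substr(s, nchar(s) - pad + 1L, nchar(s)) <-
      paste(rep("=", pad), collapse = "")
  s
}

.mzmlActivationXml <- function(activation) {
  cv <- function(acc, name) sprintf(
    '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', acc, name)
  switch(activation,
    CID = cv("MS:1000133", "collision-induced dissociation"),
    HCD = cv("MS:1000422", "beam-type collision-induced dissociation"),
    ETD = cv("MS:1000598", "electron transfer dissociation"),
    EThcD = paste0(cv("MS:1000598", "electron transfer dissociation"),
                   cv("MS:1000422",
                      "beam-type collision-induced dissociation")),
    cv("MS:1000422", "beam-type collision-induced dissociation"))
}

#' Write spectra to a minimal mzML 1.1 file
#'
#' Centroid spectra only; 64-bit float, uncompressed, base64-encoded peak
#' arrays. Intended for fixture generation and round-trip testing.
#'
#' @param spectra List of [MsSpectrum-class] objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMzml <- function(spectra, path) {
  spectrumXml <- function(s, idx) {
    mzEnc <- .b64doubles(s@mz)
    intEnc <- .b64doubles(s@intensity)
    prec <- if (s@msLevel >= 2L) sprintf(paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '%s</selectedIon></selectedIonList><activation>%s</activation>',
      '</precursor></precursorList>'),
      s@precursorMz, s@precursorMz,
      if (!is.na(s@precursorCharge)) sprintf(
        '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
        s@precursorCharge) else "",
      .mzmlActivationXml(s@activation)) else ""
    sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.4f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
      '%s<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      idx - 1L,
      if (grepl("^scan=[0-9]+$", s@scanId)) s@scanId
      else sprintf("scan=%d", idx),
      length(s@mz), s@msLevel,
      if (s@msLevel == 1L) "MS:1000579" else "MS:1000580",
      if (s@msLevel == 1L) "MS1 spectrum" else "MSn spectrum",
      if (is.na(s@rtime)) 0 else s@rtime,
      prec, nchar(mzEnc), mzEnc, nchar(intEnc), intEnc)
  }
  header <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="AcylMS"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="ic">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(spectra)))
  body <- vapply(seq_along(spectra), function(i)
    spectrumXml(spectra[[i]], i), character(1))
  writeLines(c(header, body, "</spectrumList>\n</run>\n</mzML>"), path,
             sep = "\n")
  invisible(path)
}
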