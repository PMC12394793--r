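#' Construct an MsSpectrum
#'
#' Peaks are sorted ascending by m/z on construction.
#'
#' @param mz,intensity Numeric peak vectors.
#' @param scanId Scan identifier.
#' @param msLevel 1 or 2.
#' @param precursorMz,precursorCharge,activation,rtime Precursor and scan
#'   metadata (NA when unknown; retention time in seconds).
#' @return A validated [MsSpectrum-class].
#' @export
msSpectrum <- function(mz, intensity, scanId = NA_character_, msLevel = 2L,
                       precursorMz = NA_real_,
                       precursorCharge = NA_integer_,
                       activation = NA_character_, rtime = NA_real_) {
  ord <- order(mz)
  new("MsSpectrum", scanId = as.character(scanId),
      msLevel = as.integer(msLevel),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      activation = as.character(activation), rtime = as.numeric(rtime),
      mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]))
}

#' @describeIn MsSpectrum-class scan identifier.
#' @export
setMethod("scanId", "MsSpectrum", function(x) x@scanId)
#' @describeIn MsSpectrum-class precursor m/z.
#' @export
setMethod("precursorMz", "MsSpectrum", function(x) x@precursorMz)
#' @describeIn MsSpectrum-class precursor charge.
#' @export
setMethod("precursorCharge", "MsSpectrum", function(x) x@precursorCharge)
#' @describeIn MsSpectrum-class activation type.
#' @export
setMethod("activationType", "MsSpectrum", function(x) x@activation)
#' @describeIn MsSpectrum-class retention time in seconds.
#' @export
setMethod("retentionTime", "MsSpectrum", function(x) x@rtime)
#' @describeIn MsSpectrum-class MS level.
#' @export
setMethod("msLevel", "MsSpectrum", function(x) x@msLevel)
#' @describeIn MsSpectrum-class two-column data.frame of peaks.
#' @export
setMethod("peakTable", "MsSpectrum", function(x)
  data.frame(mz = x@mz, intensity = x@intensity))

setMethod("show", "MsSpectrum", function(object) {
  cat(sprintf("MsSpectrum '%s' (MS%d), %d peaks\n", object@scanId,
              object@msLevel, length(object@mz)))
  if (object@msLevel > 1L)
    cat(sprintf("  precursor m/z %.4f, charge %s, activation %s\n",
                object@precursorMz,
                ifelse(is.na(object@precursorCharge), "?",
                       object@precursorCharge),
                ifelse(is.na(object@activation), "?", object@activation)))
  cat(sprintf("  retention time %.1f s\n", object@rtime))
  invisible(NULL)
})

## --- MGF ---------------------------------------------------------------

#' Read an MGF (Mascot generic format) file
#'
#' Parses BEGIN/END IONS blocks honoring TITLE, PEPMASS, CHARGE (both
#' "2+" and "+2" conventions) and RTINSECONDS. Unsorted peak lists are
#' sorted ascending. An optional non-standard ACTIVATION= key is honored
#' (written by [writeMgf()]); otherwise activation defaults to HCD with a
#' one-time warning.
#'
#' @param path MGF file path.
#' @return List of [MsSpectrum-class] objects.
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("MGF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(nzchar(lines))) {
    warning(sprintf("empty MGF file: %s", path))
    return(list())
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins)))
    stop(sprintf(
      "truncated MGF block in %s (%d BEGIN IONS vs %d END IONS)",
      path, length(begins), length(ends)))
  out <- vector("list", length(begins))
  warnedActivation <- FALSE
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    names(vals) <- toupper(keys)
    title <- if ("TITLE" %in% names(vals)) vals[["TITLE"]]
             else sprintf("index=%d", b)
    if (!"PEPMASS" %in% names(vals))
      stop(sprintf("MGF block '%s' is missing PEPMASS", title))
    pepmass <- as.numeric(strsplit(vals[["PEPMASS"]], "\\s+")[[1]][1])
    charge <- NA_integer_
    if ("CHARGE" %in% names(vals)) {
      cs <- vals[["CHARGE"]]
      if (grepl("-", cs, fixed = TRUE))
        stop(sprintf("negative charge in MGF block '%s' not supported", title))
      charge <- as.integer(gsub("[^0-9]", "", cs))
    }
    rt <- if ("RTINSECONDS" %in% names(vals))
      as.numeric(vals[["RTINSECONDS"]]) else NA_real_
    act <- if ("ACTIVATION" %in% names(vals)) toupper(vals[["ACTIVATION"]])
           else NA_character_
    if (is.na(act)) {
      if (!warnedActivation) {
        warning(sprintf(
          "%s: no activation metadata in MGF; assuming HCD", path))
        warnedActivation <- TRUE
      }
      act <- "HCD"
    }
    peakLines <- block[!kv & nzchar(block)]
    if (length(peakLines)) {
      pk <- do.call(rbind, lapply(strsplit(peakLines, "[ \t]+"),
                                  function(x) as.numeric(x[1:2])))
      if (anyNA(pk))
        stop(sprintf("unparseable peak line in MGF block '%s'", title))
    } else pk <- matrix(numeric(0), ncol = 2)
    out[[b]] <- msSpectrum(pk[, 1], pk[, 2], scanId = title,
                           msLevel = 2L, precursorMz = pepmass,
                           precursorCharge = charge, activation = act,
                           rtime = rt)
  }
  out
}

#' Write spectra to MGF
#'
#' @param spectra List of [MsSpectrum-class] objects (MS2).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s@scanId), con)
    writeLines(sprintf("PEPMASS=%.6f", s@precursorMz), con)
    if (!is.na(s@precursorCharge))
      writeLines(sprintf("CHARGE=%d+", s@precursorCharge), con)
    if (!is.na(s@rtime))
      writeLines(sprintf("RTINSECONDS=%.3f", s@rtime), con)
    if (!is.na(s@activation))
      writeLines(sprintf("ACTIVATION=%s", s@activation), con)
    if (length(s@mz))
      writeLines(sprintf("%.6f %.4f", s@mz, s@intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

## --- annotated-match TSV ----------------------------------------------

#' Write annotation results as TSV
#'
#' One row per matched peak (scan, peptidoform, ion label, theoretical and
#' observed m/z, ppm error, intensity), ordered by scan then theoretical
#' m/z; deterministic, so re-runs are byte-identical.
#'
#' @param results List of [AnnotationResult-class] objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotatedTsv <- function(results, path) {
  if (!length(results)) stop("no annotation results to write")
  rows <- lapply(results, function(r) {
    m <- r@matches
    if (!nrow(m)) return(NULL)
    data.frame(scan_id = r@spectrumId,
               peptidoform = formatPeptidoform(r@peptidoform),
               ion = m$label, theo_mz = sprintf("%.6f", m$theoMz),
               obs_mz = sprintf("%.6f", m$obsMz),
               ppm_error = sprintf("%.3f", m$ppmError),
               intensity = sprintf("%.4f", m$intensity),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(scan_id = character(0), peptidoform = character(0),
                     ion = character(0), theo_mz = character(0),
                     obs_mz = character(0), ppm_error = character(0),
                     intensity = character(0))
  else df <- df[order(df$scan_id, as.numeric(df$theo_mz)), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
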