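#' Peptidoform: a peptide sequence with localized modifications
#'
#' A \code{Peptidoform} is the unit of identification in lipidated-peptide
#' proteomics: one peptide sequence together with a specific assignment of
#' modifications to residues (or a terminus). Residue numbering is 1-based;
#' position 0 denotes the peptide N-terminus.
#'
#' @slot sequence Character scalar, the peptide in one-letter code (standard
#'   20 residues only; ambiguity codes are rejected).
#' @slot modPositions Integer vector of modification positions (0 for the
#'   N-terminus, otherwise 1..nchar(sequence)).
#' @slot modNames Character vector, parallel to \code{modPositions}; each
#'   entry is a modification name resolvable in the modification registry.
#' @slot proteinAccession Character scalar or NA; optional protein context.
#' @slot proteinStart Integer scalar or NA; 1-based start of the peptide in
#'   the protein.
#'
#' @seealso [peptidoform()], [parsePeptidoform()], [peptideMass()]
#' @export
setClass("Peptidoform",
  representation(
    sequence = "character",
    modPositions = "integer",
    modNames = "character",
    proteinAccession = "character",
    proteinStart = "integer"
  ),
  prototype(
    sequence = "",
    modPositions = integer(0),
    modNames = character(0),
    proteinAccession = NA_character_,
    proteinStart = NA_integer_
  )
)

setValidity("Peptidoform", function(object) {
  msgs <- character(0)
  seq <- object@sequence
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    msgs <- c(msgs, "sequence must be a non-empty character scalar")
  else {
    bad <- setdiff(strsplit(seq, "")[[1]], names(.RESIDUE_FORMULA))
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown residue letter(s): %s",
                              paste(unique(bad), collapse = ", ")))
  }
  if (length(object@modPositions) != length(object@modNames))
    msgs <- c(msgs, "modPositions and modNames must have equal length")
  if (length(object@modPositions)) {
    n <- nchar(seq)
    if (any(object@modPositions < 0L | object@modPositions > n))
      msgs <- c(msgs, "modification positions must be 0 (N-terminus) or within the sequence")
    resi <- object@modPositions[object@modPositions > 0L]
    if (anyDuplicated(resi))
      msgs <- c(msgs, "two modifications assigned to the same residue")
    ## each mod must target the residue at its position
    reg <- tryCatch(modificationRegistry(), error = function(e) NULL)
    if (!is.null(reg)) {
      for (k in seq_along(object@modPositions)) {
        nm <- object@modNames[k]
        if (!nm %in% reg$name) {
          msgs <- c(msgs, sprintf("unknown modification '%s'", nm))
          next
        }
        pos <- object@modPositions[k]
        targets <- strsplit(reg$targets[reg$name == nm][1], "")[[1]]
        if (pos > 0L && !"*" %in% targets &&
            !substr(seq, pos, pos) %in% targets)
          msgs <- c(msgs, sprintf(
            "modification '%s' does not target residue %s at position %d",
            nm, substr(seq, pos, pos), pos))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Centroided mass spectrum
#'
#' Container for one centroided spectrum (MS1 or MS2) with precursor and
#' activation metadata. Peaks are kept sorted ascending by m/z; retention
#' time is in seconds.
#'
#' @slot scanId Character scalar identifying the scan.
#' @slot msLevel Integer, 1 for survey scans, 2 for fragment spectra.
#' @slot precursorMz Numeric; NA for MS1 scans.
#' @slot precursorCharge Integer; NA when unknown.
#' @slot activation Character: "CID", "HCD", "ETD", "EThcD" or NA.
#' @slot rtime Numeric retention time in seconds.
#' @slot mz Numeric vector of peak m/z values, sorted ascending.
#' @slot intensity Numeric vector of peak intensities, parallel to \code{mz}.
#'
#' @seealso [readMgf()], [readMzml()], [annotateSpectrum()]
#' @export
setClass("MsSpectrum",
  representation(
    scanId = "character",
    msLevel = "integer",
    precursorMz = "numeric",
    precursorCharge = "integer",
    activation = "character",
    rtime = "numeric",
    mz = "numeric",
    intensity = "numeric"
  ),
  prototype(
    scanId = NA_character_, msLevel = 2L, precursorMz = NA_real_,
    precursorCharge = NA_integer_, activation = NA_character_,
    rtime = NA_real_, mz = numeric(0), intensity = numeric(0)
  )
)

setValidity("MsSpectrum", function(object) {
  msgs <- character(0)
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msgs <- c(msgs, "peaks must be sorted ascending by m/z")
  if (length(object@intensity) && any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be >= 0")
  if (!is.na(object@precursorMz) && object@precursorMz <= 0)
    msgs <- c(msgs, "precursorMz must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Annotation of one peptidoform against one spectrum
#'
#' Holds the matched peaks, backbone ion coverage (fraction of the n-1
#' cleavage sites supported by at least one matched sequence ion, including
#' neutral-loss variants), per-series coverage, and the fraction of total
#' ion current explained by the matches.
#'
#' @slot peptidoform The [Peptidoform-class] that was annotated.
#' @slot spectrumId Character scan identifier.
#' @slot matches data.frame with one row per matched theoretical ion
#'   (columns: series, index, charge, nloss, loss, water, label, theoMz,
#'   obsMz, intensity, ppmError, ambiguous).
#' @slot ionCoverage Numeric in [0, 1].
#' @slot perSeriesCoverage Named numeric vector, coverage per backbone series.
#' @slot matchedIntensityFraction Numeric in [0, 1].
#'
#' @seealso [annotateSpectrum()], [ionCoverage()]
#' @export
setClass("AnnotationResult",
  representation(
    peptidoform = "Peptidoform",
    spectrumId = "character",
    matches = "data.frame",
    ionCoverage = "numeric",
    perSeriesCoverage = "numeric",
    matchedIntensityFraction = "numeric"
  )
)

setValidity("AnnotationResult", function(object) {
  msgs <- character(0)
  if (object@ionCoverage < 0 || object@ionCoverage > 1)
    msgs <- c(msgs, "ionCoverage must lie in [0, 1]")
  if (object@matchedIntensityFraction < 0 ||
      object@matchedIntensityFraction > 1 + 1e-9)
    msgs <- c(msgs, "matchedIntensityFraction must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
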