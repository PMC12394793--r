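#' @rdname Peptidoform-class
#' @param object,x An object.
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname Peptidoform-class
#' @export
setGeneric("modifications", function(x) standardGeneric("modifications"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("activationType", function(x) standardGeneric("activationType"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("retentionTime", function(x) standardGeneric("retentionTime"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname MsSpectrum-class
#' @export
setGeneric("msLevel", function(x) standardGeneric("msLevel"))

#' Backbone ion coverage of an annotation
#'
#' Fraction of the \eqn{n-1} backbone cleavage sites of an \eqn{n}-residue
#' peptide supported by at least one matched sequence ion (b/c at index i,
#' or y/z-dot at index n-i). Neutral-loss variants count by default because
#' they retain sequence information; precursor and diagnostic ions never
#' count.
#'
#' @param x An [AnnotationResult-class].
#' @param ... Passed to methods.
#' @return Numeric scalar in [0, 1].
#' @export
setGeneric("ionCoverage", function(x, ...) standardGeneric("ionCoverage"))

#' @rdname AnnotationResult-class
#' @export
setGeneric("peakMatches", function(x) standardGeneric("peakMatches"))

#' @rdname AnnotationResult-class
#' @export
setGeneric("matchedIntensityFraction",
           function(x) standardGeneric("matchedIntensityFraction"))

#' Monoisotopic neutral mass of a peptidoform
#'
#' @param x A [Peptidoform-class] or a plain sequence string.
#' @param ... Passed to methods.
#' @return Neutral monoisotopic mass in Da.
#' @export
setGeneric("peptideMass", function(x, ...) standardGeneric("peptideMass"))
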