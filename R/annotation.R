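#' Match theoretical fragment ions to observed peaks
#'
#' Each theoretical ion is matched to the observed peak minimizing the
#' absolute ppm error within the tolerance. One observed peak may satisfy
#' several theoretical ions; such matches are retained and flagged
#' \code{ambiguous}.
#'
#' @param spectrum An [MsSpectrum-class] (peaks sorted ascending).
#' @param theo data.frame of theoretical ions from [generateFragments()].
#' @param tolPpm Match tolerance in ppm (> 0), default 20.
#' @return \code{theo} subset with added columns \code{obsMz},
#'   \code{intensity}, \code{ppmError}, \code{obsIndex}, \code{ambiguous}.
#' @export
matchPeaks <- function(spectrum, theo, tolPpm = 20) {
  stopifnot(is(spectrum, "MsSpectrum"), tolPpm > 0)
  obs <- spectrum@mz
  if (!length(obs) || !nrow(theo)) {
    out <- theo[integer(0), , drop = FALSE]
    out$obsMz <- numeric(0); out$intensity <- numeric(0)
    out$ppmError <- numeric(0); out$obsIndex <- integer(0)
    out$ambiguous <- logical(0)
    return(out)
  }
  idx <- findInterval(theo$mz, obs)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(obs))
  dLo <- abs(obs[lo] - theo$mz)
  dHi <- abs(obs[hi] - theo$mz)
  best <- ifelse(dHi < dLo, hi, lo)
  ppm <- 1e6 * (obs[best] - theo$mz) / theo$mz
  keep <- abs(ppm) <= tolPpm
  out <- theo[keep, , drop = FALSE]
  out$obsMz <- obs[best][keep]
  out$intensity <- spectrum@intensity[best][keep]
  out$ppmError <- ppm[keep]
  out$obsIndex <- best[keep]
  out$ambiguous <- duplicated(out$obsIndex) |
    duplicated(out$obsIndex, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

## covered cleavage sites given matched sequence ions; b/c index i covers
## site i, y/zdot index j covers site n-j
.coveredSites <- function(matches, n, countLossIons = TRUE) {
  m <- matches[matches$series %in% c("b", "y", "c", "zdot"), , drop = FALSE]
  if (!countLossIons) m <- m[m$nloss == 0L, , drop = FALSE]
  if (!nrow(m)) return(integer(0))
  site <- ifelse(m$series %in% c("b", "c"), m$index, n - m$index)
  sort(unique(site[site >= 1L & site <= n - 1L]))
}

#' Annotate a spectrum with a peptidoform
#'
#' Generates the theoretical ions for the spectrum's activation type and
#' precursor charge, matches them against the observed peaks, and computes
#' backbone ion coverage (fraction of the n-1 cleavage sites supported by
#' a matched sequence ion), per-series coverage and the fraction of total
#' ion current carried by matched peaks. Precursor (p/p*) and diagnostic
#' (d*) matches are reported but never counted toward coverage.
#'
#' @param spectrum An [MsSpectrum-class] MS2 scan.
#' @param pf A [Peptidoform-class].
#' @param tolPpm Fragment tolerance in ppm (default 20).
#' @param rules Activation rules; default derived from the spectrum's
#'   activation type.
#' @param maxFragmentCharge Default \code{min(2, precursor charge)}.
#' @param countLossIons Should neutral-loss ions count toward coverage
#'   (default TRUE; they retain sequence information)?
#' @param lossCap Maximum simultaneous neutral losses per ion.
#' @return An [AnnotationResult-class].
#' @export
annotateSpectrum <- function(spectrum, pf, tolPpm = 20, rules = NULL,
                             maxFragmentCharge = NULL,
                             countLossIons = TRUE, lossCap = 2L) {
  stopifnot(is(spectrum, "MsSpectrum"), is(pf, "Peptidoform"))
  z <- spectrum@precursorCharge
  if (is.na(z)) z <- 2L
  if (is.null(rules)) {
    act <- spectrum@activation
    if (is.na(act)) act <- "HCD"
    rules <- activationRules(act)
  }
  if (is.null(maxFragmentCharge)) maxFragmentCharge <- min(2L, z)
  theo <- generateFragments(pf, rules, maxFragmentCharge = maxFragmentCharge,
                            precursorCharge = z, lossCap = lossCap)
  matches <- matchPeaks(spectrum, theo, tolPpm)
  names(matches)[names(matches) == "mz"] <- "theoMz"
  n <- nchar(pf@sequence)
  covered <- .coveredSites(matches, n, countLossIons)
  perSeries <- vapply(rules$backboneSeries, function(s) {
    length(.coveredSites(matches[matches$series == s, , drop = FALSE], n,
                         countLossIons)) / (n - 1L)
  }, 0)
  tic <- sum(spectrum@intensity)
  mif <- if (tic > 0 && nrow(matches))
    sum(spectrum@intensity[unique(matches$obsIndex)]) / tic else 0
  new("AnnotationResult", peptidoform = pf, spectrumId = spectrum@scanId,
      matches = matches, ionCoverage = length(covered) / (n - 1L),
      perSeriesCoverage = perSeries, matchedIntensityFraction = mif)
}

#' @describeIn ionCoverage coverage stored in an annotation result.
#' @export
setMethod("ionCoverage", "AnnotationResult", function(x, ...) x@ionCoverage)

#' @describeIn AnnotationResult-class matched-peak table.
#' @export
setMethod("peakMatches", "AnnotationResult", function(x) x@matches)

#' @describeIn AnnotationResult-class fraction of total ion current matched.
#' @export
setMethod("matchedIntensityFraction", "AnnotationResult",
          function(x) x@matchedIntensityFraction)

setMethod("show", "AnnotationResult", function(object) {
  cat(sprintf("AnnotationResult: %s vs scan '%s'\n",
              formatPeptidoform(object@peptidoform), object@spectrumId))
  cat(sprintf("  %d matched ions, ion coverage %.1f%%, matched TIC %.1f%%\n",
              nrow(object@matches), 100 * object@ionCoverage,
              100 * object@matchedIntensityFraction))
  ps <- object@perSeriesCoverage
  if (length(ps))
    cat("  per-series coverage:",
        paste(sprintf("%s %.1f%%", names(ps), 100 * ps), collapse = ", "),
        "\n")
  invisible(NULL)
})

#' Ion coverage from a match table
#'
#' Direct computation of backbone cleavage-site coverage from a matched-ion
#' table and the peptide length; used when no [AnnotationResult-class] has
#' been built.
#'
#' @param matches data.frame with columns \code{series}, \code{index},
#'   \code{nloss}.
#' @param n Peptide length (>= 2).
#' @param countLossIons Count neutral-loss variants (default TRUE).
#' @return Fraction of covered cleavage sites in [0, 1].
#' @export
ionCoverageFromMatches <- function(matches, n, countLossIons = TRUE) {
  stopifnot(n >= 2L)
  length(.coveredSites(matches, n, countLossIons)) / (n - 1L)
}
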