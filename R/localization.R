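## Modification-site localization by site-determining ions.
##
## Candidate peptidoforms are every distinct assignment of the given
## modification multiset to the candidate sites. An ion is
## site-determining when its theoretical m/z is not shared by all
## candidate assignments; the score is the number of matched
## site-determining ions plus a small matched-intensity tie-break term.

.assignments <- function(mods, sites) {
  mods <- sort(mods)
  out <- list()
  recurse <- function(i, remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    if (i > length(sites)) return(invisible())
    ## leave site i empty (only if enough sites remain)
    if (length(sites) - i >= length(remaining))
      recurse(i + 1L, remaining, acc)
    for (nm in unique(remaining)) {
      rest <- remaining[-match(nm, remaining)]
      recurse(i + 1L, rest,
              rbind(acc, data.frame(position = sites[i], name = nm)))
    }
  }
  recurse(1L, mods, data.frame(position = integer(0), name = character(0)))
  out
}

#' Localize labile modifications among candidate sites
#'
#' Scores every distinct assignment of a modification multiset to the
#' candidate sites against the observed spectrum. Ions unique to a subset
#' of the assignments (site-determining ions) drive the score; when the
#' spectrum contains none, all assignments tie and \code{deltaScore} is 0
#' (flagged ambiguous).
#'
#' @param spectrum An [MsSpectrum-class] MS2 scan.
#' @param peptide Peptide sequence string.
#' @param modNames Character vector (multiset) of modification names to
#'   place, e.g. \code{c("palmitoyl", "stearoyl")}.
#' @param candidateSites Integer vector of candidate residue positions
#'   (>= 2 candidate assignments must exist).
#' @param tolPpm Fragment tolerance in ppm.
#' @param rules Activation rules; default from the spectrum's activation.
#' @param fixedMods Optional data.frame (position, name) of modifications
#'   present on every candidate (e.g. NEM on non-candidate cysteines).
#' @return List of class \code{"LocalizationResult"}: \code{ranked}
#'   (data.frame peptidoform/score, descending), \code{peptidoforms}
#'   (list, same order), \code{deltaScore}, \code{ambiguous}, and
#'   \code{siteDeterminingMatches} (matches unique to the top form).
#' @examples
#' ## see vignette for a worked two-isoform example
#' @export
localize <- function(spectrum, peptide, modNames, candidateSites,
                     tolPpm = 20, rules = NULL, fixedMods = NULL) {
  stopifnot(is(spectrum, "MsSpectrum"))
  candidateSites <- sort(unique(as.integer(candidateSites)))
  if (!length(candidateSites))
    stop("no candidate sites supplied")
  if (length(modNames) > length(candidateSites))
    stop("more modifications than candidate sites")
  asn <- .assignments(modNames, candidateSites)
  if (length(asn) < 2L)
    stop("localization requires >= 2 candidate assignments")
  results <- lapply(asn, function(a) {
    mods <- rbind(a, fixedMods)
    pf <- peptidoform(peptide, mods)
    annotateSpectrum(spectrum, pf, tolPpm = tolPpm, rules = rules)
  })
  ## site-determining = theoretical keys not shared by all assignments
  z <- spectrum@precursorCharge; if (is.na(z)) z <- 2L
  if (is.null(rules)) {
    act <- spectrum@activation
    rules <- activationRules(if (is.na(act)) "HCD" else act)
  }
  theoKeys <- lapply(asn, function(a) {
    pf <- peptidoform(peptide, rbind(a, fixedMods))
    th <- generateFragments(pf, rules,
                            maxFragmentCharge = min(2L, z),
                            precursorCharge = z)
    sprintf("%.5f", th$mz)
  })
  shared <- Reduce(intersect, theoKeys)
  scores <- vapply(seq_along(results), function(i) {
    m <- results[[i]]@matches
    sd <- !sprintf("%.5f", m$theoMz) %in% shared
    sum(sd) + 0.01 * results[[i]]@matchedIntensityFraction
  }, 0)
  pfText <- vapply(results, function(r) formatPeptidoform(r@peptidoform), "")
  ord <- order(-scores, pfText)
  ranked <- data.frame(peptidoform = pfText[ord], score = scores[ord],
                       stringsAsFactors = FALSE)
  delta <- if (length(ord) > 1L) ranked$score[1] - ranked$score[2] else 0
  topM <- results[[ord[1]]]@matches
  sdTop <- topM[!sprintf("%.5f", topM$theoMz) %in% shared, , drop = FALSE]
  structure(list(
    ranked = ranked,
    peptidoforms = lapply(ord, function(i) results[[i]]@peptidoform),
    annotations = results[ord],
    deltaScore = delta,
    ambiguous = delta <= 0,
    siteDeterminingMatches = sdTop
  ), class = "LocalizationResult")
}

#' @export
print.LocalizationResult <- function(x, ...) {
  cat("LocalizationResult\n")
  print(utils::head(x$ranked, 5))
  cat(sprintf("deltaScore = %.3f%s\n", x$deltaScore,
              if (x$ambiguous) " (ambiguous)" else ""))
  invisible(x)
}
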