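#' Search parameters
#'
#' Defaults mirror a lipid-aware discovery search: 20 ppm precursor and
#' fragment tolerances, strict tryptic digestion with two missed
#' cleavages, reversed decoys and a 1% PSM FDR threshold.
#'
#' @param precursorTolPpm,fragmentTolPpm Mass tolerances in ppm.
#' @param digest A [digestParams()] object.
#' @param modNames Variable modifications considered (registry names).
#' @param maxMods Maximum variable modifications per peptide.
#' @param fdrThreshold PSM q-value cut-off in (0, 1].
#' @param lipidIons Should neutral-loss and diagnostic ions contribute to
#'   the score (TRUE; set FALSE for ablation)?
#' @param minMatchedIons Minimum number of matched scoreable ions for a
#'   candidate to be reported as a PSM (default 4; sparser matches carry
#'   no sequence evidence and only dilute the target-decoy estimate).
#' @return List of class \code{"SearchParams"}.
#' @export
searchParams <- function(precursorTolPpm = 20, fragmentTolPpm = 20,
                         digest = digestParams(),
                         modNames = c("palmitoyl", "NEM"),
                         maxMods = 3L, fdrThreshold = 0.01,
                         lipidIons = TRUE, minMatchedIons = 4L) {
  stopifnot(precursorTolPpm > 0, fragmentTolPpm > 0,
            fdrThreshold > 0, fdrThreshold <= 1, minMatchedIons >= 0)
  structure(list(precursorTolPpm = precursorTolPpm,
                 fragmentTolPpm = fragmentTolPpm, digest = digest,
                 modNames = modNames, maxMods = as.integer(maxMods),
                 fdrThreshold = fdrThreshold,
                 lipidIons = isTRUE(lipidIons),
                 minMatchedIons = as.integer(minMatchedIons)),
            class = "SearchParams")
}

## reversed decoy keeping the C-terminal residue (preserves tryptic
## C-terminal K/R at the protein end)
.reverseDecoy <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  paste(c(rev(chars[-n]), chars[n]), collapse = "")
}

#' Build a peptidoform candidate index
#'
#' Digests every target protein and its reversed decoy (per-protein
#' reversal with the C-terminal residue fixed), enumerates
#' variable-modification peptidoforms, and stores them keyed by neutral
#' mass for precursor-window queries.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   protein sequences.
#' @param params A [searchParams()] object.
#' @return List of class \code{"PeptidoformIndex"}: \code{table}
#'   (data.frame sorted by \code{mass}: mass, peptidoform, peptide,
#'   protein, start, isDecoy) and \code{peptidoforms} (parallel list of
#'   [Peptidoform-class] objects).
#' @export
buildIndex <- function(fasta, params = searchParams()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) readFasta(fasta) else fasta
  if (!length(seqs)) stop("empty protein set")
  if (is.null(names(seqs))) stop("protein sequences must be named")
  decoys <- vapply(seqs, .reverseDecoy, "")
  names(decoys) <- paste0("rev_", names(seqs))
  all <- c(seqs, decoys)
  isDecoy <- c(rep(FALSE, length(seqs)), rep(TRUE, length(decoys)))
  pfs <- list(); rows <- list()
  for (i in seq_along(all)) {
    peps <- digestProtein(all[[i]], params$digest)
    if (!nrow(peps)) next
    for (j in seq_len(nrow(peps))) {
      forms <- enumeratePeptidoforms(peps$peptide[j], params$modNames,
                                     maxMods = params$maxMods,
                                     proteinStart = peps$start[j])
      for (pf in forms) {
        pf@proteinAccession <- names(all)[i]
        pfs[[length(pfs) + 1L]] <- pf
        rows[[length(rows) + 1L]] <- data.frame(
          mass = peptideMass(pf), peptidoform = formatPeptidoform(pf),
          peptide = peps$peptide[j], protein = names(all)[i],
          start = peps$start[j], isDecoy = isDecoy[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$mass)
  structure(list(table = tab[ord, , drop = FALSE],
                 peptidoforms = pfs[ord]),
            class = "PeptidoformIndex")
}

#' @export
print.PeptidoformIndex <- function(x, ...) {
  cat(sprintf("PeptidoformIndex: %d peptidoforms (%d decoy), mass %.2f-%.2f Da\n",
              nrow(x$table), sum(x$table$isDecoy),
              min(x$table$mass), max(x$table$mass)))
  invisible(x)
}

#' Score one spectrum against the candidate index
#'
#' Candidates within the precursor tolerance of the observed neutral mass
#' are scored as the number of matched backbone ions (neutral-loss
#' variants and the d* diagnostic included when \code{lipidIons}) plus
#' 0.01 x matched-intensity fraction as a tie-break.
#'
#' @param spectrum An [MsSpectrum-class] MS2 scan.
#' @param index A [buildIndex()] result.
#' @param params A [searchParams()] object.
#' @return data.frame of candidate PSMs ranked by descending score
#'   (columns: spectrumId, peptidoform, peptide, protein, start, isDecoy,
#'   score, chargeAssumed); zero rows when nothing falls in the window.
#' @export
searchSpectrum <- function(spectrum, index, params = searchParams()) {
  z <- spectrum@precursorCharge
  charges <- if (is.na(z)) 2:4 else z
  act <- spectrum@activation
  rules <- activationRules(if (is.na(act)) "HCD" else act)
  hits <- list()
  masses <- index$table$mass
  for (zz in charges) {
    obsMass <- neutralMass(spectrum@precursorMz, zz)
    tol <- obsMass * params$precursorTolPpm * 1e-6
    lo <- findInterval(obsMass - tol, masses) + 1L
    hi <- findInterval(obsMass + tol, masses)
    if (hi < lo) next
    for (k in lo:hi) {
      pf <- index$peptidoforms[[k]]
      theo <- generateFragments(pf, rules,
                                maxFragmentCharge = min(2L, zz),
                                precursorCharge = zz)
      m <- matchPeaks(spectrum, theo, params$fragmentTolPpm)
      scoreable <- m$series %in% c("b", "y", "c", "zdot", "d")
      if (!params$lipidIons)
        scoreable <- scoreable & m$nloss == 0L & m$series != "d"
      if (sum(scoreable) < params$minMatchedIons) next
      tic <- sum(spectrum@intensity)
      mif <- if (tic > 0 && nrow(m))
        sum(spectrum@intensity[unique(m$obsIndex)]) / tic else 0
      hits[[length(hits) + 1L]] <- data.frame(
        spectrumId = spectrum@scanId,
        peptidoform = index$table$peptidoform[k],
        peptide = index$table$peptide[k],
        protein = index$table$protein[k],
        start = index$table$start[k],
        isDecoy = index$table$isDecoy[k],
        score = sum(scoreable) + 0.01 * mif,
        chargeAssumed = is.na(z), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(spectrumId = character(0), peptidoform = character(0),
                      peptide = character(0), protein = character(0),
                      start = integer(0), isDecoy = logical(0),
                      score = numeric(0), chargeAssumed = logical(0)))
  df <- do.call(rbind, hits)
  df[order(-df$score, df$peptidoform), , drop = FALSE]
}

#' Target-decoy q-values
#'
#' Sorts PSMs by descending score; the running FDR at each threshold is
#' decoys/targets (1 when no target has been seen), and the q-value is the
#' monotone minimum of downstream FDRs.
#'
#' @param psms data.frame with columns \code{score} and \code{isDecoy}.
#' @return \code{psms} with an added \code{qValue} column (input order
#'   preserved).
#' @export
computeFdr <- function(psms) {
  if (!nrow(psms)) { psms$qValue <- numeric(0); return(psms) }
  ord <- order(-psms$score)
  dec <- cumsum(psms$isDecoy[ord])
  tar <- cumsum(!psms$isDecoy[ord])
  fdr <- ifelse(tar == 0, 1, dec / pmax(tar, 1))
  q <- rev(cummin(rev(pmin(fdr, 1))))
  psms$qValue <- NA_real_
  psms$qValue[ord] <- q
  psms
}

#' Search a set of spectra and estimate FDR
#'
#' Keeps the top-scoring candidate per spectrum and assigns target-decoy
#' q-values over the retained PSMs.
#'
#' @param spectra List of [MsSpectrum-class] MS2 scans.
#' @param index A [buildIndex()] result.
#' @param params A [searchParams()] object.
#' @return data.frame of PSMs with \code{qValue}; spectra with no
#'   candidate in the precursor window are absent.
#' @export
runSearch <- function(spectra, index, params = searchParams()) {
  tops <- lapply(spectra, function(s) {
    h <- searchSpectrum(s, index, params)
    if (nrow(h)) h[1, , drop = FALSE] else NULL
  })
  psms <- do.call(rbind, tops)
  if (is.null(psms))
    return(data.frame(spectrumId = character(0), peptidoform = character(0),
                      peptide = character(0), protein = character(0),
                      start = integer(0), isDecoy = logical(0),
                      score = numeric(0), chargeAssumed = logical(0),
                      qValue = numeric(0)))
  rownames(psms) <- NULL
  computeFdr(psms)
}

#' Write a PSM table as TSV
#' @param psms data.frame from [runSearch()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePsmTsv <- function(psms, path) {
  df <- psms
  df$score <- sprintf("%.4f", df$score)
  if ("qValue" %in% names(df)) df$qValue <- sprintf("%.6f", df$qValue)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
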