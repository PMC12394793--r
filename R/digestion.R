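#' In-silico digestion parameters
#'
#' Defaults mirror a discovery-proteomics configuration: strict trypsin
#' (cleave C-terminal to K/R except before proline), two missed cleavages,
#' peptide length 7-50 and protein N-terminal methionine clipping.
#'
#' @param enzyme Only \code{"trypsin_strict"} is implemented.
#' @param missedCleavages Integer 0-5.
#' @param minLength,maxLength Retained peptide length bounds (residues).
#' @param clipNtermMet Also emit peptides from the Met-clipped protein when
#'   the sequence starts with M (clipped and unclipped sets are both kept,
#'   deduplicated).
#' @return List of class \code{"DigestParams"}.
#' @export
digestParams <- function(enzyme = "trypsin_strict", missedCleavages = 2L,
                         minLength = 7L, maxLength = 50L,
                         clipNtermMet = TRUE) {
  enzyme <- match.arg(enzyme)
  missedCleavages <- as.integer(missedCleavages)
  stopifnot(missedCleavages >= 0L, missedCleavages <= 5L,
            minLength <= maxLength, minLength >= 1L)
  structure(list(enzyme = enzyme, missedCleavages = missedCleavages,
                 minLength = as.integer(minLength),
                 maxLength = as.integer(maxLength),
                 clipNtermMet = isTRUE(clipNtermMet)),
            class = "DigestParams")
}

.trypticSegments <- function(sequence, params, offset = 0L) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  ## cleavage after K/R not followed by P
  sites <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  bounds <- c(0L, sites, n)
  out <- vector("list", 0L)
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + params$missedCleavages)) {
      pep <- substr(sequence, bounds[i] + 1L, bounds[j])
      len <- bounds[j] - bounds[i]
      if (len < params$minLength || len > params$maxLength) next
      out[[length(out) + 1L]] <- list(peptide = pep,
                                      start = bounds[i] + 1L + offset,
                                      missed = j - i - 1L)
    }
  }
  out
}

#' Digest a protein sequence with strict trypsin
#'
#' Cleaves C-terminal to K or R except when the next residue is proline,
#' allows up to \code{missedCleavages} skipped sites, filters on peptide
#' length, and (optionally) also digests the Met-clipped form of proteins
#' starting with M. Duplicate peptides arising from the clipped and
#' unclipped forms are removed by (sequence, start).
#'
#' @param sequence Protein sequence string.
#' @param params A [digestParams()] object.
#' @return data.frame with columns \code{peptide}, \code{start} (1-based
#'   position in the supplied protein), \code{missed}.
#' @examples
#' digestProtein("MKAKRPCDEKLR", digestParams(missedCleavages = 0,
#'   minLength = 1, clipNtermMet = FALSE))
#' @export
digestProtein <- function(sequence, params = digestParams()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]], names(.RESIDUE_FORMULA))
  if (length(bad))
    stop(sprintf("non-standard residue(s) in protein: %s",
                 paste(unique(bad), collapse = ", ")))
  segs <- .trypticSegments(sequence, params)
  if (params$clipNtermMet && startsWith(sequence, "M") && nchar(sequence) > 1L)
    segs <- c(segs, .trypticSegments(substr(sequence, 2L, nchar(sequence)),
                                     params, offset = 1L))
  if (!length(segs))
    return(data.frame(peptide = character(0), start = integer(0),
                      missed = integer(0)))
  df <- data.frame(
    peptide = vapply(segs, `[[`, "", "peptide"),
    start = vapply(segs, `[[`, 0L, "start"),
    missed = vapply(segs, `[[`, 0L, "missed"))
  df <- df[!duplicated(df[c("peptide", "start")]), ]
  df[order(df$start, nchar(df$peptide)), , drop = FALSE]
}

#' Enumerate variable-modification peptidoforms
#'
#' Every assignment giving each eligible site one of {unmodified} or an
#' applicable modification, with at most \code{maxMods} modifications in
#' total. Ordering is deterministic: sites left to right, and at each site
#' "unmodified" first, then modification names alphabetically.
#'
#' @param peptide Peptide sequence string.
#' @param modNames Character vector of registry modification names to
#'   consider as variable.
#' @param maxMods Maximum total number of variable modifications on one
#'   peptide (default 3).
#' @param proteinStart 1-based start of the peptide within its protein (NA
#'   when unknown); protein-N-terminal modifications are only eligible when
#'   the peptide starts at position 1 or 2 (Met-clipped).
#' @param registry Modification registry data.frame.
#' @return List of [Peptidoform-class] objects; the unmodified form is
#'   always first.
#' @examples
#' length(enumeratePeptidoforms("ACDCK", c("palmitoyl", "NEM")))  # 9
#' @export
enumeratePeptidoforms <- function(peptide, modNames, maxMods = 3L,
                                  proteinStart = NA_integer_,
                                  registry = modificationRegistry()) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  maxMods <- as.integer(maxMods)
  res <- strsplit(peptide, "")[[1]]
  mods <- lapply(sort(unique(modNames)), getModification, registry = registry)
  ## site -> applicable modification names
  siteMods <- list()
  for (mod in mods) {
    if (mod$positionRule == "protein-N-term") {
      if (!is.na(proteinStart) && proteinStart <= 2L)
        siteMods[["0"]] <- sort(c(siteMods[["0"]], mod$name))
      next
    }
    posn <- if ("*" %in% mod$targets) seq_along(res)
            else which(res %in% mod$targets)
    if (mod$positionRule == "peptide-N-term") posn <- intersect(posn, 1L)
    for (p in posn)
      siteMods[[as.character(p)]] <- sort(c(siteMods[[as.character(p)]],
                                            mod$name))
  }
  sitePos <- sort(as.integer(names(siteMods)))
  out <- list()
  assign_df <- function(pos, nms) {
    keep <- nzchar(nms)
    pf <- peptidoform(peptide,
                      if (any(keep)) data.frame(position = pos[keep],
                                                name = nms[keep]),
                      proteinStart = proteinStart)
    out[[length(out) + 1L]] <<- pf
  }
  recurse <- function(i, pos, nms, used) {
    if (i > length(sitePos)) { assign_df(pos, nms); return(invisible()) }
    p <- sitePos[i]
    ## unmodified first
    recurse(i + 1L, c(pos, p), c(nms, ""), used)
    if (used < maxMods)
      for (nm in siteMods[[as.character(p)]])
        recurse(i + 1L, c(pos, p), c(nms, nm), used + 1L)
  }
  recurse(1L, integer(0), character(0), 0L)
  out
}

#' Read a protein FASTA file
#'
#' Multi-record FASTA with wrapped lines; the accession is the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop(sprintf("no FASTA records in %s", path))
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write a protein FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
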