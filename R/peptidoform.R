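#' Construct a Peptidoform
#'
#' @param sequence Peptide sequence (one-letter code, standard residues).
#' @param modifications NULL, or a data.frame with columns \code{position}
#'   (0 for the peptide N-terminus, otherwise 1-based residue index) and
#'   \code{name} (registry modification name).
#' @param proteinAccession,proteinStart Optional protein context.
#' @return A validated [Peptidoform-class].
#' @examples
#' peptidoform("ACDK", data.frame(position = 2, name = "palmitoyl"))
#' @export
peptidoform <- function(sequence, modifications = NULL,
                        proteinAccession = NA_character_,
                        proteinStart = NA_integer_) {
  if (is.null(modifications) || !nrow(modifications)) {
    pos <- integer(0); nms <- character(0)
  } else {
    ord <- order(modifications$position, modifications$name)
    pos <- as.integer(modifications$position[ord])
    nms <- as.character(modifications$name[ord])
  }
  new("Peptidoform", sequence = as.character(sequence),
      modPositions = pos, modNames = nms,
      proteinAccession = as.character(proteinAccession),
      proteinStart = as.integer(proteinStart))
}

#' Parse peptidoform text notation
#'
#' The user-facing grammar is the sequence with bracketed modification
#' names after the modified residue and an optional \code{"/charge"}
#' suffix, e.g. \code{"IC[palmitoyl]LR/2"}. An N-terminal modification is
#' written as a leading \code{"[name]-"} prefix.
#'
#' @param text Peptidoform string.
#' @return List with elements \code{peptidoform} ([Peptidoform-class]) and
#'   \code{charge} (integer, NA when no suffix given).
#' @examples
#' parsePeptidoform("IC[palmitoyl]LR/2")
#' @export
parsePeptidoform <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  charge <- NA_integer_
  if (grepl("/", text, fixed = TRUE)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !grepl("^[0-9]+$", parts[2]))
      stop(sprintf("malformed charge suffix in '%s' (expected e.g. '/2')", text))
    charge <- as.integer(parts[2])
    if (charge < 1L) stop("charge must be >= 1")
    text <- parts[1]
  }
  pos <- integer(0); nms <- character(0)
  ## N-terminal prefix "[name]-"
  ntm <- regmatches(text, regexec("^\\[([^]]+)\\]-", text))[[1]]
  if (length(ntm)) {
    pos <- c(pos, 0L); nms <- c(nms, ntm[2])
    text <- sub("^\\[[^]]+\\]-", "", text)
  }
  seqChars <- character(0)
  i <- 1L
  while (i <= nchar(text)) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(text, i, nchar(text)), fixed = TRUE)
      if (j < 0) stop(sprintf("unclosed '[' at position %d in '%s'", i, text))
      if (!length(seqChars))
        stop("modification bracket before any residue; use '[name]-' for the N-terminus")
      nms <- c(nms, substr(text, i + 1L, i + j - 2L))
      pos <- c(pos, length(seqChars))
      i <- i + j
    } else if (grepl("^[A-Za-z]$", ch)) {
      seqChars <- c(seqChars, toupper(ch))
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d in '%s'",
                   ch, i, text))
    }
  }
  if (!length(seqChars)) stop("empty peptide sequence")
  pf <- peptidoform(paste(seqChars, collapse = ""),
                    if (length(pos)) data.frame(position = pos, name = nms))
  list(peptidoform = pf, charge = charge)
}

#' Format a peptidoform in text notation
#' @param x A [Peptidoform-class].
#' @return Character scalar like \code{"IC[palmitoyl]LR"}.
#' @export
formatPeptidoform <- function(x) {
  stopifnot(is(x, "Peptidoform"))
  res <- strsplit(x@sequence, "")[[1]]
  out <- res
  for (k in seq_along(x@modPositions)) {
    p <- x@modPositions[k]
    if (p > 0L) out[p] <- paste0(out[p], "[", x@modNames[k], "]")
  }
  pre <- ""
  nt <- which(x@modPositions == 0L)
  if (length(nt)) pre <- paste0("[", x@modNames[nt[1]], "]-")
  paste0(pre, paste(out, collapse = ""))
}

#' @describeIn Peptidoform-class the bare sequence.
#' @export
setMethod("peptideSequence", "Peptidoform", function(x) x@sequence)

#' @describeIn Peptidoform-class data.frame of (position, name).
#' @export
setMethod("modifications", "Peptidoform", function(x)
  data.frame(position = x@modPositions, name = x@modNames,
             stringsAsFactors = FALSE))

setMethod("show", "Peptidoform", function(object) {
  cat("Peptidoform:", formatPeptidoform(object), "\n")
  cat(sprintf("  length %d, %d modification(s), neutral mass %.5f Da\n",
              nchar(object@sequence), length(object@modNames),
              peptideMass(object)))
  if (!is.na(object@proteinAccession))
    cat(sprintf("  protein %s @ %d\n", object@proteinAccession,
                object@proteinStart))
  invisible(NULL)
})
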