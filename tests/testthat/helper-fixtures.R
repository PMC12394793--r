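# shared fixture builders (all generated in code; nothing on disk)

# random tryptic-style peptide: body without C/K/R/P, nCys cysteines at
# random interior positions, K or R terminus
random_peptide <- function(len, nCys = 1L) {
  pool <- c("A", "G", "L", "V", "F", "D", "E", "N", "Q", "H", "S", "T",
            "Y", "I", "W", "M")
  body <- sample(pool, len - 1L, replace = TRUE)
  if (nCys > 0L)
    body[sample(seq_len(len - 1L), nCys)] <- "C"
  paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
}

# random peptidoform with lipid mods on a subset of its cysteines
random_lipid_peptidoform <- function(len = 10L, nCys = 1L,
                                     mods = "palmitoyl") {
  pep <- random_peptide(len, nCys)
  cys <- which(strsplit(pep, "")[[1]] == "C")
  if (!length(cys)) return(peptidoform(pep))
  peptidoform(pep, data.frame(position = cys,
                              name = sample(mods, length(cys),
                                            replace = TRUE)))
}

proton <- 1.007276466
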