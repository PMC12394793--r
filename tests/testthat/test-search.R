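toy_proteins <- c(
  TPA = "MACDEFKGHCIKLMNQRAAGK",
  TPB = "MKLCAAEGRDDFNCHKAAAR")

toy_params <- function(...) searchParams(
  digest = digestParams(missedCleavages = 1, minLength = 5,
                        maxLength = 30, clipNtermMet = TRUE),
  modNames = c("palmitoyl", "NEM"), maxMods = 2, ...)

test_that("index size equals brute-force enumeration over both strands", {
  params <- toy_params()
  idx <- buildIndex(toy_proteins, params)
  ## oracle: digest targets and reversed decoys, count peptidoforms
  revFix <- function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(c(rev(ch[-length(ch)]), ch[length(ch)]), collapse = "")
  }
  all <- c(toy_proteins, vapply(toy_proteins, revFix, ""))
  oracle <- 0L
  for (s in all) {
    peps <- digestProtein(s, params$digest)
    for (j in seq_len(nrow(peps)))
      oracle <- oracle + length(
        enumeratePeptidoforms(peps$peptide[j], params$modNames,
                              maxMods = params$maxMods,
                              proteinStart = peps$start[j]))
  }
  expect_equal(nrow(idx$table), oracle)
  expect_false(is.unsorted(idx$table$mass))
  ## decoy peptides disjoint from targets for these non-palindromic toys
  expect_length(intersect(idx$table$peptide[!idx$table$isDecoy],
                          idx$table$peptide[idx$table$isDecoy]), 0L)
})

test_that("length bounds propagate into the index", {
  p7 <- toy_params()
  p7$digest <- digestParams(missedCleavages = 0, minLength = 7,
                            maxLength = 50, clipNtermMet = FALSE)
  p1 <- toy_params()
  p1$digest <- digestParams(missedCleavages = 0, minLength = 1,
                            maxLength = 50, clipNtermMet = FALSE)
  i7 <- buildIndex(toy_proteins, p7)
  i1 <- buildIndex(toy_proteins, p1)
  expect_true(all(nchar(i7$table$peptide) >= 7))
  expect_true(any(nchar(i1$table$peptide) < 7))
  expect_gt(nrow(i1$table), nrow(i7$table))
})

test_that("a planted spectrum is identified at rank 1", {
  params <- toy_params()
  idx <- buildIndex(toy_proteins, params)
  truth <- peptidoform("GHCIK", data.frame(position = 3, name = "palmitoyl"))
  sim <- simulateSpectrum(truth, "HCD", 2, jitterPpm = 2, noisePeaks = 10,
                          seed = 5, scanId = "planted")
  hits <- searchSpectrum(sim$spectrum, idx, params)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$peptidoform[1], formatPeptidoform(truth))
  expect_false(hits$isDecoy[1])
})

test_that("precursors far from all candidates return nothing", {
  params <- toy_params()
  idx <- buildIndex(toy_proteins, params)
  sp <- msSpectrum(c(200, 300), c(1, 1), precursorMz = 5000,
                   precursorCharge = 2L, activation = "HCD",
                   scanId = "far")
  expect_equal(nrow(searchSpectrum(sp, idx, params)), 0L)
})

test_that("isobaric acyl-swap candidates are resolved by site ions", {
  pep <- "ACDDACDK"
  protein <- c(ISOP = paste0("M", pep, "AAAK"))
  params <- toy_params()
  params$modNames <- c("palmitoyl", "stearoyl")
  idx <- buildIndex(protein, params)
  truth <- peptidoform(pep, data.frame(position = c(2, 6),
                                       name = c("palmitoyl", "stearoyl")))
  swapped <- peptidoform(pep, data.frame(position = c(2, 6),
                                         name = c("stearoyl", "palmitoyl")))
  expect_equal(peptideMass(truth), peptideMass(swapped))  # isobaric pair
  sim <- simulateSpectrum(truth, "HCD", 2, jitterPpm = 1, seed = 8,
                          scanId = "iso")
  hits <- searchSpectrum(sim$spectrum, idx, params)
  expect_true(all(c(formatPeptidoform(truth), formatPeptidoform(swapped))
                  %in% hits$peptidoform))
  expect_equal(hits$peptidoform[1], formatPeptidoform(truth))
})

test_that("q-values follow the target-decoy formula on a hand example", {
  psms <- data.frame(score = c(10, 9, 8, 7),
                     isDecoy = c(FALSE, FALSE, TRUE, FALSE))
  q <- computeFdr(psms)$qValue
  ## running FDR: 0/1, 0/2, 1/2, 1/3; monotone minimum from the bottom
  expect_equal(q, c(0, 0, 1/3, 1/3))
  ## all decoys outscore all targets
  worst <- data.frame(score = c(10, 9, 2, 1),
                      isDecoy = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(computeFdr(worst)$qValue[3:4] == 1))
  ## no decoys at all
  none <- data.frame(score = 3:1, isDecoy = rep(FALSE, 3))
  expect_equal(computeFdr(none)$qValue, rep(0, 3))
  ## q-values are non-increasing with score
  set.seed(31)
  rnd <- data.frame(score = runif(50), isDecoy = runif(50) < 0.5)
  qq <- computeFdr(rnd)
  ord <- order(-qq$score)
  expect_true(all(diff(qq$qValue[ord]) >= -1e-12))
})

test_that("runSearch keeps one PSM per spectrum and assigns q-values", {
  params <- toy_params()
  idx <- buildIndex(toy_proteins, params)
  truths <- list(
    peptidoform("GHCIK", data.frame(position = 3, name = "palmitoyl")),
    peptidoform("LCAAEGR", data.frame(position = 2, name = "NEM")))
  spectra <- lapply(seq_along(truths), function(i)
    simulateSpectrum(truths[[i]], "HCD", 2, jitterPpm = 2, seed = 50 + i,
                     scanId = sprintf("s%d", i))$spectrum)
  psms <- runSearch(spectra, idx, params)
  expect_equal(nrow(psms), 2L)
  expect_setequal(psms$peptidoform,
                  vapply(truths, formatPeptidoform, ""))
  expect_true(all(psms$qValue == 0))
  tf <- tempfile(fileext = ".tsv")
  writePsmTsv(psms, tf)
  expect_equal(nrow(read.delim(tf)), 2L)
})
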