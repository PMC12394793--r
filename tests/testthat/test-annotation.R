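test_that("peak matching minimizes |ppm| within tolerance", {
  theo <- data.frame(series = "y", index = 1L, charge = 1L, nloss = 0L,
                     loss = "", water = 0L, mz = 500.0, label = "y1",
                     extrapolated = FALSE)
  sp <- msSpectrum(c(500.0050), c(10), precursorMz = 500, scanId = "s")
  m <- matchPeaks(sp, theo, 20)
  expect_equal(m$ppmError, 10, tolerance = 1e-6)
  sp2 <- msSpectrum(c(500.0150), c(10), precursorMz = 500)
  expect_equal(nrow(matchPeaks(sp2, theo, 20)), 0L)  # 30 ppm away
  ## tie-break by |ppm|: +5 ppm beats -8 ppm
  sp3 <- msSpectrum(c(500 * (1 - 8e-6), 500 * (1 + 5e-6)), c(1, 2),
                    precursorMz = 500)
  m3 <- matchPeaks(sp3, theo, 20)
  expect_equal(m3$ppmError, 5, tolerance = 1e-3)
})

test_that("match sets are monotone in tolerance", {
  pf <- random_lipid_peptidoform(10, 1)
  sim <- simulateSpectrum(pf, "HCD", 2, jitterPpm = 5, noisePeaks = 30,
                          seed = 3)
  theo <- generateFragments(pf, activationRules("HCD"),
                            precursorCharge = 2)
  for (pair in list(c(2, 5), c(5, 10), c(10, 20))) {
    m1 <- matchPeaks(sim$spectrum, theo, pair[1])
    m2 <- matchPeaks(sim$spectrum, theo, pair[2])
    expect_true(all(m1$label %in% m2$label))
  }
})

test_that("ion coverage follows the cleavage-site definition", {
  ## n=8, only y2* and b5 matched -> sites {6, 5} -> 2/7
  matches <- data.frame(series = c("y", "b"), index = c(2L, 5L),
                        nloss = c(1L, 0L))
  expect_equal(ionCoverageFromMatches(matches, 8), 2 / 7)
  ## loss ions can be excluded in strict mode
  expect_equal(ionCoverageFromMatches(matches, 8, countLossIons = FALSE),
               1 / 7)
  ## all of y1..y7 -> 1.0
  expect_equal(ionCoverageFromMatches(
    data.frame(series = "y", index = 1:7, nloss = 0L), 8), 1)
  ## precursor/diagnostic ions never count
  expect_equal(ionCoverageFromMatches(
    data.frame(series = c("p", "d"), index = c(0L, 0L),
               nloss = c(1L, 1L)), 8), 0)
  expect_equal(ionCoverageFromMatches(
    data.frame(series = character(0), index = integer(0),
               nloss = integer(0)), 8), 0)
})

test_that("noiseless self-annotation reaches full coverage", {
  set.seed(9)
  for (i in 1:5) {
    pf <- random_lipid_peptidoform(sample(8:12, 1), sample(1:2, 1))
    sim <- simulateSpectrum(pf, "HCD", 2, ionSamplingFraction = 1,
                            jitterPpm = 0, noisePeaks = 0,
                            seed = 40 + i)
    ann <- annotateSpectrum(sim$spectrum, pf, tolPpm = 5)
    expect_equal(ionCoverage(ann), 1)
    ## near-coincident theoretical ions can leave the odd peak unclaimed,
    ## so the matched ion current is high but not exactly 1
    expect_gt(matchedIntensityFraction(ann), 0.95)
  }
})

test_that("localization ranks the true isoform first when evidence exists", {
  ## palmitoyl@C2 / stearoyl@C6 vs the swapped isobaric isoform
  pep <- "ACDDACDK"
  truth <- peptidoform(pep, data.frame(position = c(2, 6),
                                       name = c("palmitoyl", "stearoyl")))
  sim <- simulateSpectrum(truth, "HCD", 2, seed = 77)
  loc <- localize(sim$spectrum, pep, c("palmitoyl", "stearoyl"),
                  candidateSites = c(2, 6))
  expect_equal(loc$ranked$peptidoform[1], formatPeptidoform(truth))
  expect_gt(loc$deltaScore, 0)
  expect_false(loc$ambiguous)
  expect_gt(nrow(loc$siteDeterminingMatches), 0)
})

test_that("spectra without site-determining ions are flagged ambiguous", {
  pep <- "ACDDACDK"
  truth <- peptidoform(pep, data.frame(position = c(2, 6),
                                       name = c("palmitoyl", "stearoyl")))
  ## spectrum holding only the precursor ion: shared by all assignments
  sp <- msSpectrum(mzFromMass(peptideMass(truth), 2), 100,
                   precursorMz = mzFromMass(peptideMass(truth), 2),
                   precursorCharge = 2L, activation = "HCD", scanId = "amb")
  loc <- localize(sp, pep, c("palmitoyl", "stearoyl"),
                  candidateSites = c(2, 6))
  expect_equal(loc$deltaScore, 0)
  expect_true(loc$ambiguous)
})

test_that("localization demands at least two candidate assignments", {
  pep <- "ACDDK"
  expect_error(localize(msSpectrum(100, 1, precursorMz = 100), pep,
                        "palmitoyl", candidateSites = 2),
               ">= 2 candidate")
  expect_error(localize(msSpectrum(100, 1, precursorMz = 100), pep,
                        "palmitoyl", candidateSites = integer(0)),
               "no candidate")
})
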