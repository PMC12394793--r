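make_spectra <- function(n = 3) {
  lapply(seq_len(n), function(i) {
    set.seed(100 + i)
    mz <- sort(runif(20, 150, 1500))
    msSpectrum(mz, runif(20, 1, 1000), scanId = sprintf("scan=%d", i),
               msLevel = 2L, precursorMz = 500.25 + i,
               precursorCharge = 2L, activation = "HCD", rtime = 60 * i)
  })
}

test_that("MGF round-trip preserves peaks and metadata", {
  sp <- make_spectra(3)
  tf <- tempfile(fileext = ".mgf")
  writeMgf(sp, tf)
  back <- readMgf(tf)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(peakTable(back[[i]])$mz, peakTable(sp[[i]])$mz,
                 tolerance = 1e-4 / 500)
    expect_equal(peakTable(back[[i]])$intensity,
                 peakTable(sp[[i]])$intensity, tolerance = 1e-3)
    expect_equal(precursorCharge(back[[i]]), 2L)
    expect_equal(activationType(back[[i]]), "HCD")
    expect_equal(retentionTime(back[[i]]), 60 * i)
  }
})

test_that("MGF parser handles charge conventions, sorting and errors", {
  tf <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=t1", "PEPMASS=500.1", "CHARGE=+2",
               "300.2 10", "100.1 5", "END IONS"), tf)
  expect_warning(sp <- readMgf(tf), "assuming HCD")
  expect_equal(precursorCharge(sp[[1]]), 2L)
  expect_equal(peakTable(sp[[1]])$mz, c(100.1, 300.2))  # sorted on read
  writeLines(c("BEGIN IONS", "TITLE=broken", "CHARGE=2+",
               "100 1", "END IONS"), tf)
  expect_error(readMgf(tf), "broken")     # missing PEPMASS names the title
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=1"), tf)
  expect_error(readMgf(tf), "truncated")
  writeLines(character(0), tf)
  expect_warning(out <- readMgf(tf), "empty")
  expect_length(out, 0L)
})

test_that("mzML round-trip matches the MGF rendering of the same spectra", {
  sp <- make_spectra(2)
  fmz <- tempfile(fileext = ".mzML")
  fmgf <- tempfile(fileext = ".mgf")
  writeMzml(sp, fmz)
  writeMgf(sp, fmgf)
  a <- readMzml(fmz)
  b <- readMgf(fmgf)
  expect_length(a, 2L)
  for (i in 1:2) {
    ## MGF text is written at 6 (m/z) / 4 (intensity) decimals
    expect_equal(peakTable(a[[i]]), peakTable(b[[i]]), tolerance = 1e-6)
    expect_equal(precursorMz(a[[i]]), precursorMz(b[[i]]),
                 tolerance = 1e-9)
    expect_equal(precursorCharge(a[[i]]), precursorCharge(b[[i]]))
    expect_equal(activationType(a[[i]]), activationType(b[[i]]))
    expect_equal(retentionTime(a[[i]]), retentionTime(b[[i]]),
                 tolerance = 1e-6)
    expect_equal(msLevel(a[[i]]), 2L)
  }
})

test_that("mzML reader extracts activation CV terms per scan", {
  sp <- make_spectra(3)
  sp[[1]]@activation <- "CID"
  sp[[2]]@activation <- "ETD"
  sp[[3]]@activation <- "EThcD"
  fmz <- tempfile(fileext = ".mzML")
  writeMzml(sp, fmz)
  back <- readMzml(fmz)
  expect_equal(vapply(back, activationType, ""), c("CID", "ETD", "EThcD"))
})

test_that("MS1-only mzML gives an empty MS2 list with a warning", {
  ms1 <- list(msSpectrum(c(400.1, 500.2), c(10, 20), scanId = "scan=1",
                         msLevel = 1L, rtime = 5))
  fmz <- tempfile(fileext = ".mzML")
  writeMzml(ms1, fmz)
  expect_warning(out <- readMzml(fmz, msLevel = 2L), "no MS2")
  expect_length(out, 0L)
  all <- readMzml(fmz, msLevel = 1L)
  expect_equal(msLevel(all[[1]]), 1L)
  expect_true(is.na(precursorMz(all[[1]])))
})

test_that("corrupted mzML fails with a parse error", {
  tf <- tempfile(fileext = ".mzML")
  writeLines("<mzML><run><spectrumList>", tf)
  expect_error(readMzml(tf))
})

test_that("annotated TSV output is deterministic and complete", {
  pf <- peptidoform("ACDLK", data.frame(position = 2, name = "palmitoyl"))
  sim <- simulateSpectrum(pf, "HCD", 2, seed = 7)
  ann <- annotateSpectrum(sim$spectrum, pf)
  t1 <- tempfile(); t2 <- tempfile()
  writeAnnotatedTsv(list(ann), t1)
  writeAnnotatedTsv(list(ann), t2)
  expect_identical(readLines(t1), readLines(t2))
  tab <- read.delim(t1)
  expect_equal(nrow(tab), nrow(peakMatches(ann)))
  ## header-only file for an empty match set
  empty <- annotateSpectrum(msSpectrum(5000, 1, scanId = "s",
                                       precursorMz = mzFromMass(peptideMass(pf), 2),
                                       precursorCharge = 2L,
                                       activation = "HCD"), pf)
  writeAnnotatedTsv(list(empty), t1)
  expect_length(readLines(t1), 1L)
  expect_error(writeAnnotatedTsv(list(), t1), "no annotation")
})
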