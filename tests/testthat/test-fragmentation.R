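hAtom <- 1.00782503207

test_that("default rules encode the activation-specific loss channels", {
  hcd <- activationRules("HCD")
  expect_setequal(hcd$backboneSeries, c("b", "y"))
  acyl <- hcd$channels[hcd$channels$lability == "thioester_acyl" &
                         hcd$channels$kind == "intact", ]
  expect_setequal(acyl$series, c("b", "y", "p"))
  cid <- activationRules("CID")
  cidAcyl <- cid$channels[cid$channels$lability == "thioester_acyl" &
                            cid$channels$kind == "intact", ]
  expect_setequal(cidAcyl$series, c("y", "p"))   # no b* under CID
  etd <- activationRules("ETD")
  expect_setequal(etd$backboneSeries, c("c", "zdot"))
  expect_true(any(etd$channels$kind == "sidechain_S"))
  expect_false(etd$diagnosticIons)               # d* absent in ETD
  expect_error(activationRules("UVPD"))
})

test_that("unmodified peptides yield no loss ions", {
  pf <- peptidoform("ALDEFK")
  fr <- generateFragments(pf, activationRules("CID"), precursorCharge = 2)
  expect_true(all(fr$nloss[fr$series != "d"] == 0L))
  expect_false("d" %in% fr$series)
  prec <- precursorIons(pf, 2, activationRules("HCD"))
  expect_true(all(prec$nloss == 0L))             # p and p±H2O only
  expect_setequal(unique(prec$water), c(-1L, 0L, 1L))
})

test_that("b/y and c/zdot complementarity holds over random peptidoforms", {
  set.seed(21)
  for (i in 1:50) {
    pf <- random_lipid_peptidoform(sample(7:14, 1), sample(0:2, 1),
                                   c("palmitoyl", "farnesyl"))
    M <- peptideMass(pf)
    n <- nchar(peptideSequence(pf))
    hcd <- generateFragments(pf, activationRules("HCD"),
                             maxFragmentCharge = 1)
    etd <- generateFragments(pf, activationRules("ETD"),
                             maxFragmentCharge = 1)
    b <- hcd[hcd$series == "b" & hcd$nloss == 0, ]
    y <- hcd[hcd$series == "y" & hcd$nloss == 0, ]
    cc <- etd[etd$series == "c" & etd$nloss == 0, ]
    z <- etd[etd$series == "zdot" & etd$nloss == 0, ]
    for (idx in seq_len(n - 1)) {
      expect_lt(abs(b$mz[b$index == idx] + y$mz[y$index == n - idx] -
                      2 * proton - M), 1e-6)
      expect_lt(abs(cc$mz[cc$index == idx] + z$mz[z$index == n - idx] -
                      2 * proton - (M + hAtom)), 1e-6)
      ## series offsets at matching index
      expect_equal(cc$mz[cc$index == idx] - b$mz[b$index == idx],
                   17.026549, tolerance = 1e-6 / 17)
      expect_equal(y$mz[y$index == idx] - z$mz[z$index == idx],
                   16.018724, tolerance = 1e-6 / 16)
    }
  }
})

test_that("every loss ion differs from its parent by lossMass/charge", {
  set.seed(22)
  for (i in 1:20) {
    pf <- random_lipid_peptidoform(10, 2, c("palmitoyl", "stearoyl",
                                            "geranylgeranyl"))
    for (act in c("HCD", "CID", "ETD")) {
      fr <- generateFragments(pf, activationRules(act),
                              precursorCharge = 2)
      losses <- fr[fr$nloss > 0 & fr$series != "d", ]
      for (r in seq_len(nrow(losses))) {
        parent <- fr[fr$series == losses$series[r] &
                       fr$index == losses$index[r] &
                       fr$charge == losses$charge[r] &
                       fr$nloss == 0 & fr$water == 0, ]
        expect_equal(nrow(parent), 1L)
        lm <- sum(vapply(strsplit(losses$loss[r], "+", fixed = TRUE)[[1]],
                         formulaMass, 0))
        expect_lt(abs(parent$mz - losses$mz[r] - lm / losses$charge[r]),
                  1e-9)
      }
    }
  }
})

test_that("loss variants exist only for spans containing the labile site", {
  pf <- peptidoform("AAACAAAK", data.frame(position = 4, name = "palmitoyl"))
  fr <- generateFragments(pf, activationRules("HCD"),
                          maxFragmentCharge = 1)
  n <- 8
  bLoss <- fr[fr$series == "b" & fr$nloss > 0, ]
  expect_true(all(bLoss$index >= 4))      # b1..b3 exclude Cys4
  yLoss <- fr[fr$series == "y" & fr$nloss > 0, ]
  expect_true(all(yLoss$index >= n - 4 + 1))  # y1..y4 exclude Cys4
  bPlain <- fr[fr$series == "b" & fr$nloss == 0, ]
  expect_setequal(bPlain$index, 1:7)
})

test_that("asterisk count in labels equals the number of losses", {
  pf <- peptidoform("ACACAK", data.frame(position = c(2, 4),
                                         name = "palmitoyl"))
  fr <- generateFragments(pf, activationRules("HCD"), precursorCharge = 2)
  stars <- nchar(gsub("[^*]", "", fr$label))
  expect_equal(stars, fr$nloss)
  ## double loss from a di-acylated span
  expect_true(any(fr$nloss == 2 & fr$series == "p"))
})

test_that("diagnostic and prenyl precursor ions match reference masses", {
  pf <- peptidoform("ACDLK", data.frame(position = 2, name = "palmitoyl"))
  prec <- precursorIons(pf, 3, activationRules("HCD"))
  d <- prec[prec$series == "d", ]
  expect_equal(d$mz, 239.2369, tolerance = 5e-4 / 239)
  gg <- peptidoform("ACDLK", data.frame(position = 2,
                                        name = "geranylgeranyl"))
  pg <- precursorIons(gg, 2, activationRules("HCD"))
  expect_true(any(pg$loss == "C20H32"))
  expect_true(any(pg$loss == "C10H16"))   # partial moiety loss
  lossesMass <- vapply(pg$loss[pg$loss != ""], formulaMass, 0)
  expect_true(any(abs(lossesMass - 272.2504) < 5e-5))
  expect_true(any(abs(lossesMass - 136.1252) < 5e-5))
  far <- peptidoform("ACDLK", data.frame(position = 2, name = "farnesyl"))
  pfar <- precursorIons(far, 2, activationRules("HCD"))
  expect_true(any(pfar$loss == "C15H24"))
  expect_false(any(pfar$loss == "C10H16"))  # partial loss is GG-specific
})

test_that("ETD sheds acyl+S side-chain radicals from the precursor", {
  pf <- peptidoform("ACDLK", data.frame(position = 2, name = "palmitoyl"))
  prec <- precursorIons(pf, 2, activationRules("ETD"))
  lm <- vapply(prec$loss[prec$nloss == 1], formulaMass, 0)
  expect_true(any(abs(lm - 270.2017) < 5e-4))
  expect_true(any(abs(lm - 271.2096) < 5e-4))
  expect_false(any(prec$series == "d"))
  ## non-palmitoyl chains are flagged extrapolated
  st <- peptidoform("ACDLK", data.frame(position = 2, name = "stearoyl"))
  ps <- precursorIons(st, 2, activationRules("ETD"))
  expect_true(any(ps$extrapolated))
})

test_that("activation rules round-trip through the config file", {
  tf <- tempfile(fileext = ".yml")
  rules <- activationRules("CID")
  writeActivationRules(rules, tf)
  back <- readActivationRules(tf)
  expect_equal(back$activation, "CID")
  expect_equal(back$backboneSeries, rules$backboneSeries)
  expect_equal(back$channels$kind, rules$channels$kind)
  ## a user-extended rule table drives fragment generation
  back$channels <- rbind(back$channels,
                         data.frame(lability = "thioester_acyl",
                                    kind = "intact", series = "b"))
  pf <- peptidoform("ACDLK", data.frame(position = 2, name = "palmitoyl"))
  fr <- generateFragments(pf, back, maxFragmentCharge = 1)
  expect_true(any(fr$series == "b" & fr$nloss > 0))  # b* now emitted
  expect_error(readActivationRules(tempfile()), "not found")
})

test_that("fragment TSV export is written with stable columns", {
  pf <- peptidoform("ACDLK", data.frame(position = 2, name = "palmitoyl"))
  fr <- generateFragments(pf, activationRules("HCD"), precursorCharge = 2)
  tf <- tempfile(fileext = ".tsv")
  writeFragmentTsv(fr, pf, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(fr))
  expect_true(all(c("peptidoform", "series", "index", "charge", "loss",
                    "mz", "label") %in% names(back)))
})
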