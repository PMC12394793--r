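ms1_scan <- function(rt, mz, int)
  msSpectrum(mz, int, scanId = sprintf("scan=%d", round(rt)),
             msLevel = 1L, rtime = rt)

test_that("XIC extraction sums matching peaks per scan", {
  scans <- lapply(1:5, function(i) ms1_scan(i, c(400, 700.0), c(5, 10)))
  tr <- extractXic(scans, 700.0, tolPpm = 10)
  expect_s3_class(tr, "XicTrace")
  expect_equal(tr$intensity, rep(10, 5))
  ## two near-isobaric peaks inside the window add up
  scans2 <- list(ms1_scan(1, c(700.000, 700.002), c(10, 4)),
                 ms1_scan(2, 700.000, 10))
  tr2 <- extractXic(scans2, 700.0, tolPpm = 10)
  expect_equal(tr2$intensity, c(14, 10))
  ## nothing in tolerance anywhere -> all-zero trace with a warning
  expect_warning(tr3 <- extractXic(scans, 900.0, tolPpm = 5),
                 "no signal")
  expect_true(all(tr3$intensity == 0))
  expect_error(extractXic(scans, 700, rtWindow = c(100, 200)),
               "retention-time window")
})

test_that("peak integration follows the apex-region trapezoid rule", {
  expect_equal(integratePeak(data.frame(rt = 0:2,
                                        intensity = c(0, 10, 0))), 10)
  expect_equal(integratePeak(data.frame(rt = 0:2,
                                        intensity = c(10, 10, 10))), 20)
  ## two baseline-separated peaks: only the apex peak is integrated
  two <- data.frame(rt = 0:8,
                    intensity = c(0, 10, 20, 10, 0, 0, 4, 8, 0))
  expect_equal(integratePeak(two), 0.5 * 10 + 15 + 15 + 0.5 * 10)
  z <- integratePeak(data.frame(rt = 0:3, intensity = rep(0, 4)))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "empty"))
})

test_that("integrated area is shift-invariant and scales linearly", {
  set.seed(14)
  base <- data.frame(rt = 0:40,
                     intensity = 1000 * dnorm(0:40, 20, 4))
  a0 <- integratePeak(base)
  shifted <- base; shifted$rt <- shifted$rt + 123.4
  expect_equal(integratePeak(shifted), a0, tolerance = 1e-12)
  scaled <- base; scaled$intensity <- scaled$intensity * 7.5
  expect_equal(integratePeak(scaled), a0 * 7.5, tolerance = 1e-12)
})

test_that("normalization divides by the control mean (control mean = 1)", {
  r <- normalizeAndTest(list(control = c(2, 2, 2), treated = c(1, 1, 1)),
                        "control")
  expect_equal(mean(r$normalized$control), 1)
  expect_equal(mean(r$normalized$treated), 0.5)
  ## identical groups: t = 0, p = 1, ns
  r2 <- normalizeAndTest(list(control = c(1, 2, 3), treated = c(1, 2, 3)),
                         "control")
  expect_equal(r2$comparisons$adjustedP, 1)
  expect_equal(r2$comparisons$label, "ns")
  expect_error(normalizeAndTest(list(control = 1, treated = c(1, 2)),
                                "control"), ">= 2 replicates")
  expect_error(normalizeAndTest(list(a = c(1, 2), b = c(1, 2)), "ctrl"),
               "not present")
})

test_that("one-way ANOVA F matches the hand-computed value", {
  ## groups (1,2,3), (2,3,4), (3,4,5): SSB = 6 (df 2), SSW = 6 (df 6)
  r <- normalizeAndTest(list(control = c(1, 2, 3), t1 = c(2, 3, 4),
                             t2 = c(3, 4, 5)), "control")
  expect_equal(r$test, "anova_tukey")
  expect_equal(r$anovaF, 3, tolerance = 1e-12)
  expect_equal(r$anovaDf[1:2], c(2, 6))
  expect_equal(nrow(r$comparisons), 3L)   # all pairs, Tukey-adjusted
  expect_true(all(r$comparisons$adjustedP >= 0 &
                    r$comparisons$adjustedP <= 1))
})

test_that("Tukey adjustment matches TukeyHSD on the same normalized data", {
  set.seed(88)
  areas <- list(control = rlnorm(3, 13, 0.1), ha = rlnorm(3, 12, 0.1),
                dtt = rlnorm(3, 13, 0.1))
  r <- normalizeAndTest(areas, "control")
  values <- unlist(lapply(areas, function(a) a / mean(areas$control)))
  cond <- factor(rep(names(areas), lengths(areas)),
                 levels = names(areas))
  tk <- TukeyHSD(aov(values ~ cond))$cond
  expect_equal(sort(r$comparisons$adjustedP),
               sort(unname(tk[, "p adj"])), tolerance = 1e-12)
})

test_that("quantifyStability runs the full trace-to-test pipeline", {
  q <- simulateQuantDataset(trueLossFraction = 0.5, nReplicates = 3,
                            cv = 0, seed = 2)
  res <- quantifyStability(q$traces, q$runList, "control")
  expect_equal(mean(res$normalized$control), 1, tolerance = 1e-9)
  expect_equal(mean(res$normalized$treated), 0.5, tolerance = 1e-3)
  expect_equal(res$comparisons$label, "***")
})
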