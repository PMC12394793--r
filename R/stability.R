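#' Extract an ion chromatogram from MS1 scans
#'
#' Per MS1 scan inside the retention-time window, the intensities of all
#' peaks within ±tolPpm of the target m/z are summed (isotopolog peaks
#' inside the window add up); scans with no matching peak contribute zero.
#'
#' @param ms1Spectra List of [MsSpectrum-class] MS1 scans.
#' @param targetMz Target m/z.
#' @param tolPpm Extraction tolerance in ppm.
#' @param rtWindow Numeric length-2 retention-time window in seconds, or
#'   NULL for all scans.
#' @return data.frame of class \code{"XicTrace"} with columns \code{rt}
#'   and \code{intensity}, ordered by \code{rt}; attributes
#'   \code{targetMz}, \code{tolPpm}.
#' @export
extractXic <- function(ms1Spectra, targetMz, tolPpm = 10, rtWindow = NULL) {
  stopifnot(targetMz > 0, tolPpm > 0)
  ms1 <- Filter(function(s) s@msLevel == 1L, ms1Spectra)
  if (!is.null(rtWindow))
    ms1 <- Filter(function(s) !is.na(s@rtime) &&
                    s@rtime >= rtWindow[1] && s@rtime <= rtWindow[2], ms1)
  if (!length(ms1))
    stop(sprintf("no MS1 scans in retention-time window [%s]",
                 if (is.null(rtWindow)) "all"
                 else paste(rtWindow, collapse = ", ")))
  tol <- targetMz * tolPpm * 1e-6
  rt <- vapply(ms1, function(s) s@rtime, 0)
  ord <- order(rt)
  intensity <- vapply(ms1[ord], function(s)
    sum(s@intensity[abs(s@mz - targetMz) <= tol]), 0)
  if (all(intensity == 0))
    warning(sprintf("no signal within %.1f ppm of m/z %.4f", tolPpm,
                    targetMz))
  structure(data.frame(rt = rt[ord], intensity = intensity),
            targetMz = targetMz, tolPpm = tolPpm,
            class = c("XicTrace", "data.frame"))
}

#' Integrate the apex peak of an XIC trace
#'
#' Peak boundaries are the widest contiguous region around the apex with
#' intensity above \code{boundaryFraction} of the apex (default 5%); the
#' area is the trapezoidal integral over that region, in
#' intensity-seconds. Baseline-separated secondary peaks are excluded.
#'
#' @param trace An [extractXic()] trace (or any data.frame with \code{rt},
#'   \code{intensity}).
#' @param boundaryFraction Boundary threshold as a fraction of the apex
#'   intensity.
#' @return Numeric area; attribute \code{empty = TRUE} when the trace is
#'   all zero.
#' @examples
#' integratePeak(data.frame(rt = 0:2, intensity = c(0, 10, 0)))  # 10
#' @export
integratePeak <- function(trace, boundaryFraction = 0.05) {
  stopifnot(nrow(trace) >= 3L)
  y <- trace$intensity; x <- trace$rt
  if (is.unsorted(x, strictly = TRUE))
    stop("retention times must be strictly increasing")
  apex <- which.max(y)
  if (y[apex] <= 0) return(structure(0, empty = TRUE))
  thr <- boundaryFraction * y[apex]
  lo <- apex
  while (lo > 1L && y[lo - 1L] > thr) lo <- lo - 1L
  hi <- apex
  while (hi < length(y) && y[hi + 1L] > thr) hi <- hi + 1L
  ## include the boundary-crossing points so the peak flanks are integrated
  lo <- max(1L, lo - 1L)
  hi <- min(length(y), hi + 1L)
  idx <- lo:hi
  if (length(idx) < 2L) return(0)
  sum(diff(x[idx]) * (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
}

#' Normalize replicate peak areas to control and test for differences
#'
#' Each replicate area is divided by the mean of the control condition, so
#' the control normalizes to mean 1 by construction. Two groups are
#' compared with a Student's unpaired two-sided t-test (equal-variance;
#' Welch via \code{varEqual = FALSE}); three or more with a one-way ANOVA
#' followed by Tukey's HSD adjusted pairwise p-values. Significance labels:
#' ns, * (p <= 0.05), ** (p <= 0.01), *** (p <= 0.001).
#'
#' @param areas Named list: condition label -> numeric vector of replicate
#'   areas. Must include \code{control}.
#' @param control Control condition label.
#' @param design "auto" picks t-test for 2 groups, ANOVA+Tukey otherwise.
#' @param varEqual Equal-variance t-test (default TRUE).
#' @return List of class \code{"StabilityResult"}: \code{normalized}
#'   (named list), \code{test}, \code{comparisons} (data.frame:
#'   comparison, estimate, adjustedP, label), \code{anovaF},
#'   \code{anovaDf}, \code{anovaP}.
#' @examples
#' normalizeAndTest(list(control = c(2, 2.1, 1.9), HA = c(1, 1.1, 0.9)),
#'                  "control")
#' @export
normalizeAndTest <- function(areas, control,
                             design = c("auto", "two_group", "multi_group"),
                             varEqual = TRUE) {
  design <- match.arg(design)
  if (!control %in% names(areas))
    stop(sprintf("control condition '%s' not present", control))
  if (any(vapply(areas, length, 0L) < 2L))
    stop("every condition needs >= 2 replicates")
  ctrlMean <- mean(areas[[control]])
  if (ctrlMean <= 0) stop("control mean area must be positive")
  normalized <- lapply(areas, function(a) a / ctrlMean)
  grp <- setdiff(names(areas), control)
  if (design == "auto")
    design <- if (length(areas) == 2L) "two_group" else "multi_group"
  lab <- function(p) ifelse(p <= 0.001, "***",
                     ifelse(p <= 0.01, "**",
                     ifelse(p <= 0.05, "*", "ns")))
  if (design == "two_group") {
    if (length(grp) != 1L)
      stop("two_group design requires exactly one non-control condition")
    est <- mean(normalized[[grp]]) - mean(normalized[[control]])
    p <- tryCatch(
      stats::t.test(normalized[[grp]], normalized[[control]],
                    var.equal = varEqual)$p.value,
      error = function(e) if (abs(est) < .Machine$double.eps^0.5) 1 else 0)
    comp <- data.frame(
      comparison = sprintf("%s-%s", grp, control),
      estimate = est, adjustedP = p, stringsAsFactors = FALSE)
    comp$label <- lab(comp$adjustedP)
    res <- list(normalized = normalized, test = "t_test",
                comparisons = comp, anovaF = NA_real_, anovaDf = NULL,
                anovaP = NA_real_)
  } else {
    values <- unlist(normalized, use.names = FALSE)
    cond <- factor(rep(names(normalized), lengths(normalized)),
                   levels = names(normalized))
    fit <- stats::aov(values ~ cond)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$cond
    comp <- data.frame(comparison = rownames(tk),
                       estimate = tk[, "diff"],
                       adjustedP = tk[, "p adj"], stringsAsFactors = FALSE)
    comp$label <- lab(comp$adjustedP)
    rownames(comp) <- NULL
    res <- list(normalized = normalized, test = "anova_tukey",
                comparisons = comp, anovaF = an$`F value`[1],
                anovaDf = an$Df, anovaP = an$`Pr(>F)`[1])
  }
  structure(c(res, list(control = control)), class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  cat(sprintf("StabilityResult (%s; control = %s)\n", x$test, x$control))
  means <- vapply(x$normalized, mean, 0)
  cat("normalized means:",
      paste(sprintf("%s %.3f", names(means), means), collapse = ", "), "\n")
  print(x$comparisons)
  invisible(x)
}

#' End-to-end stability quantification from XIC traces
#'
#' Integrates one trace per run, groups areas by condition, and runs
#' [normalizeAndTest()].
#'
#' @param traces Named list of XIC traces (one per run).
#' @param runList data.frame with columns \code{run} (names into
#'   \code{traces}) and \code{condition}.
#' @param control Control condition label.
#' @param ... Passed to [normalizeAndTest()].
#' @return A \code{"StabilityResult"}.
#' @export
quantifyStability <- function(traces, runList, control, ...) {
  stopifnot(all(c("run", "condition") %in% names(runList)))
  missing <- setdiff(runList$run, names(traces))
  if (length(missing))
    stop(sprintf("no trace for run(s): %s", paste(missing, collapse = ", ")))
  areas <- split(
    vapply(runList$run, function(r) integratePeak(traces[[r]]), 0),
    runList$condition)
  normalizeAndTest(areas, control, ...)
}
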