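## Synthetic fixtures with known ground truth.
##
## The spectrum simulator emulates the qualitative fragmentation patterns
## of lipidated peptides: HCD spectra dominated by y-ions with
## neutral-loss y* companions rivalling them at higher charge; CID at 3+
## dominated by the p* precursor-loss ion; ETD producing c/z-dot ladders
## with precursor side-chain losses. It does not model isotope envelopes,
## chromatographic peak shape in MS2, or collision-energy dependence.
##
## RNG contract: each simulator consumes a single RNG stream seeded once
## at entry (seed recorded in the fixture manifest), so any subsample can
## be recomputed independently by replaying the same draws.

.seriesWeight <- function(theo, activation, precursorCharge,
                          lossIntensityFactor) {
  w <- numeric(nrow(theo))
  base <- c(b = 0.45, y = 1.0, c = 1.0, zdot = 0.9, p = 0.25, d = 0.5)
  w <- base[theo$series]
  loss <- theo$nloss > 0L & theo$series != "d"
  w[loss] <- w[loss] * lossIntensityFactor
  if (activation == "CID" && precursorCharge >= 3L) {
    pstar <- theo$series == "p" & theo$nloss > 0L
    w[pstar] <- 3.0                       # p* dominates CID at 3+
  }
  if (activation == "HCD" && precursorCharge >= 3L) {
    ystar <- theo$series == "y" & theo$nloss > 0L
    w[ystar] <- base[["y"]]               # y* rivals y at 3+
  }
  if (activation %in% c("ETD", "EThcD")) {
    pstar <- theo$series == "p" & theo$nloss > 0L
    w[pstar] <- 2.0
  }
  unname(w)
}

#' Simulate an MS2 spectrum with ground truth
#'
#' Generates the theoretical ions of a peptidoform, subsamples them,
#' draws intensities from a seeded log-normal with activation-specific
#' series weighting, jitters m/z values, adds noise peaks and returns the
#' spectrum together with the retained ground-truth ion table.
#'
#' @param pf A [Peptidoform-class].
#' @param activation Activation type.
#' @param precursorCharge Precursor charge.
#' @param ionSamplingFraction Fraction of theoretical ions retained
#'   (first RNG draws: one uniform per theoretical ion, kept when
#'   < fraction).
#' @param lossIntensityFactor Relative intensity of neutral-loss ions.
#' @param noisePeaks Number of uniform random noise peaks.
#' @param noiseIntensityRange Noise intensity range (absolute units; the
#'   signal log-normal has median 100).
#' @param jitterPpm Gaussian m/z jitter sigma in ppm (<= 10 recommended).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param scanId,rtime Metadata for the simulated scan.
#' @return List: \code{spectrum} ([MsSpectrum-class]) and \code{truth}
#'   (the retained theoretical-ion data.frame with an
#'   \code{intensity} column).
#' @export
simulateSpectrum <- function(pf, activation = "HCD", precursorCharge = 2L,
                             ionSamplingFraction = 1.0,
                             lossIntensityFactor = 0.6,
                             noisePeaks = 0L,
                             noiseIntensityRange = c(1, 20),
                             jitterPpm = 0, seed = NULL,
                             scanId = "sim=1", rtime = 0) {
  stopifnot(ionSamplingFraction > 0, ionSamplingFraction <= 1)
  rules <- activationRules(activation)
  theo <- generateFragments(pf, rules,
                            maxFragmentCharge = min(2L, precursorCharge),
                            precursorCharge = precursorCharge)
  if (!is.null(seed)) set.seed(as.integer(seed))
  keep <- stats::runif(nrow(theo)) < ionSamplingFraction
  if (!any(keep)) keep[1] <- TRUE
  truth <- theo[keep, , drop = FALSE]
  w <- .seriesWeight(truth, activation, precursorCharge,
                     lossIntensityFactor)
  intensity <- w * stats::rlnorm(nrow(truth), meanlog = log(100),
                                 sdlog = 0.3)
  mz <- truth$mz
  if (jitterPpm > 0)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, jitterPpm * 1e-6))
  if (noisePeaks > 0L) {
    nmz <- stats::runif(noisePeaks, min = 100,
                        max = max(mz) * 1.1)
    nint <- stats::runif(noisePeaks, noiseIntensityRange[1],
                         noiseIntensityRange[2])
    mz <- c(mz, nmz); intensity <- c(intensity, nint)
  }
  truth$intensity <- intensity[seq_len(nrow(truth))]
  spec <- msSpectrum(mz, intensity, scanId = scanId, msLevel = 2L,
                     precursorMz = mzFromMass(peptideMass(pf),
                                              precursorCharge),
                     precursorCharge = precursorCharge,
                     activation = activation, rtime = rtime)
  list(spectrum = spec, truth = truth)
}

#' Simulate a spike-in stability-quantification dataset
#'
#' Emulates the spike-before vs spike-after design: control and treated
#' extracted-ion chromatograms as Gaussian elution peaks whose areas are
#' \code{controlMean} and \code{controlMean * (1 - trueLossFraction)},
#' with replicate areas perturbed by a log-normal of the given CV (the
#' log-normal is mean-corrected, so the expected area is exact).
#'
#' @param trueLossFraction Fraction of signal lost in the treated
#'   condition (0-1).
#' @param nReplicates Replicates per condition.
#' @param cv Coefficient of variation of replicate areas.
#' @param seed Integer seed.
#' @param controlMean Mean control area (intensity-seconds).
#' @param targetMz m/z at which the MS1 traces are placed.
#' @param rtCenter,peakSigma,rtStep,rtSpan Elution-peak shape/grid (s).
#' @param nControlReplicates Control replicate count (defaults to
#'   \code{nReplicates}; the pooled-control designs use more).
#' @return List: \code{runList} (data.frame run/condition), \code{traces}
#'   (named list of XIC-style data.frames), \code{ms1} (named list of MS1
#'   [MsSpectrum-class] lists, one per run), \code{trueAreas}.
#' @export
simulateQuantDataset <- function(trueLossFraction = 0.5, nReplicates = 3L,
                                 cv = 0.1, seed = NULL,
                                 controlMean = 1e6, targetMz = 700.0,
                                 rtCenter = 30, peakSigma = 3,
                                 rtStep = 1, rtSpan = 60,
                                 nControlReplicates = nReplicates) {
  stopifnot(trueLossFraction >= 0, trueLossFraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  drawAreas <- function(mu, n) {
    if (mu <= 0) return(rep(0, n))
    if (cv <= 0) return(rep(mu, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  areas <- list(
    control = drawAreas(controlMean, nControlReplicates),
    treated = drawAreas(controlMean * (1 - trueLossFraction), nReplicates))
  rt <- seq(0, rtSpan, by = rtStep)
  mkTrace <- function(A) {
    intensity <- A * stats::dnorm(rt, rtCenter, peakSigma)
    structure(data.frame(rt = rt, intensity = intensity),
              targetMz = targetMz, tolPpm = 10,
              class = c("XicTrace", "data.frame"))
  }
  runs <- c(paste0("control_", seq_len(nControlReplicates)),
            paste0("treated_", seq_len(nReplicates)))
  cond <- c(rep("control", nControlReplicates),
            rep("treated", nReplicates))
  traces <- stats::setNames(lapply(unlist(areas), mkTrace), runs)
  ms1 <- lapply(traces, function(tr)
    lapply(seq_len(nrow(tr)), function(i)
      msSpectrum(mz = targetMz,
                 intensity = tr$intensity[i],
                 scanId = sprintf("scan=%d", i), msLevel = 1L,
                 rtime = tr$rt[i])))
  list(runList = data.frame(run = runs, condition = cond,
                            stringsAsFactors = FALSE),
       traces = traces, ms1 = ms1, trueAreas = areas)
}

.randomTrypticPeptide <- function(len, withCys = TRUE) {
  pool <- c("A", "G", "L", "V", "F", "D", "E", "N", "Q", "H", "W", "M",
            "S", "T", "Y", "I")
  body <- sample(pool, len - 1L, replace = TRUE)
  if (withCys) {
    nc <- sample(1:2, 1)
    body[sample(seq_len(len - 1L), min(nc, len - 1L))] <- "C"
  }
  paste(c(body, sample(c("K", "R"), 1)), collapse = "")
}

#' Generate a toy Cys-rich protein set
#'
#' Proteins are concatenations of tryptic peptides (each ending K/R, no
#' proline after the cleavage site), about half of them carrying one or
#' two cysteines, mimicking the sequence context of S-acylation
#' substrates. Entirely synthetic; no real protein sequences are used.
#'
#' @param nProteins Number of proteins.
#' @param seed Integer seed.
#' @return Named character vector of protein sequences.
#' @export
simulateProteinSet <- function(nProteins = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  seqs <- vapply(seq_len(nProteins), function(i) {
    npep <- sample(8:12, 1)
    peps <- vapply(seq_len(npep), function(j)
      .randomTrypticPeptide(sample(7:14, 1),
                            withCys = stats::runif(1) < 0.6), "")
    paste0("M", paste(peps, collapse = ""))
  }, "")
  names(seqs) <- sprintf("SYNPROT%02d", seq_len(nProteins))
  seqs
}

#' Write a complete synthetic fixture bundle
#'
#' Writes a versioned, fully synthetic benchmark: a toy Cys-rich protein
#' FASTA, planted MS2 spectra of known lipidated peptidoforms plus pure
#' noise spectra (MGF), a spike-in quantification dataset (MS1 mzML per
#' run + run list TSV), and a plain-text manifest recording the seed and
#' the ground truth for every scan. Bit-reproducible for a fixed seed.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param nProteins,nPlanted,nNoise Bundle sizes.
#' @param modNames Variable modifications planted on Cys peptides.
#' @return Invisibly, a list with the manifest data.frame and file paths.
#' @export
writeFixtureFiles <- function(outDir, seed = 1L, nProteins = 20L,
                              nPlanted = 100L, nNoise = 100L,
                              modNames = c("palmitoyl", "NEM")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  proteins <- simulateProteinSet(nProteins, seed = seed)
  fastaPath <- file.path(outDir, "proteins.fasta")
  writeFasta(proteins, fastaPath)
  ## candidate planted peptidoforms: Cys tryptic peptides with >= 1 lipid
  dig <- digestParams(missedCleavages = 1L, minLength = 7L,
                      maxLength = 30L)
  cands <- list()
  for (acc in names(proteins)) {
    peps <- digestProtein(proteins[[acc]], dig)
    peps <- peps[grepl("C", peps$peptide) & peps$missed == 0L, ,
                 drop = FALSE]
    for (j in seq_len(nrow(peps)))
      cands[[length(cands) + 1L]] <- list(acc = acc,
                                          peptide = peps$peptide[j],
                                          start = peps$start[j])
  }
  set.seed(seed + 1L)
  pick <- sample(length(cands), nPlanted, replace = length(cands) < nPlanted)
  spectra <- vector("list", nPlanted + nNoise)
  manifest <- vector("list", nPlanted + nNoise)
  for (i in seq_len(nPlanted)) {
    cand <- cands[[pick[i]]]
    cysPos <- which(strsplit(cand$peptide, "")[[1]] == "C")
    mods <- data.frame(position = cysPos,
                       name = sample(modNames, length(cysPos),
                                     replace = TRUE))
    ## at least one lipid on the peptide
    if (!any(mods$name == "palmitoyl")) mods$name[1] <- "palmitoyl"
    pf <- peptidoform(cand$peptide, mods, proteinAccession = cand$acc,
                      proteinStart = cand$start)
    z <- sample(2:3, 1)
    sim <- simulateSpectrum(pf, "HCD", z, ionSamplingFraction = 0.95,
                            noisePeaks = 15L, jitterPpm = 2,
                            seed = seed + 100L + i,
                            scanId = sprintf("planted_%03d", i),
                            rtime = 10 * i)
    spectra[[i]] <- sim$spectrum
    manifest[[i]] <- data.frame(
      scan = sprintf("planted_%03d", i), planted = TRUE,
      peptidoform = formatPeptidoform(pf), charge = z,
      protein = cand$acc, seed = seed + 100L + i,
      stringsAsFactors = FALSE)
  }
  set.seed(seed + 2L)
  for (i in seq_len(nNoise)) {
    nPk <- sample(40:80, 1)
    mz <- sort(stats::runif(nPk, 150, 1500))
    spectra[[nPlanted + i]] <- msSpectrum(
      mz, stats::runif(nPk, 1, 50),
      scanId = sprintf("noise_%03d", i), msLevel = 2L,
      precursorMz = stats::runif(1, 400, 1200),
      precursorCharge = sample(2:3, 1), activation = "HCD",
      rtime = 10 * (nPlanted + i))
    manifest[[nPlanted + i]] <- data.frame(
      scan = sprintf("noise_%03d", i), planted = FALSE,
      peptidoform = "", charge = NA_integer_, protein = "",
      seed = seed + 2L, stringsAsFactors = FALSE)
  }
  mgfPath <- file.path(outDir, "spectra.mgf")
  writeMgf(spectra, mgfPath)
  ## quantification dataset
  quant <- simulateQuantDataset(trueLossFraction = 0.5, nReplicates = 3L,
                                cv = 0.1, seed = seed + 3L)
  quantDir <- file.path(outDir, "quant")
  dir.create(quantDir, showWarnings = FALSE)
  for (r in names(quant$ms1))
    writeMzml(quant$ms1[[r]], file.path(quantDir, paste0(r, ".mzML")))
  utils::write.table(quant$runList, file.path(quantDir, "runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifestDf <- do.call(rbind, manifest)
  manifestPath <- file.path(outDir, "manifest.tsv")
  utils::write.table(manifestDf, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(sprintf("bundle_version\t1"),
               sprintf("master_seed\t%d", seed),
               sprintf("n_proteins\t%d", nProteins),
               sprintf("n_planted\t%d", nPlanted),
               sprintf("n_noise\t%d", nNoise)),
             file.path(outDir, "bundle.info"))
  invisible(list(manifest = manifestDf, fasta = fastaPath, mgf = mgfPath,
                 quantDir = quantDir))
}
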