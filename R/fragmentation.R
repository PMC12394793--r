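## Activation-specific fragmentation rules for lipidated peptides.
##
## The chemistry encoded here: collisional activation (CID/HCD) breaks the
## thioester bond of S-acylated cysteines, shedding the intact acyl chain
## (e.g. C16H30O, 238.23 Da for palmitoyl) from sequence ions and the
## precursor; ETD leaves the thioester intact but cleaves the S-C bond of
## the cysteine side chain, shedding acyl+S radical species (C16H30OS and
## C16H31OS for palmitoyl). Prenyl thioethers shed the intact isoprenoid
## (C15H24 farnesyl / C20H32 geranylgeranyl) under collisional activation,
## geranylgeranyl additionally losing a C10H16 half-moiety from the
## precursor. A low-mass acylium-type diagnostic ion (acyl delta + proton;
## 239.24 for palmitoyl) accompanies collisional spectra of acylated
## peptides.

#' Default activation rules
#'
#' Returns the rule set describing which backbone series, neutral-loss
#' channels and diagnostic ions a given activation type produces.
#'
#' Channel kinds: \code{intact} sheds the whole modification;
#' \code{sidechain_S}/\code{sidechain_SH} shed modification+S
#' (+H) radicals (ETD S-C cleavage); \code{partial_gg} sheds C10H16 from
#' geranylgeranylated precursors.
#'
#' @param activation One of "CID", "HCD", "ETD", "EThcD".
#' @return List of class \code{"ActivationRules"} with elements
#'   \code{activation}, \code{backboneSeries}, \code{channels} (data.frame:
#'   lability, kind, series), \code{diagnosticIons}, \code{precursorWater}.
#' @examples
#' activationRules("HCD")$channels
#' @export
activationRules <- function(activation = c("HCD", "CID", "ETD", "EThcD")) {
  activation <- match.arg(activation)
  ch <- function(lability, kind, series)
    data.frame(lability = lability, kind = kind, series = series,
               stringsAsFactors = FALSE)
  collisional <- function(bLoss) rbind(
    ch("thioester_acyl", "intact",
       c(if (bLoss) "b", "y", "p")),
    ch("thioether_prenyl", "intact", c("b", "y", "p")),
    ch("thioether_prenyl", "partial_gg", "p"))
  etdChannels <- rbind(
    ch("thioester_acyl", "intact", "p"),
    ch("thioester_acyl", "sidechain_S", c("p", "zdot")),
    ch("thioester_acyl", "sidechain_SH", c("p", "zdot")),
    ch("thioether_prenyl", "intact", "p"))
  switch(activation,
    CID = structure(list(activation = "CID",
                         backboneSeries = c("b", "y"),
                         channels = collisional(bLoss = FALSE),
                         diagnosticIons = TRUE, precursorWater = TRUE),
                    class = "ActivationRules"),
    HCD = structure(list(activation = "HCD",
                         backboneSeries = c("b", "y"),
                         channels = collisional(bLoss = TRUE),
                         diagnosticIons = TRUE, precursorWater = TRUE),
                    class = "ActivationRules"),
    ETD = structure(list(activation = "ETD",
                         backboneSeries = c("c", "zdot"),
                         channels = etdChannels,
                         diagnosticIons = FALSE, precursorWater = TRUE),
                    class = "ActivationRules"),
    EThcD = structure(list(activation = "EThcD",
                           backboneSeries = c("b", "y", "c", "zdot"),
                           channels = unique(rbind(collisional(TRUE),
                                                   etdChannels)),
                           diagnosticIons = TRUE, precursorWater = TRUE),
                      class = "ActivationRules"))
}

#' Serialize activation rules to a config file
#'
#' Rule sets round-trip through a small YAML document (keys:
#' \code{activation}, \code{backboneSeries}, \code{channels} with
#' lability/kind/series, \code{diagnosticIons}, \code{precursorWater}),
#' so users can customize channels — e.g. enable b-series losses under
#' CID — without touching code.
#'
#' @param rules An [activationRules()] object.
#' @param path Config file path.
#' @return \code{writeActivationRules}: invisibly, \code{path};
#'   \code{readActivationRules}: the rule set.
#' @export
writeActivationRules <- function(rules, path) {
  stopifnot(inherits(rules, "ActivationRules"))
  yaml::write_yaml(list(
    activation = rules$activation,
    backboneSeries = rules$backboneSeries,
    channels = lapply(seq_len(nrow(rules$channels)), function(i)
      as.list(rules$channels[i, ])),
    diagnosticIons = rules$diagnosticIons,
    precursorWater = rules$precursorWater), path)
  invisible(path)
}

#' @rdname writeActivationRules
#' @export
readActivationRules <- function(path) {
  if (!file.exists(path)) stop(sprintf("rules file not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("activation", "backboneSeries", "channels")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop(sprintf("rules file is missing key(s): %s",
                 paste(miss, collapse = ", ")))
  structure(list(
    activation = y$activation,
    backboneSeries = unlist(y$backboneSeries),
    channels = do.call(rbind, lapply(y$channels, as.data.frame)),
    diagnosticIons = isTRUE(y$diagnosticIons),
    precursorWater = isTRUE(y$precursorWater)),
    class = "ActivationRules")
}

## Loss composition for one channel applied to one modification, or NULL
## when the channel does not apply (e.g. partial_gg to farnesyl).
.channelLoss <- function(kind, mod) {
  if (kind == "intact")
    return(list(formula = mod$formula, mass = mod$delta,
                radical = FALSE, extrapolated = FALSE))
  if (kind == "sidechain_S") {
    f <- .addFormulas(mod$formula, c(S = 1L))
    return(list(formula = f, mass = formulaMass(f), radical = TRUE,
                extrapolated = !identical(mod$name, "palmitoyl")))
  }
  if (kind == "sidechain_SH") {
    f <- .addFormulas(mod$formula, c(S = 1L, H = 1L))
    return(list(formula = f, mass = formulaMass(f), radical = TRUE,
                extrapolated = !identical(mod$name, "palmitoyl")))
  }
  if (kind == "partial_gg") {
    if (!identical(mod$name, "geranylgeranyl")) return(NULL)
    f <- c(C = 10L, H = 16L)
    return(list(formula = f, mass = formulaMass(f), radical = FALSE,
                extrapolated = FALSE))
  }
  stop(sprintf("unknown loss channel kind '%s'", kind))
}

.H2O <- function() formulaMass(c(H = 2L, O = 1L))
.NH3 <- function() formulaMass(c(N = 1L, H = 3L))

.ionLabel <- function(series, index, nloss, charge, water = 0L) {
  base <- switch(series, p = "p", d = "d",
                 paste0(sub("dot", "", series), index))
  wat <- if (water > 0L) "+H2O" else if (water < 0L) "-H2O" else ""
  chg <- if (charge > 1L) sprintf("^%d+", charge) else ""
  paste0(base, strrep("*", nloss), wat, chg)
}

## Enumerate loss-variant rows for one ion. spanMods: data.frame of labile
## mods in the ion's residue span (name, lability). Returns data.frame of
## (nloss, lossMass, lossFormula, extrapolated), one row per distinct loss
## combination, at most lossCap losses.
.lossVariants <- function(spanMods, series, rules, lossCap) {
  if (!nrow(spanMods)) return(NULL)
  chs <- rules$channels[rules$channels$series == series, , drop = FALSE]
  if (!nrow(chs)) return(NULL)
  perMod <- vector("list", nrow(spanMods))
  for (i in seq_len(nrow(spanMods))) {
    mod <- getModification(spanMods$name[i])
    kinds <- chs$kind[chs$lability == mod$lability]
    opts <- list()
    for (k in unique(kinds)) {
      l <- .channelLoss(k, mod)
      if (!is.null(l)) opts[[length(opts) + 1L]] <- l
    }
    perMod[[i]] <- opts
  }
  rows <- list()
  nm <- nrow(spanMods)
  subsets <- function(idx, chosen) {
    if (length(chosen) > 0L && length(chosen) <= lossCap) {
      ## cartesian product of channel options over chosen mods
      grids <- lapply(chosen, function(i) seq_along(perMod[[i]]))
      if (all(lengths(grids) > 0L)) {
        combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
        for (r in seq_len(nrow(combos))) {
          ls <- lapply(seq_along(chosen), function(j)
            perMod[[chosen[j]]][[combos[r, j][[1]]]])
          rows[[length(rows) + 1L]] <<- list(
            nloss = length(ls),
            lossMass = sum(vapply(ls, `[[`, 0, "mass")),
            lossFormula = paste(sort(vapply(ls, function(l)
              formulaString(l$formula), "")), collapse = "+"),
            extrapolated = any(vapply(ls, `[[`, TRUE, "extrapolated")))
        }
      }
    }
    if (idx > nm || length(chosen) >= lossCap) return(invisible())
    for (i in idx:nm) subsets(i + 1L, c(chosen, i))
  }
  subsets(1L, integer(0))
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df[!duplicated(df$lossFormula), , drop = FALSE]
}

#' Generate theoretical fragment ions
#'
#' Produces all backbone ions of the rule set's series at charges
#' 1..\code{maxFragmentCharge}, neutral-loss variants for every ion whose
#' residue span contains a labile modification (multiplicity up to
#' \code{lossCap}), and — when \code{precursorCharge} is given — the
#' precursor ion series (p, p±H2O, p*) and the acyl diagnostic ion d*.
#'
#' Ion mass relations (singly protonated): y = C-terminal residues + H2O +
#' proton; b = N-terminal residues + proton; c = b + NH3; z-dot = y -
#' 16.018724 (radical z+1 species).
#'
#' @param pf A [Peptidoform-class] (length >= 2).
#' @param rules An [activationRules()] object.
#' @param maxFragmentCharge Highest fragment charge generated (default 2).
#' @param precursorCharge Precursor charge; NA skips precursor/diagnostic
#'   ions.
#' @param lossCap Maximum number of simultaneous neutral losses per ion.
#' @return data.frame with columns series, index, charge, nloss, loss
#'   (loss composition string), water, mz, label, extrapolated.
#' @examples
#' pf <- parsePeptidoform("AC[palmitoyl]DLK")$peptidoform
#' head(generateFragments(pf, activationRules("HCD"), precursorCharge = 2))
#' @export
generateFragments <- function(pf, rules = activationRules("HCD"),
                              maxFragmentCharge = 2L,
                              precursorCharge = NA_integer_,
                              lossCap = 2L) {
  stopifnot(is(pf, "Peptidoform"))
  n <- nchar(pf@sequence)
  if (n < 2L) stop("peptide must have at least 2 residues")
  res <- strsplit(pf@sequence, "")[[1]]
  rmass <- .residueMasses()[res]
  ## per-position modification deltas (terminus mods fold into position 1)
  delta <- numeric(n)
  labile <- data.frame(position = integer(0), name = character(0),
                       lability = character(0))
  for (k in seq_along(pf@modPositions)) {
    mod <- getModification(pf@modNames[k])
    p <- max(pf@modPositions[k], 1L)
    delta[p] <- delta[p] + mod$delta
    if (mod$lability != "stable" && pf@modPositions[k] > 0L)
      labile <- rbind(labile, data.frame(position = pf@modPositions[k],
                                         name = mod$name,
                                         lability = mod$lability))
  }
  prefix <- cumsum(rmass + delta)            # b_i neutral mass
  total <- prefix[n] + .H2O()
  suffixY <- total - prefix                  # y_{n-i} neutral = M - prefix_i
  rows <- list()
  emit <- function(series, index, charge, neutral, nloss = 0L, loss = "",
                   water = 0L, extrapolated = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, index = index, charge = charge, nloss = nloss,
      loss = loss, water = water,
      mz = mzFromMass(neutral + water * .H2O(), charge),
      label = .ionLabel(series, index, nloss, charge, water),
      extrapolated = extrapolated, stringsAsFactors = FALSE)
  }
  charges <- seq_len(max(1L, as.integer(maxFragmentCharge)))
  for (series in rules$backboneSeries) {
    for (i in seq_len(n - 1L)) {
      neutral <- switch(series,
        b = prefix[i],
        c = prefix[i] + .NH3(),
        y = suffixY[i],                      # y_{n-i}: residues i+1..n
        zdot = suffixY[i] - .NH3() + .ATOMIC_MASS[["H"]])
      index <- if (series %in% c("b", "c")) i else n - i
      span <- if (series %in% c("b", "c"))
        labile[labile$position <= i, , drop = FALSE]
      else
        labile[labile$position > i, , drop = FALSE]
      for (z in charges) {
        emit(series, index, z, neutral)
        lv <- .lossVariants(span, series, rules, lossCap)
        if (!is.null(lv))
          for (r in seq_len(nrow(lv)))
            emit(series, index, z, neutral - lv$lossMass[r],
                 nloss = lv$nloss[r], loss = lv$lossFormula[r],
                 extrapolated = lv$extrapolated[r])
      }
    }
  }
  if (!is.na(precursorCharge)) {
    prec <- precursorIons(pf, precursorCharge, rules, lossCap = lossCap)
    rows[[length(rows) + 1L]] <- prec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precursor and diagnostic ions
#'
#' Emits the intact precursor p at charges 1..\code{precursorCharge}
#' (the reduced-charge entries double as the ETD charge-reduced series),
#' p±H2O, one p* per applicable labile-modification loss channel (up to
#' \code{lossCap} simultaneous losses), and — for collisional activation of
#' acylated peptidoforms — the acylium-type diagnostic ion d* (acyl delta +
#' proton, singly charged).
#'
#' @inheritParams generateFragments
#' @param precursorCharge Precursor charge (>= 1).
#' @return data.frame in the same layout as [generateFragments()].
#' @export
precursorIons <- function(pf, precursorCharge, rules = activationRules("HCD"),
                          lossCap = 2L) {
  stopifnot(is(pf, "Peptidoform"), precursorCharge >= 1L)
  precursorCharge <- as.integer(precursorCharge)
  M <- peptideMass(pf)
  labile <- data.frame(position = integer(0), name = character(0))
  for (k in seq_along(pf@modPositions)) {
    mod <- getModification(pf@modNames[k])
    if (mod$lability != "stable" && pf@modPositions[k] > 0L)
      labile <- rbind(labile, data.frame(position = pf@modPositions[k],
                                         name = mod$name))
  }
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  row1 <- function(series, charge, neutral, nloss = 0L, loss = "",
                   water = 0L, extrapolated = FALSE)
    data.frame(series = series, index = 0L, charge = charge, nloss = nloss,
               loss = loss, water = water, mz = mzFromMass(neutral, charge),
               label = .ionLabel(series, 0L, nloss, charge, water),
               extrapolated = extrapolated, stringsAsFactors = FALSE)
  for (z in seq_len(precursorCharge))
    add(row1("p", z, M))
  if (isTRUE(rules$precursorWater)) {
    add(row1("p", precursorCharge, M - .H2O(), water = -1L))
    add(row1("p", precursorCharge, M + .H2O(), water = +1L))
  }
  lv <- .lossVariants(labile, "p", rules, lossCap)
  if (!is.null(lv))
    for (r in seq_len(nrow(lv)))
      add(row1("p", precursorCharge, M - lv$lossMass[r],
               nloss = lv$nloss[r], loss = lv$lossFormula[r],
               extrapolated = lv$extrapolated[r]))
  if (isTRUE(rules$diagnosticIons) && nrow(labile)) {
    acyl <- unique(labile$name[vapply(labile$name, function(nm)
      getModification(nm)$lability == "thioester_acyl", TRUE)])
    for (nm in acyl) {
      mod <- getModification(nm)
      add(data.frame(series = "d", index = 0L, charge = 1L, nloss = 1L,
                     loss = formulaString(mod$formula), water = 0L,
                     mz = mod$delta + .PROTON_MASS, label = "d*",
                     extrapolated = FALSE, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fragment table as TSV
#' @param fragments data.frame from [generateFragments()].
#' @param pf The [Peptidoform-class] the fragments belong to.
#' @param path Output file path (or "" for stdout).
#' @return Invisibly, \code{path}.
#' @export
writeFragmentTsv <- function(fragments, pf, path) {
  df <- cbind(peptidoform = formatPeptidoform(pf), fragments)
  df$mz <- sprintf("%.6f", df$mz)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
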