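#' Parse an elemental formula string
#'
#' Parses a concatenation of element symbols (C, H, N, O, S, P) with
#' optional positive integer counts, e.g. \code{"C16H30O"}, into a named
#' integer vector of element counts. An optional \code{radical = TRUE}
#' attribute marks odd-electron species; this affects labelling only, not
#' mass (electron mass is neglected throughout).
#'
#' @param text Formula string.
#' @param radical Logical; mark the parsed formula as a radical species.
#' @return Named integer vector of element counts with attribute
#'   \code{radical}.
#' @examples
#' parseFormula("C16H30O")
#' formulaMass(parseFormula("H2O"))
#' @export
parseFormula <- function(text, radical = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  toks <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(text))
    stop(sprintf("malformed formula '%s'", text))
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    if (!el %in% names(.ATOMIC_MASS))
      stop(sprintf("unknown element %s in formula '%s'", el, text))
    nstr <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (is.na(n) || n <= 0L)
      stop(sprintf("invalid count in token '%s'", p))
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(counts, radical = isTRUE(radical))
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f Named integer vector of element counts (as from
#'   [parseFormula()]) or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' formulaMass("C16H30O")  # palmitoyl neutral loss
#' @export
formulaMass <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  if (!length(f)) stop("formula has no elements")
  bad <- setdiff(names(f), names(.ATOMIC_MASS))
  if (length(bad)) stop(sprintf("unknown element %s", bad[1]))
  if (any(f < 0)) stop("negative element count")
  m <- sum(.ATOMIC_MASS[names(f)] * as.numeric(f))
  if (m <= 0) stop("formula mass must be strictly positive")
  m
}

#' @rdname parseFormula
#' @param f Named integer vector of element counts.
#' @export
formulaString <- function(f) {
  f <- f[f > 0]
  ord <- intersect(c("C", "H", "N", "O", "S", "P"), names(f))
  paste0(vapply(ord, function(el)
    paste0(el, if (f[[el]] > 1L) f[[el]] else ""), character(1)),
    collapse = "")
}

.addFormulas <- function(a, b) {
  els <- union(names(a), names(b))
  out <- integer(length(els)); names(out) <- els
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out
}

## --- modification registry ---------------------------------------------

#' Built-in and user-supplied modification registries
#'
#' The built-in registry (shipped as a TSV under \code{inst/extdata}) covers
#' the lipid modifications handled by the fragmentation model plus the
#' common sample-preparation modifications: myristoyl (C14H26O), palmitoyl
#' (C16H30O), stearoyl (C18H34O), farnesyl (C15H24), geranylgeranyl
#' (C20H32), NEM (C6H7NO2), carbamidomethyl (C2H3NO), protein N-terminal
#' acetyl (C2H2O) and methionine oxidation (O). The \code{lability} column
#' drives the neutral-loss channels: \code{thioester_acyl} entries shed the
#' acyl chain under collisional activation and the acyl+S side chain under
#' ETD; \code{thioether_prenyl} entries shed the isoprenoid; \code{stable}
#' entries shed nothing.
#'
#' @param path Optional path to a user registry in the same TSV dialect
#'   (columns: name, formula, delta_mass, targets, position_rule, lability).
#'   \code{formula} may be empty when only a delta mass is known.
#' @return data.frame with columns name, formula, delta_mass (Da, computed
#'   from the formula when present), targets, position_rule, lability.
#' @examples
#' modificationRegistry()
#' getModification("palmitoyl")$delta
#' @export
modificationRegistry <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .acylms_env$registry
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "modifications.tsv", package = "AcylMS",
                        mustWork = TRUE)
    builtin <- TRUE
  } else builtin <- FALSE
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "formula", "delta_mass", "targets", "position_rule",
            "lability")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop(sprintf("registry is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  reg$delta_mass <- ifelse(
    nzchar(reg$formula),
    vapply(reg$formula, function(s) formulaMass(parseFormula(s)), 0),
    suppressWarnings(as.numeric(reg$delta_mass)))
  if (anyNA(reg$delta_mass) || any(reg$delta_mass <= 0))
    stop("every registry entry needs a formula or a positive delta_mass")
  if (builtin) .acylms_env$registry <- reg
  reg
}

#' @rdname modificationRegistry
#' @param name Modification name.
#' @param registry Registry data.frame; defaults to the built-in one.
#' @return \code{getModification}: list with elements \code{name},
#'   \code{formula} (parsed counts, or NULL), \code{delta} (Da),
#'   \code{targets}, \code{positionRule}, \code{lability}.
#' @export
getModification <- function(name, registry = modificationRegistry()) {
  i <- match(name, registry$name)
  if (is.na(i))
    stop(sprintf("unknown modification '%s'; registry has: %s", name,
                 paste(registry$name, collapse = ", ")))
  list(
    name = registry$name[i],
    formula = if (nzchar(registry$formula[i]))
      parseFormula(registry$formula[i]) else NULL,
    delta = registry$delta_mass[i],
    targets = strsplit(registry$targets[i], "")[[1]],
    positionRule = registry$position_rule[i],
    lability = registry$lability[i]
  )
}

## --- mass / m-z arithmetic ---------------------------------------------

#' m/z of a protonated species
#'
#' \code{mzFromMass} computes \eqn{(M + z \cdot m_p)/z} with the proton
#' mass \eqn{m_p = 1.007276466} Da; \code{neutralMass} inverts it.
#'
#' @param neutralMass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @return m/z (or neutral mass) in Da.
#' @examples
#' mzFromMass(1000, 2)
#' @export
mzFromMass <- function(neutralMass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  (neutralMass + charge * .PROTON_MASS) / charge
}

#' @rdname mzFromMass
#' @param mz Observed m/z.
#' @export
neutralMass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  mz * charge - charge * .PROTON_MASS
}

#' @describeIn peptideMass mass of a bare sequence string.
#' @export
setMethod("peptideMass", "character", function(x, ...) {
  if (length(x) != 1L || !nzchar(x)) stop("empty sequence")
  res <- strsplit(x, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_FORMULA))
  if (length(bad))
    stop(sprintf("unknown residue letter(s): %s",
                 paste(unique(bad), collapse = ", ")))
  sum(.residueMasses()[res]) + formulaMass(c(H = 2L, O = 1L))
})

#' @describeIn peptideMass residue masses + water + modification deltas.
#' @export
setMethod("peptideMass", "Peptidoform", function(x, ...) {
  m <- peptideMass(x@sequence)
  if (length(x@modNames))
    m <- m + sum(vapply(x@modNames, function(nm) getModification(nm)$delta, 0))
  m
})

## residue monoisotopic masses, computed once from the elemental table
.residueMasses <- function() {
  rm <- .acylms_env$residueMass
  if (is.null(rm)) {
    rm <- vapply(.RESIDUE_FORMULA, formulaMass, 0)
    .acylms_env$residueMass <- rm
  }
  rm
}

#' Elemental formula of a whole peptidoform
#'
#' Assembles residue compositions + H2O + modification formulas. Errors if
#' any modification lacks a formula (delta-only registry entries).
#'
#' @param x A [Peptidoform-class].
#' @return Named integer vector of element counts.
#' @export
peptidoformFormula <- function(x) {
  stopifnot(is(x, "Peptidoform"))
  f <- c(H = 2L, O = 1L)
  for (r in strsplit(x@sequence, "")[[1]])
    f <- .addFormulas(f, .RESIDUE_FORMULA[[r]])
  for (nm in x@modNames) {
    mod <- getModification(nm)
    if (is.null(mod$formula))
      stop(sprintf("modification '%s' has no elemental formula", nm))
    f <- .addFormulas(f, mod$formula)
  }
  f
}
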