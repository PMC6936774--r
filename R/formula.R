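#' @title Elemental formulas, monoisotopic masses and RDBE
#' @name formula-tools
#' @description
#' Small utilities shared by the annotation layer: parsing of molecular
#' formulas such as `"C28H43NO6"` into element counts, monoisotopic mass
#' computation, ring-plus-double-bond equivalents (RDBE) and ppm mass errors.
NULL

# Monoisotopic atomic masses (Da). C is exactly 12 by definition of the scale.
.MONOISOTOPIC <- c(
  C = 12.0,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200
)

#' Mass of a proton in Da
#'
#' Used for `[M+H]+` / `[M-H]-` neutral-mass conversion. The electron mass is
#' absorbed into this constant; at masses above 150 Da the difference is below
#' 0.5 ppm, under the accuracy of an Orbitrap-class instrument.
#' @export
PROTON_MASS <- 1.007276

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas over the supported element set
#' (C, H, N, O, S, P by default), e.g. `"C22H22N2O4"` or `"H2O"`.
#'
#' @param x character vector of formula strings.
#' @param elements character vector of allowed element symbols.
#' @return A named list of named integer vectors (element -> count).
#' @examples
#' parse_formula("C28H43NO6")
#' @export
parse_formula <- function(x, elements = names(.MONOISOTOPIC)) {
  stopifnot(is.character(x))
  lapply(x, function(f) {
    f0 <- gsub("\\s", "", f)
    if (!nzchar(f0)) stop("empty formula string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f0)[[1]]
    toks <- regmatches(f0, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(f0)) {
      stop("malformed formula '", f, "': unparseable token near '",
           substr(f0, sum(nchar(toks)) + 1, nchar(f0)), "'")
    }
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
    cnt <- sub("^[A-Z][a-z]?", "", toks)
    cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
    bad <- setdiff(sym, elements)
    if (length(bad)) {
      stop("malformed formula '", f, "': unknown element token '",
           bad[[1]], "'")
    }
    counts <- stats::setNames(integer(length(elements)), elements)
    for (i in seq_along(sym)) counts[[sym[i]]] <- counts[[sym[i]]] + cnt[i]
    if (sum(counts) < 1L) stop("formula '", f, "' contains no atoms")
    counts
  })
}

#' Format element counts back into a formula string
#'
#' Hill order: C, then H, then remaining elements alphabetically.
#' @param counts named integer vector (element -> count).
#' @return A single formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- c(intersect(c("C", "H"), names(counts)), rest)
  paste0(vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' @param formula a formula string, or a named integer vector of element
#'   counts as returned by [parse_formula()].
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' monoisotopic_mass("C28H43NO6") # borrelidin, 489.3090
#' @export
monoisotopic_mass <- function(formula) {
  counts <- .as_counts(formula)
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown)) stop("unknown element symbol: ", unknown[[1]])
  sum(counts * .MONOISOTOPIC[names(counts)])
}

#' Ring-plus-double-bond equivalents (RDBE)
#'
#' RDBE = 1 + C - H/2 + N/2 + P/2. Oxygen and sulfur (divalent) contribute
#' zero. A half-integer value indicates an odd-electron species; stable
#' even-electron neutrals have integer RDBE >= 0.
#'
#' @inheritParams monoisotopic_mass
#' @return RDBE as a (half-)integer numeric.
#' @examples
#' rdbe("C22H22N2O4") # 13
#' @export
rdbe <- function(formula) {
  counts <- .as_counts(formula)
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  1 + g("C") - g("H") / 2 + g("N") / 2 + g("P") / 2
}

#' Signed mass error in parts per million
#'
#' @param observed observed mass (Da).
#' @param theoretical theoretical mass (Da).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

.as_counts <- function(formula) {
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    parse_formula(formula)[[1]]
  } else if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula[formula > 0]
    if (length(counts) == 0) stop("formula contains no atoms")
    counts
  } else {
    stop("formula must be a string or a named count vector")
  }
}
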