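#' @title Formula prediction, dereplication and novelty summaries
#' @name annotation
#' @description
#' Molecular-formula enumeration at a ppm tolerance with RDBE and
#' element-ratio filtering, exact-mass dereplication of neutral features
#' against a compound database, and per-isolate known/unknown summaries.
#' Both formula search and database matching operate on neutral masses
#' (after adduct resolution), matching how dereplication tables report
#' neutral MW against predicted formulas.
NULL

#' Element count bounds for formula enumeration
#'
#' @param C,H,N,O,S,P integer vectors `c(min, max)` of allowed counts.
#' @return A named list of class `element_spec`.
#' @examples
#' element_spec()                 # CHNOSP defaults
#' element_spec(S = c(0, 0), P = c(0, 0)) # CHNO only
#' @export
element_spec <- function(C = c(0L, 60L), H = c(0L, 120L), N = c(0L, 10L),
                         O = c(0L, 20L), S = c(0L, 3L), P = c(0L, 2L)) {
  spec <- list(C = C, H = H, N = N, O = O, S = S, P = P)
  for (el in names(spec)) {
    b <- spec[[el]]
    stopifnot(length(b) == 2, b[1] >= 0, b[2] >= b[1])
  }
  structure(spec, class = "element_spec")
}

# convenience: "CHNO" -> element_spec with S and P zeroed
.as_element_spec <- function(elements) {
  if (inherits(elements, "element_spec")) return(elements)
  if (is.character(elements) && length(elements) == 1) {
    keep <- strsplit(elements, "")[[1]]
    spec <- element_spec()
    for (el in setdiff(names(spec), keep)) spec[[el]] <- c(0L, 0L)
    return(spec)
  }
  stop("elements must be an element_spec or a string like 'CHNO'")
}

# heavy-atom (non-H) count grid with precomputed mass, memoized per element
# spec so repeated queries share the enumeration table
.grid_cache <- new.env(parent = emptyenv())

.heavy_atom_grid <- function(spec) {
  key <- paste(unlist(spec[c("C", "N", "O", "S", "P")]), collapse = "_")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  rng <- function(el) seq.int(spec[[el]][1], spec[[el]][2])
  g <- expand.grid(C = rng("C"), N = rng("N"), O = rng("O"),
                   S = rng("S"), P = rng("P"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$heavy <- g$C * .MONOISOTOPIC[["C"]] + g$N * .MONOISOTOPIC[["N"]] +
    g$O * .MONOISOTOPIC[["O"]] + g$S * .MONOISOTOPIC[["S"]] +
    g$P * .MONOISOTOPIC[["P"]]
  g <- g[order(g$heavy), , drop = FALSE]
  .grid_cache[[key]] <- g
  g
}

#' Enumerate molecular-formula candidates for a neutral mass
#'
#' Exhaustive search over the element-count box defined by `elements`.
#' Candidates must match the query mass within `tol_ppm`, have RDBE >= 0,
#' integer RDBE (an even-electron neutral), and, when `hc_filter` is on and
#' carbon is present, an H/C ratio between 0 and 3 (a standard
#' element-ratio plausibility heuristic; switchable). The result is ranked
#' by absolute ppm error; an empty result means "no prediction".
#'
#' @param neutral_mass query neutral monoisotopic mass (Da).
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @param elements an [element_spec()] or a string such as `"CHNO"`.
#' @param hc_filter apply the 0 <= H/C <= 3 heuristic (default TRUE).
#' @return tibble with `formula`, `theoretical_mass`, `ppm_error`, `rdbe`
#'   and per-element counts, ranked by `abs(ppm_error)`.
#' @examples
#' enumerate_formulas(378.158, elements = "CHNO")
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm = 5,
                               elements = element_spec(),
                               hc_filter = TRUE) {
  stopifnot(length(neutral_mass) == 1, neutral_mass > 0, tol_ppm > 0)
  spec <- .as_element_spec(elements)
  lo_mass <- neutral_mass * (1 - tol_ppm * 1e-6)
  hi_mass <- neutral_mass * (1 + tol_ppm * 1e-6)

  full <- .heavy_atom_grid(spec)
  g <- full[seq_len(findInterval(hi_mass, full$heavy)), , drop = FALSE]

  mH <- .MONOISOTOPIC[["H"]]
  h_lo <- pmax(ceiling((lo_mass - g$heavy) / mH), spec$H[1])
  h_hi <- pmin(floor((hi_mass - g$heavy) / mH), spec$H[2])
  ok <- h_hi >= h_lo
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0) return(.empty_candidates())
  # the ppm window is far narrower than one hydrogen mass, so at most one
  # H count can fit; keep a loop-free single candidate per heavy combo
  g$H <- h_lo[ok]

  mass <- g$heavy + g$H * mH
  rdbe_v <- 1 + g$C - g$H / 2 + g$N / 2 + g$P / 2
  keep <- mass >= lo_mass & mass <= hi_mass &
    rdbe_v >= 0 & abs(rdbe_v - round(rdbe_v)) < 1e-9 &
    (g$C + g$H + g$N + g$O + g$S + g$P) >= 1
  if (hc_filter) {
    keep <- keep & (g$C == 0 | (g$H / g$C >= 0 & g$H / g$C <= 3))
  }
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(.empty_candidates())
  mass <- mass[keep]
  rdbe_v <- rdbe_v[keep]
  ppm <- ppm_error(neutral_mass, mass)
  ord <- order(abs(ppm), mass)
  g <- g[ord, , drop = FALSE]
  tibble::tibble(
    formula = vapply(seq_len(nrow(g)), function(i) {
      format_formula(c(C = g$C[i], H = g$H[i], N = g$N[i],
                       O = g$O[i], S = g$S[i], P = g$P[i]))
    }, character(1)),
    theoretical_mass = mass[ord],
    ppm_error = ppm[ord],
    rdbe = rdbe_v[ord],
    C = g$C, H = g$H, N = g$N, O = g$O, S = g$S, P = g$P
  )
}

.empty_candidates <- function() {
  tibble::tibble(formula = character(), theoretical_mass = numeric(),
                 ppm_error = numeric(), rdbe = numeric(),
                 C = integer(), H = integer(), N = integer(),
                 O = integer(), S = integer(), P = integer())
}

#' Dereplicate neutral features against a compound database
#'
#' Each feature is matched to every database compound whose exact mass lies
#' within `tol_ppm`. Hits are sorted per feature by absolute ppm error and
#' the output is independent of database row order. A feature with at least
#' one hit is "known"; one with none is "unknown".
#'
#' @param features a `neutral_features` tibble (or a numeric vector of
#'   neutral masses).
#' @param db compound database as returned by [read_compound_db()].
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @return tibble with `feature_row`, `neutral_mass`, `name`, `exact_mass`,
#'   `ppm_error`.
#' @export
dereplicate <- function(features, db, tol_ppm = 5) {
  if (is.numeric(features)) {
    masses <- features
  } else {
    masses <- features$neutral_mass
  }
  if (nrow(db) == 0) stop("compound database is empty")
  ord <- order(db$exact_mass)
  dbm <- db$exact_mass[ord]
  pw <- .window_pairs(dbm, masses, masses * tol_ppm * 1e-6)
  if (length(pw$i) == 0) {
    return(tibble::tibble(feature_row = integer(), neutral_mass = numeric(),
                          name = character(), exact_mass = numeric(),
                          ppm_error = numeric()))
  }
  hit_db <- ord[pw$j]
  out <- tibble::tibble(
    feature_row = pw$i,
    neutral_mass = masses[pw$i],
    name = db$name[hit_db],
    exact_mass = db$exact_mass[hit_db],
    ppm_error = ppm_error(masses[pw$i], db$exact_mass[hit_db])
  )
  out[order(out$feature_row, abs(out$ppm_error), out$name), , drop = FALSE]
}

#' Per-isolate known/unknown dereplication summary
#'
#' A feature counts for an isolate when its intensity in that isolate's
#' extract is above zero; it is "known" when it has at least one
#' dereplication hit. Isolates with no detected features are omitted with
#' a warning.
#'
#' @param features a `neutral_features` tibble.
#' @param hits output of [dereplicate()] on the same features.
#' @param meta sample metadata mapping extract samples to isolates.
#' @return tibble with `isolate_id`, `n_features`, `n_known`, `n_unknown`,
#'   `unknown_fraction`.
#' @export
novelty_summary <- function(features, hits,
                            meta = attr(features, "meta")) {
  known <- seq_len(nrow(features)) %in% hits$feature_row
  extract <- meta[meta$role == "extract", , drop = FALSE]
  res <- lapply(seq_len(nrow(extract)), function(i) {
    sc <- extract$sample_id[i]
    if (!sc %in% names(features)) return(NULL)
    present <- features[[sc]] > 0
    n <- sum(present)
    if (n == 0) {
      warning("isolate ", extract$isolate_id[i],
              " has no detected features; omitted from novelty summary")
      return(NULL)
    }
    nk <- sum(known & present)
    tibble::tibble(isolate_id = extract$isolate_id[i],
                   n_features = n, n_known = nk, n_unknown = n - nk,
                   unknown_fraction = (n - nk) / n)
  })
  dplyr::bind_rows(res)
}
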