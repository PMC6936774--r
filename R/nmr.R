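#' @title 1D 1H-NMR bucketing for chemometrics
#' @name nmr
#' @description
#' Converts point-wise 1D proton spectra (ppm, intensity) into a bucket
#' table comparable across samples: trapezoid integration into fixed-width
#' ppm bins over a 0.5-12.5 ppm window, removal of every bucket touching a
#' solvent exclusion zone (DMSO, water), and per-spectrum total-area
#' normalization so relative profiles are compared rather than absolute
#' receiver gain.
NULL

#' A 1D spectrum
#'
#' @param sample_id sample identifier.
#' @param ppm chemical-shift axis, strictly monotonic, >= 2 points.
#' @param intensity intensity per point.
#' @return list of class `spectrum_1d` (axis stored ascending).
#' @export
spectrum_1d <- function(sample_id, ppm, intensity) {
  stopifnot(length(ppm) == length(intensity), length(ppm) >= 2)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("ppm axis must be strictly monotonic")
  }
  if (d[1] < 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(sample_id = as.character(sample_id),
                 ppm = ppm, intensity = intensity),
            class = "spectrum_1d")
}

#' Read a two-column (ppm, intensity) spectrum file
#'
#' @param path delimited text with a header row.
#' @param sample_id identifier (default: file name without extension).
#' @param delim optional delimiter override.
#' @export
read_nmr_spectrum <- function(path, sample_id = NULL, delim = NULL) {
  d <- .detect_delim(path, delim)
  tab <- .read_delim_quiet(path, d)
  if (ncol(tab) < 2) stop("expected ppm and intensity columns in ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  spectrum_1d(sample_id, as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

#' Solvent exclusion zones
#'
#' Default zones delete residual DMSO (2.40-2.60 ppm) and water
#' (3.25-3.45 ppm) solvent signals before bucketing.
#' @param low,high,label zone bounds (ppm, `low < high`) and a name.
#' @export
exclusion_zone <- function(low, high, label = "") {
  stopifnot(low < high)
  tibble::tibble(low = low, high = high, label = label)
}

#' @rdname exclusion_zone
#' @export
default_exclusions <- function() {
  dplyr::bind_rows(exclusion_zone(2.40, 2.60, "DMSO"),
                   exclusion_zone(3.25, 3.45, "water"))
}

# exact integral of the piecewise-linear spectrum over [a, b]
.trapz_between <- function(ppm, intensity, a, b) {
  cum <- c(0, cumsum(diff(ppm) * (utils::head(intensity, -1) +
                                    utils::tail(intensity, -1)) / 2))
  at <- function(x) {
    x <- pmin(pmax(x, ppm[1]), ppm[length(ppm)])
    stats::approx(ppm, cum, xout = x, rule = 2)$y
  }
  at(b) - at(a)
}

#' Bucket a set of 1D spectra
#'
#' Intensity is integrated (trapezoid) over consecutive buckets of
#' `width` ppm covering `window`; any bucket intersecting an exclusion
#' zone is removed entirely. When `normalize` is on (default) each
#' spectrum's remaining bucket areas are rescaled to a total of 100.
#'
#' @param spectra list of [spectrum_1d()] objects.
#' @param width bucket width in ppm (default 0.04, standard metabolomics
#'   binning).
#' @param window analysis window in ppm (default `c(0.5, 12.5)`).
#' @param exclusions tibble of exclusion zones (see [exclusion_zone()]).
#' @param normalize total-area normalize each spectrum to 100.
#' @return list of class `bucket_table`: `centers` (ppm), `intensities`
#'   (samples x buckets matrix with rownames = sample ids).
#' @export
bucket_spectra <- function(spectra, width = 0.04, window = c(0.5, 12.5),
                           exclusions = default_exclusions(),
                           normalize = TRUE) {
  if (width <= 0) stop("bucket width must be positive")
  if (inherits(spectra, "spectrum_1d")) spectra <- list(spectra)
  edges <- seq(window[1], window[2], by = width)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  lo <- utils::head(edges, -1); hi <- utils::tail(edges, -1)
  centers <- (lo + hi) / 2
  keep <- rep(TRUE, length(centers))
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    for (i in seq_len(nrow(exclusions))) {
      z <- exclusions[i, ]
      if (z$high < window[1] || z$low > window[2]) {
        warning("exclusion zone '", z$label,
                "' lies outside the analysis window")
      }
      keep <- keep & !(hi > z$low & lo < z$high)
    }
  }
  M <- t(vapply(spectra, function(sp) {
    if (sp$ppm[1] > window[1] || sp$ppm[length(sp$ppm)] < window[2]) {
      if (max(sp$ppm) < window[1] || min(sp$ppm) > window[2]) {
        stop("spectrum '", sp$sample_id,
             "' does not overlap the analysis window")
      }
    }
    vapply(seq_along(lo), function(b) {
      .trapz_between(sp$ppm, sp$intensity, lo[b], hi[b])
    }, numeric(1))
  }, numeric(length(lo))))
  rownames(M) <- vapply(spectra, function(sp) sp$sample_id, character(1))
  M <- M[, keep, drop = FALSE]
  centers <- centers[keep]
  if (normalize) {
    tot <- rowSums(M)
    if (any(tot <= 0)) stop("spectrum with non-positive total area")
    M <- sweep(M, 1, tot, "/") * 100
  }
  colnames(M) <- sprintf("%.3fppm", centers)
  structure(list(centers = centers, intensities = M,
                 width = width, window = window, normalized = normalize),
            class = "bucket_table")
}

#' Turn a bucket table into a chemometrics-ready matrix
#'
#' Rows restricted and checked against the sample metadata; columns keyed
#' by bucket center so loadings stay interpretable in ppm.
#'
#' @param table a `bucket_table`.
#' @param meta sample metadata; every spectrum must be listed.
#' @param roles which sample roles to keep (default extract + medium, the
#'   samples compared in the published NMR models).
#' @return numeric samples-by-buckets matrix for [pareto_scale()].
#' @export
nmr_to_features <- function(table, meta,
                            roles = c("extract", "medium")) {
  M <- table$intensities
  if (ncol(M) == 0 || nrow(M) == 0) stop("empty bucket table")
  unknown <- setdiff(rownames(M), meta$sample_id)
  if (length(unknown)) {
    stop("spectrum sample '", unknown[[1]], "' missing from metadata")
  }
  want <- meta$sample_id[meta$role %in% roles]
  M[intersect(rownames(M), want), , drop = FALSE]
}
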