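#' @title Reading and writing feature tables, metadata, compound databases
#'   and bioassay grids
#' @name feature-io
#' @description
#' The pipeline exchanges plain delimited text: aligned peak lists exported
#' per ionization mode (`feature_id,mz,rt,<sample...>`), a sample-metadata
#' table (`sample_id,role,isolate_id`), a compound database
#' (`name,formula,exact_mass,source,class`) and a bioassay grid of
#' inhibition-zone diameters or Active/Inactive calls. Comma and tab
#' delimiters are auto-detected (first match wins) because aligned-export
#' dialects vary between tools.
NULL

.detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

.read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Build a sample metadata table
#'
#' @param sample_id character vector of sample identifiers.
#' @param role one of `"extract"`, `"medium"`, `"blank"` per sample.
#' @param isolate_id isolate identifier for extract samples (`NA` otherwise).
#' @return A validated `tbl_df` with class `sample_meta`.
#' @export
sample_meta <- function(sample_id, role, isolate_id = NA_character_) {
  meta <- tibble::tibble(
    sample_id = as.character(sample_id),
    role = as.character(role),
    isolate_id = as.character(isolate_id)
  )
  validate_sample_meta(meta)
}

#' @rdname sample_meta
#' @param meta a data frame with columns `sample_id`, `role`, `isolate_id`.
#' @export
validate_sample_meta <- function(meta) {
  stopifnot(all(c("sample_id", "role") %in% names(meta)))
  if (!"isolate_id" %in% names(meta)) meta$isolate_id <- NA_character_
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  }
  bad <- setdiff(meta$role, c("extract", "medium", "blank"))
  if (length(bad)) stop("unknown sample role: '", bad[[1]], "'")
  need_iso <- meta$role == "extract" &
    (is.na(meta$isolate_id) | meta$isolate_id == "")
  if (any(need_iso)) {
    stop("extract sample without isolate_id: ",
         meta$sample_id[need_iso][1])
  }
  class(meta) <- unique(c("sample_meta", class(meta)))
  meta
}

#' Read a sample metadata CSV/TSV
#'
#' Expected columns: `sample_id`, `role`, `isolate_id`.
#' @param path file path.
#' @param delim optional delimiter override (default: auto-detect).
#' @export
read_sample_meta <- function(path, delim = NULL) {
  d <- .detect_delim(path, delim)
  tab <- .read_delim_quiet(path, d)
  validate_sample_meta(tab[, intersect(c("sample_id", "role", "isolate_id"),
                                       names(tab))])
}

#' Construct a single-polarity feature table
#'
#' A feature table is a tibble with columns `feature_id`, `mz`, `rt` followed
#' by one intensity column per sample, plus attributes `polarity` (the shared
#' ionization mode of every record) and `meta` (the sample metadata).
#'
#' @param features tibble with `feature_id`, `mz`, `rt` and sample columns.
#' @param meta sample metadata covering every intensity column.
#' @param polarity `"positive"` or `"negative"`.
#' @param mz_range allowed instrument m/z window, default 150-1500.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, meta, polarity,
                          mz_range = c(150, 1500)) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  meta <- validate_sample_meta(meta)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)))
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature ids: ",
         features$feature_id[duplicated(features$feature_id)][1])
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    stop("non-numeric or non-positive m/z values present")
  }
  out_of_range <- features$mz < mz_range[1] | features$mz > mz_range[2]
  if (any(out_of_range)) {
    stop("m/z outside instrument range [", mz_range[1], ", ", mz_range[2],
         "]: feature ", features$feature_id[out_of_range][1])
  }
  if (any(features$rt < 0)) stop("negative retention time present")
  sample_cols <- setdiff(names(features), c("feature_id", "mz", "rt"))
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta)) {
    stop("intensity column not described in metadata: '",
         missing_meta[[1]], "'")
  }
  for (sc in sample_cols) {
    v <- features[[sc]]
    if (anyNA(v)) {
      warning("missing intensities in sample '", sc, "' stored as 0")
      v[is.na(v)] <- 0
    }
    if (any(v < 0)) {
      warning("negative intensities in sample '", sc, "' clipped to 0")
      v[v < 0] <- 0
    }
    features[[sc]] <- v
  }
  structure(tibble::as_tibble(features),
            polarity = polarity,
            meta = meta,
            class = c("feature_table", class(tibble::tibble())))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x), " features x ",
      length(sample_ids(x)), " samples, ", attr(x, "polarity"),
      " mode\n", sep = "")
  NextMethod()
}

#' Sample columns of a feature table
#' @param table a `feature_table` or neutral-feature tibble.
#' @export
sample_ids <- function(table) {
  setdiff(names(table), c("feature_id", "mz", "rt", "neutral_mass",
                          "modes_seen", "provenance"))
}

#' Polarity of a feature table
#' @param table a `feature_table`.
#' @export
table_polarity <- function(table) attr(table, "polarity")

#' Metadata attached to a feature table
#' @param table a `feature_table`.
#' @export
table_meta <- function(table) attr(table, "meta")

#' Read an aligned peak-list export
#'
#' Expects a header row `feature_id,mz,rt,<sample...>` (comma or tab
#' separated). Missing intensity cells are stored as 0 with a warning;
#' negative intensities are clipped to 0.
#'
#' @param path file path.
#' @param polarity ionization mode of the export.
#' @param meta sample metadata (see [sample_meta()]).
#' @param delim optional delimiter override.
#' @param mz_range allowed instrument m/z window.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, polarity, meta, delim = NULL,
                               mz_range = c(150, 1500)) {
  d <- .detect_delim(path, delim)
  raw <- .read_delim_quiet(path, d)
  if (ncol(raw) < 4) {
    stop("expected at least feature_id, mz, rt and one sample column in ",
         path)
  }
  names(raw)[1:3] <- c("feature_id", "mz", "rt")
  for (col in c("mz", "rt")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(v)
    if (any(bad)) {
      stop("non-numeric ", col, " '", raw[[col]][bad][1], "' at row ",
           which(bad)[1], " of ", path)
    }
    raw[[col]] <- v
  }
  for (sc in setdiff(names(raw), c("feature_id", "mz", "rt"))) {
    raw[[sc]] <- suppressWarnings(as.numeric(raw[[sc]]))
  }
  feature_table(raw, meta, polarity, mz_range = mz_range)
}

#' Write a feature table back to delimited text
#'
#' m/z values round-trip at 6 significant digits; intensities are written
#' as given.
#' @param table a `feature_table`.
#' @param path output path.
#' @param delim delimiter (default comma).
#' @export
write_feature_table <- function(table, path, delim = ",") {
  out <- tibble::as_tibble(table)
  out$mz <- signif(out$mz, 6)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a compound database
#'
#' Columns: `name` plus at least one of `formula`, `exact_mass`; optional
#' `source` and `class`. The exact (neutral monoisotopic) mass is computed
#' from the formula when absent and cross-checked within 1e-4 Da when both
#' are present.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return tibble with `name`, `formula`, `exact_mass`, `source`,
#'   `compound_class`.
#' @export
read_compound_db <- function(path, delim = NULL) {
  d <- .detect_delim(path, delim)
  tab <- .read_delim_quiet(path, d)
  if (!"name" %in% names(tab)) stop("compound DB needs a 'name' column")
  if (!"formula" %in% names(tab)) tab$formula <- NA_character_
  if (!"exact_mass" %in% names(tab)) tab$exact_mass <- NA_character_
  mass <- suppressWarnings(as.numeric(tab$exact_mass))
  formula <- ifelse(is.na(tab$formula) | tab$formula == "",
                    NA_character_, tab$formula)
  for (i in seq_len(nrow(tab))) {
    if (is.na(formula[i]) && is.na(mass[i])) {
      stop("compound '", tab$name[i],
           "' has neither a formula nor an exact mass")
    }
    if (!is.na(formula[i])) {
      m <- monoisotopic_mass(formula[i])
      if (!is.na(mass[i]) && abs(mass[i] - m) > 1e-4) {
        stop("compound '", tab$name[i], "': stated mass ", mass[i],
             " disagrees with formula mass ", round(m, 5))
      }
      mass[i] <- m
    }
  }
  if (any(mass <= 0)) stop("non-positive exact mass in compound DB")
  tibble::tibble(
    name = tab$name,
    formula = formula,
    exact_mass = mass,
    source = if ("source" %in% names(tab)) tab$source else NA_character_,
    compound_class = if ("class" %in% names(tab)) tab$class
                     else NA_character_
  )
}

#' Read a bioassay grid
#'
#' A delimited isolate-by-strain grid. Cells hold either an inhibition-zone
#' diameter in mm or the words `Active` / `Inactive` (case-insensitive).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return tibble with one row per (isolate, strain): `isolate_id`,
#'   `strain`, `zone_mm` (NA when only a flag was given) and `flag`
#'   (`"active"` / `"inactive"`, NA when only a zone was given).
#' @export
read_bioassay_table <- function(path, delim = NULL) {
  d <- .detect_delim(path, delim)
  tab <- .read_delim_quiet(path, d)
  strains <- names(tab)[-1]
  long <- tidyr::pivot_longer(tab, -1, names_to = "strain",
                              values_to = "cell")
  names(long)[1] <- "isolate_id"
  cell <- trimws(long$cell)
  zone <- suppressWarnings(as.numeric(cell))
  flag <- rep(NA_character_, length(cell))
  is_word <- is.na(zone) & !is.na(cell) & cell != ""
  word <- tolower(cell[is_word])
  if (any(!word %in% c("active", "inactive"))) {
    bad <- cell[is_word][!word %in% c("active", "inactive")][1]
    stop("unknown bioassay cell token '", bad, "'")
  }
  flag[is_word] <- word
  if (any(!is.na(zone) & zone < 0)) {
    stop("negative inhibition zone: ",
         zone[!is.na(zone) & zone < 0][1], " mm")
  }
  missing_both <- is.na(zone) & is.na(flag)
  if (any(missing_both)) {
    stop("empty bioassay cell for isolate '",
         long$isolate_id[missing_both][1], "'")
  }
  tibble::tibble(isolate_id = long$isolate_id, strain = long$strain,
                 zone_mm = zone, flag = flag)
}
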