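#' @title Isolate prioritization
#' @name prioritize
#' @description
#' Combines bioassay activity calls, PCA outlier status, dereplication
#' novelty and discriminant-marker ownership into a ranked isolate
#' shortlist. Ranking is lexicographic gating rather than a weighted
#' score: activity against the target strain first, then chemical
#' uniqueness (Hotelling outlier), then number of discriminant markers
#' owned, then unknown fraction. Isolates active only against non-target
#' strains fall behind every target-active isolate.
NULL

#' Call activity from bioassay records
#'
#' A zone of inhibition strictly greater than `zone_threshold` mm counts
#' as active; records carrying only an Active/Inactive flag pass through.
#'
#' @param records tibble from [read_bioassay_table()].
#' @param zone_threshold activity cut-off in mm (default 12, strict
#'   inequality).
#' @return tibble with `isolate_id`, `strain`, `zone_mm`, `active`.
#' @export
call_activity <- function(records, zone_threshold = 12) {
  active <- ifelse(!is.na(records$zone_mm),
                   records$zone_mm > zone_threshold,
                   records$flag == "active")
  tibble::tibble(isolate_id = records$isolate_id,
                 strain = records$strain,
                 zone_mm = records$zone_mm,
                 active = active)
}

#' Attribute discriminant features to producing isolates
#'
#' Each selected feature is owned by the isolate whose extract shows the
#' highest intensity; exact ties go to the lexicographically first isolate
#' with a warning.
#'
#' @param variables selected variables: integer feature rows, or variable
#'   names in the `mass@rt` convention of [features_to_matrix()].
#' @param features a `neutral_features` tibble.
#' @param meta sample metadata mapping extract samples to isolates.
#' @return tibble with `variable`, `feature_row`, `owner_isolate`.
#' @export
assign_marker_ownership <- function(variables, features,
                                    meta = attr(features, "meta")) {
  if (is.numeric(variables)) {
    rows <- as.integer(variables)
    labels <- sprintf("%.4f@%.2f", features$neutral_mass[rows],
                      features$rt[rows])
  } else {
    labels <- as.character(variables)
    all_labels <- sprintf("%.4f@%.2f", features$neutral_mass,
                          features$rt)
    rows <- match(labels, all_labels)
    if (anyNA(rows)) {
      stop("selected variable '", labels[is.na(rows)][1],
           "' not found in the feature list")
    }
  }
  extract <- meta[meta$role == "extract", , drop = FALSE]
  cols <- intersect(extract$sample_id, names(features))
  iso <- extract$isolate_id[match(cols, extract$sample_id)]
  ord <- order(iso)
  cols <- cols[ord]; iso <- iso[ord]
  M <- as.matrix(features[rows, cols, drop = FALSE])
  owner <- character(length(rows))
  for (i in seq_along(rows)) {
    v <- M[i, ]
    best <- which(v == max(v))
    if (length(best) > 1) {
      warning("intensity tie for feature ", labels[i],
              "; lexicographically first isolate wins")
    }
    owner[i] <- iso[best[1]]
  }
  tibble::tibble(variable = labels, feature_row = rows,
                 owner_isolate = owner)
}

#' Rank isolates for scale-up
#'
#' @param calls activity calls from [call_activity()].
#' @param outliers character vector of isolate ids flagged as Hotelling
#'   outliers.
#' @param novelty novelty summary from [novelty_summary()] (may be empty).
#' @param ownership marker ownership from [assign_marker_ownership()]
#'   (may be empty).
#' @param target_strain the strain whose activity gates the ranking.
#' @return tibble with one row per isolate: `isolate_id`,
#'   `target_active`, `pca_outlier`, `n_markers_owned`,
#'   `unknown_fraction`, `rank`, `rationale`. Ranks are unique; every
#'   target-active isolate precedes every target-inactive one.
#' @export
rank_isolates <- function(calls, outliers, novelty, ownership,
                          target_strain) {
  isolates <- sort(unique(calls$isolate_id))
  if (length(isolates) == 0) stop("empty isolate set")
  if (!target_strain %in% calls$strain) {
    stop("target strain '", target_strain, "' absent from bioassay calls")
  }
  tgt <- calls[calls$strain == target_strain, , drop = FALSE]
  target_active <- stats::setNames(rep(FALSE, length(isolates)), isolates)
  target_active[tgt$isolate_id[tgt$active]] <- TRUE
  n_mark <- table(factor(ownership$owner_isolate, levels = isolates))
  unk <- stats::setNames(rep(0, length(isolates)), isolates)
  if (!is.null(novelty) && nrow(novelty) > 0) {
    unk[novelty$isolate_id] <- novelty$unknown_fraction
  }
  out <- tibble::tibble(
    isolate_id = isolates,
    target_active = unname(target_active),
    pca_outlier = isolates %in% outliers,
    n_markers_owned = as.integer(n_mark),
    unknown_fraction = unname(unk)
  )
  ord <- order(-out$target_active, -out$pca_outlier,
               -out$n_markers_owned, -out$unknown_fraction,
               out$isolate_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rationale <- vapply(seq_len(nrow(out)), function(i) {
    r <- out[i, ]
    paste0(
      if (r$target_active) paste0("active vs ", target_strain)
      else paste0("inactive vs ", target_strain, " (demoted)"),
      if (r$pca_outlier) "; chemically unique (T2 outlier)" else "",
      "; owns ", r$n_markers_owned, " discriminant marker(s)",
      "; unknown fraction ", sprintf("%.2f", r$unknown_fraction)
    )
  }, character(1))
  out
}

#' Assemble the prioritization report
#'
#' @param scores ranked isolates from [rank_isolates()].
#' @param markers discriminant-marker table (one row per selected
#'   feature: id, rt, neutral mass, formula, RDBE, database hits, owner,
#'   p-value); may be empty.
#' @param dir optional output directory; when given,
#'   `isolate_ranking.csv`, `discriminant_markers.csv` and a
#'   human-readable `summary.txt` are written there.
#' @return list with `ranking` and `markers` (invisibly when written).
#' @export
build_report <- function(scores, markers = NULL, dir = NULL) {
  if (is.null(markers)) {
    markers <- tibble::tibble(feature_id = character(), rt = numeric(),
                              neutral_mass = numeric(),
                              formula = character(), rdbe = numeric(),
                              hits = character(), owner = character(),
                              p_value = numeric())
  }
  rep <- list(ranking = scores, markers = markers)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(scores, file.path(dir, "isolate_ranking.csv"))
    readr::write_csv(markers, file.path(dir, "discriminant_markers.csv"))
    lines <- c(
      "Isolate prioritization summary",
      "==============================",
      "",
      sprintf("%2d. %-12s %s", scores$rank, scores$isolate_id,
              scores$rationale),
      "",
      sprintf("%d discriminant marker(s) tabulated.", nrow(markers))
    )
    writeLines(lines, file.path(dir, "summary.txt"))
    return(invisible(rep))
  }
  rep
}
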