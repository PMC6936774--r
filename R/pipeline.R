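#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' Runs the fixed stage order — generate/load, clean, annotate,
#' multivariate analysis, prioritize — under a single configuration with
#' one seed, writing per-stage artifacts, a stage log with feature counts
#' and a reproducibility manifest. Re-running with an identical
#' configuration reproduces every numeric artifact byte for byte.
NULL

#' Pipeline configuration
#'
#' All thresholds default to the screening campaign's anchor values:
#' blank removal above 1e4 counts, 20-fold medium rule, 5 ppm mass
#' tolerance, 12 mm activity cut-off, p <= 0.10 discriminant selection.
#'
#' @param synth a [synth_config()] to generate inputs, or `NULL` to read
#'   them from `data_dir`.
#' @param data_dir directory holding the [write_dataset()] file dialect.
#' @param out_dir artifact directory (`NULL` for in-memory only).
#' @param cleanup a [cleanup_config()].
#' @param tol_ppm annotation/dereplication mass tolerance (ppm).
#' @param elements an [element_spec()] for formula prediction of the
#'   selected discriminant features.
#' @param target_strain strain gating the supervised model and ranking.
#' @param n_ortho orthogonal OPLS-DA components.
#' @param p_threshold S-plot p-value cut-off for discriminant selection.
#' @param pca_components components for the PCA outlier scan (default 4,
#'   enough to resolve a handful of chemically distinct strains).
#' @param zone_threshold bioassay activity cut-off in mm.
#' @param drop_inactive_outliers remove target-inactive Hotelling
#'   outliers before fitting the OPLS-DA (default TRUE): their unique
#'   chemistry otherwise dominates the within-class variation.
#' @param seed integer seed for every stochastic step.
#' @export
pipeline_config <- function(synth = synth_config(),
                            data_dir = NULL,
                            out_dir = NULL,
                            cleanup = cleanup_config(),
                            tol_ppm = 5,
                            elements = element_spec(),
                            target_strain = "MRSA",
                            n_ortho = 1L,
                            p_threshold = 0.10,
                            pca_components = 4L,
                            zone_threshold = 12,
                            drop_inactive_outliers = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$synth)) cfg$synth$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

.grid_to_records <- function(grid) {
  long <- tidyr::pivot_longer(grid, -1, names_to = "strain",
                              values_to = "zone_mm")
  names(long)[1] <- "isolate_id"
  tibble::tibble(isolate_id = long$isolate_id, strain = long$strain,
                 zone_mm = as.numeric(long$zone_mm),
                 flag = NA_character_)
}

.stage_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "': ", msg, call. = FALSE)
}

#' Run the full screening pipeline
#'
#' @param cfg a [pipeline_config()].
#' @return list with every intermediate: `features` (neutral features),
#'   `hits`, `novelty`, `pca`, `outlier_isolates`, `oplsda`,
#'   `splot_stats`, `selected`, `ownership`, `ranking`, `markers`,
#'   `counts` (per-stage feature counts) and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  counts <- list()
  log_count <- function(stage, n) {
    counts[[stage]] <<- n
    message(sprintf("[%s] %d features", stage, n))
  }

  # ---- stage 1: inputs -------------------------------------------------
  if (!is.null(cfg$synth)) {
    ds <- generate_dataset(cfg$synth)
  } else {
    if (is.null(cfg$data_dir)) {
      .stage_fail("input", "neither synth config nor data_dir given")
    }
    f <- function(p) file.path(cfg$data_dir, p)
    if (!file.exists(f("sample_meta.csv"))) {
      .stage_fail("input", "sample_meta.csv not found")
    }
    meta <- read_sample_meta(f("sample_meta.csv"))
    ds <- list(
      meta = meta,
      pos = read_feature_table(f("pos_features.csv"), "positive", meta),
      neg = read_feature_table(f("neg_features.csv"), "negative", meta),
      bioassay = if (file.exists(f("bioassay.csv"))) {
        readr::read_csv(f("bioassay.csv"), show_col_types = FALSE)
      },
      compound_db = if (file.exists(f("compounds.csv"))) {
        read_compound_db(f("compounds.csv"))
      },
      truth = NULL)
  }
  log_count("input_pos", nrow(ds$pos))
  log_count("input_neg", nrow(ds$neg))

  # ---- stage 2: clean --------------------------------------------------
  clean_one <- function(tab) {
    tab <- subtract_blank(tab, cfg$cleanup)
    tab <- subtract_medium(tab, cfg$cleanup)
    collapse_ions(tab, cfg = cfg$cleanup)
  }
  pos <- clean_one(ds$pos)
  neg <- clean_one(ds$neg)
  log_count("clean_pos", nrow(pos))
  log_count("clean_neg", nrow(neg))
  features <- merge_modes(pos, neg, cfg$cleanup)
  log_count("merged", nrow(features))

  # ---- stage 3: annotate ----------------------------------------------
  if (is.null(ds$compound_db)) {
    .stage_fail("annotate", "compound database not available")
  }
  hits <- dereplicate(features, ds$compound_db, cfg$tol_ppm)
  novelty <- novelty_summary(features, hits)
  log_count("dereplicated", length(unique(hits$feature_row)))

  # ---- stage 4: multivariate analysis ---------------------------------
  X <- features_to_matrix(features)
  scaled <- pareto_scale(X)
  A <- min(cfg$pca_components, nrow(scaled$X) - 1, ncol(scaled$X))
  # strict = FALSE: the outlier scan needs the dominant subspace; strains
  # of near-identical chemical uniqueness create near-degenerate
  # eigenpairs whose exact axes are immaterial for T-squared
  pca <- pca_nipals(scaled, A, strict = FALSE)
  out_samples <- hotelling_outliers(pca, 0.05)
  meta <- attr(features, "meta")
  ext <- meta[meta$role == "extract", ]
  outlier_isolates <- ext$isolate_id[match(out_samples, ext$sample_id)]

  if (is.null(ds$bioassay)) {
    .stage_fail("prioritize", "bioassay table not available")
  }
  calls <- call_activity(.grid_to_records(ds$bioassay),
                         cfg$zone_threshold)
  tgt <- calls[calls$strain == cfg$target_strain, ]
  if (nrow(tgt) == 0) {
    .stage_fail("mva", paste0("no bioassay results for target strain '",
                              cfg$target_strain, "'"))
  }
  iso_of_row <- ext$isolate_id[match(rownames(scaled$X), ext$sample_id)]
  y <- ifelse(iso_of_row %in% tgt$isolate_id[tgt$active], 1, -1)
  keep <- rep(TRUE, length(y))
  if (cfg$drop_inactive_outliers) {
    keep <- !(iso_of_row %in% outlier_isolates & y == -1)
  }
  sub <- pareto_scale(X[keep, , drop = FALSE])
  model <- oplsda_fit(sub, y[keep], cfg$n_ortho)
  stats <- splot(model, sub)
  selected <- select_discriminating(
    stats, model, selection_config(cfg$p_threshold))
  log_count("discriminant", nrow(selected))

  # ---- stage 5: prioritize --------------------------------------------
  ownership <- if (nrow(selected) > 0) {
    assign_marker_ownership(selected$variable, features)
  } else {
    tibble::tibble(variable = character(), feature_row = integer(),
                   owner_isolate = character())
  }
  ranking <- rank_isolates(calls, outlier_isolates, novelty, ownership,
                           cfg$target_strain)
  markers <- NULL
  if (nrow(selected) > 0) {
    rows <- ownership$feature_row
    best_formula <- character(length(rows))
    best_rdbe <- rep(NA_real_, length(rows))
    for (i in seq_along(rows)) {
      cand <- enumerate_formulas(features$neutral_mass[rows[i]],
                                 cfg$tol_ppm, cfg$elements)
      if (nrow(cand) > 0) {
        best_formula[i] <- cand$formula[1]
        best_rdbe[i] <- cand$rdbe[1]
      } else {
        best_formula[i] <- "no prediction"
      }
    }
    hit_str <- vapply(rows, function(r) {
      h <- hits[hits$feature_row == r, ]
      if (nrow(h) == 0) return("no hits")
      paste(sprintf("%s@%.2fppm", h$name, h$ppm_error), collapse = ";")
    }, character(1))
    markers <- tibble::tibble(
      feature_id = selected$variable,
      rt = features$rt[rows],
      neutral_mass = features$neutral_mass[rows],
      formula = best_formula,
      rdbe = best_rdbe,
      hits = hit_str,
      owner = ownership$owner_isolate,
      p_value = selected$p_value)
  }
  report <- build_report(ranking, markers, dir = NULL)

  manifest <- list(
    package_version = as.character(utils::packageVersion("strainsift")),
    r_version = R.version.string,
    seed = cfg$seed,
    target_strain = cfg$target_strain,
    thresholds = list(blank = cfg$cleanup$blank_intensity_threshold,
                      medium_fold = cfg$cleanup$medium_fold,
                      ppm = cfg$cleanup$mz_ppm_tol,
                      zone_mm = cfg$zone_threshold,
                      p_threshold = cfg$p_threshold),
    counts = counts)

  result <- list(features = features, hits = hits, novelty = novelty,
                 pca = pca, outlier_isolates = outlier_isolates,
                 oplsda = model, splot_stats = stats,
                 selected = selected, ownership = ownership,
                 ranking = ranking, markers = report$markers,
                 calls = calls, counts = counts, manifest = manifest,
                 truth = ds$truth)

  if (!is.null(cfg$out_dir)) {
    d <- cfg$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    feat_out <- tibble::as_tibble(features)
    readr::write_csv(feat_out, file.path(d, "neutral_features.csv"))
    readr::write_csv(novelty, file.path(d, "novelty.csv"))
    readr::write_csv(hits, file.path(d, "dereplication.csv"))
    readr::write_csv(stats, file.path(d, "splot.csv"))
    readr::write_csv(tibble::tibble(isolate_id = outlier_isolates),
                     file.path(d, "pca_outliers.csv"))
    build_report(ranking, report$markers, dir = d)
    cfg_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
    writeLines(cfg_json, file.path(d, "manifest.json"))
    manifest$config_md5 <- unname(tools::md5sum(file.path(d,
                                                          "manifest.json")))
    result$manifest <- manifest
  }
  result
}
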