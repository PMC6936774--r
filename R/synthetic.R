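#' @title Synthetic LC-MS / NMR screening datasets with ground truth
#' @name synthetic-data
#' @description
#' Generates the full input suite the pipeline consumes — positive- and
#' negative-mode aligned feature tables with medium and blank columns,
#' sample metadata, a bioassay grid, a compound database and 1D 1H-NMR
#' spectra — with the statistical structure the analysis assumes, plus a
#' ground-truth record for every planted signal so recovery can be
#' measured. A fixed seed reproduces the dataset bit for bit.
NULL

# dereplication-anchor formulas used as planted discriminant markers; their
# monoisotopic masses double as regression anchors for the neutral-mass
# arithmetic downstream
.MARKER_FORMULAS <- c(
  "indole diketopiperazine"      = "C22H22N2O4",
  "triphenyl hydroxypiperidine"  = "C37H33N3O3",
  "deoxyguanosine congener"      = "C21H24N6O5",
  "oxoindoline benzofuran"       = "C17H11N3O4",
  "diazaspirodecenone"           = "C35H31N3O6",
  "benzimidazole dihydrazide"    = "C13H18N6O3",
  "nitrobiphenyl carboxamide"    = "C33H33N3O6",
  "aminoacetamido benzofuran"    = "C18H23N3O3",
  "talathermophilin E"           = "C18H21N3O2",
  "lankacyclinol"                = "C24H35NO5",
  "borrelidin"                   = "C28H43NO6",
  "lankacyclinol A"              = "C26H37NO6",
  "8,15-dideoxylankamycin"       = "C42H72O14",
  "antibiotic T 2636K"           = "C34H43NO12"
)

#' Configuration of the synthetic dataset
#'
#' Defaults emulate a 25-isolate actinomycete screening campaign profiled
#' at about 8,800 combined-mode features per extract over m/z 150-1500,
#' with log-normal peak intensities, medium- and blank-derived background,
#' adduct/isotope satellites, a handful of chemically distinct (outlier)
#' isolates and planted group-discriminant markers at the masses of known
#' dereplication anchors.
#'
#' @param n_isolates number of extract samples (default 25).
#' @param n_base_features target ion-feature count per ionization mode
#'   after background clean-up (default 4400, so combined about 8800).
#' @param n_medium_features culture-medium background features (removed by
#'   the 20-fold rule).
#' @param n_blank_features solvent-blank contaminants (blank intensity
#'   always above the 1e4 removal threshold).
#' @param n_markers planted discriminant features (default 12); masses are
#'   taken from the built-in dereplication-anchor formulas.
#' @param marker_effect_size marker boost in active-class isolates, in
#'   units of the within-feature log-intensity sd (default 3).
#' @param marker_owner_extra additional boost (same units) in the producing
#'   isolate so ownership is identifiable (default 4; producer strains
#'   dominate trace cross-occurrence by an order of magnitude).
#' @param adduct_probability,isotope_probability per-ion probability of an
#'   adduct/dimer or 13C satellite.
#' @param intensity_log_mu,intensity_log_sd natural-log parameters of the
#'   base feature intensities (default 11 and 1.5, heavy-tailed as typical
#'   for LC-MS peak heights, straddling the blank threshold).
#' @param within_sd within-feature between-isolate log-intensity sd.
#' @param detection_probability chance a compound ionizes in a given mode.
#' @param mz_noise_ppm mass-measurement noise (1 ppm, Orbitrap-like).
#' @param mz_range,rt_range instrument windows.
#' @param n_outliers chemically distinct isolates (default 4; the first
#'   two are target-active marker producers, the others are active only
#'   against the secondary strain).
#' @param n_outlier_features extra unique features per outlier isolate.
#' @param frac_known fraction of base compounds present in the emitted
#'   compound database.
#' @param n_active_target isolates active against the target strain.
#' @param target_strain,strains strain names for the bioassay grid.
#' @param seed integer seed fixing the whole dataset.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_isolates = 25,
                         n_base_features = 4400,
                         n_medium_features = 400,
                         n_blank_features = 150,
                         n_markers = 12,
                         marker_effect_size = 3,
                         marker_owner_extra = 4,
                         adduct_probability = 0.10,
                         isotope_probability = 0.15,
                         intensity_log_mu = 11,
                         intensity_log_sd = 1.5,
                         within_sd = 0.4,
                         detection_probability = 0.75,
                         mz_noise_ppm = 1,
                         mz_range = c(150, 1500),
                         rt_range = c(1, 35),
                         n_outliers = 4,
                         n_outlier_features = 250,
                         frac_known = 0.5,
                         n_active_target = 9,
                         target_strain = "MRSA",
                         strains = c("B.subtilis", "MRSA", "E.coli",
                                     "C.albicans"),
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_isolates >= 4, n_base_features > 0, n_markers >= 0,
            n_markers <= length(.MARKER_FORMULAS),
            n_outliers >= 2, n_outliers < n_isolates,
            n_active_target >= 2, n_active_target <= n_isolates,
            target_strain %in% strains)
  if (n_markers > n_base_features) {
    stop("infeasible config: more markers than features")
  }
  structure(cfg, class = "synth_config")
}

# deterministic isolate roles: outliers, marker owners, per-strain activity
.assign_roles <- function(cfg) {
  set.seed(cfg$seed)
  iso <- sprintf("iso%02d", seq_len(cfg$n_isolates))
  outliers <- sample(iso, cfg$n_outliers)
  owners <- outliers[1:2]              # target-active, chemically unique
  off_target <- outliers[3:min(4, cfg$n_outliers)] # secondary-strain only
  pool <- setdiff(iso, outliers)
  extra_active <- sample(pool, cfg$n_active_target - length(owners))
  target_active <- c(owners, extra_active)
  sec_pool <- setdiff(pool, extra_active)
  secondary_active <- c(off_target, owners,
                        sample(sec_pool, min(5, length(sec_pool))))
  strains <- cfg$strains
  secondary <- setdiff(strains, cfg$target_strain)[2] # third strain slot
  if (is.na(secondary)) secondary <- setdiff(strains, cfg$target_strain)[1]
  activity <- matrix(FALSE, cfg$n_isolates, length(strains),
                     dimnames = list(iso, strains))
  activity[, strains[1]] <- TRUE                 # broad first-strain hits
  activity[target_active, cfg$target_strain] <- TRUE
  activity[secondary_active, secondary] <- TRUE
  list(isolates = iso, outliers = outliers, owners = owners,
       target_active = target_active, activity = activity,
       secondary_strain = secondary)
}

.lorentz <- function(x, x0, gamma, height) {
  height * gamma^2 / ((x - x0)^2 + gamma^2)
}

#' Generate the full synthetic dataset
#'
#' @param cfg a [synth_config()].
#' @return list with `pos` and `neg` [feature_table()]s (extracts plus one
#'   medium and one blank column each), `meta`, `bioassay` (grid tibble of
#'   mm zones), `compound_db`, `nmr` (list of [spectrum_1d()]) and
#'   `truth`, a list recording planted marker masses/owners/known flags,
#'   outlier isolates, per-strain activity and the planted background
#'   feature ids.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  roles <- .assign_roles(cfg)
  set.seed(cfg$seed + 2L)
  iso <- roles$isolates
  n_iso <- cfg$n_isolates

  # n_base_features is the per-mode ion count surviving the full clean-up
  # (satellites collapsed away): size the compound pool so that detected
  # base ions per mode hit that target in expectation
  n_cmpd <- max(cfg$n_markers, round(
    cfg$n_base_features / cfg$detection_probability))
  n_noise <- n_cmpd - cfg$n_markers

  marker_formulas <- .MARKER_FORMULAS[seq_len(cfg$n_markers)]
  marker_mass <- vapply(marker_formulas, monoisotopic_mass, numeric(1))
  marker_owner <- rep(roles$owners, length.out = cfg$n_markers)
  marker_known <- rep(c(TRUE, FALSE), length.out = cfg$n_markers)

  m_lo <- cfg$mz_range[1] + 10
  m_hi <- cfg$mz_range[2] - 60
  cmpd <- tibble::tibble(
    neutral_mass = c(marker_mass, stats::runif(n_noise, m_lo, m_hi)),
    rt = stats::runif(n_cmpd, cfg$rt_range[1], cfg$rt_range[2]),
    kind = c(rep("marker", cfg$n_markers), rep("base", n_noise)),
    owner = c(marker_owner, rep(NA_character_, n_noise)),
    mu = stats::rnorm(n_cmpd, cfg$intensity_log_mu, cfg$intensity_log_sd)
  )

  # per-isolate log intensities: shared compound level + isolate noise,
  # markers boosted in the active group and further in the owner
  eps <- matrix(stats::rnorm(n_cmpd * n_iso, 0, cfg$within_sd),
                n_cmpd, n_iso, dimnames = list(NULL, iso))
  L <- cmpd$mu + eps
  is_marker <- cmpd$kind == "marker"
  L[is_marker, roles$target_active] <-
    L[is_marker, roles$target_active] +
    cfg$marker_effect_size * cfg$within_sd
  for (k in which(is_marker)) {
    L[k, cmpd$owner[k]] <- L[k, cmpd$owner[k]] +
      cfg$marker_owner_extra * cfg$within_sd
  }
  I_cmpd <- exp(L)

  # chemically unique features making the designated isolates outliers
  uniq <- NULL
  if (cfg$n_outliers > 0 && cfg$n_outlier_features > 0) {
    uniq <- tibble::tibble(
      neutral_mass = stats::runif(cfg$n_outliers * cfg$n_outlier_features,
                                  m_lo, m_hi),
      rt = stats::runif(cfg$n_outliers * cfg$n_outlier_features,
                        cfg$rt_range[1], cfg$rt_range[2]),
      kind = "unique",
      owner = rep(roles$outliers, each = cfg$n_outlier_features),
      mu = stats::rnorm(cfg$n_outliers * cfg$n_outlier_features, 12.5, 0.8)
    )
    I_uniq <- matrix(0, nrow(uniq), n_iso, dimnames = list(NULL, iso))
    for (i in seq_len(nrow(uniq))) {
      I_uniq[i, uniq$owner[i]] <- exp(uniq$mu[i])
    }
    cmpd <- dplyr::bind_rows(cmpd, uniq)
    I_cmpd <- rbind(I_cmpd, I_uniq)
  }
  n_all <- nrow(cmpd)

  rules <- default_adduct_rules()
  # markers are spiked observable metabolites: guarantee ionization in at
  # least one mode (background compounds may escape both by chance)
  det_pos <- stats::runif(n_all) < cfg$detection_probability
  det_neg <- stats::runif(n_all) < cfg$detection_probability
  mk <- which(cmpd$kind == "marker")
  neither <- mk[!det_pos[mk] & !det_neg[mk]]
  if (length(neither)) {
    to_pos <- neither[seq_along(neither) %% 2L == 1L]
    det_pos[to_pos] <- TRUE
    det_neg[setdiff(neither, to_pos)] <- TRUE
  }
  make_mode <- function(polarity, prefix) {
    base <- .base_rule(polarity, rules)
    sat_rules <- rules[rules$polarity == polarity & !rules$base, ,
                       drop = FALSE]
    detected <- if (polarity == "positive") det_pos else det_neg
    idx <- which(detected)
    resp <- stats::runif(length(idx), 0.2, 1)
    noise <- function(k) 1 + stats::rnorm(k, 0, cfg$mz_noise_ppm * 1e-6)
    mz <- (cmpd$neutral_mass[idx] * base$multiplicity + base$mass_shift) *
      noise(length(idx))
    rt <- cmpd$rt[idx] + stats::rnorm(length(idx), 0, 0.01)
    inten <- I_cmpd[idx, , drop = FALSE] * resp
    rows <- tibble::tibble(cmpd_row = idx, mz = mz, rt = rt,
                           satellite = "base")
    I_rows <- inten
    # 13C isotope satellites
    iso_sat <- stats::runif(length(idx)) < cfg$isotope_probability
    if (any(iso_sat)) {
      k <- which(iso_sat)
      frac <- stats::runif(length(k), 0.1, 0.5)
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        cmpd_row = idx[k],
        mz = (mz[k] + C13_C12_DELTA) * noise(length(k)),
        rt = rt[k], satellite = "isotope"))
      I_rows <- rbind(I_rows, inten[k, , drop = FALSE] * frac)
    }
    # adduct/dimer satellites
    add_sat <- stats::runif(length(idx)) < cfg$adduct_probability
    if (any(add_sat)) {
      k <- which(add_sat)
      rk <- sample(nrow(sat_rules), length(k), replace = TRUE)
      smz <- (cmpd$neutral_mass[idx[k]] * sat_rules$multiplicity[rk] +
                sat_rules$mass_shift[rk]) * noise(length(k))
      ok <- smz >= cfg$mz_range[1] & smz <= cfg$mz_range[2]
      if (any(ok)) {
        frac <- stats::runif(sum(ok), 0.1, 0.6)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          cmpd_row = idx[k][ok], mz = smz[ok], rt = rt[k][ok],
          satellite = sat_rules$label[rk][ok]))
        I_rows <- rbind(I_rows, inten[k, , drop = FALSE][ok, , drop = FALSE] *
                          frac)
      }
    }
    # medium background: strong in the medium, sub-fold in extracts
    med_mz <- stats::runif(cfg$n_medium_features, cfg$mz_range[1] + 5,
                           cfg$mz_range[2] - 5)
    med_rt <- stats::runif(cfg$n_medium_features, cfg$rt_range[1],
                           cfg$rt_range[2])
    med_int <- exp(stats::rnorm(cfg$n_medium_features, 11.5, 1))
    med_ext <- med_int * matrix(stats::runif(cfg$n_medium_features * n_iso,
                                             0, 3),
                                cfg$n_medium_features, n_iso)
    # blank contaminants: always above the removal threshold in the blank
    blk_mz <- stats::runif(cfg$n_blank_features, cfg$mz_range[1] + 5,
                           cfg$mz_range[2] - 5)
    blk_rt <- stats::runif(cfg$n_blank_features, cfg$rt_range[1],
                           cfg$rt_range[2])
    blk_int <- exp(stats::runif(cfg$n_blank_features, log(2e4), log(5e5)))
    blk_ext <- matrix(exp(stats::rnorm(cfg$n_blank_features * n_iso, 10, 1)),
                      cfg$n_blank_features, n_iso)

    n_sig <- nrow(rows)
    n_tot <- n_sig + cfg$n_medium_features + cfg$n_blank_features
    origin <- rep(c("signal", "medium", "blank"),
                  c(n_sig, cfg$n_medium_features, cfg$n_blank_features))
    tab <- tibble::tibble(
      feature_id = paste0(prefix, "_", sprintf("%05d", seq_len(n_tot))),
      mz = c(rows$mz, med_mz, blk_mz),
      rt = c(rows$rt, med_rt, blk_rt)
    )
    Iall <- rbind(I_rows, med_ext, blk_ext)
    colnames(Iall) <- iso
    for (s in iso) tab[[s]] <- Iall[, s]
    tab$medium <- c(rep(0, n_sig), med_int, rep(0, cfg$n_blank_features))
    tab$blank <- c(rep(0, n_sig + cfg$n_medium_features), blk_int)
    # clip stray ions that drifted outside the instrument window
    in_range <- tab$mz >= cfg$mz_range[1] & tab$mz <= cfg$mz_range[2]
    tab <- tab[in_range, , drop = FALSE]
    origin <- origin[in_range]
    list(table = tab,
         ids = split(tab$feature_id, origin))
  }

  pos_raw <- make_mode("positive", "P")
  neg_raw <- make_mode("negative", "N")

  meta <- validate_sample_meta(tibble::tibble(
    sample_id = c(iso, "medium", "blank"),
    role = c(rep("extract", n_iso), "medium", "blank"),
    isolate_id = c(iso, NA, NA)))

  pos <- feature_table(pos_raw$table, meta, "positive",
                       mz_range = cfg$mz_range)
  neg <- feature_table(neg_raw$table, meta, "negative",
                       mz_range = cfg$mz_range)

  # bioassay grid in mm: active zones 13-22, inactive 6-12 (cut-off 12)
  act <- roles$activity
  zones <- matrix(sample(6:12, length(act), replace = TRUE),
                  nrow(act), ncol(act), dimnames = dimnames(act))
  zones[act] <- sample(13:22, sum(act), replace = TRUE)
  bioassay <- tibble::as_tibble(cbind(
    tibble::tibble(isolate = rownames(zones)),
    tibble::as_tibble(as.data.frame(zones))))

  # compound database: known markers plus a fraction of the base compounds
  base_rows <- which(cmpd$kind == "base")
  n_known <- round(cfg$frac_known * length(base_rows))
  known_base <- sort(sample(base_rows, n_known))
  db <- dplyr::bind_rows(
    tibble::tibble(name = names(marker_formulas)[marker_known],
                   formula = unname(marker_formulas)[marker_known],
                   exact_mass = marker_mass[marker_known],
                   source = "planted marker", compound_class = "marker"),
    tibble::tibble(name = sprintf("db_compound_%04d",
                                  seq_along(known_base)),
                   formula = NA_character_,
                   exact_mass = cmpd$neutral_mass[known_base],
                   source = "synthetic library",
                   compound_class = "background"))

  truth <- list(
    markers = tibble::tibble(
      name = names(marker_formulas), formula = unname(marker_formulas),
      neutral_mass = unname(marker_mass),
      rt = cmpd$rt[seq_len(cfg$n_markers)],
      owner = marker_owner, known = marker_known),
    outliers = roles$outliers,
    owners = roles$owners,
    target_active = roles$target_active,
    activity = roles$activity,
    secondary_strain = roles$secondary_strain,
    base_masses = cmpd$neutral_mass[base_rows],
    unique_masses = cmpd$neutral_mass[cmpd$kind == "unique"],
    known_base_masses = cmpd$neutral_mass[known_base],
    background_ids = list(
      medium = c(pos_raw$ids$medium, neg_raw$ids$medium),
      blank = c(pos_raw$ids$blank, neg_raw$ids$blank))
  )

  nmr <- generate_nmr(cfg)

  list(pos = pos, neg = neg, meta = meta, bioassay = bioassay,
       compound_db = db, nmr = nmr, truth = truth, config = cfg)
}

#' Generate synthetic 1D 1H-NMR spectra
#'
#' One spectrum per isolate plus a medium control. Normal isolates carry
#' aliphatic (0.8-1.8 ppm) and aromatic (6-8 ppm) Lorentzian resonances;
#' chemically distinct (outlier) isolates are dominated by glycosidic /
#' acetylated signals in 2-5 ppm. Residual DMSO (2.50 ppm) and water
#' (3.33 ppm) solvent peaks are always present.
#'
#' @param cfg a [synth_config()].
#' @return named list of [spectrum_1d()] (isolates plus `"medium"`).
#' @export
generate_nmr <- function(cfg = synth_config()) {
  roles <- .assign_roles(cfg)
  set.seed(cfg$seed + 1L)
  ppm <- seq(0.3, 12.7, by = 0.002)
  peak_set <- function(centers_lo, centers_hi, n, h_lo, h_hi) {
    tibble::tibble(x0 = stats::runif(n, centers_lo, centers_hi),
                   gamma = stats::runif(n, 0.004, 0.010),
                   h = stats::runif(n, h_lo, h_hi))
  }
  render <- function(peaks) {
    y <- numeric(length(ppm))
    for (i in seq_len(nrow(peaks))) {
      y <- y + .lorentz(ppm, peaks$x0[i], peaks$gamma[i], peaks$h[i])
    }
    y
  }
  solvent <- tibble::tibble(x0 = c(2.50, 3.33),
                            gamma = c(0.012, 0.015), h = c(60, 40))
  medium_peaks <- peak_set(6, 8, 6, 1, 4)
  spectra <- list()
  for (s in roles$isolates) {
    if (s %in% roles$outliers) {
      pk <- dplyr::bind_rows(
        peak_set(3.0, 5.0, 14, 6, 14),   # dominant glycosidic band
        peak_set(2.0, 3.0, 4, 2, 5),
        peak_set(0.8, 1.8, 2, 0.5, 1.5),
        peak_set(6.0, 8.0, 2, 0.5, 1.5))
    } else {
      pk <- dplyr::bind_rows(
        peak_set(0.8, 1.8, 8, 3, 8),     # saturated fatty-acid band
        peak_set(6.0, 8.0, 5, 1, 4),
        peak_set(3.0, 5.0, 2, 0.3, 1.2))
    }
    y <- render(dplyr::bind_rows(pk, medium_peaks, solvent)) +
      abs(stats::rnorm(length(ppm), 0, 0.01))
    spectra[[s]] <- spectrum_1d(s, ppm, y)
  }
  spectra[["medium"]] <- spectrum_1d(
    "medium", ppm, render(dplyr::bind_rows(medium_peaks, solvent)) +
      abs(stats::rnorm(length(ppm), 0, 0.01)))
  spectra
}

#' Write a generated dataset to a directory as delimited text
#'
#' Emits exactly the file dialects the readers consume:
#' `pos_features.csv`, `neg_features.csv`, `sample_meta.csv`,
#' `bioassay.csv`, `compounds.csv` and one `nmr_<sample>.csv` per
#' spectrum.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(ds$pos, file.path(dir, "pos_features.csv"))
  write_feature_table(ds$neg, file.path(dir, "neg_features.csv"))
  readr::write_csv(ds$meta, file.path(dir, "sample_meta.csv"))
  readr::write_csv(ds$bioassay, file.path(dir, "bioassay.csv"))
  db <- ds$compound_db
  names(db)[names(db) == "compound_class"] <- "class"
  readr::write_csv(db, file.path(dir, "compounds.csv"))
  for (s in names(ds$nmr)) {
    sp <- ds$nmr[[s]]
    readr::write_csv(tibble::tibble(ppm = sp$ppm,
                                    intensity = sp$intensity),
                     file.path(dir, paste0("nmr_", s, ".csv")))
  }
  invisible(dir)
}

#' Score a pipeline run against the generator's ground truth
#'
#' Convenience for recovery studies on synthetic data: how many planted
#' markers were selected as discriminant (within `ppm_tol` of the planted
#' neutral mass), how many selections were false positives, whether the
#' planted blank contaminants survived clean-up, whether the designated
#' outlier isolates were flagged, and how often marker ownership was
#' attributed to the true producer.
#'
#' @param result a [run_pipeline()] result whose dataset came from
#'   [generate_dataset()] (so `result$truth` is populated).
#' @param ppm_tol mass tolerance for matching selections to planted
#'   markers (default 10 ppm, twice the merge tolerance).
#' @return list of scalar metrics.
#' @export
evaluate_recovery <- function(result, ppm_tol = 10) {
  if (is.null(result$truth)) stop("result carries no ground truth")
  tm <- result$truth$markers
  feats <- result$features
  labels <- sprintf("%.4f@%.2f", feats$neutral_mass, feats$rt)
  sel_rows <- match(result$selected$variable, labels)
  sel_mass <- feats$neutral_mass[sel_rows]

  near_marker <- function(m) abs(sel_mass - m) / m * 1e6 < ppm_tol
  recovered <- vapply(tm$neutral_mass,
                      function(m) any(near_marker(m)), logical(1))

  # ownership: best-matching selected feature per recovered marker
  owner_ok <- logical(0)
  if (any(recovered)) {
    owner_ok <- vapply(which(recovered), function(i) {
      d <- abs(sel_mass - tm$neutral_mass[i]) / tm$neutral_mass[i] * 1e6
      k <- which.min(d)
      result$ownership$owner_isolate[k] == tm$owner[i]
    }, logical(1))
  }

  # false positives among non-marker variables
  is_marker_sel <- vapply(sel_mass, function(m) {
    any(abs(tm$neutral_mass - m) / m * 1e6 < ppm_tol)
  }, logical(1))
  n_marker_vars <- sum(vapply(feats$neutral_mass, function(m) {
    any(abs(tm$neutral_mass - m) / m * 1e6 < ppm_tol)
  }, logical(1)))
  n_noise_vars <- nrow(feats) - n_marker_vars

  blank_ids <- result$truth$background_ids$blank
  blank_left <- if (length(blank_ids)) {
    prov <- paste(feats$provenance, collapse = ";")
    sum(vapply(paste0(blank_ids, ":"), grepl, logical(1), x = prov,
               fixed = TRUE))
  } else 0

  list(
    n_markers = nrow(tm),
    n_recovered = sum(recovered),
    recovery = mean(recovered),
    owner_attribution = if (length(owner_ok)) mean(owner_ok) else NA_real_,
    n_selected = length(sel_mass),
    false_positive_rate = sum(!is_marker_sel) / max(n_noise_vars, 1),
    blank_features_left = blank_left,
    outliers_all_flagged = all(result$truth$outliers %in%
                                 result$outlier_isolates),
    outliers_exact = setequal(result$truth$outliers,
                              result$outlier_isolates)
  )
}
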