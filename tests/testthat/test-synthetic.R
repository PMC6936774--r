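test_that("the same seed reproduces the dataset bit for bit", {
  d1 <- generate_dataset(small_synth(seed = 5))
  d2 <- generate_dataset(small_synth(seed = 5))
  expect_identical(tibble::as_tibble(d1$pos), tibble::as_tibble(d2$pos))
  expect_identical(tibble::as_tibble(d1$neg), tibble::as_tibble(d2$neg))
  expect_identical(d1$bioassay, d2$bioassay)
  expect_identical(d1$truth$markers, d2$truth$markers)
  d3 <- generate_dataset(small_synth(seed = 6))
  expect_false(identical(tibble::as_tibble(d1$pos),
                         tibble::as_tibble(d3$pos)))
})

test_that("clean-up removes all blank and nearly all medium background", {
  ds <- generate_dataset(small_synth(seed = 9))
  cfg <- cleanup_config()
  for (mode in c("pos", "neg")) {
    cleaned <- subtract_medium(subtract_blank(ds[[mode]], cfg), cfg)
    blank_ids <- intersect(ds$truth$background_ids$blank,
                           cleaned$feature_id)
    expect_length(blank_ids, 0)    # 100% of blank contaminants removed
    med_ids <- intersect(ds$truth$background_ids$medium,
                         cleaned$feature_id)
    n_med_planted <- sum(startsWith(
      ds$truth$background_ids$medium,
      if (mode == "pos") "P" else "N"))
    expect_lte(length(med_ids), 0.05 * n_med_planted)
  }
})

test_that("collapse and merge recover planted neutral masses", {
  ds <- generate_dataset(small_synth(seed = 13))
  cfg <- cleanup_config()
  clean <- function(t) collapse_ions(subtract_medium(
    subtract_blank(t, cfg), cfg), cfg = cfg)
  merged <- merge_modes(clean(ds$pos), clean(ds$neg), cfg)
  planted <- c(ds$truth$base_masses, ds$truth$unique_masses,
               ds$truth$markers$neutral_mass)
  # detection: a planted compound that ionized in either mode must come
  # back as a neutral feature within 5 ppm
  hit <- vapply(planted, function(m) {
    any(abs(merged$neutral_mass - m) / m * 1e6 < 5)
  }, logical(1))
  expect_gte(mean(hit), 0.90)  # some compounds ionize in neither mode
  # ...and among both-mode features, >= 95% sit on a planted mass: no
  # spurious merges between compounds more than 20 ppm apart
  both <- merged$neutral_mass[merged$modes_seen == "both"]
  near <- vapply(both, function(m) {
    min(abs(planted - m) / m * 1e6) < 5
  }, logical(1))
  expect_gte(mean(near), 0.95)
})

test_that("known/unknown fractions propagate to the novelty summary", {
  ds <- generate_dataset(small_synth(seed = 17))
  cfg <- cleanup_config()
  clean <- function(t) collapse_ions(subtract_medium(
    subtract_blank(t, cfg), cfg), cfg = cfg)
  merged <- merge_modes(clean(ds$pos), clean(ds$neg), cfg)
  hits <- dereplicate(merged, ds$compound_db)
  nov <- novelty_summary(merged, hits)
  # planted: half the base compounds in the database -> binomial 95% CI
  n <- mean(nov$n_features)
  expect_lt(abs(mean(nov$unknown_fraction) - 0.5),
            2 * sqrt(0.25 / n) + 0.02)
})

test_that("a planted marker with a database entry dereplicates cleanly", {
  ds <- generate_dataset(small_synth(seed = 19))
  known <- ds$truth$markers[ds$truth$markers$known, ]
  hits <- dereplicate(known$neutral_mass, ds$compound_db)
  expect_true(all(known$name %in% hits$name))
  expect_true(all(abs(hits$ppm_error[hits$name %in% known$name]) < 1))
})

test_that("bioassay zones encode the planted activity truth", {
  ds <- generate_dataset(small_synth(seed = 23))
  calls <- call_activity(strainsift:::.grid_to_records(ds$bioassay))
  tgt <- calls[calls$strain == ds$config$target_strain, ]
  expect_setequal(tgt$isolate_id[tgt$active], ds$truth$target_active)
  expect_equal(sum(tgt$active), ds$config$n_active_target)
})

test_that("synthetic NMR spectra have the designed band structure", {
  cfg <- small_synth(seed = 29)
  sp <- generate_nmr(cfg)
  sp2 <- generate_nmr(cfg)
  expect_identical(sp, sp2)           # seeded determinism
  roles <- strainsift:::.assign_roles(cfg)
  # every spectrum carries a DMSO resonance inside 2.40-2.60 ppm
  for (s in names(sp)) {
    seg <- sp[[s]]$intensity[sp[[s]]$ppm > 2.40 & sp[[s]]$ppm < 2.60]
    base <- stats::median(sp[[s]]$intensity)
    expect_gt(max(seg), 10 * base)
  }
  # outlier-group spectra are dominated by the 2-5 ppm glycosidic band
  bt <- bucket_spectra(unname(sp))
  for (s in roles$outliers) {
    v <- bt$intensities[s, ]
    frac <- sum(v[bt$centers >= 2 & bt$centers <= 5]) / sum(v)
    expect_gte(frac, 0.60)
  }
})

test_that("the default campaign yields about 8,800 features per extract", {
  ds <- generate_dataset(synth_config(seed = 1))
  cfg <- cleanup_config()
  clean <- function(t) collapse_ions(subtract_medium(
    subtract_blank(t, cfg), cfg), cfg = cfg)
  merged <- merge_modes(clean(ds$pos), clean(ds$neg), cfg)
  meta <- attr(merged, "meta")
  ext <- meta$sample_id[meta$role == "extract"]
  ion_mult <- 1 + (merged$modes_seen == "both")
  per_extract <- vapply(ext, function(sc) {
    sum(ion_mult[merged[[sc]] > 0])
  }, numeric(1))
  expect_true(all(abs(per_extract - 8800) / 8800 < 0.10))
})
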