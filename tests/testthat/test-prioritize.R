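test_that("activity calls follow the strict 12 mm rule", {
  rec <- tibble::tibble(
    isolate_id = c("i13", "i9", "i22", "iF"),
    strain = "MRSA",
    zone_mm = c(19, 12, 13, NA),
    flag = c(NA, NA, NA, "active"))
  calls <- call_activity(rec)
  expect_equal(calls$active, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("marker ownership is the intensity argmax with a stable tie rule", {
  feats <- structure(
    tibble::tibble(neutral_mass = c(378.158, 489.309), rt = c(10, 19),
                   modes_seen = "both", provenance = "x",
                   isoA = c(5e6, 2e5), isoB = c(1e5, 2e5)),
    meta = tiny_meta(),
    class = c("neutral_features", class(tibble::tibble())))
  own <- assign_marker_ownership(1L, feats)
  expect_equal(own$owner_isolate, "isoA")
  expect_warning(own2 <- assign_marker_ownership(2L, feats), "tie")
  expect_equal(own2$owner_isolate, "isoA")  # lexicographically first
  # name-based selection resolves through the mass@rt convention
  own3 <- assign_marker_ownership("378.1580@10.00", feats)
  expect_equal(own3$feature_row, 1L)
  expect_error(assign_marker_ownership("999.0000@1.00", feats),
               "not found")
})

test_that("ranking reproduces the published prioritization outcome", {
  # the campaign situation: 13 and 22 active vs the target and outlying;
  # 3 and 6 outlying but target-inactive; the rest active vs the first
  # strain only
  rec <- read_bioassay_table(extdata("actinomycete_screen.csv"))
  calls <- call_activity(rec)
  outliers <- c("MS.REE.3", "MS.REE.6", "MS.REE.13", "MS.REE.22")
  novelty <- tibble::tibble(
    isolate_id = c("MS.REE.13", "MS.REE.22"),
    n_features = c(8885L, 8831L), n_known = c(4265L, 4151L),
    n_unknown = c(4620L, 4680L),
    unknown_fraction = c(0.52, 0.53))
  ownership <- tibble::tibble(
    variable = paste0("m", 1:12), feature_row = 1:12,
    owner_isolate = rep(c("MS.REE.13", "MS.REE.22"), 6))
  rk <- rank_isolates(calls, outliers, novelty, ownership, "MRSA")
  expect_setequal(rk$isolate_id[1:2], c("MS.REE.13", "MS.REE.22"))
  # target-inactive outliers are demoted below every target-active isolate
  active_ranks <- rk$rank[rk$target_active]
  expect_true(all(rk$rank[rk$isolate_id %in% c("MS.REE.3", "MS.REE.6")] >
                    max(active_ranks)))
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))  # total order
})

test_that("ranking is invariant to input row order", {
  rec <- read_bioassay_table(extdata("actinomycete_screen.csv"))
  calls <- call_activity(rec)
  novelty <- tibble::tibble(isolate_id = "MS.REE.13", n_features = 10L,
                            n_known = 5L, n_unknown = 5L,
                            unknown_fraction = 0.5)
  ownership <- tibble::tibble(variable = "m1", feature_row = 1L,
                              owner_isolate = "MS.REE.22")
  r1 <- rank_isolates(calls, c("MS.REE.13"), novelty, ownership, "MRSA")
  set.seed(3)
  r2 <- rank_isolates(calls[sample(nrow(calls)), ], c("MS.REE.13"),
                      novelty, ownership, "MRSA")
  expect_equal(r1$isolate_id, r2$isolate_id)
  expect_error(rank_isolates(calls[0, ], character(0), novelty,
                             ownership, "MRSA"), "empty")
  expect_error(rank_isolates(calls, character(0), novelty, ownership,
                             "no-such-strain"), "target strain")
})

test_that("single-isolate and degenerate inputs still rank", {
  calls <- tibble::tibble(isolate_id = "only", strain = "MRSA",
                          zone_mm = 15, active = TRUE)
  rk <- rank_isolates(calls, character(0), NULL,
                      tibble::tibble(variable = character(),
                                     feature_row = integer(),
                                     owner_isolate = character()),
                      "MRSA")
  expect_equal(rk$rank, 1L)
})

test_that("reports carry ranking plus a possibly-empty marker table", {
  calls <- tibble::tibble(isolate_id = c("a", "b"), strain = "MRSA",
                          zone_mm = c(15, 8), active = c(TRUE, FALSE))
  rk <- rank_isolates(calls, character(0), NULL,
                      tibble::tibble(variable = character(),
                                     feature_row = integer(),
                                     owner_isolate = character()),
                      "MRSA")
  d <- withr::local_tempdir()
  rep <- build_report(rk, NULL, dir = d)
  expect_true(file.exists(file.path(d, "isolate_ranking.csv")))
  expect_true(file.exists(file.path(d, "discriminant_markers.csv")))
  expect_true(file.exists(file.path(d, "summary.txt")))
  expect_equal(nrow(rep$markers), 0)
})
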