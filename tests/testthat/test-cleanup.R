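test_that("blank subtraction removes whole features above the threshold", {
  tab <- tiny_table(blank = c(2e4, 9e3, 0))
  out <- subtract_blank(tab, cleanup_config())
  expect_equal(out$feature_id, c("P2", "P3")) # 2e4 gone; 9e3 and 0 stay
  expect_false("blank" %in% names(out))       # blank column dropped
  expect_error(subtract_blank(tiny_table(), cleanup_config()) |>
                 subtract_blank(), "stage")
  no_blank <- feature_table(
    tibble::tibble(feature_id = "P1", mz = 200, rt = 1, isoA = 1),
    sample_meta("isoA", "extract", "isoA"), "positive")
  expect_error(subtract_blank(no_blank), "allow_missing")
  expect_silent(subtract_blank(no_blank, allow_missing = TRUE))
})

test_that("medium subtraction applies the 20-fold rule", {
  tab <- tiny_table(isoA = c(2.1e6, 1.9e6, 5e4),
                    isoB = c(1.0e5, 1.5e6, 0),
                    medium = c(1.0e5, 1.0e5, 0),
                    blank = c(0, 0, 0))
  out <- subtract_medium(subtract_blank(tab), cleanup_config())
  # ratio 21 >= 20 kept; ratio 19 dropped; medium 0 with signal kept
  expect_equal(out$feature_id, c("P1", "P3"))
  expect_false("medium" %in% names(out))
  # sub-fold residual signal in kept features is zeroed per sample
  expect_equal(out$isoB[out$feature_id == "P1"], 0)
  expect_equal(out$isoA[out$feature_id == "P1"], 2.1e6)
})

test_that("background subtraction is a monotone filter", {
  set.seed(11)
  n <- 60
  tab <- tiny_table(mz = runif(n, 150, 1500), rt = runif(n, 1, 35),
                    isoA = rlnorm(n, 11, 1.5), isoB = rlnorm(n, 11, 1.5),
                    medium = rlnorm(n, 9, 2) * rbinom(n, 1, 0.5),
                    blank = rlnorm(n, 9, 2) * rbinom(n, 1, 0.3))
  s1 <- subtract_blank(tab)
  s2 <- subtract_medium(s1)
  for (step in list(list(tab, s1), list(s1, s2))) {
    before <- step[[1]]; after <- step[[2]]
    expect_lte(nrow(after), nrow(before))
    expect_true(all(after$feature_id %in% before$feature_id))
    idx <- match(after$feature_id, before$feature_id)
    for (s in intersect(sample_ids(after), sample_ids(before))) {
      expect_true(all(after[[s]] <= before[[s]][idx] + 1e-9))
    }
  }
})

test_that("the clean-up stage order is enforced", {
  tab <- tiny_table()
  expect_error(subtract_medium(tab), "blank")
  expect_error(collapse_ions(tab), "stage")
  expect_error(merge_modes(at_stage(tab, "collapsed"),
                           tiny_table(polarity = "negative")),
               "stage")
})

test_that("neutral-mass conversion matches the printed adduct table", {
  expect_equal(round(to_neutral_mass(379.165, "positive"), 3), 378.158)
  expect_equal(round(to_neutral_mass(566.245, "negative"), 3), 567.252)
  expect_equal(round(to_neutral_mass(490.316, "positive"), 3), 489.309)
  # general rule: sodiated dimer-free conversion
  rules <- default_adduct_rules()
  na_rule <- rules[rules$label == "sodiated", ]
  expect_equal(to_neutral_mass(401.1472, rule = na_rule),
               401.1472 - 22.989218)
  dimer <- rules[rules$label == "dimer_protonated", ]
  expect_equal(to_neutral_mass(757.3233, rule = dimer),
               (757.3233 - 1.007276) / 2)
})

test_that("ion collapse removes isotope and adduct satellites", {
  # 13C satellite: +1.0034 Da at lower intensity, same RT
  tab <- tiny_table(mz = c(379.1653, 380.1687, 450.3),
                    rt = c(10.66, 10.66, 10.66),
                    isoA = c(1e6, 2.3e5, 5e5), isoB = c(0, 0, 0),
                    medium = c(0, 0, 0), blank = c(0, 0, 0))
  out <- collapse_ions(at_stage(tab, "medium_subtracted"))
  expect_equal(out$feature_id, c("P1", "P3"))
  log <- attr(out, "collapse_log")
  expect_equal(log$explained_as, "isotope_13C")
  expect_equal(log$base_feature_id, "P1")

  # sodiated satellite: shift from the protonated ion derived brute force
  # from the rule table (22.989218 - 1.007276)
  shift <- 22.989218 - 1.007276
  expect_equal(round(shift, 4), 21.9819)
  tab2 <- tiny_table(mz = c(379.1653, 379.1653 + shift),
                     rt = c(10.66, 10.66),
                     isoA = c(1e6, 2e5), isoB = c(0, 0),
                     medium = c(0, 0), blank = c(0, 0))
  out2 <- collapse_ions(at_stage(tab2, "medium_subtracted"))
  expect_equal(out2$feature_id, "P1")
  expect_equal(attr(out2, "collapse_log")$explained_as, "sodiated")

  # unrelated ions 50 ppm apart both survive
  tab3 <- tiny_table(mz = c(500.0, 500.0 * (1 + 50e-6)),
                     rt = c(5, 5), isoA = c(1e6, 9e5), isoB = c(0, 0),
                     medium = c(0, 0), blank = c(0, 0))
  out3 <- collapse_ions(at_stage(tab3, "medium_subtracted"))
  expect_equal(nrow(out3), 2)
})

test_that("mode merging overlays matching neutral masses", {
  pos <- at_stage(tiny_table(mz = c(379.1653, 431.2),
                             rt = c(10.66, 15),
                             isoA = c(1e6, 4e5), isoB = c(2e5, 0),
                             medium = c(0, 0), blank = c(0, 0)),
                  "collapsed")
  neg <- at_stage(tiny_table(polarity = "negative",
                             mz = c(377.1507, 610.4),
                             rt = c(10.66, 22),
                             isoA = c(8e5, 1e5), isoB = c(3e5, 2e5),
                             medium = c(0, 0), blank = c(0, 0),
                             ids = c("N1", "N2")),
                  "collapsed")
  merged <- merge_modes(pos, neg, cleanup_config())
  expect_equal(nrow(merged), 2 + 2 - 1)  # |pos| + |neg| - matched pairs
  both <- merged[merged$modes_seen == "both", ]
  expect_equal(nrow(both), 1)
  expect_equal(both$neutral_mass, 378.158, tolerance = 1e-3)
  # overlaid intensity is the per-sample maximum, not the sum
  expect_equal(both$isoA, 1e6)
  expect_equal(both$isoB, 3e5)
  expect_match(both$provenance, "P1.*N1")
  expect_setequal(merged$modes_seen[merged$modes_seen != "both"],
                  c("positive", "negative"))

  # symmetry up to provenance ordering and row order
  swapped <- merge_modes(neg, pos, cleanup_config())
  expect_equal(swapped$neutral_mass, merged$neutral_mass)
  expect_equal(swapped$isoA, merged$isoA)

  # far-apart ions stay single-mode
  neg40 <- at_stage(tiny_table(polarity = "negative",
                               mz = 377.1507 * (1 + 40e-6), rt = 10.66,
                               isoA = 1, isoB = 1, medium = 0, blank = 0,
                               ids = "N9"),
                    "collapsed")
  m2 <- merge_modes(pos, neg40, cleanup_config())
  expect_true(all(m2$modes_seen != "both"))

  # shared ids across modes are rejected
  neg_dup <- at_stage(tiny_table(polarity = "negative", mz = 377.15,
                                 rt = 1, isoA = 1, isoB = 1, medium = 0,
                                 blank = 0, ids = "P1"), "collapsed")
  expect_error(merge_modes(pos, neg_dup), "share")
})
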