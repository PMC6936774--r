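#' @title Background subtraction, ion-species collapse and mode merging
#' @name cleanup-merge
#' @description
#' Reproduces the data clean-up applied to aligned LC-HRMS exports before
#' multivariate analysis: (1) removal of every feature detected in the
#' solvent blank above an intensity threshold, (2) removal of culture-medium
#' background by a fold-change rule, (3) collapse of isotope satellites and
#' adduct/dimer ions onto their base ion, and (4) merging of the positive-
#' and negative-mode tables on neutral monoisotopic mass. The stages must run
#' in that order; each stage stamps the table so re-ordering is rejected.
NULL

C13_C12_DELTA <- 1.003355 # Da, 13C - 12C isotope spacing

#' Clean-up configuration
#'
#' @param blank_intensity_threshold features whose solvent-blank intensity
#'   exceeds this are removed entirely (intensity units; default 1e4).
#' @param medium_fold a feature survives medium subtraction only if some
#'   extract shows at least this fold-change over the medium (default 20).
#' @param mz_ppm_tol mass tolerance in ppm for satellite matching and
#'   mode merging (default 5).
#' @param rt_tol retention-time tolerance in minutes (default 0.1).
#' @return A list of class `cleanup_config`.
#' @export
cleanup_config <- function(blank_intensity_threshold = 1e4,
                           medium_fold = 20,
                           mz_ppm_tol = 5,
                           rt_tol = 0.1) {
  stopifnot(blank_intensity_threshold > 0, medium_fold > 0,
            mz_ppm_tol > 0, rt_tol > 0)
  structure(list(blank_intensity_threshold = blank_intensity_threshold,
                 medium_fold = medium_fold,
                 mz_ppm_tol = mz_ppm_tol,
                 rt_tol = rt_tol),
            class = "cleanup_config")
}

#' Default adduct/ion-species rules
#'
#' Each rule maps a neutral molecule M to an observed ion:
#' `mz = (multiplicity * M + mass_shift) / 1` under the singly-charged
#' assumption. The `base` rules (`[M+H]+`, `[M-H]-`) define the neutral
#' mass of a feature; the others describe satellites eliminated during
#' ion collapse. The table is editable: pass your own to [collapse_ions()].
#'
#' @return tibble with `label`, `polarity`, `mass_shift`, `multiplicity`,
#'   `base`.
#' @export
default_adduct_rules <- function() {
  tibble::tribble(
    ~label,               ~polarity,  ~mass_shift, ~multiplicity, ~base,
    "protonated",         "positive",  1.007276,   1L,            TRUE,
    "sodiated",           "positive",  22.989218,  1L,            FALSE,
    "ammoniated",         "positive",  18.033823,  1L,            FALSE,
    "dimer_protonated",   "positive",  1.007276,   2L,            FALSE,
    "deprotonated",       "negative", -1.007276,   1L,            TRUE,
    "chloride",           "negative",  34.969402,  1L,            FALSE,
    "dimer_deprotonated", "negative", -1.007276,   2L,            FALSE
  )
}

.base_rule <- function(polarity, rules = default_adduct_rules()) {
  r <- rules[rules$polarity == polarity & rules$base, , drop = FALSE]
  if (nrow(r) != 1) stop("need exactly one base rule for ", polarity)
  r
}

#' Convert an ion m/z to a neutral monoisotopic mass
#'
#' Protonated ions give `mz - 1.007276`, deprotonated `mz + 1.007276`;
#' a general rule gives `(mz - mass_shift) / multiplicity` (singly charged).
#'
#' @param mz ion m/z (Da/charge).
#' @param polarity ionization mode, used to pick the base rule when `rule`
#'   is not given.
#' @param rule a one-row rule (see [default_adduct_rules()]) or a rule label.
#' @param rules rule table to look labels up in.
#' @return Neutral mass in Da.
#' @examples
#' to_neutral_mass(379.165, "positive") # 378.158
#' @export
to_neutral_mass <- function(mz, polarity = c("positive", "negative"),
                            rule = NULL, rules = default_adduct_rules()) {
  stopifnot(all(mz > 0))
  if (is.null(rule)) {
    polarity <- match.arg(polarity)
    rule <- .base_rule(polarity, rules)
  } else if (is.character(rule)) {
    rule <- rules[rules$label == rule, , drop = FALSE]
    if (nrow(rule) != 1) stop("unknown adduct rule label")
  }
  (mz - rule$mass_shift) / rule$multiplicity
}

.stage <- function(table) {
  s <- attr(table, "cleanup_stage")
  if (is.null(s)) "raw" else s
}

.set_stage <- function(table, stage) {
  attr(table, "cleanup_stage") <- stage
  table
}

.require_stage <- function(table, expected, op, check = TRUE) {
  if (check && !identical(.stage(table), expected)) {
    stop(op, " must run on a table at stage '", expected,
         "' (got '", .stage(table),
         "'); the clean-up order is blank -> medium -> collapse -> merge")
  }
}

.cols_by_role <- function(table, role) {
  meta <- table_meta(table)
  intersect(meta$sample_id[meta$role == role], sample_ids(table))
}

# per-feature aggregate over possibly several background columns
# (conservative: maximum)
.role_intensity <- function(table, cols) {
  if (length(cols) == 0) return(rep(0, nrow(table)))
  if (length(cols) == 1) return(table[[cols]])
  do.call(pmax, lapply(cols, function(cc) table[[cc]]))
}

.drop_samples <- function(table, cols) {
  meta <- table_meta(table)
  meta <- meta[!meta$sample_id %in% cols, , drop = FALSE]
  out <- table[, setdiff(names(table), cols), drop = FALSE]
  attr(out, "meta") <- meta
  attr(out, "polarity") <- table_polarity(table)
  class(out) <- class(table)
  out
}

#' Remove solvent-blank background features
#'
#' Every feature whose blank intensity exceeds
#' `cfg$blank_intensity_threshold` is removed entirely (whole-feature
#' removal, not intensity arithmetic). Multiple blank columns are aggregated
#' by per-feature maximum. The blank column(s) are dropped from the output.
#'
#' @param table a raw `feature_table` containing a blank-role sample.
#' @param cfg a [cleanup_config()].
#' @param allow_missing proceed as a no-op stage when no blank is present.
#' @return Filtered `feature_table` at stage `"blank_subtracted"`.
#' @export
subtract_blank <- function(table, cfg = cleanup_config(),
                           allow_missing = FALSE) {
  .require_stage(table, "raw", "subtract_blank")
  blanks <- .cols_by_role(table, "blank")
  if (length(blanks) == 0) {
    if (!allow_missing) stop("no blank-role sample in table; set ",
                             "allow_missing = TRUE to skip blank subtraction")
    return(.set_stage(table, "blank_subtracted"))
  }
  keep <- .role_intensity(table, blanks) <= cfg$blank_intensity_threshold
  out <- .drop_samples(table[keep, , drop = FALSE], blanks)
  .set_stage(out, "blank_subtracted")
}

#' Remove culture-medium background features
#'
#' A feature is retained iff the maximum over extract samples of
#' intensity / medium-intensity reaches `cfg$medium_fold`. A feature absent
#' from the medium (intensity 0) is retained whenever any extract shows
#' signal. In retained features, individual extract intensities below
#' `medium * medium_fold` are zeroed so that sub-fold residual signal does
#' not leak into the statistics. Medium column(s) are dropped.
#'
#' @inheritParams subtract_blank
#' @param allow_missing proceed as a no-op stage when no medium is present.
#' @return Filtered `feature_table` at stage `"medium_subtracted"`.
#' @export
subtract_medium <- function(table, cfg = cleanup_config(),
                            allow_missing = FALSE) {
  .require_stage(table, "blank_subtracted", "subtract_medium")
  med_cols <- .cols_by_role(table, "medium")
  if (length(med_cols) == 0) {
    if (!allow_missing) stop("no medium-role sample in table; set ",
                             "allow_missing = TRUE to skip medium subtraction")
    return(.set_stage(table, "medium_subtracted"))
  }
  med <- .role_intensity(table, med_cols)
  extract_cols <- .cols_by_role(table, "extract")
  if (length(extract_cols) == 0) stop("no extract samples in table")
  ext <- as.matrix(table[, extract_cols, drop = FALSE])
  max_ext <- do.call(pmax, as.data.frame(ext))
  keep <- ifelse(med > 0, max_ext / med >= cfg$medium_fold, max_ext > 0)
  out <- table[keep, , drop = FALSE]
  med_kept <- med[keep]
  for (sc in extract_cols) {
    v <- out[[sc]]
    v[med_kept > 0 & v < med_kept * cfg$medium_fold] <- 0
    out[[sc]] <- v
  }
  out <- .drop_samples(out, med_cols)
  .set_stage(out, "medium_subtracted")
}

# indices j with sorted_mz[j] in [pred - tol, pred + tol], expanded to pairs
.window_pairs <- function(mz_sorted, pred, tol) {
  lo <- findInterval(pred - tol, mz_sorted) + 1L
  hi <- findInterval(pred + tol, mz_sorted)
  n_hit <- pmax(hi - lo + 1L, 0L)
  i <- rep.int(seq_along(pred), n_hit)
  j <- sequence(n_hit, from = lo)
  list(i = i, j = j)
}

#' Collapse isotope satellites and adduct/dimer ions
#'
#' Within the retention-time tolerance, an ion is removed when it is
#' explained relative to a base ion as (a) a 13C isotope satellite
#' (+1.003355 Da at lower intensity) or (b) a non-base adduct or dimer of
#' the base ion's neutral mass (any rule in `rules` with `base = FALSE`).
#' Base ions keep their own intensities. Removals are recorded in the
#' `collapse_log` attribute with an explanation.
#'
#' @param table a `feature_table` at stage `"medium_subtracted"`.
#' @param rules adduct rule table (rows for the table's polarity are used).
#' @param cfg a [cleanup_config()].
#' @param check_order set `FALSE` to run on a hand-built table in tests.
#' @return `feature_table` at stage `"collapsed"`.
#' @export
collapse_ions <- function(table, rules = default_adduct_rules(),
                          cfg = cleanup_config(), check_order = TRUE) {
  .require_stage(table, "medium_subtracted", "collapse_ions", check_order)
  pol <- table_polarity(table)
  rules <- rules[rules$polarity == pol, , drop = FALSE]
  base <- .base_rule(pol, rules)
  sat_rules <- rules[!rules$base, , drop = FALSE]

  n <- nrow(table)
  if (n < 2) {
    attr(table, "collapse_log") <- tibble::tibble(
      feature_id = character(), explained_as = character(),
      base_feature_id = character())
    return(.set_stage(table, "collapsed"))
  }
  ord <- order(table$mz)
  mz_s <- table$mz[ord]
  rt_s <- table$rt[ord]
  inten <- .role_intensity(table, .cols_by_role(table, "extract"))
  if (all(inten == 0)) inten <- .role_intensity(table, sample_ids(table))
  inten_s <- inten[ord]
  tol_of <- function(mz) mz * cfg$mz_ppm_tol * 1e-6

  pairs_i <- integer(0); pairs_j <- integer(0); expl <- character(0)

  # 13C isotope satellites: base -> base + 1.003355, lower intensity
  pred <- mz_s + C13_C12_DELTA
  pw <- .window_pairs(mz_s, pred, tol_of(pred))
  ok <- abs(rt_s[pw$i] - rt_s[pw$j]) <= cfg$rt_tol &
    inten_s[pw$j] < inten_s[pw$i] & pw$i != pw$j
  pairs_i <- c(pairs_i, pw$i[ok]); pairs_j <- c(pairs_j, pw$j[ok])
  expl <- c(expl, rep("isotope_13C", sum(ok)))

  # adducts/dimers of the base ion's neutral mass
  neutral_s <- (mz_s - base$mass_shift) / base$multiplicity
  for (k in seq_len(nrow(sat_rules))) {
    r <- sat_rules[k, ]
    pred <- neutral_s * r$multiplicity + r$mass_shift
    pw <- .window_pairs(mz_s, pred, tol_of(pred))
    ok <- abs(rt_s[pw$i] - rt_s[pw$j]) <= cfg$rt_tol & pw$i != pw$j
    pairs_i <- c(pairs_i, pw$i[ok]); pairs_j <- c(pairs_j, pw$j[ok])
    expl <- c(expl, rep(r$label, sum(ok)))
  }

  removed <- unique(pairs_j)
  first <- !duplicated(pairs_j)
  log <- tibble::tibble(
    feature_id = table$feature_id[ord][pairs_j[first]],
    explained_as = expl[first],
    base_feature_id = table$feature_id[ord][pairs_i[first]]
  )
  keep_idx <- setdiff(seq_len(n), ord[removed])
  out <- table[sort(keep_idx), , drop = FALSE]
  attr(out, "meta") <- table_meta(table)
  attr(out, "polarity") <- pol
  class(out) <- class(table)
  attr(out, "collapse_log") <- log
  .set_stage(out, "collapsed")
}

#' Merge positive- and negative-mode tables on neutral mass
#'
#' Base ions whose neutral masses agree within `cfg$mz_ppm_tol` and whose
#' retention times agree within `cfg$rt_tol` are overlaid into a single
#' neutral feature observed in both modes; the merged per-sample intensity
#' is the maximum of the contributing ions (overlaying, not summing, so one
#' analyte is not double-counted). Pairing is greedy by smallest ppm gap,
#' ties broken by retention-time gap then feature id, so the output is
#' deterministic and symmetric in its arguments. Unmatched ions pass
#' through as single-mode neutral features.
#'
#' @param pos,neg collapsed `feature_table`s of opposite polarity.
#' @param cfg a [cleanup_config()].
#' @param check_order set `FALSE` to merge hand-built tables in tests.
#' @return A tibble of class `neutral_features` with `neutral_mass`, `rt`,
#'   `modes_seen`, `provenance` and one intensity column per sample;
#'   `nrow = nrow(pos) + nrow(neg) - n_matched_pairs`.
#' @export
merge_modes <- function(pos, neg, cfg = cleanup_config(),
                        check_order = TRUE) {
  if (table_polarity(pos) == "negative" && table_polarity(neg) == "positive") {
    tmp <- pos; pos <- neg; neg <- tmp
  }
  stopifnot(table_polarity(pos) == "positive",
            table_polarity(neg) == "negative")
  .require_stage(pos, "collapsed", "merge_modes", check_order)
  .require_stage(neg, "collapsed", "merge_modes", check_order)
  if (length(intersect(pos$feature_id, neg$feature_id))) {
    stop("positive and negative tables share feature ids")
  }
  samples <- union(sample_ids(pos), sample_ids(neg))
  m_pos <- to_neutral_mass(pos$mz, "positive")
  m_neg <- to_neutral_mass(neg$mz, "negative")

  # candidate cross-mode pairs within mass ppm and rt tolerance
  ordn <- order(m_neg)
  mn_s <- m_neg[ordn]
  pw <- .window_pairs(mn_s, m_pos, m_pos * cfg$mz_ppm_tol * 1e-6)
  jj <- ordn[pw$j]; ii <- pw$i
  ok <- abs(pos$rt[ii] - neg$rt[jj]) <= cfg$rt_tol
  ii <- ii[ok]; jj <- jj[ok]
  ppm_gap <- abs(ppm_error(m_pos[ii], m_neg[jj]))
  rt_gap <- abs(pos$rt[ii] - neg$rt[jj])
  ordp <- order(ppm_gap, rt_gap, pos$feature_id[ii], neg$feature_id[jj])
  used_p <- logical(nrow(pos)); used_n <- logical(nrow(neg))
  mi <- integer(0); mj <- integer(0)
  for (k in ordp) {
    if (!used_p[ii[k]] && !used_n[jj[k]]) {
      used_p[ii[k]] <- TRUE; used_n[jj[k]] <- TRUE
      mi <- c(mi, ii[k]); mj <- c(mj, jj[k])
    }
  }

  inten <- function(tab, rows, sc) {
    if (sc %in% names(tab)) tab[[sc]][rows] else rep(0, length(rows))
  }
  prov <- function(ids, polarity, label) {
    paste(ids, polarity, label, sep = ":")
  }

  blocks <- list()
  if (length(mi)) {
    b <- tibble::tibble(
      neutral_mass = (m_pos[mi] + m_neg[mj]) / 2,
      rt = (pos$rt[mi] + neg$rt[mj]) / 2,
      modes_seen = "both",
      provenance = paste(prov(pos$feature_id[mi], "positive", "protonated"),
                         prov(neg$feature_id[mj], "negative", "deprotonated"),
                         sep = ";")
    )
    for (sc in samples) b[[sc]] <- pmax(inten(pos, mi, sc), inten(neg, mj, sc))
    blocks$both <- b
  }
  lone_p <- which(!used_p); lone_n <- which(!used_n)
  if (length(lone_p)) {
    b <- tibble::tibble(
      neutral_mass = m_pos[lone_p], rt = pos$rt[lone_p],
      modes_seen = "positive",
      provenance = prov(pos$feature_id[lone_p], "positive", "protonated"))
    for (sc in samples) b[[sc]] <- inten(pos, lone_p, sc)
    blocks$pos <- b
  }
  if (length(lone_n)) {
    b <- tibble::tibble(
      neutral_mass = m_neg[lone_n], rt = neg$rt[lone_n],
      modes_seen = "negative",
      provenance = prov(neg$feature_id[lone_n], "negative", "deprotonated"))
    for (sc in samples) b[[sc]] <- inten(neg, lone_n, sc)
    blocks$neg <- b
  }
  out <- dplyr::bind_rows(blocks)
  out <- out[order(out$neutral_mass, out$rt), , drop = FALSE]
  meta <- dplyr::distinct(dplyr::bind_rows(table_meta(pos), table_meta(neg)))
  structure(out, meta = meta,
            class = c("neutral_features", class(tibble::tibble())))
}

#' Intensity matrix (samples x features) from a neutral-feature table
#'
#' Rows are extract samples (named by isolate), columns are features named
#' by rounded neutral mass and retention time.
#' @param features a `neutral_features` tibble.
#' @param meta optional metadata override.
#' @return numeric matrix suitable for [pareto_scale()].
#' @export
features_to_matrix <- function(features, meta = attr(features, "meta")) {
  extract <- meta$sample_id[meta$role == "extract"]
  extract <- intersect(extract, names(features))
  x <- t(as.matrix(features[, extract, drop = FALSE]))
  colnames(x) <- sprintf("%.4f@%.2f", features$neutral_mass, features$rt)
  rownames(x) <- extract
  x
}
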