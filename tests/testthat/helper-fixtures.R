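# shared in-code fixtures: tiny feature tables and metadata built fresh
# per call so tests cannot interfere through shared state

tiny_meta <- function() {
  sample_meta(
    sample_id = c("isoA", "isoB", "medium", "blank"),
    role = c("extract", "extract", "medium", "blank"),
    isolate_id = c("isoA", "isoB", NA, NA)
  )
}

tiny_table <- function(polarity = "positive",
                       mz = c(379.1653, 420.2001, 515.3303),
                       rt = c(10.66, 12.1, 20.5),
                       isoA = c(2.1e6, 5e4, 8e5),
                       isoB = c(1.0e5, 3e6, 2e5),
                       medium = c(1.0e5, 0, 0),
                       blank = c(0, 0, 0),
                       ids = NULL) {
  n <- length(mz)
  if (is.null(ids)) {
    ids <- paste0(if (polarity == "positive") "P" else "N", seq_len(n))
  }
  feature_table(
    tibble::tibble(feature_id = ids, mz = mz, rt = rt,
                   isoA = isoA, isoB = isoB,
                   medium = medium, blank = blank),
    tiny_meta(), polarity
  )
}

# lift a hand-built table to a given clean-up stage without running the
# earlier stages (for direct unit tests of later stages)
at_stage <- function(table, stage) {
  attr(table, "cleanup_stage") <- stage
  table
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small, fast synthetic configuration for property tests that do not need
# the full-scale default dataset
small_synth <- function(seed = 1, ...) {
  synth_config(n_base_features = 600, n_medium_features = 60,
               n_blank_features = 30, n_outlier_features = 80,
               seed = seed, ...)
}

extdata <- function(f) {
  system.file("extdata", f, package = "strainsift", mustWork = TRUE)
}
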