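# small in-code fixtures shared across the suite

make_table <- function(counts, features = NULL, samples = NULL) {
  m <- as.matrix(counts)
  if (is.null(features)) features <- sprintf("T%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  feature_table(m)
}

# random integer table under a fixed seed, for property-style loops
random_table <- function(n_feat, n_samp, max_count = 50L) {
  m <- matrix(sample.int(max_count + 1L, n_feat * n_samp, replace = TRUE) - 1L,
              nrow = n_feat)
  # ensure at least one read so S > 0
  if (sum(m) == 0L) m[1L, 1L] <- 1L
  make_table(m)
}

make_taxonomy <- function(feature_id, lineage) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(feature_id, lineage, sep = "\t"), tf)
  on.exit(unlink(tf))
  read_taxonomy(tf)
}

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# metadata for a toy larval design: named vector stage -> sample count
make_metadata <- function(per_stage, years = 2019L, habitat = "larva") {
  stage <- rep(names(per_stage), times = per_stage)
  data.frame(sample_id = sprintf("S%02d", seq_along(stage)), stage = stage,
             year = rep_len(years, length(stage)), habitat = habitat,
             gut_dev = unname(DEFAULT_GUTDEV_MAP[stage]),
             stringsAsFactors = FALSE)
}
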