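#' Construct a validated feature table
#'
#' A feature table is the central container of the package: an integer matrix
#' of read counts with features (ASVs or collapsed taxa) as rows and samples
#' as columns. The constructor enforces the container invariants: counts are
#' non-negative and integral (numeric values within `1e-9` of an integer are
#' rounded, anything else is rejected), identifiers are unique and non-empty,
#' and the table has at least one feature and one sample. Counts are stored in
#' double precision so that downstream products of large read totals do not
#' overflow.
#'
#' @param counts numeric matrix of read counts, features x samples.
#' @param feature_ids,sample_ids row/column identifiers; default to the
#'   dimnames of `counts`.
#' @return an object of class `feature_table` (a classed numeric matrix).
#' @examples
#' ft <- feature_table(matrix(c(5, 1, 0, 0, 2, 7), nrow = 3,
#'                            dimnames = list(c("A", "B", "C"), c("S1", "S2"))))
#' colSums(ft)
#' @export
feature_table <- function(counts, feature_ids = rownames(counts),
                          sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("feature table counts must be numeric", call. = FALSE)
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("feature table needs at least 1 feature and 1 sample", call. = FALSE)
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature table needs feature and sample identifiers", call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("feature table counts must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("negative counts are not allowed in a feature table", call. = FALSE)
  }
  off <- abs(counts - round(counts))
  if (any(off > 1e-9)) {
    bad <- which(off > 1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count %.6g at feature %s, sample %s",
                 counts[bad[1L], bad[2L]], feature_ids[bad[1L]],
                 sample_ids[bad[2L]]), call. = FALSE)
  }
  counts <- round(counts)
  .check_unique(feature_ids, "feature")
  .check_unique(sample_ids, "sample")
  dimnames(counts) <- list(feature_ids, sample_ids)
  class(counts) <- c("feature_table", class(counts))
  counts
}

.check_unique <- function(ids, what) {
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop(sprintf("empty or missing %s identifier", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples, %d reads\n",
              nrow(x), ncol(x), sum(x)))
  m <- unclass(x)
  print(m[seq_len(min(6L, nrow(m))), seq_len(min(6L, ncol(m))), drop = FALSE])
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i, j, ...) {
  m <- unclass(x)[i, j, drop = FALSE]
  feature_table(m)
}

# strip the class for plain matrix work
ft_counts <- function(x) {
  m <- unclass(x)
  class(m) <- setdiff(class(m), "feature_table")
  m
}

# is x a feature_table (or coercible count matrix)? used by ops that accept both
as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) x else feature_table(x)
}
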