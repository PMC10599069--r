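#' Remove organelle-derived features
#'
#' 16S amplicon libraries from animal hosts carry mitochondrial and
#' chloroplast reads that must be excluded before community analysis. A
#' feature is removed when any rank of its lineage -- raw string or canonical
#' form -- case-insensitively contains any of the `patterns`. Substring
#' matching is used because database capitalization and suffixes vary
#' ("Mitochondria" vs "mitochondrial"). The operation is idempotent and never
#' alters the sample set. The removal report is attached as the `"removed"`
#' attribute of the result (a data.frame of feature id, matched reads).
#'
#' @param table a [feature_table()].
#' @param taxonomy a taxonomy map from [read_taxonomy()].
#' @param patterns character vector of case-insensitive substrings; default
#'   `c("mitochondri", "chloroplast")`.
#' @param missing policy for features absent from the taxonomy: `"error"`
#'   (default) or `"unassigned"` (treated as matching nothing).
#' @return the filtered [feature_table()] with attribute `"removed"`.
#' @export
filter_organelles <- function(table, taxonomy,
                              patterns = c("mitochondri", "chloroplast"),
                              missing = c("error", "unassigned")) {
  table <- as_feature_table(table)
  idx <- match_taxonomy(table, taxonomy, missing)
  hay <- rep("", nrow(table))
  ok <- !is.na(idx)
  hay[ok] <- paste(taxonomy$taxonomy[idx[ok]],
                   apply(taxonomy[idx[ok], TAX_RANKS, drop = FALSE], 1L,
                         function(r) paste(r[!is.na(r)], collapse = ";")))
  hit <- rep(FALSE, nrow(table))
  for (p in patterns) {
    hit <- hit | grepl(p, hay, ignore.case = TRUE, fixed = FALSE)
  }
  if (all(hit)) {
    stop("all features matched the organelle patterns; empty table refused",
         call. = FALSE)
  }
  removed <- data.frame(feature_id = rownames(table)[hit],
                        reads = unname(rowSums(ft_counts(table))[hit]),
                        stringsAsFactors = FALSE)
  out <- if (any(hit)) table[!hit, , drop = FALSE] else table
  attr(out, "removed") <- removed
  out
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads uniformly at random WITHOUT replacement
#' (hypergeometric subsampling, via [vegan::rrarefy()]) so that every retained
#' sample sums exactly to `depth`. Samples with fewer than `depth` reads are
#' dropped (default) or left untouched with a warning. Identical
#' `(table, depth, seed)` always yields identical output.
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample; default the minimum sample total.
#' @param seed integer RNG seed (required for reproducibility).
#' @param drop_below drop samples with fewer than `depth` reads (default TRUE).
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(table, depth = NULL, seed = 1L, drop_below = TRUE) {
  table <- as_feature_table(table)
  totals <- colSums(ft_counts(table))
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L) {
    stop("rarefaction depth must be a single integer >= 1", call. = FALSE)
  }
  keep <- totals >= depth
  if (!any(keep)) {
    stop(sprintf("no samples remain: depth %d exceeds every sample total (max %d)",
                 depth, max(totals)), call. = FALSE)
  }
  if (any(!keep)) {
    msg <- sprintf("%d sample(s) below depth %d: %s", sum(!keep), depth,
                   paste(colnames(table)[!keep], collapse = ", "))
    if (drop_below) message("rarefy: dropping ", msg) else
      warning("rarefy: leaving untouched ", msg, call. = FALSE)
  }
  m <- ft_counts(table)
  sub <- withr::with_seed(seed, {
    # muffle vegan's are-these-really-counts heuristic; counts are validated
    # by the feature_table constructor
    withCallingHandlers(
      t(vegan::rrarefy(t(m[, keep, drop = FALSE]), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  out <- if (drop_below) sub else {
    m[, keep] <- sub
    m
  }
  feature_table(out)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Features sharing the same label at the requested rank are summed per
#' sample. Features unassigned at that rank are grouped under
#' `Unclassified_<nearest assigned parent>` (the deepest assigned rank above),
#' or `Unclassified_Unassigned` when nothing is assigned. `rank = "asv"` is
#' the identity. Total reads are conserved exactly.
#'
#' @param table a [feature_table()].
#' @param taxonomy a taxonomy map from [read_taxonomy()].
#' @param rank one of `"order"`, `"family"`, `"genus"`, `"asv"`.
#' @param missing mismatch policy, see [filter_organelles()].
#' @return a collapsed [feature_table()].
#' @export
collapse_rank <- function(table, taxonomy,
                          rank = c("family", "order", "genus", "asv"),
                          missing = c("error", "unassigned")) {
  rank <- match.arg(rank)
  table <- as_feature_table(table)
  if (rank == "asv") return(table)
  idx <- match_taxonomy(table, taxonomy, missing)
  ri <- match(rank, TAX_RANKS)
  labels <- vapply(seq_len(nrow(table)), function(i) {
    if (is.na(idx[i])) return("Unclassified_Unassigned")
    lin <- as.character(taxonomy[idx[i], TAX_RANKS])
    if (!is.na(lin[ri])) return(lin[ri])
    above <- lin[seq_len(ri - 1L)]
    above <- above[!is.na(above)]
    if (length(above)) paste0("Unclassified_", above[length(above)])
    else "Unclassified_Unassigned"
  }, character(1L))
  agg <- rowsum(ft_counts(table), group = labels, reorder = TRUE)
  feature_table(agg)
}

#' Convert counts to relative abundances
#'
#' @param table a [feature_table()] (every sample total must be > 0).
#' @return a plain numeric matrix of fractions; each column sums to 1 within
#'   `1e-12`.
#' @export
to_relative <- function(table) {
  table <- as_feature_table(table)
  m <- ft_counts(table)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2L, cs, "/")
}
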