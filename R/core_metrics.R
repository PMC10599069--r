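#' Abundance criterion: ranked prefix covering a share of total reads
#'
#' Ranks taxa by total reads (descending, ties broken by taxon name ascending
#' for determinism) and returns the shortest prefix whose cumulative share of
#' total dataset reads reaches `cum_threshold`. With the default 0.75 this is
#' the "top 75% of total reads" abundance criterion of the hybrid core
#' definition.
#'
#' @param table a [feature_table()].
#' @param cum_threshold cumulative read-share threshold in (0, 1]; default 0.75.
#' @return list with `taxa` (character, the abundance set) and `table`
#'   (data.frame of taxon, reads, share, cumulative_share, in_set).
#' @export
abundance_core_set <- function(table, cum_threshold = 0.75) {
  table <- as_feature_table(table)
  if (!(cum_threshold > 0 && cum_threshold <= 1)) {
    stop("cum_threshold must be in (0, 1]", call. = FALSE)
  }
  totals <- rowSums(ft_counts(table))
  S <- sum(totals)
  if (S == 0) stop("table has no reads", call. = FALSE)
  ord <- order(-totals, rownames(table))
  totals <- totals[ord]
  share <- totals / S
  cum <- cumsum(share)
  k <- which(cum >= cum_threshold - 1e-12)[1L]
  in_set <- seq_along(totals) <= k
  list(
    taxa = names(totals)[in_set],
    table = data.frame(taxon = names(totals), reads = unname(totals),
                       share = unname(share), cumulative_share = unname(cum),
                       in_set = in_set, stringsAsFactors = FALSE)
  )
}

#' Occupancy criterion: presence in more than a fraction of samples
#'
#' A taxon passes when it is detected (count > 0) in strictly more than
#' `occ_threshold` of the samples -- "over 70%" is a strict inequality, so a
#' taxon present in exactly 70% of samples is excluded. The comparison
#' `n > occ_threshold * N` is snapped to the nearest integer when
#' `occ_threshold * N` is within 1e-9 of one, so boundary cases are decided
#' exactly rather than by floating-point rounding.
#'
#' @param table a [feature_table()].
#' @param occ_threshold occupancy fraction threshold; default 0.70.
#' @return list with `taxa` (character, the occupancy set) and `table`
#'   (data.frame of taxon, occupancy_n, occupancy_frac, in_set).
#' @export
occupancy_core_set <- function(table, occ_threshold = 0.70) {
  table <- as_feature_table(table)
  m <- ft_counts(table)
  N <- ncol(m)
  n <- rowSums(m > 0)
  cut <- occ_threshold * N
  if (abs(cut - round(cut)) < 1e-9) cut <- round(cut)
  in_set <- n > cut
  list(
    taxa = rownames(m)[in_set],
    table = data.frame(taxon = rownames(m), occupancy_n = unname(n),
                       occupancy_frac = unname(n) / N, in_set = unname(in_set),
                       stringsAsFactors = FALSE)
  )
}

#' Core Index (CI) for an evaluation set of taxa
#'
#' For each taxon the Core Index combines its dataset frequency, occupancy
#' and read total:
#' \deqn{CI = \frac{f \cdot n \cdot s}{N \cdot S}}
#' where `s` is the taxon's total reads, `S` the dataset total reads, `n` the
#' number of samples containing the taxon (count > 0), `N` the total number
#' of samples, and `f` the taxon's frequency within the dataset. With the
#' default `f_definition = "rel_freq"`, `f = s/S`, giving
#' `CI = (n/N) (s/S)^2`, bounded in \[0, 1\] with CI = 1 only for a taxon
#' owning all reads in all samples; `f_definition = "occupancy"` (`f = n/N`)
#' reproduces the alternative reading.
#'
#' @param table a [feature_table()]; `N`, `S`, `n` and `s` are all taken from
#'   this table, so pass a sample-restricted table for stage-scoped CI.
#' @param taxa character vector of taxa to evaluate (subset of the features).
#' @param f_definition `"rel_freq"` (default, `f = s/S`) or `"occupancy"`
#'   (`f = n/N`).
#' @return a `core_scores` data.frame with columns taxon, reads_s,
#'   total_reads_S, occupancy_n, total_samples_N, occupancy_frac, freq_f,
#'   abundance_share, ci.
#' @export
compute_ci <- function(table, taxa,
                       f_definition = c("rel_freq", "occupancy")) {
  f_definition <- match.arg(f_definition)
  table <- as_feature_table(table)
  if (!length(taxa)) stop("empty evaluation set", call. = FALSE)
  miss <- setdiff(taxa, rownames(table))
  if (length(miss)) {
    stop("evaluation taxa missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- ft_counts(table)
  S <- sum(m)
  if (S <= 0) stop("table has no reads (S = 0)", call. = FALSE)
  N <- ncol(m)
  s <- rowSums(m)[taxa]
  n <- rowSums(m > 0)[taxa]
  f <- if (f_definition == "rel_freq") s / S else n / N
  ci <- f * n * s / (N * S)
  out <- data.frame(taxon = taxa, reads_s = unname(s), total_reads_S = S,
                    occupancy_n = unname(n), total_samples_N = N,
                    occupancy_frac = unname(n) / N, freq_f = unname(f),
                    abundance_share = unname(s) / S, ci = unname(ci),
                    stringsAsFactors = FALSE)
  class(out) <- c("core_scores", class(out))
  out
}

#' Normalized Core Index (NorCI)
#'
#' Min-max normalization of CI over the evaluated collection:
#' \deqn{NorCI = \frac{CI' - CI_{min}}{CI_{max} - CI_{min}}}
#' so the minimum-CI taxon scores 0 and the maximum scores 1. Normalization
#' spans exactly the collection passed in -- the top-20 families for the
#' whole-dataset core, or the candidate pool for a stage core -- because the
#' index is computed separately per analysis. When all CI values are equal no
#' taxon can be ranked: NorCI is set to `NA` with a warning.
#'
#' @param scores a `core_scores` data.frame from [compute_ci()] (>= 2 rows).
#' @return `scores` with a `norci` column added.
#' @export
compute_norci <- function(scores) {
  if (nrow(scores) < 2L) {
    stop("NorCI needs at least 2 evaluated taxa", call. = FALSE)
  }
  lo <- min(scores$ci)
  hi <- max(scores$ci)
  if (hi == lo) {
    warning("all CI values equal; NorCI is undefined for this set",
            call. = FALSE)
    scores$norci <- NA_real_
  } else {
    scores$norci <- (scores$ci - lo) / (hi - lo)
  }
  scores
}

#' Hybrid core-microbiome classification
#'
#' The full hybrid definition: CI and NorCI are computed over the evaluation
#' set of the `top_k` most abundant taxa (ties broken by name), and a taxon is
#' labelled `core` only when it satisfies all three criteria -- membership in
#' the cumulative-abundance set ([abundance_core_set()]), membership in the
#' occupancy set ([occupancy_core_set()]), and `NorCI > norci_threshold`
#' (strict). Evaluated taxa failing any criterion are `non_core`; taxa outside
#' the evaluation set are `not_evaluated` but still reported with their reads,
#' share and occupancy. The result is invariant to the row and column order of
#' the input table.
#'
#' @param table a [feature_table()] with >= 2 features.
#' @param top_k size of the CI evaluation set; default 20.
#' @param cum_threshold abundance criterion threshold; default 0.75.
#' @param occ_threshold occupancy criterion threshold; default 0.70.
#' @param norci_threshold NorCI core threshold (strict); default 0.3.
#' @param f_definition passed to [compute_ci()].
#' @return a `core_scores` data.frame, one row per taxon ordered by
#'   decreasing reads, with criterion flags, `ci`, `norci` and `core_label`
#'   (`core` / `non_core` / `not_evaluated`); run parameters are attached as
#'   the `"params"` attribute.
#' @export
classify_core <- function(table, top_k = 20L, cum_threshold = 0.75,
                          occ_threshold = 0.70, norci_threshold = 0.3,
                          f_definition = c("rel_freq", "occupancy")) {
  f_definition <- match.arg(f_definition)
  table <- as_feature_table(table)
  if (nrow(table) < 2L) {
    stop("classify_core needs at least 2 features", call. = FALSE)
  }
  totals <- rowSums(ft_counts(table))
  ord <- order(-totals, rownames(table))
  taxa <- rownames(table)[ord]
  eval_taxa <- taxa[seq_len(min(top_k, length(taxa)))]
  if (length(eval_taxa) < 2L) {
    stop("fewer than 2 features in the evaluation set", call. = FALSE)
  }
  ab <- abundance_core_set(table, cum_threshold)
  oc <- occupancy_core_set(table, occ_threshold)
  sc <- compute_norci(compute_ci(table, eval_taxa, f_definition))

  out <- data.frame(taxon = taxa, reads_s = unname(totals[ord]),
                    total_reads_S = sum(totals),
                    occupancy_n = oc$table$occupancy_n[match(taxa, oc$table$taxon)],
                    total_samples_N = ncol(table),
                    stringsAsFactors = FALSE)
  out$occupancy_frac <- out$occupancy_n / out$total_samples_N
  out$abundance_share <- out$reads_s / out$total_reads_S
  out$in_abundance_set <- out$taxon %in% ab$taxa
  out$in_occupancy_set <- out$taxon %in% oc$taxa
  i <- match(out$taxon, sc$taxon)
  out$freq_f <- sc$freq_f[i]
  out$ci <- sc$ci[i]
  out$norci <- sc$norci[i]
  evaluated <- !is.na(i)
  is_core <- evaluated & out$in_abundance_set & out$in_occupancy_set &
    !is.na(out$norci) & out$norci > norci_threshold
  out$core_label <- ifelse(is_core, "core",
                           ifelse(evaluated, "non_core", "not_evaluated"))
  attr(out, "params") <- list(top_k = top_k, cum_threshold = cum_threshold,
                              occ_threshold = occ_threshold,
                              norci_threshold = norci_threshold,
                              f_definition = f_definition)
  class(out) <- c("core_scores", class(out))
  out
}

#' @export
print.core_scores <- function(x, ...) {
  ncore <- if ("core_label" %in% names(x)) sum(x$core_label == "core") else NA
  cat(sprintf("core_scores: %d taxa%s\n", nrow(x),
              if (!is.na(ncore)) sprintf(", %d core", ncore) else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
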