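# tie-corrected Kruskal-Wallis statistic from pooled ranks
# r: ranks (ties.method = "average"); g: factor of group labels
kw_statistic <- function(r, g) {
  n <- length(r)
  tie <- table(r)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (corr <= 0) return(0)
  sums <- tapply(r, g, sum)
  ng <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / ng) - 3 * (n + 1)
  h / corr
}

# exact permutation p-value of the KW statistic: enumerate every distinct
# assignment of the observed ranks to groups of the observed sizes and count
# assignments with a statistic >= the observed one (the observed assignment
# is part of the enumeration, so p > 0 always)
kw_exact_p <- function(x, g) {
  r <- rank(x)
  obs <- kw_statistic(r, g)
  sizes <- tabulate(g)
  total <- 0L
  hits <- 0L
  recurse <- function(remaining, gi, assign) {
    if (gi == length(sizes)) {
      assign[remaining] <- gi
      stat <- kw_statistic(r, factor(assign, levels = seq_along(sizes)))
      total <<- total + 1L
      if (stat >= obs - 1e-12) hits <<- hits + 1L
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) {
      a <- assign
      a[p] <- gi
      recurse(setdiff(remaining, p), gi + 1L, a)
    }
  }
  recurse(seq_along(r), 1L, integer(length(r)))
  list(statistic = obs, p_value = hits / total, n_assignments = total)
}

#' Rank-based differential-abundance screen across groups
#'
#' A per-taxon Kruskal-Wallis test of relative abundance across developmental
#' stages or gut-development groups, used (together with
#' [effect_size_score()]) as a documented stand-in for the LEfSe
#' candidate-detection step. For designs with more than `exact_max_n` samples
#' the tie-corrected chi-squared p-value from [stats::kruskal.test()] is
#' used; for small designs (total n <= `exact_max_n`, default 10) an exact
#' permutation p-value over all distinct group assignments is computed
#' instead. Benjamini-Hochberg adjusted p-values across taxa are reported
#' alongside the raw ones. Seawater samples are excluded by habitat filter.
#'
#' @param relabund relative-abundance matrix (taxa x samples), e.g. from
#'   [to_relative()]; a [feature_table()] is converted automatically.
#' @param metadata sample metadata data.frame (see [read_metadata()]).
#' @param grouping `"stage"` or `"gut_dev"`.
#' @param exact_max_n largest total sample count for the exact branch.
#' @return data.frame of taxon, statistic, p_value, p_adjusted (BH), method.
#' @export
kruskal_wallis_screen <- function(relabund, metadata,
                                  grouping = c("stage", "gut_dev"),
                                  exact_max_n = 10L) {
  grouping <- match.arg(grouping)
  if (inherits(relabund, "feature_table")) relabund <- to_relative(relabund)
  sel <- metadata$habitat == "larva" & metadata$sample_id %in% colnames(relabund)
  md <- metadata[sel, , drop = FALSE]
  if (nrow(md) < 4L) stop("need >= 4 larval samples for the screen", call. = FALSE)
  x <- relabund[, md$sample_id, drop = FALSE]
  g <- factor(md[[grouping]])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  small <- names(which(table(g) < 2L))
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  n <- ncol(x)
  exact <- n <= exact_max_n
  res <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    if (all(v == v[1L])) {
      return(list(statistic = 0, p_value = 1))
    }
    if (exact) {
      kw_exact_p(v, g)[c("statistic", "p_value")]
    } else {
      kt <- stats::kruskal.test(v, g)
      st <- unname(kt$statistic)
      pv <- kt$p.value
      if (!is.finite(st)) {
        st <- 0
        pv <- 1
      }
      list(statistic = st, p_value = pv)
    }
  })
  out <- data.frame(
    taxon = rownames(x),
    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$method <- if (exact) "exact_permutation" else "chisq_approx"
  out
}

#' Effect-size score for enrichment in a target class
#'
#' Scores the mean relative-abundance difference between a target class and
#' all other larval samples on the conventional 10^6-scaled log10 axis used
#' for LDA effect sizes:
#' `score = log10(1 + |mean_target - mean_other| * 1e6 / 2)`.
#' The directional sign is reported separately (`"up"` = enriched in the
#' target class). A mean difference of about 0.0063 corresponds to the
#' conventional 3.5 cut-off.
#'
#' @param relabund relative-abundance matrix (taxa x samples) or
#'   [feature_table()].
#' @param metadata sample metadata data.frame.
#' @param taxon taxa to score (default: all rows).
#' @param target_class a stage label (FE...JN) or `"preGD"`/`"postGD"`.
#' @param grouping `"stage"` or `"gut_dev"`; inferred from `target_class`
#'   when `NULL`.
#' @return data.frame of taxon, target_class, mean_target, mean_other,
#'   effect_score, direction.
#' @export
effect_size_score <- function(relabund, metadata, taxon = NULL, target_class,
                              grouping = NULL) {
  if (inherits(relabund, "feature_table")) relabund <- to_relative(relabund)
  if (is.null(grouping)) {
    grouping <- if (target_class %in% STAGES) "stage" else "gut_dev"
  }
  sel <- metadata$habitat == "larva" & metadata$sample_id %in% colnames(relabund)
  md <- metadata[sel, , drop = FALSE]
  x <- relabund[, md$sample_id, drop = FALSE]
  if (is.null(taxon)) taxon <- rownames(x)
  miss <- setdiff(taxon, rownames(x))
  if (length(miss)) {
    stop("taxon not present in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  inside <- md[[grouping]] == target_class
  if (!any(inside) || all(inside)) {
    stop("target class '", target_class, "' must split the samples",
         call. = FALSE)
  }
  m1 <- rowMeans(x[taxon, inside, drop = FALSE])
  m0 <- rowMeans(x[taxon, !inside, drop = FALSE])
  d <- m1 - m0
  data.frame(taxon = taxon, target_class = target_class,
             mean_target = unname(m1), mean_other = unname(m0),
             effect_score = log10(1 + abs(d) * 1e6 / 2),
             direction = ifelse(d > 0, "up", ifelse(d < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

#' Combined enrichment screen for one target class
#'
#' Runs [kruskal_wallis_screen()] and [effect_size_score()] and flags a taxon
#' significant when its p-value is below `alpha`, its effect score reaches
#' `effect_threshold` and it is enriched (not depleted) in the target class.
#' This mirrors the p < 0.05 / LDA >= 3.5 candidate-detection convention of
#' LEfSe, which tests each taxon at the per-test level; `adjust = TRUE`
#' switches to Benjamini-Hochberg adjusted p-values instead. Note that with
#' six stage groups a taxon elevated in a single stage cannot reach a very
#' small Kruskal-Wallis p (clean separation of one group of five among 28
#' samples bottoms out near p ~ 0.01), so BH adjustment across hundreds of
#' taxa is conservative for single-stage enrichment; the effect-score
#' cut-off is what controls false calls in either mode.
#'
#' @inheritParams effect_size_score
#' @param alpha significance level; default 0.05.
#' @param effect_threshold effect-score cut-off; default 3.5.
#' @param adjust use BH-adjusted p-values instead of per-test p-values
#'   (default FALSE, the LEfSe convention).
#' @return an `enrichment_result` data.frame: taxon, target_class, p_value,
#'   p_adjusted, effect_score, direction, significant.
#' @export
enrichment_screen <- function(relabund, metadata, target_class,
                              grouping = NULL, alpha = 0.05,
                              effect_threshold = 3.5, adjust = FALSE) {
  if (inherits(relabund, "feature_table")) relabund <- to_relative(relabund)
  if (is.null(grouping)) {
    grouping <- if (target_class %in% STAGES) "stage" else "gut_dev"
  }
  kw <- kruskal_wallis_screen(relabund, metadata, grouping)
  ef <- effect_size_score(relabund, metadata, kw$taxon, target_class,
                          grouping)
  p_used <- if (adjust) kw$p_adjusted else kw$p_value
  out <- data.frame(taxon = kw$taxon, target_class = target_class,
                    p_value = kw$p_value, p_adjusted = kw$p_adjusted,
                    effect_score = ef$effect_score, direction = ef$direction,
                    stringsAsFactors = FALSE)
  out$significant <- p_used < alpha & out$effect_score >= effect_threshold &
    out$direction == "up"
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Taxa appearing exclusively at one stage
#'
#' Returns the taxa detected (count > 0) in at least one larval sample of
#' `stage_label` and in no larval sample of any other stage. Seawater samples
#' are excluded by the habitat filter. A taxon absent everywhere is not
#' exclusive (it must appear at least once).
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata data.frame.
#' @param stage_label one of the stage labels (FE...JN).
#' @return character vector of exclusive taxa.
#' @export
detect_exclusive_taxa <- function(table, metadata, stage_label) {
  table <- as_feature_table(table)
  if (!stage_label %in% STAGES) {
    stop("unknown stage '", stage_label, "'; allowed: ",
         paste(STAGES, collapse = ", "), call. = FALSE)
  }
  md <- metadata[metadata$habitat == "larva" &
                   metadata$sample_id %in% colnames(table), , drop = FALSE]
  inside <- md$sample_id[md$stage == stage_label]
  outside <- md$sample_id[md$stage != stage_label]
  if (!length(inside)) {
    stop("stage '", stage_label, "' has no samples", call. = FALSE)
  }
  m <- ft_counts(table)
  hit_in <- rowSums(m[, inside, drop = FALSE] > 0) > 0
  hit_out <- if (length(outside)) {
    rowSums(m[, outside, drop = FALSE] > 0) > 0
  } else {
    rep(FALSE, nrow(m))
  }
  rownames(m)[hit_in & !hit_out]
}

#' Assemble a stage-core candidate pool
#'
#' Unions significantly enriched taxa, stage-exclusive taxa and any externally
#' supplied candidate list (e.g. a genuine LEfSe result read with
#' [read_taxa_list()]), tagging each candidate with its provenance
#' (`enriched`, `exclusive`, `both` when found by both internal routes, or
#' `supplied`).
#'
#' @param enriched an `enrichment_result` data.frame (its significant rows are
#'   used) or a character vector of taxa.
#' @param exclusive character vector of stage-exclusive taxa.
#' @param supplied optional externally supplied character vector of taxa.
#' @return data.frame of taxon, provenance; errors when the union is empty.
#' @export
assemble_candidate_pool <- function(enriched = NULL, exclusive = NULL,
                                    supplied = NULL) {
  e <- if (is.data.frame(enriched)) {
    enriched$taxon[enriched$significant]
  } else {
    as.character(enriched)
  }
  x <- as.character(exclusive)
  s <- as.character(supplied)
  taxa <- unique(c(e, x, s))
  if (!length(taxa)) {
    stop("empty candidate pool: no enriched, exclusive or supplied taxa",
         call. = FALSE)
  }
  provenance <- vapply(taxa, function(t) {
    if (t %in% e && t %in% x) "both"
    else if (t %in% e) "enriched"
    else if (t %in% x) "exclusive"
    else "supplied"
  }, character(1L), USE.NAMES = FALSE)
  data.frame(taxon = taxa, provenance = provenance, stringsAsFactors = FALSE)
}

#' Stage-restricted core extraction
#'
#' Computes CI/NorCI for a candidate pool over the samples of one scope -- a
#' single stage (e.g. FE for the pioneer core, JN for the juvenile core), a
#' gut-development group (`preGD`/`postGD` for the initial/later stage
#' cores), or `"all"` larval samples -- and returns the pool members with
#' `NorCI > norci_threshold` as the stage core. By default `N`, `S`, `n` and
#' `s` are restricted to the scope's samples (`scope = "restricted"`), since
#' CI over stage-specific candidates only discriminates within the stage's
#' own sample set; `scope = "global"` scores the pool on all larval samples
#' instead. For `preGD`/`postGD`/`all` scopes the pool defaults to the
#' scope's `top_k` most abundant taxa (provenance `"abundance"`). Pool
#' members absent from the scope samples score CI = 0. Seawater samples are
#' always excluded.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata data.frame.
#' @param stage_scope `"FE"`...`"JN"`, `"preGD"`, `"postGD"` or `"all"`.
#' @param pool candidate pool: a data.frame from [assemble_candidate_pool()]
#'   or a character vector (tagged `supplied`). Required for single-stage
#'   scopes; must have >= 2 members (NorCI is undefined on one point).
#' @param norci_threshold NorCI core threshold (strict); default 0.3.
#' @param top_k default pool size for group scopes; default 20.
#' @param f_definition passed to [compute_ci()].
#' @param scope `"restricted"` (default) or `"global"`, see Details.
#' @return a `stage_core_result` list: `stage_label`, `n_samples`,
#'   `candidate_pool`, `scores` (CoreScore rows with `norci`, `provenance`,
#'   `core` flag) and `core_members`.
#' @export
stage_core_extraction <- function(table, metadata, stage_scope, pool = NULL,
                                  norci_threshold = 0.3, top_k = 20L,
                                  f_definition = c("rel_freq", "occupancy"),
                                  scope = c("restricted", "global")) {
  f_definition <- match.arg(f_definition)
  scope <- match.arg(scope)
  table <- as_feature_table(table)
  md <- metadata[metadata$habitat == "larva" &
                   metadata$sample_id %in% colnames(table), , drop = FALSE]
  sel <- if (stage_scope == "all") {
    rep(TRUE, nrow(md))
  } else if (stage_scope %in% STAGES) {
    md$stage == stage_scope
  } else if (stage_scope %in% c("preGD", "postGD")) {
    md$gut_dev == stage_scope
  } else {
    stop("unknown stage_scope '", stage_scope, "'", call. = FALSE)
  }
  if (sum(sel) < 2L) {
    stop("scope '", stage_scope, "' selects fewer than 2 samples",
         call. = FALSE)
  }
  scoped <- table[, md$sample_id[sel], drop = FALSE]
  score_table <- if (scope == "restricted") scoped else
    table[, md$sample_id, drop = FALSE]

  if (is.null(pool)) {
    if (stage_scope %in% STAGES) {
      stop("a candidate pool is required for single-stage scopes", call. = FALSE)
    }
    totals <- rowSums(ft_counts(scoped))
    ord <- order(-totals, rownames(scoped))
    taxa <- rownames(scoped)[ord][seq_len(min(top_k, nrow(scoped)))]
    pool <- data.frame(taxon = taxa, provenance = "abundance",
                       stringsAsFactors = FALSE)
  } else if (!is.data.frame(pool)) {
    pool <- data.frame(taxon = as.character(pool), provenance = "supplied",
                       stringsAsFactors = FALSE)
  }
  if (nrow(pool) < 2L) {
    stop("candidate pool of size ", nrow(pool),
         ": NorCI is undefined on fewer than 2 candidates", call. = FALSE)
  }
  present <- pool$taxon[pool$taxon %in% rownames(score_table)]
  absent <- setdiff(pool$taxon, present)
  if (length(present) > 0L) {
    sc <- compute_ci(score_table, present, f_definition)
  } else {
    stop("no pool member is present in the table", call. = FALSE)
  }
  if (length(absent)) {
    zero <- data.frame(taxon = absent, reads_s = 0,
                       total_reads_S = sc$total_reads_S[1L], occupancy_n = 0L,
                       total_samples_N = sc$total_samples_N[1L],
                       occupancy_frac = 0, freq_f = 0, abundance_share = 0,
                       ci = 0, stringsAsFactors = FALSE)
    sc <- rbind(as.data.frame(sc), zero)
    class(sc) <- c("core_scores", class(sc))
  }
  sc <- compute_norci(sc)
  sc$provenance <- pool$provenance[match(sc$taxon, pool$taxon)]
  sc$core <- !is.na(sc$norci) & sc$norci > norci_threshold
  sc <- sc[order(-sc$ci, sc$taxon), , drop = FALSE]
  rownames(sc) <- NULL
  res <- list(stage_label = stage_scope, n_samples = sum(sel),
              scope = scope, norci_threshold = norci_threshold,
              candidate_pool = pool, scores = sc,
              core_members = sc$taxon[sc$core])
  class(res) <- "stage_core_result"
  res
}

#' @export
print.stage_core_result <- function(x, ...) {
  cat(sprintf("stage_core_result: scope %s (%d samples, %s CI)\n",
              x$stage_label, x$n_samples, x$scope))
  cat(sprintf("  candidates: %d; core members (NorCI > %g): %s\n",
              nrow(x$candidate_pool), x$norci_threshold,
              if (length(x$core_members)) paste(x$core_members, collapse = ", ")
              else "(none)"))
  invisible(x)
}
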