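# curated marine-bacteria labels for the planted taxa so reports read like a
# real family-level amplicon analysis; generic names are generated past these
CORE_LINEAGES <- c(
  "d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Alteromonadales; f__Alteromonadaceae; g__Alteromonas",
  "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhodobacterales; f__Rhodobacteraceae; g__Sulfitobacter",
  "d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Alteromonadales; f__Marinobacteraceae; g__Marinobacter",
  "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Flavobacteriales; f__Flavobacteriaceae; g__Kordia"
)

ENRICHED_FAMILIES <- list(
  FE = c("Pseudoalteromonadaceae", "Colwelliaceae"),
  GL = c("Vibrionaceae", "Alcanivoracaceae"),
  EA = c("Saccharospirillaceae", "Shewanellaceae"),
  LA = c("Stappiaceae", "Microbacteriaceae"),
  PT = c("Bdellovibrionaceae", "Nannocystaceae"),
  JN = c("Hyphomonadaceae", "Saprospiraceae")
)

EXCLUSIVE_FAMILIES <- c(FE = "Idiomarinaceae", JN = "Methyloligellaceae")

#' Specification for the synthetic community generator
#'
#' Defines the study conditions the generator emulates: 28 larval samples
#' across the six developmental stages (FE...JN) over three rearing years,
#' with a handful of universally present high-abundance core taxa,
#' stage-enriched and stage-exclusive taxa, sparse background taxa with
#' year batch structure, organelle-contaminant features, variable lognormal
#' sequencing depth, and Dirichlet-multinomial count noise.
#'
#' All planted relative abundances are target composition weights before
#' per-sample normalization; validation requires their per-stage sum to stay
#' below 1 so the composition is feasible.
#'
#' @param samples_per_stage named integer vector of larval samples per stage;
#'   default `c(FE=5, GL=5, EA=5, LA=5, PT=4, JN=4)` (28 total).
#' @param years rearing years cycled over the samples of each stage.
#' @param n_background number of sparse background taxa; default 150.
#' @param n_universal_core number of universal core taxa; default 4.
#' @param core_mean_relabund target relative abundance of each core taxon;
#'   default 0.08.
#' @param core_occupancy per-sample presence probability of core taxa;
#'   default 1 (universal).
#' @param n_stage_enriched stage-enriched taxa per stage; default 2.
#' @param enrichment_fold fold-increase of enriched taxa in their own stage
#'   over the background level; default 20.
#' @param n_stage_exclusive stage-exclusive taxa per stage in
#'   `exclusive_stages`; default 1.
#' @param exclusive_stages stages receiving exclusive taxa; default FE and JN.
#' @param exclusive_mean_relabund target relative abundance of an exclusive
#'   taxon within its stage; default 0.40 (a dominant pioneer).
#' @param background_occupancy_prob per-sample presence probability of each
#'   background taxon; default 0.25.
#' @param background_level target relative abundance of a present background
#'   taxon; default 0.005.
#' @param year_batch_sd lognormal sd of the per-(background taxon, year)
#'   batch multipliers; default 0.5.
#' @param depth_log_mean,depth_log_sd lognormal read-depth parameters;
#'   defaults give a median depth of 20,000 reads.
#' @param overdispersion Dirichlet concentration scalar; default 50 (smaller
#'   is noisier).
#' @param organelle_frac fraction of features that are organelle
#'   contaminants; default 0.05.
#' @param organelle_level target relative abundance of each organelle
#'   feature; default 0.002.
#' @param n_seawater number of additional seawater samples (habitat
#'   `seawater`, SAR11-like taxa absent from larvae); default 0.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(samples_per_stage = c(FE = 5L, GL = 5L, EA = 5L,
                                                 LA = 5L, PT = 4L, JN = 4L),
                           years = c(2019L, 2020L, 2021L),
                           n_background = 150L,
                           n_universal_core = 4L,
                           core_mean_relabund = 0.08,
                           core_occupancy = 1.0,
                           n_stage_enriched = 2L,
                           enrichment_fold = 20,
                           n_stage_exclusive = 1L,
                           exclusive_stages = c("FE", "JN"),
                           exclusive_mean_relabund = 0.40,
                           background_occupancy_prob = 0.25,
                           background_level = 0.005,
                           year_batch_sd = 0.5,
                           depth_log_mean = log(20000),
                           depth_log_sd = 0.3,
                           overdispersion = 50,
                           organelle_frac = 0.05,
                           organelle_level = 0.002,
                           n_seawater = 0L,
                           seed = 1L) {
  spec <- list(samples_per_stage = samples_per_stage, years = years,
               n_background = as.integer(n_background),
               n_universal_core = as.integer(n_universal_core),
               core_mean_relabund = core_mean_relabund,
               core_occupancy = core_occupancy,
               n_stage_enriched = as.integer(n_stage_enriched),
               enrichment_fold = enrichment_fold,
               n_stage_exclusive = as.integer(n_stage_exclusive),
               exclusive_stages = exclusive_stages,
               exclusive_mean_relabund = exclusive_mean_relabund,
               background_occupancy_prob = background_occupancy_prob,
               background_level = background_level,
               year_batch_sd = year_batch_sd,
               depth_log_mean = depth_log_mean,
               depth_log_sd = depth_log_sd,
               overdispersion = overdispersion,
               organelle_frac = organelle_frac,
               organelle_level = organelle_level,
               n_seawater = as.integer(n_seawater),
               seed = as.integer(seed))
  probs <- c(core_occupancy = core_occupancy,
             background_occupancy_prob = background_occupancy_prob,
             organelle_frac = organelle_frac)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop("probabilities outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(c(spec$n_background, spec$n_universal_core, spec$n_stage_enriched,
            spec$n_stage_exclusive, spec$n_seawater, samples_per_stage) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (is.null(names(samples_per_stage)) ||
      !all(names(samples_per_stage) %in% STAGES)) {
    stop("samples_per_stage must be named with stage labels (",
         paste(STAGES, collapse = ", "), ")", call. = FALSE)
  }
  # feasibility: planted target abundances must leave room for the rest
  for (st in names(samples_per_stage)) {
    planted <- spec$n_universal_core * core_mean_relabund +
      spec$n_stage_enriched * background_level * enrichment_fold +
      (st %in% exclusive_stages) * spec$n_stage_exclusive *
        exclusive_mean_relabund
    if (planted >= 1) {
      stop(sprintf(
        "infeasible composition: planted mean relative abundances sum to %.3f >= 1 at stage %s",
        planted, st), call. = FALSE)
    }
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds, for each sample, an expected composition (universal cores at their
#' target abundance, stage-enriched taxa boosted `enrichment_fold`-fold in
#' their own stage, stage-exclusive taxa present only in their stage,
#' background taxa present per Bernoulli draw with year-specific batch
#' multipliers, organelle contaminants at a low constant level), draws the
#' realized composition from a Dirichlet with concentration
#' `overdispersion * expected`, draws a lognormal sequencing depth, and
#' finally draws counts from a multinomial. Organelle features receive
#' lineages containing "Chloroplast"/"Mitochondria"; planted cores receive
#' recognizable marine family labels.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` ([feature_table()]), `taxonomy`
#'   (taxonomy_map data.frame), `metadata` (data.frame) and `truth`
#'   (data.frame of feature_id, family, role, stage) where role is one of
#'   `universal_core`, `stage_enriched`, `stage_exclusive`, `background`,
#'   `organelle`, `seawater`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, .generate_dataset_impl(spec))
}

.generate_dataset_impl <- function(spec) {
  stages <- names(spec$samples_per_stage)

  ## ---- sample metadata -------------------------------------------------
  stage_vec <- rep(stages, times = spec$samples_per_stage)
  n_larva <- length(stage_vec)
  year_vec <- unlist(lapply(spec$samples_per_stage, function(k) {
    rep_len(spec$years, k)
  }), use.names = FALSE)
  sample_id <- sprintf("S%02d", seq_len(n_larva))
  metadata <- data.frame(sample_id = sample_id, stage = stage_vec,
                         year = year_vec, habitat = "larva",
                         gut_dev = unname(DEFAULT_GUTDEV_MAP[stage_vec]),
                         stringsAsFactors = FALSE)
  if (spec$n_seawater > 0L) {
    sw_stage <- rep_len(stages, spec$n_seawater)
    metadata <- rbind(metadata, data.frame(
      sample_id = sprintf("SW%02d", seq_len(spec$n_seawater)),
      stage = sw_stage, year = rep_len(spec$years, spec$n_seawater),
      habitat = "seawater", gut_dev = unname(DEFAULT_GUTDEV_MAP[sw_stage]),
      stringsAsFactors = FALSE))
  }

  ## ---- feature roster --------------------------------------------------
  roster <- list()
  add <- function(role, family, order, stage = NA_character_,
                  lineage = NULL) {
    roster[[length(roster) + 1L]] <<- list(role = role, family = family,
                                           order = order, stage = stage,
                                           lineage = lineage)
  }
  for (i in seq_len(spec$n_universal_core)) {
    if (i <= length(CORE_LINEAGES)) {
      lin <- CORE_LINEAGES[i]
      fam <- sub(".*f__([^;]+);.*", "\\1", lin)
      add("universal_core", fam, NA, lineage = lin)
    } else {
      add("universal_core", sprintf("CoreFamily%02d", i),
          sprintf("CoreOrder%02d", i))
    }
  }
  for (st in stages) {
    known <- ENRICHED_FAMILIES[[st]]
    for (i in seq_len(spec$n_stage_enriched)) {
      fam <- if (!is.null(known) && i <= length(known)) known[i] else
        sprintf("%sEnrichedFamily%02d", st, i)
      add("stage_enriched", fam, sprintf("%sEnrichedOrder%02d", st, i),
          stage = st)
    }
  }
  for (st in intersect(spec$exclusive_stages, stages)) {
    for (i in seq_len(spec$n_stage_exclusive)) {
      fam <- if (i == 1L && st %in% names(EXCLUSIVE_FAMILIES)) {
        EXCLUSIVE_FAMILIES[[st]]
      } else {
        sprintf("%sExclusiveFamily%02d", st, i)
      }
      add("stage_exclusive", fam, sprintf("%sExclusiveOrder%02d", st, i),
          stage = st)
    }
  }
  for (i in seq_len(spec$n_background)) {
    add("background", sprintf("BgFamily%03d", i),
        sprintf("BgOrder%02d", 1L + (i - 1L) %% 30L))
  }
  n_planted <- length(roster)
  n_org <- round(spec$organelle_frac * n_planted / (1 - spec$organelle_frac))
  for (i in seq_len(n_org)) {
    if (i %% 2L == 1L) {
      add("organelle", "Chloroplast", "Chloroplast",
          lineage = "d__Bacteria; p__Cyanobacteria; c__Cyanobacteriia; o__Chloroplast; f__Chloroplast")
    } else {
      add("organelle", "Mitochondria", "Rickettsiales",
          lineage = "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__Mitochondria")
    }
  }
  if (spec$n_seawater > 0L) {
    add("seawater", "Clade_I", "SAR11_clade",
        lineage = "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__SAR11_clade; f__Clade_I; g__Clade_Ia")
    add("seawater", "Clade_II", "SAR11_clade",
        lineage = "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__SAR11_clade; f__Clade_II")
  }

  K <- length(roster)
  feature_id <- sprintf("ASV%04d", seq_len(K))
  role <- vapply(roster, `[[`, character(1L), "role")
  family <- vapply(roster, `[[`, character(1L), "family")
  stage_of <- vapply(roster, function(r) as.character(r$stage), character(1L))
  lineage <- vapply(seq_len(K), function(i) {
    r <- roster[[i]]
    if (!is.null(r$lineage)) return(r$lineage)
    # ~10% of background lineages stop at order to exercise rank collapse
    if (r$role == "background" && i %% 10L == 0L) {
      sprintf("d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__%s",
              r$order)
    } else {
      sprintf("d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__%s; f__%s; g__Genus%04d",
              r$order, r$family, i)
    }
  }, character(1L))
  taxonomy <- parse_lineages(feature_id, lineage,
                             round(stats::runif(K, 0.85, 1), 3))

  ## ---- per-sample composition and counts -------------------------------
  is_core <- role == "universal_core"
  is_enr <- role == "stage_enriched"
  is_exc <- role == "stage_exclusive"
  is_bg <- role == "background"
  is_org <- role == "organelle"
  is_sw <- role == "seawater"
  bg_idx <- which(is_bg)
  year_mult <- matrix(
    exp(stats::rnorm(length(bg_idx) * length(spec$years), 0,
                     spec$year_batch_sd)),
    nrow = length(bg_idx),
    dimnames = list(NULL, as.character(spec$years)))

  n_samples <- nrow(metadata)
  counts <- matrix(0, nrow = K, ncol = n_samples,
                   dimnames = list(feature_id, metadata$sample_id))
  for (j in seq_len(n_samples)) {
    st <- metadata$stage[j]
    yr <- as.character(metadata$year[j])
    w <- numeric(K)
    if (metadata$habitat[j] == "larva") {
      w[is_core] <- spec$core_mean_relabund *
        stats::rbinom(sum(is_core), 1L, spec$core_occupancy)
      w[is_enr] <- spec$background_level *
        ifelse(stage_of[is_enr] == st, spec$enrichment_fold, 1)
      w[is_exc] <- ifelse(stage_of[is_exc] == st,
                          spec$exclusive_mean_relabund, 0)
      w[is_bg] <- spec$background_level * year_mult[, yr] *
        stats::rbinom(length(bg_idx), 1L, spec$background_occupancy_prob)
      w[is_org] <- spec$organelle_level
    } else {
      # seawater: SAR11-like dominance over a background community
      w[is_sw] <- 0.3
      w[is_bg] <- spec$background_level * year_mult[, yr] *
        stats::rbinom(length(bg_idx), 1L, spec$background_occupancy_prob)
      w[is_org] <- spec$organelle_level
    }
    w <- w / sum(w)
    pos <- w > 0
    alpha <- spec$overdispersion * w[pos]
    comp <- stats::rgamma(sum(pos), shape = alpha, rate = 1)
    if (all(comp == 0)) comp[] <- w[pos]  # pathological gamma underflow guard
    comp <- comp / sum(comp)
    depth <- max(1000L, round(stats::rlnorm(1L, spec$depth_log_mean,
                                            spec$depth_log_sd)))
    counts[pos, j] <- stats::rmultinom(1L, depth, comp)[, 1L]
  }

  truth <- data.frame(feature_id = feature_id, family = family, role = role,
                      stage = stage_of, stringsAsFactors = FALSE)
  list(table = feature_table(counts), taxonomy = taxonomy,
       metadata = metadata, truth = truth, spec = spec)
}

#' Precision/recall of core recovery against planted truth
#'
#' Compares the taxa called core by the pipeline against the planted roles of
#' the synthetic generator, per role. Precision is `NA` when nothing was
#' predicted (no false sense of perfection from an empty call).
#'
#' @param predicted character vector of taxa called core (e.g.
#'   `subset(scores, core_label == "core")$taxon`, or a
#'   `stage_core_result$core_members`).
#' @param truth the `truth` data.frame from [generate_dataset()].
#' @param role planted role to evaluate against; default `"universal_core"`.
#' @param stage restrict the expected set to one stage (for stage-core
#'   calls); default `NULL` (no restriction).
#' @param level truth column the predictions are expressed in:
#'   `"family"` (default, for collapsed tables) or `"feature_id"`.
#' @return one-row data.frame: role, n_expected, n_predicted,
#'   true_positives, precision, recall.
#' @export
recovery_report <- function(predicted, truth, role = "universal_core",
                            stage = NULL, level = c("family", "feature_id")) {
  level <- match.arg(level)
  predicted <- unique(as.character(predicted))
  if (length(predicted) &&
      !any(predicted %in% unique(truth[[level]]))) {
    stop("predicted taxa share nothing with the truth universe; ",
         "was the right `level` used?", call. = FALSE)
  }
  keep <- truth$role == role
  if (!is.null(stage)) keep <- keep & !is.na(truth$stage) &
      truth$stage == stage
  expected <- unique(truth[[level]][keep])
  tp <- length(intersect(predicted, expected))
  data.frame(role = role,
             n_expected = length(expected),
             n_predicted = length(predicted),
             true_positives = tp,
             precision = if (length(predicted)) tp / length(predicted)
                         else NA_real_,
             recall = if (length(expected)) tp / length(expected)
                      else NA_real_,
             stringsAsFactors = FALSE)
}
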