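PIPELINE_DEFAULTS <- list(
  simulate = NULL,          # TRUE / synthetic_spec argument list / NULL
  feature_table = NULL,     # input TSV paths when not simulating
  taxonomy = NULL,
  metadata = NULL,
  orientation = "features_as_rows",
  ranks = c("order", "family", "genus", "asv"),
  top_k = 20L,
  cum_threshold = 0.75,
  occ_threshold = 0.70,
  norci_threshold = 0.3,
  f_definition = "rel_freq",
  alpha = 0.05,
  effect_threshold = 3.5,
  adjust_p = FALSE,
  organelle_patterns = c("mitochondri", "chloroplast"),
  rarefy = TRUE,
  rarefaction_depth = NULL, # NULL = dataset minimum sample total
  reproduction_mode = FALSE,
  stage_scopes = c("FE", "JN", "preGD", "postGD"),
  stage_scope_mode = "restricted",
  seed = 1L
)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a path to a YAML/JSON file, injects the default
#' thresholds (cumulative abundance 0.75, occupancy 0.70, NorCI 0.3, top-20
#' evaluation set) and rejects contradictions. In reproduction mode the
#' rarefaction depth defaults to 5683 reads per sample, the depth used for
#' the original larval dataset.
#'
#' @param config named list, or path to a YAML (or JSON) config file, or
#'   `NULL` for all defaults with simulation enabled.
#' @param strict reject unknown keys (default TRUE); otherwise drop them with
#'   a warning.
#' @return a normalized `corescope_config` list.
#' @export
validate_config <- function(config = NULL, strict = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list(simulate = TRUE)
  if (inherits(config, "corescope_config")) config <- unclass(config)
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config, keep.null = TRUE)
  if (isTRUE(cfg$simulate)) cfg$simulate <- list()
  # JSON/YAML round-trips deliver character vectors as lists
  for (key in c("ranks", "stage_scopes", "organelle_patterns")) {
    cfg[[key]] <- unlist(cfg[[key]], use.names = FALSE)
  }
  for (key in c("cum_threshold", "occ_threshold", "norci_threshold")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop(sprintf("%s = %s is outside (0, 1]", key,
                   paste(v, collapse = ",")), call. = FALSE)
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  cfg$ranks <- match.arg(cfg$ranks, c("order", "family", "genus", "asv"),
                         several.ok = TRUE)
  cfg$f_definition <- match.arg(cfg$f_definition, c("rel_freq", "occupancy"))
  cfg$stage_scope_mode <- match.arg(cfg$stage_scope_mode,
                                    c("restricted", "global"))
  bad_scope <- setdiff(cfg$stage_scopes, c(STAGES, "preGD", "postGD", "all"))
  if (length(bad_scope)) {
    stop("unknown stage scope(s): ", paste(bad_scope, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(cfg$reproduction_mode) && is.null(cfg$rarefaction_depth)) {
    cfg$rarefaction_depth <- 5683L
  }
  cfg$top_k <- as.integer(cfg$top_k)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$simulate)) {
    for (key in c("feature_table", "taxonomy", "metadata")) {
      if (is.null(cfg[[key]])) {
        stop("config needs either a `simulate` block or input paths; '",
             key, "' is missing", call. = FALSE)
      }
    }
  }
  class(cfg) <- "corescope_config"
  cfg
}

#' Run the full core-extraction pipeline
#'
#' Orchestrates organelle filtering, optional rarefaction, rank collapse,
#' hybrid core classification and stage-core extraction from one
#' configuration, writing per-rank core reports, per-scope stage-core
#' reports, a machine-readable run manifest (all normalized parameters, seed
#' and input checksums) and a human-readable summary into `out_dir`. The run
#' is fully deterministic: identical config and inputs give byte-identical
#' output files, and the manifest's `config` entry alone suffices to replay
#' the run.
#'
#' @param config anything accepted by [validate_config()].
#' @param out_dir output directory (created, must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with the run `manifest`, per-rank `core`
#'   score tables and per-scope `stage` results.
#' @export
run_pipeline <- function(config = NULL, out_dir, overwrite = FALSE) {
  cfg <- validate_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(out_dir, "inputs")
  dir.create(input_dir, showWarnings = FALSE)

  ## ---- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = cfg$seed),
                                      as.list(cfg$simulate)))
    ds <- generate_dataset(spec)
    table <- ds$table
    taxonomy <- ds$taxonomy
    metadata <- ds$metadata
    write_feature_table(table, file.path(input_dir, "feature_table.tsv"))
    utils::write.table(ds$taxonomy[, c("feature_id", "taxonomy",
                                       "confidence")],
                       file.path(input_dir, "taxonomy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(metadata, file.path(input_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ds$truth, file.path(input_dir, "planted_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    input_paths <- file.path(input_dir, c("feature_table.tsv", "taxonomy.tsv",
                                          "metadata.tsv"))
  } else {
    for (key in c("feature_table", "taxonomy", "metadata")) {
      if (!file.exists(cfg[[key]])) {
        stop("input path does not exist: ", cfg[[key]],
             " (config key '", key, "')", call. = FALSE)
      }
    }
    table <- read_feature_table(cfg$feature_table, cfg$orientation)
    taxonomy <- read_taxonomy(cfg$taxonomy)
    metadata <- read_metadata(cfg$metadata)
    input_paths <- c(cfg$feature_table, cfg$taxonomy, cfg$metadata)
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("input: %d features x %d samples, %d reads", nrow(table), ncol(table),
      sum(table))

  ## ---- preprocess ------------------------------------------------------
  filtered <- filter_organelles(table, taxonomy,
                                patterns = cfg$organelle_patterns)
  removed <- attr(filtered, "removed")
  say("organelle filter: removed %d feature(s), %d reads", nrow(removed),
      sum(removed$reads))
  depth_used <- NA_integer_
  if (isTRUE(cfg$rarefy)) {
    depth_used <- if (is.null(cfg$rarefaction_depth)) {
      as.integer(min(colSums(ft_counts(filtered))))
    } else {
      as.integer(cfg$rarefaction_depth)
    }
    before <- ncol(filtered)
    filtered <- rarefy(filtered, depth_used, seed = cfg$seed)
    say("rarefaction: depth %d, %d of %d samples retained", depth_used,
        ncol(filtered), before)
  }
  metadata <- metadata[metadata$sample_id %in% colnames(filtered), ,
                       drop = FALSE]

  ## ---- per-rank core classification ------------------------------------
  core_results <- list()
  for (rank in cfg$ranks) {
    tb <- collapse_rank(filtered, taxonomy, rank)
    scores <- classify_core(tb, top_k = cfg$top_k,
                            cum_threshold = cfg$cum_threshold,
                            occ_threshold = cfg$occ_threshold,
                            norci_threshold = cfg$norci_threshold,
                            f_definition = cfg$f_definition)
    params <- c(attr(scores, "params"),
                list(rank = rank, seed = cfg$seed,
                     rarefaction_depth = depth_used))
    write_core_report(scores, file.path(out_dir,
                                        sprintf("core_%s.tsv", rank)),
                      params = params)
    core_results[[rank]] <- scores
    say("rank %s: %d taxa, core = {%s}", rank, nrow(tb),
        paste(scores$taxon[scores$core_label == "core"], collapse = ", "))
  }

  ## ---- stage cores (family rank) ---------------------------------------
  fam <- collapse_rank(filtered, taxonomy, "family")
  rel <- to_relative(fam)
  stage_results <- list()
  for (sc in cfg$stage_scopes) {
    pool <- NULL
    if (sc %in% STAGES) {
      enr <- enrichment_screen(rel, metadata, target_class = sc,
                               alpha = cfg$alpha,
                               effect_threshold = cfg$effect_threshold,
                               adjust = cfg$adjust_p)
      excl <- detect_exclusive_taxa(fam, metadata, sc)
      pool <- assemble_candidate_pool(enr, excl)
    }
    res <- stage_core_extraction(fam, metadata, sc, pool = pool,
                                 norci_threshold = cfg$norci_threshold,
                                 top_k = cfg$top_k,
                                 f_definition = cfg$f_definition,
                                 scope = cfg$stage_scope_mode)
    rep_df <- res$scores
    utils::write.table(rep_df,
                       file.path(out_dir, sprintf("stage_core_%s.tsv", sc)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_results[[sc]] <- res
    say("stage scope %s: pool %d, core = {%s}", sc, nrow(res$candidate_pool),
        paste(res$core_members, collapse = ", "))
  }

  ## ---- manifest and summary --------------------------------------------
  manifest <- list(
    package = "corescope",
    version = as.character(utils::packageVersion("corescope")),
    config = unclass(cfg),
    rarefaction_depth_used = depth_used,
    input_checksums = stats::setNames(as.list(unname(tools::md5sum(input_paths))),
                                      basename(input_paths)),
    outputs = sort(grep("^inputs/", dir(out_dir, recursive = TRUE),
                        value = TRUE, invert = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out_dir, "summary.txt"))
  invisible(list(manifest = manifest, core = core_results,
                 stage = stage_results, dir = out_dir))
}
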