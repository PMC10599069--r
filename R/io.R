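#' Read a feature table from TSV
#'
#' Reads a tab-separated count table with a header row and identifiers in the
#' first column. Both orientations produced by common amplicon pipelines are
#' accepted; the internal canonical orientation is always features x samples.
#' BIOM-compatible dense TSV exports are tolerated: leading `#`-prefixed
#' comment lines are skipped and a header line itself beginning with `#`
#' (e.g. `#OTU ID`) is used after stripping the marker.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows",
                                               "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop("parse error: empty file: ", path, call. = FALSE)
  }
  # drop comment preamble; the last '#'-line before data may itself be the header
  while (length(lines) >= 2L && startsWith(lines[1L], "#") &&
         startsWith(lines[2L], "#")) {
    lines <- lines[-1L]
  }
  if (startsWith(lines[1L], "#")) {
    lines[1L] <- sub("^#\\s*", "", lines[1L])
  }
  if (length(lines) < 2L) {
    stop("parse error: no data rows in ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    stop("parse error: header must contain an id column and >= 1 sample",
         call. = FALSE)
  }
  body <- fields[-1L]
  ragged <- which(lengths(body) != length(header))
  if (length(ragged)) {
    stop(sprintf("parse error: ragged row(s) at line(s) %s of %s",
                 paste(ragged + 1L, collapse = ", "), path), call. = FALSE)
  }
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE)),
           nrow = length(body), byrow = TRUE)
  )
  if (anyNA(vals)) {
    stop("parse error: non-numeric count cell(s) in ", path, call. = FALSE)
  }
  dimnames(vals) <- list(row_ids, header[-1L])
  if (orientation == "samples_as_rows") vals <- t(vals)
  feature_table(vals)
}

#' Write a feature table to TSV
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @param id_column name for the identifier column of the header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  x <- as_feature_table(x)
  df <- data.frame(rownames(x), ft_counts(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Developmental stage labels
#'
#' The six larval developmental stages, in ontogenetic order: fertilized egg
#' (FE), gastrula (GL), early auricularia (EA), late auricularia (LA),
#' pentactula (PT) and juvenile (JN).
#' @export
STAGES <- c("FE", "GL", "EA", "LA", "PT", "JN")

#' Default stage to gut-development mapping
#'
#' The microbiota changes between the EA and LA stages, when the gut develops
#' and feeding starts; samples are therefore grouped as pre-gut-development
#' (preGD: FE, GL, EA) and post-gut-development (postGD: LA, PT, JN).
#' @export
DEFAULT_GUTDEV_MAP <- c(FE = "preGD", GL = "preGD", EA = "preGD",
                        LA = "postGD", PT = "postGD", JN = "postGD")

#' Read sample metadata from TSV
#'
#' Expects a header with at least sample-id and stage columns (names
#' configurable). QIIME-style `#q2:types` comment lines are tolerated, as is a
#' leading `#` on the header line. When the file lacks a gut-development
#' column, it is derived from the stage via `stage_to_gutdev`; when present,
#' larval records are checked for consistency with the mapping.
#'
#' @param path path to a TSV file.
#' @param stage_to_gutdev named character vector mapping stage to
#'   `"preGD"`/`"postGD"`; default [DEFAULT_GUTDEV_MAP].
#' @param sample_col,stage_col,year_col,habitat_col,gutdev_col column names.
#' @return a data.frame with columns `sample_id`, `stage`, `year`, `habitat`,
#'   `gut_dev`.
#' @export
read_metadata <- function(path, stage_to_gutdev = DEFAULT_GUTDEV_MAP,
                          sample_col = "sample_id", stage_col = "stage",
                          year_col = "year", habitat_col = "habitat",
                          gutdev_col = "gut_dev") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty metadata file", call. = FALSE)
  lines <- lines[!startsWith(lines, "#q2:types")]
  lines[1L] <- sub("^#\\s*", "", lines[1L])
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c(sample_col, stage_col)) {
    if (!col %in% names(df)) {
      stop("metadata is missing required column '", col, "'", call. = FALSE)
    }
  }
  sample_id <- trimws(df[[sample_col]])
  if (any(!nzchar(sample_id))) {
    stop("metadata has row(s) with a missing sample id", call. = FALSE)
  }
  .check_unique(sample_id, "sample")
  stage <- trimws(df[[stage_col]])
  bad <- setdiff(unique(stage), STAGES)
  if (length(bad)) {
    stop(sprintf("unknown stage label(s) %s; allowed stages: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(STAGES, collapse = ", ")), call. = FALSE)
  }
  year <- if (year_col %in% names(df)) {
    suppressWarnings(as.integer(df[[year_col]]))
  } else {
    NA_integer_
  }
  habitat <- if (habitat_col %in% names(df)) trimws(df[[habitat_col]]) else "larva"
  bad_hab <- setdiff(unique(habitat), c("larva", "seawater"))
  if (length(bad_hab)) {
    stop(sprintf("unknown habitat label(s) %s; allowed: larva, seawater",
                 paste(sQuote(bad_hab), collapse = ", ")), call. = FALSE)
  }
  if (!all(STAGES %in% names(stage_to_gutdev))) {
    stop("stage_to_gutdev must map every stage (",
         paste(STAGES, collapse = ", "), ")", call. = FALSE)
  }
  derived <- unname(stage_to_gutdev[stage])
  if (gutdev_col %in% names(df)) {
    gut_dev <- trimws(df[[gutdev_col]])
    bad_gd <- setdiff(unique(gut_dev), c("preGD", "postGD"))
    if (length(bad_gd)) {
      stop(sprintf("unknown gut_dev label(s) %s; allowed: preGD, postGD",
                   paste(sQuote(bad_gd), collapse = ", ")), call. = FALSE)
    }
    clash <- habitat == "larva" & gut_dev != derived
    if (any(clash)) {
      stop(sprintf(
        "gut_dev inconsistent with stage mapping for sample(s): %s",
        paste(sample_id[clash], collapse = ", ")), call. = FALSE)
    }
  } else {
    gut_dev <- derived
  }
  data.frame(sample_id = sample_id, stage = stage, year = year,
             habitat = habitat, gut_dev = gut_dev,
             stringsAsFactors = FALSE)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

# canonicalize raw semicolon-delimited lineages into one column per rank;
# rank prefixes such as "f__" are stripped, empties and "Unassigned" become NA
parse_lineages <- function(feature_id, taxonomy, confidence = NA_real_) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  canon <- matrix(NA_character_, nrow = length(parts), ncol = 7L,
                  dimnames = list(NULL, TAX_RANKS))
  warned <- FALSE
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[A-Za-z]__", "", p)
    p[!nzchar(p) | tolower(p) %in% c("unassigned", "na")] <- NA_character_
    if (length(p) > 7L) {
      if (!warned) {
        warning(sprintf("lineage with > 7 ranks for '%s'; extra ranks ignored",
                        feature_id[i]), call. = FALSE)
        warned <- TRUE
      }
      p <- p[seq_len(7L)]
    }
    if (length(p)) canon[i, seq_along(p)] <- p
  }
  out <- data.frame(feature_id = feature_id, taxonomy = taxonomy,
                    confidence = as.numeric(confidence), canon,
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_map", class(out))
  out
}

#' Read a taxonomy map from TSV
#'
#' QIIME-style 2-3 column TSV: feature id, semicolon-delimited lineage,
#' optional confidence. The raw lineage string is retained alongside a
#' canonical per-rank form (surrounding whitespace and `f__`-style prefixes
#' stripped, missing ranks as `NA`). A header row is detected from its first
#' field. Lineages deeper than 7 ranks trigger a warning and are truncated.
#' The reader performs no filtering: contaminant labels such as "Chloroplast"
#' are retained verbatim for [filter_organelles()] to act on downstream.
#'
#' @param path path to a TSV file.
#' @return a `taxonomy_map` data.frame with columns `feature_id`, `taxonomy`,
#'   `confidence` and one column per rank (`domain` ... `species`).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty taxonomy file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(sub("^#", "", fields[[1L]][1L])))
  if (first %in% c("feature id", "feature_id", "otu id", "otu_id", "id",
                   "feature-id")) {
    fields <- fields[-1L]
  }
  if (!length(fields)) stop("parse error: taxonomy has no records", call. = FALSE)
  if (any(lengths(fields) < 2L)) {
    stop("parse error: taxonomy rows need (feature id, lineage)", call. = FALSE)
  }
  id <- vapply(fields, `[[`, character(1L), 1L)
  lineage <- vapply(fields, `[[`, character(1L), 2L)
  conf <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[[3L]])) else NA_real_
  }, numeric(1L))
  .check_unique(id, "feature")
  parse_lineages(id, lineage, conf)
}

# resolve table features against a taxonomy map according to the mismatch
# policy; returns row indices into `taxonomy` (NA for unassigned rows)
match_taxonomy <- function(table, taxonomy,
                           missing = c("error", "unassigned")) {
  missing <- match.arg(missing)
  idx <- match(rownames(table), taxonomy$feature_id)
  if (anyNA(idx) && missing == "error") {
    lost <- rownames(table)[is.na(idx)]
    stop(sprintf("feature(s) missing from taxonomy: %s%s",
                 paste(utils::head(lost, 5L), collapse = ", "),
                 if (length(lost) > 5L) sprintf(" (+%d more)", length(lost) - 5L)
                 else ""), call. = FALSE)
  }
  idx
}

#' Write a core-microbiome report
#'
#' Writes one row per scored taxon (reads, occupancy, abundance share,
#' criterion flags, CI, NorCI, final core label) as a TSV, plus a JSON sidecar
#' (`<path-minus-extension>_params.json`) recording the run parameters
#' (thresholds, seed, rarefaction depth, ...). Numeric fields round-trip
#' through [read_core_report()] at full double precision.
#'
#' @param scores a `core_scores` data.frame from [classify_core()] (or any
#'   non-empty data.frame of per-taxon scores).
#' @param path output TSV path.
#' @param params named list of run parameters for the sidecar; defaults to the
#'   `params` attribute of `scores`.
#' @return `path`, invisibly.
#' @export
write_core_report <- function(scores, path, params = attr(scores, "params")) {
  if (is.null(scores) || !nrow(scores)) {
    stop("empty score collection: nothing to report", call. = FALSE)
  }
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), "_params.json")
  if (is.null(params)) params <- list()
  jsonlite::write_json(params, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a core-microbiome report
#'
#' @param path TSV written by [write_core_report()].
#' @return a data.frame.
#' @export
read_core_report <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a plain list of taxa (one per line)
#'
#' Used to supply an externally computed candidate list (for example a genuine
#' LEfSe output) to [assemble_candidate_pool()].
#'
#' @param path text file with one taxon name per line; blank lines and
#'   `#` comments are ignored.
#' @return character vector.
#' @export
read_taxa_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
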