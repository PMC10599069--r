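# full-enumeration oracle for two-group permutation p-values, written
# independently of the implementation: ranks via rank(), statistic via
# stats::kruskal.test on every combn() split
oracle_two_group_p <- function(x, sizes) {
  n <- length(x)
  g_obs <- factor(rep(1:2, times = sizes))
  obs <- unname(suppressWarnings(stats::kruskal.test(x, g_obs)$statistic))
  splits <- utils::combn(n, sizes[1], simplify = FALSE)
  stats <- vapply(splits, function(idx) {
    g <- factor(ifelse(seq_len(n) %in% idx, 1L, 2L))
    unname(suppressWarnings(stats::kruskal.test(x, g)$statistic))
  }, numeric(1))
  mean(stats >= obs - 1e-12)
}

screen_md <- function(per_stage) make_metadata(per_stage)

rel_matrix <- function(values, sample_ids, taxa = "tax1") {
  m <- matrix(values, nrow = length(taxa), byrow = TRUE,
              dimnames = list(taxa, sample_ids))
  m
}

test_that("exact permutation p matches the textbook separated case", {
  md <- screen_md(c(FE = 4L, GL = 4L))
  rel <- rel_matrix(c(1, 2, 3, 4, 10, 11, 12, 13), md$sample_id)
  kw <- kruskal_wallis_screen(rel, md, grouping = "stage")
  expect_equal(kw$method, "exact_permutation")
  expect_equal(kw$p_value, 2 / 70)
})

test_that("exact permutation p agrees with the enumeration oracle", {
  designs <- list(c(FE = 2L, GL = 2L), c(FE = 3L, GL = 3L),
                  c(FE = 4L, GL = 4L), c(FE = 5L, GL = 5L),
                  c(FE = 3L, GL = 5L), c(FE = 2L, GL = 7L))
  for (d in designs) {
    md <- screen_md(d)
    for (rep in 1:3) {
      x <- withr::with_seed(sum(d) * 10 + rep, round(stats::runif(sum(d)), 2))
      rel <- rel_matrix(x, md$sample_id)
      kw <- kruskal_wallis_screen(rel, md, grouping = "stage")
      expect_equal(kw$p_value, oracle_two_group_p(x, unname(d)),
                   tolerance = 1e-12,
                   info = paste("design", paste(d, collapse = "/")))
    }
  }
})

test_that("degenerate and multi-group screens behave", {
  md <- screen_md(c(FE = 3L, GL = 3L, EA = 3L))
  # identical values in every sample: statistic 0, p = 1
  rel <- rel_matrix(rep(0.2, 9), md$sample_id)
  kw <- kruskal_wallis_screen(rel, md, grouping = "stage")
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)

  # three identical groups of distinct values: never significant
  rel2 <- rel_matrix(rep(c(0.1, 0.2, 0.3), 3), md$sample_id)
  kw2 <- kruskal_wallis_screen(rel2, md, grouping = "stage")
  expect_gt(kw2$p_value, 0.05)

  md_bad <- screen_md(c(FE = 1L, GL = 4L))
  expect_error(kruskal_wallis_screen(rel_matrix(1:5, md_bad$sample_id),
                                     md_bad, "stage"),
               "fewer than 2 samples: FE")
})

test_that("asymptotic branch reproduces kruskal.test and is order-invariant", {
  md <- screen_md(c(FE = 5L, GL = 5L, EA = 4L))
  x <- withr::with_seed(3, stats::runif(14))
  rel <- rel_matrix(x, md$sample_id)
  kw <- kruskal_wallis_screen(rel, md, grouping = "stage")
  ref <- stats::kruskal.test(x, factor(md$stage))
  expect_equal(kw$method, "chisq_approx")
  expect_equal(kw$statistic, unname(ref$statistic))
  expect_equal(kw$p_value, ref$p.value)

  shuffle <- withr::with_seed(4, sample(ncol(rel)))
  kw2 <- kruskal_wallis_screen(rel[, shuffle, drop = FALSE], md, "stage")
  expect_equal(kw2$p_value, kw$p_value)
})

test_that("effect score follows the 1e6-scaled log10 mean difference", {
  md <- screen_md(c(FE = 5L, GL = 5L))
  rel <- rbind(strong = c(rep(0.10, 5), rep(0.002, 5)),
               weak = c(rep(0.008, 5), rep(0.002, 5)),
               flat = rep(0.05, 10))
  colnames(rel) <- md$sample_id
  ef <- effect_size_score(rel, md, target_class = "FE")
  expect_equal(ef$effect_score[1], log10(1 + 0.098e6 / 2), tolerance = 1e-12)
  expect_gte(ef$effect_score[1], 3.5)
  expect_equal(ef$effect_score[2], log10(1 + 3000), tolerance = 1e-12)
  expect_lt(ef$effect_score[2], 3.5)
  expect_equal(ef$effect_score[3], 0)
  expect_equal(ef$direction, c("up", "up", "none"))
})

test_that("stage-exclusive detection requires presence inside, absence outside", {
  md <- screen_md(c(FE = 2L, GL = 2L))
  m <- rbind(fe_only = c(3, 0, 0, 0),
             shared = c(2, 0, 1, 0),
             nowhere = c(0, 0, 0, 0),
             gl_only = c(0, 0, 0, 5))
  colnames(m) <- md$sample_id
  ft <- feature_table(m)
  expect_equal(detect_exclusive_taxa(ft, md, "FE"), "fe_only")
  expect_equal(detect_exclusive_taxa(ft, md, "GL"), "gl_only")

  # seawater samples never veto exclusivity
  md_sw <- rbind(md, data.frame(sample_id = "W1", stage = "GL", year = 2019L,
                                habitat = "seawater", gut_dev = "preGD"))
  m_sw <- cbind(m, W1 = c(9, 0, 0, 0))
  expect_equal(detect_exclusive_taxa(feature_table(m_sw), md_sw, "FE"),
               "fe_only")
})

test_that("candidate pools union sources with provenance tags", {
  enr <- data.frame(taxon = c("Pseudoalteromonadaceae", "Colwelliaceae",
                              "Shewanellaceae", "Idiomarinaceae"),
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  excl <- c("Idiomarinaceae", "Fusobacteriaceae", "Moraxellaceae")
  pool <- assemble_candidate_pool(enr, excl)
  expect_equal(nrow(pool), 6L)
  expect_setequal(pool$provenance[pool$taxon == "Idiomarinaceae"], "exclusive")

  both <- assemble_candidate_pool(c("A", "B"), c("B", "C"))
  expect_equal(both$provenance[both$taxon == "B"], "both")

  ext <- assemble_candidate_pool(supplied = c("X", "Y"))
  expect_equal(ext$provenance, c("supplied", "supplied"))

  expect_error(assemble_candidate_pool(), "empty candidate pool")
})

test_that("stage core extraction scores the pool on scope samples", {
  md <- screen_md(c(FE = 3L, GL = 3L))
  m <- rbind(dominant = c(40, 50, 60, 1, 0, 2),
             minor = c(5, 4, 6, 10, 12, 9),
             ghost = c(0, 0, 0, 7, 8, 6))
  colnames(m) <- md$sample_id
  ft <- feature_table(m)
  res <- stage_core_extraction(ft, md, "FE",
                               pool = c("dominant", "minor", "ghost"))
  sc <- res$scores
  # ghost is absent from every FE sample: CI = 0, NorCI = 0, not core
  expect_equal(sc$ci[sc$taxon == "ghost"], 0)
  expect_equal(sc$norci[sc$taxon == "ghost"], 0)
  expect_false(sc$core[sc$taxon == "ghost"])
  expect_equal(res$core_members, "dominant")
  # scope restriction: N and S come from the 3 FE samples only
  expect_equal(unique(sc$total_samples_N), 3L)
  expect_equal(unique(sc$total_reads_S), sum(m[, 1:3]))

  # two-candidate pool: min-max forces NorCI {0, 1}
  res2 <- stage_core_extraction(ft, md, "FE", pool = c("dominant", "minor"))
  expect_equal(sort(res2$scores$norci), c(0, 1))
  expect_equal(res2$core_members, "dominant")

  expect_error(stage_core_extraction(ft, md, "FE", pool = "dominant"),
               "fewer than 2 candidates")
  expect_error(stage_core_extraction(ft, md, "FE"), "pool is required")
})

test_that("all-sample scope with a top-k pool reproduces classify_core", {
  ds <- generate_dataset(synthetic_spec(seed = 31))
  fam <- collapse_rank(filter_organelles(ds$table, ds$taxonomy),
                       ds$taxonomy, "family")
  cc <- classify_core(fam)
  res <- stage_core_extraction(fam, ds$metadata, "all", pool = NULL)
  eval_cc <- cc[!is.na(cc$ci), c("taxon", "ci", "norci")]
  eval_sc <- res$scores[, c("taxon", "ci", "norci")]
  eval_sc <- eval_sc[match(eval_cc$taxon, eval_sc$taxon), ]
  expect_equal(eval_cc$ci, eval_sc$ci)
  expect_equal(eval_cc$norci, eval_sc$norci)
})

test_that("group scopes default to their own top-20 abundance pool", {
  ds <- generate_dataset(synthetic_spec(seed = 32))
  fam <- collapse_rank(filter_organelles(ds$table, ds$taxonomy),
                       ds$taxonomy, "family")
  res <- stage_core_extraction(fam, ds$metadata, "preGD")
  expect_equal(nrow(res$candidate_pool), 20L)
  expect_equal(unique(res$candidate_pool$provenance), "abundance")
  # universal cores dominate preGD samples too
  expect_true(all(c("Alteromonadaceae", "Rhodobacteraceae") %in%
                    res$core_members))
})
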