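test_that("organelle filter removes exactly the matching lineages", {
  ft <- make_table(rbind(c(5, 3), c(2, 8), c(1, 1)),
                   features = c("A", "B", "C"))
  tax <- make_taxonomy(
    c("A", "B", "C"),
    c("d__Bacteria; f__Rhodobacteraceae",
      "d__Bacteria; o__Chloroplast",
      "d__Bacteria; o__Rickettsiales; f__Mitochondria"))
  out <- filter_organelles(ft, tax)
  expect_equal(rownames(out), "A")
  expect_equal(attr(out, "removed")$feature_id, c("B", "C"))
  expect_equal(sum(attr(out, "removed")$reads), 12)

  # no match: identity, and idempotence on the filtered result
  none <- filter_organelles(out, tax)
  expect_identical(unclass(none)[, ], unclass(out)[, ])
  expect_equal(nrow(attr(none, "removed")), 0L)

  expect_error(filter_organelles(ft, tax, patterns = "Bacteria"),
               "all features")
})

test_that("custom patterns remove matching reads exactly (totals oracle)", {
  for (i in 1:20) {
    ft <- withr::with_seed(i, random_table(12L, 4L))
    fams <- rep(c("Rickettsiales", "Other"), length.out = 12L)
    tax <- make_taxonomy(rownames(ft), paste0("d__Bacteria; o__", fams))
    out <- filter_organelles(ft, tax, patterns = "Rickettsiales")
    kept <- rownames(ft)[fams != "Rickettsiales"]
    # direct summation oracle: output total = input total - removed reads
    removed_reads <- sum(unclass(ft)[fams == "Rickettsiales", ])
    expect_equal(sum(out), sum(ft) - removed_reads)
    expect_setequal(rownames(out), kept)
  }
})

test_that("missing taxonomy entries follow the mismatch policy", {
  ft <- make_table(rbind(c(1, 1), c(2, 2)), features = c("A", "B"))
  tax <- make_taxonomy("A", "d__Bacteria; f__Fam1")
  expect_error(filter_organelles(ft, tax), "missing from taxonomy: B")
  out <- filter_organelles(ft, tax, missing = "unassigned")
  expect_equal(nrow(out), 2L)
})

test_that("rarefaction returns exact depths without exceeding originals", {
  ft <- make_table(cbind(c(4, 6), c(10, 0), c(2, 1)),
                   features = c("f1", "f2"))
  # depth equals a sample total: that sample is returned unchanged
  out <- rarefy(ft, depth = 10L, seed = 1)
  expect_equal(unname(unclass(out)[, "S01"]), c(4, 6))
  # single nonzero feature forces the outcome
  expect_equal(unname(unclass(out)[, "S02"]), c(10, 0))
  # the 3-read sample is dropped by default
  expect_equal(colnames(out), c("S01", "S02"))

  expect_warning(keep <- rarefy(ft, depth = 10L, seed = 1, drop_below = FALSE),
                 "below depth")
  expect_equal(ncol(keep), 3L)
  expect_equal(unname(unclass(keep)[, "S03"]), c(2, 1))

  expect_error(rarefy(ft, depth = 1000L, seed = 1), "no samples remain")

  for (i in 1:10) {
    big <- withr::with_seed(i, random_table(15L, 6L, max_count = 40L))
    depth <- min(colSums(big))
    rr <- rarefy(big, depth = depth, seed = i)
    expect_equal(unname(colSums(rr)), rep(depth, ncol(rr)))
    expect_true(all(unclass(rr) <= unclass(big)[, colnames(rr)]))
  }
})

test_that("rarefaction is deterministic in (table, depth, seed)", {
  ft <- withr::with_seed(5, random_table(20L, 6L))
  a <- rarefy(ft, depth = 30L, seed = 123)
  b <- rarefy(ft, depth = 30L, seed = 123)
  c <- rarefy(ft, depth = 30L, seed = 124)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("rarefied counts match the hypergeometric mean", {
  # sample (6, 4) at depth 5: E[feature 1] = 5 * 6/10 = 3
  ft <- make_table(cbind(c(6, 4)), features = c("f1", "f2"), samples = "S")
  draws <- vapply(1:2000, function(s) unclass(rarefy(ft, 5L, seed = s))[1, 1],
                  numeric(1))
  se <- sqrt(5 * 0.6 * 0.4 * (10 - 5) / (10 - 1)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 3), 3 * se)
})

test_that("rank collapse sums by label and conserves reads", {
  ft <- make_table(rbind(c(3, 1), c(2, 0), c(4, 4)),
                   features = c("X", "Y", "Z"))
  tax <- make_taxonomy(
    c("X", "Y", "Z"),
    c("d__Bacteria; p__P; c__C; o__Rhodobacterales; f__Rhodobacteraceae",
      "d__Bacteria; p__P; c__C; o__Rhodobacterales; f__Rhodobacteraceae",
      "d__Bacteria; p__P; c__C; o__Alteromonadales"))
  fam <- collapse_rank(ft, tax, "family")
  expect_equal(unname(unclass(fam)["Rhodobacteraceae", ]), c(5, 1))
  # unassigned at family falls under the nearest assigned parent
  expect_true("Unclassified_Alteromonadales" %in% rownames(fam))
  expect_equal(sum(fam), sum(ft))

  # asv rank is the identity
  expect_identical(unclass(collapse_rank(ft, tax, "asv")), unclass(ft))
})

test_that("collapse conserves per-sample totals on random tables", {
  for (i in 1:20) {
    ft <- withr::with_seed(i, random_table(25L, 5L))
    fams <- sample(c("F1", "F2", "F3", NA), 25L, replace = TRUE)
    lin <- ifelse(is.na(fams), "d__Bacteria; p__P; c__C; o__Ord1",
                  paste0("d__Bacteria; p__P; c__C; o__Ord1; f__", fams))
    tax <- make_taxonomy(rownames(ft), lin)
    fam <- collapse_rank(ft, tax, "family")
    expect_equal(colSums(fam), colSums(ft))
    expect_equal(nrow(fam), length(unique(ifelse(is.na(fams),
                                                 "Unclassified_Ord1", fams))))
  }
})

test_that("relative abundance columns sum to one", {
  expect_equal(unname(to_relative(make_table(cbind(c(5, 0, 5))))[, 1]),
               c(0.5, 0, 0.5))
  expect_equal(unname(to_relative(make_table(cbind(3, 7)))[1, ]), c(1, 1))
  for (i in 1:10) {
    ft <- withr::with_seed(i, random_table(50L, 10L))
    rel <- to_relative(ft)
    expect_true(all(abs(colSums(rel) - 1) <= 1e-12))
  }
  zero <- make_table(cbind(c(1, 2), c(0, 0)))
  expect_error(to_relative(zero), "zero total.*S02")
})
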