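# independent brute-force CI oracle: explicit loops over raw counts
brute_ci <- function(m, taxa, f_def = "rel_freq") {
  S <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) S <- S + m[i, j]
  N <- ncol(m)
  vapply(taxa, function(t) {
    s <- 0
    n <- 0
    for (j in seq_len(ncol(m))) {
      s <- s + m[t, j]
      if (m[t, j] > 0) n <- n + 1
    }
    f <- if (f_def == "rel_freq") s / S else n / N
    f * n * s / (N * S)
  }, numeric(1))
}

test_that("abundance set is the shortest 75% prefix with name tie-breaks", {
  ft <- make_table(cbind(c(60, 20, 15, 5)), features = c("A", "B", "C", "D"))
  ab <- abundance_core_set(ft, 0.75)
  expect_equal(ab$taxa, c("A", "B"))
  expect_equal(ab$table$cumulative_share[1:2], c(0.60, 0.80))

  # threshold 1: all taxa with nonzero reads, zero-read taxa excluded
  ft2 <- make_table(cbind(c(5, 3, 0)), features = c("A", "B", "Z"))
  expect_setequal(abundance_core_set(ft2, 1)$taxa, c("A", "B"))

  single <- make_table(cbind(7), features = "only")
  one <- abundance_core_set(single)
  expect_equal(one$taxa, "only")
  expect_equal(one$table$share, 1)
})

test_that("abundance set is minimal on random tables", {
  for (i in 1:30) {
    ft <- withr::with_seed(i, random_table(12L, 4L))
    ab <- abundance_core_set(ft, 0.75)
    tab <- ab$table
    k <- length(ab$taxa)
    expect_gte(tab$cumulative_share[k], 0.75 - 1e-12)
    if (k > 1L) expect_lt(tab$cumulative_share[k - 1L], 0.75)
  }
})

test_that("occupancy uses a strict over-threshold rule decided exactly", {
  m <- matrix(0, nrow = 3, ncol = 28)
  m[1, 1:20] <- 1  # 20/28 ~ 71.4% -> in
  m[2, 1:19] <- 1  # 19/28 ~ 67.9% -> out
  m[3, ] <- 1
  oc <- occupancy_core_set(make_table(m, features = c("in20", "out19", "all")))
  expect_true("in20" %in% oc$taxa)
  expect_false("out19" %in% oc$taxa)

  # exactly 70% (7 of 10) is excluded: "over 70%" is strict
  m2 <- matrix(0, nrow = 1, ncol = 10)
  m2[1, 1:7] <- 1
  expect_length(occupancy_core_set(make_table(m2, features = "x"))$taxa, 0L)
})

test_that("CI matches the worked example and the formula bounds", {
  # N = 4, S = 100, s = 50, n = 2: f = 0.5, CI = 0.5*2*50/(4*100) = 0.125
  m <- rbind(c(25, 25, 0, 0), c(0, 0, 25, 25))
  ft <- make_table(m, features = c("t", "rest"))
  sc <- compute_ci(ft, "t")
  expect_equal(sc$freq_f, 0.5)
  expect_equal(sc$ci, 0.125)

  # absent taxon scores zero; a taxon owning all reads in all samples scores 1
  m2 <- rbind(c(10, 20), c(0, 0))
  sc2 <- compute_ci(make_table(m2, features = c("all", "none")),
                    c("all", "none"))
  expect_equal(sc2$ci, c(1, 0))

  expect_error(compute_ci(ft, character()), "empty evaluation set")
  expect_error(compute_ci(ft, "nope"), "missing from table")
})

test_that("CI equals brute-force recomputation on 200 random tables", {
  worst <- 0
  for (i in 1:200) {
    ft <- withr::with_seed(1000 + i, {
      random_table(sample(2:10, 1L), sample(2:8, 1L))
    })
    m <- unclass(ft)
    taxa <- rownames(m)
    for (fd in c("rel_freq", "occupancy")) {
      got <- compute_ci(ft, taxa, f_definition = fd)$ci
      want <- unname(brute_ci(m, taxa, fd))
      worst <- max(worst, abs(got - want))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("NorCI min-max endpoints and degenerate behaviour", {
  sc <- compute_ci(make_table(rbind(c(5, 0), c(10, 3), c(2, 2)),
                              features = c("a", "b", "c")),
                   c("a", "b", "c"))
  sc$ci <- c(0.05, 0.125, 0.20)  # direct formula check on stated values
  out <- compute_norci(sc)
  expect_equal(out$norci, c(0, 0.5, 1))

  for (i in 1:20) {
    ft <- withr::with_seed(i, random_table(8L, 5L))
    out <- compute_norci(compute_ci(ft, rownames(ft)))
    if (all(is.na(out$norci))) next
    expect_equal(out$norci[which.min(out$ci)], 0)
    expect_equal(out$norci[which.max(out$ci)], 1)
    expect_true(all(out$norci >= 0 & out$norci <= 1))
  }

  flat <- compute_ci(make_table(rbind(c(1, 1), c(1, 1)),
                                features = c("a", "b")), c("a", "b"))
  expect_warning(und <- compute_norci(flat), "undefined")
  expect_true(all(is.na(und$norci)))
  expect_error(compute_norci(flat[1, ]), "at least 2")
})

test_that("core label requires abundance, occupancy and NorCI jointly", {
  # dominant but present in 1 of 28 samples: fails occupancy regardless of CI
  m <- matrix(0, nrow = 3, ncol = 28)
  m[1, 1] <- 1000
  m[2, ] <- 30
  m[3, ] <- 20
  ft <- make_table(m, features = c("burst", "steady1", "steady2"))
  cc <- classify_core(ft)
  expect_equal(cc$core_label[cc$taxon == "burst"], "non_core")
  expect_false(cc$in_occupancy_set[cc$taxon == "burst"])
  expect_true(cc$in_abundance_set[cc$taxon == "burst"])

  # NorCI <= 1, so a threshold above 1 empties the core
  cc2 <- classify_core(ft, norci_threshold = 1.1)
  expect_false(any(cc2$core_label == "core"))
})

test_that("taxa outside the top-k evaluation set are not_evaluated", {
  ft <- withr::with_seed(7, random_table(30L, 6L))
  cc <- classify_core(ft, top_k = 10L)
  expect_equal(sum(!is.na(cc$ci)), 10L)
  expect_equal(sum(cc$core_label == "not_evaluated"), 20L)
  expect_true(all(is.na(cc$norci[cc$core_label == "not_evaluated"])))
})

test_that("classification is invariant to row and column permutations", {
  ft <- withr::with_seed(11, random_table(25L, 8L))
  cc <- classify_core(ft)
  perm <- withr::with_seed(12, {
    unclass(ft)[sample(nrow(ft)), sample(ncol(ft))]
  })
  cc2 <- classify_core(feature_table(perm))
  expect_equal(as.data.frame(cc), as.data.frame(cc2))
})

test_that("CI is monotone in added reads and added occupancy", {
  for (i in 1:20) {
    ft <- withr::with_seed(200 + i, random_table(6L, 5L))
    m <- unclass(ft)
    t1 <- rownames(m)[1]
    base <- compute_ci(feature_table(m), t1)$ci
    # add reads to a sample that already contains the taxon
    j_has <- which(m[1, ] > 0)[1]
    if (!is.na(j_has)) {
      m2 <- m
      m2[1, j_has] <- m2[1, j_has] + 5
      expect_gte(compute_ci(feature_table(m2), t1)$ci, base)
    }
    # first read in a previously empty sample
    j_empty <- which(m[1, ] == 0)[1]
    if (!is.na(j_empty)) {
      m3 <- m
      m3[1, j_empty] <- 1
      expect_gte(compute_ci(feature_table(m3), t1)$ci, base)
    }
  }
})
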