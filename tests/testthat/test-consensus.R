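panel7 <- c("ZAP70", "AKT1", "AKT2", "BTK", "MAPK1", "MAPK3", "PIK3CD")

# a dataset whose rows are all independent noise
noise_dataset <- function(genes, kinases, n = 30, id = "d1") {
  m <- matrix(rnorm((length(genes) + length(kinases)) * n),
              ncol = n,
              dimnames = list(c(kinases, genes),
                              sprintf("%s_s%d", id, seq_len(n))))
  expression_dataset(m, id)
}

# records with specified r values for one gene/kinase across datasets
records_of <- function(rs, gene = "G1", kinase = "ZAP70") {
  data.frame(dataset_id = sprintf("d%d", seq_along(rs)),
             gene = gene, kinase = kinase, r = rs,
             n_used = 50L, fallback = FALSE)
}

test_that("correlate_collection record counting and missing kinases", {
  set.seed(21)
  genes <- sprintf("G%02d", 1:10)
  d1 <- noise_dataset(genes, panel7, id = "d1")
  d2 <- noise_dataset(genes, panel7, id = "d2")
  rec <- correlate_collection(list(d1, d2), panel7)
  expect_equal(nrow(rec), 2 * 10 * 7)    # kinases excluded from gene side
  expect_false(any(rec$gene %in% panel7))

  # a kinase absent from one dataset: its records absent, no error
  d3 <- noise_dataset(genes, setdiff(panel7, "BTK"), id = "d3")
  rec3 <- correlate_collection(list(d1, d3), panel7)
  expect_equal(sum(rec3$kinase == "BTK"), 10)
  expect_equal(nrow(rec3), 10 * 7 + 10 * 6)

  # no dataset containing any panel kinase is an error
  d4 <- noise_dataset(genes, "OTHER", id = "d4")
  expect_error(correlate_collection(list(d4), panel7), "no dataset")

  # panel alias: PI3KCD spelling maps onto the HGNC symbol
  rec5 <- correlate_collection(list(d1), c("ZAP70", "PI3KCD"))
  expect_setequal(unique(rec5$kinase), c("ZAP70", "PIK3CD"))
})

test_that("vectorized and pairwise correlation paths agree", {
  set.seed(22)
  genes <- sprintf("G%02d", 1:6)
  d <- noise_dataset(genes, panel7[1:2], n = 40, id = "dv")
  rec_fast <- correlate_collection(list(d), panel7[1:2])
  # force the pairwise path by planting one missing value
  d2 <- d
  d2$values["G01", 1] <- NA
  rec_slow <- correlate_collection(list(d2), panel7[1:2])
  other <- rec_slow$gene != "G01"
  m <- merge(rec_fast, rec_slow[other, ], by = c("gene", "kinase"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
})

test_that("build_consensus applies an absolute threshold per dataset", {
  rec <- records_of(c(0.6, 0.55, -0.7, 0.2))
  cc <- build_consensus(rec, threshold = 0.5)
  expect_equal(unname(cc$counts["G1", "ZAP70"]), 3L)  # both signs count
  expect_equal(unname(build_consensus(rec, 1.0)$counts["G1", "ZAP70"]), 0L)
  rec1 <- records_of(c(1.0, 0.99))
  expect_equal(unname(build_consensus(rec1, 1.0)$counts["G1", "ZAP70"]), 1L)
  expect_error(build_consensus(rec, 0), "\\(0, 1]")
  expect_error(build_consensus(rec, 1.2), "\\(0, 1]")
  # raising the threshold never increases any count
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    expect_true(all(build_consensus(rec, th)$counts >=
                    build_consensus(rec, th + 0.1)$counts))
  }
})

# counts matrix -> records (one pass per supporting dataset)
records_from_counts <- function(counts) {
  rows <- list()
  for (g in rownames(counts)) {
    for (k in colnames(counts)) {
      n <- counts[g, k]
      rows[[paste(g, k)]] <- data.frame(
        dataset_id = sprintf("d%02d", seq_len(max(n, 1L))),
        gene = g, kinase = k,
        r = c(rep(0.9, n), rep(0, max(1L - n, 0L))),
        n_used = 50L, fallback = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("stage-1 selection: anchor plus at least one other kinase", {
  counts <- matrix(0L, 3, 3,
                   dimnames = list(c("A", "B", "C"),
                                   c("ZAP70", "BTK", "AKT1")))
  counts["A", ] <- c(5L, 5L, 0L)   # anchor + BTK: in
  counts["B", ] <- c(5L, 0L, 0L)   # anchor only: out
  counts["C", ] <- c(4L, 14L, 0L)  # anchor below cutoff: out
  cc <- build_consensus(records_from_counts(counts), 0.5)
  expect_equal(select_stage1(cc, "ZAP70", 5L), "A")
  expect_error(select_stage1(cc, "DNPEP"), "anchor")
})

test_that("stage-2 selection: anchor plus multiple kinases, ranked", {
  counts <- matrix(0L, 4, 4,
                   dimnames = list(c("A", "B", "C", "D"),
                                   c("ZAP70", "BTK", "AKT1", "MAPK3")))
  counts["A", ] <- c(6L, 6L, 6L, 0L)   # anchor + exactly 2 others: in
  counts["B", ] <- c(6L, 6L, 0L, 0L)   # only 1 other: stage-1 only
  counts["C", ] <- c(7L, 7L, 7L, 7L)   # anchor + 3 others: in
  counts["D", ] <- c(0L, 9L, 9L, 9L)   # no anchor: out
  cc <- build_consensus(records_from_counts(counts), 0.5)
  sel <- select_stage2(cc, "ZAP70", min_other_kinases = 2L,
                       min_datasets = 5L)
  expect_equal(sel$stage2, c("C", "A"))          # ranked by total support
  expect_setequal(sel$stage1, c("A", "B", "C"))
  expect_true(all(sel$stage2 %in% sel$stage1))
  # degenerate threshold: anchor-supported set
  sel0 <- select_stage2(cc, "ZAP70", min_other_kinases = 0L,
                        min_datasets = 5L)
  expect_setequal(sel0$stage2, c("A", "B", "C"))
  expect_error(select_stage2(cc, "ZAP70", min_other_kinases = 4L),
               "panel size")
})

test_that("rank_by_support orders by total support with stable ties", {
  counts <- matrix(c(12L, 0L, 7L, 0L, 7L, 0L), 3, 2, byrow = TRUE,
                   dimnames = list(c("A", "Z", "B"), c("ZAP70", "BTK")))
  cc <- build_consensus(records_from_counts(counts), 0.5)
  expect_equal(rank_by_support(c("Z", "A"), cc), c("A", "Z"))
  expect_equal(rank_by_support(c("Z", "B"), cc), c("B", "Z"))  # tie: alpha
  expect_equal(rank_by_support(c("B", "A", "Z"), cc),
               rank_by_support(c("Z", "B", "A"), cc))
})

test_that("kinase overlap matrix equals brute-force set intersections", {
  set.seed(23)
  kin <- c("ZAP70", "BTK", "AKT1")
  genes <- sprintf("G%02d", 1:10)
  counts <- matrix(sample(0:8, 30, replace = TRUE), 10, 3,
                   dimnames = list(genes, kin))
  cc <- build_consensus(records_from_counts(counts), 0.5)
  ov <- kinase_overlap_matrix(cc, genes, min_datasets = 5L)
  expect_true(isSymmetric(ov))
  sup_sets <- lapply(kin, function(k) genes[counts[, k] >= 5L])
  names(sup_sets) <- kin
  for (i in kin) for (j in kin) {
    expect_equal(unname(ov[i, j]),
                 length(intersect(sup_sets[[i]], sup_sets[[j]])))
  }
  # disjoint and identical support sets
  c2 <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
               dimnames = list(c("A", "B"), kin[1:2]))
  ov2 <- kinase_overlap_matrix(build_consensus(records_from_counts(c2), 0.5),
                               c("A", "B"), 5L)
  expect_equal(unname(ov2["ZAP70", "BTK"]), 0L)
  c3 <- matrix(5L, 2, 2, dimnames = list(c("A", "B"), kin[1:2]))
  ov3 <- kinase_overlap_matrix(build_consensus(records_from_counts(c3), 0.5),
                               c("A", "B"), 5L)
  expect_true(all(ov3 == 2L))
})

test_that("same-dataset support mode is stricter than per-kinase counts", {
  # gene passes ZAP70 in d1..d5 and BTK in d6..d10: independent counts
  # qualify it, shared-dataset counts do not
  rec <- rbind(
    data.frame(dataset_id = sprintf("d%02d", 1:10), gene = "G1",
               kinase = "ZAP70", r = c(rep(0.9, 5), rep(0, 5)),
               n_used = 50L, fallback = FALSE),
    data.frame(dataset_id = sprintf("d%02d", 1:10), gene = "G1",
               kinase = "BTK", r = c(rep(0, 5), rep(0.9, 5)),
               n_used = 50L, fallback = FALSE))
  cc <- build_consensus(rec, 0.5)
  expect_equal(select_stage1(cc, "ZAP70", 5L), "G1")
  expect_equal(select_stage1(cc, "ZAP70", 5L, same_datasets = TRUE),
               character(0))
})
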