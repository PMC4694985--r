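test_that("support counts control sets that reached significance, split by sign", {
  recs <- do.call(rbind, c(
    lapply(sprintf("c%02d", 1:9), function(cid) make_record("P1", cid, "+")),
    list(make_record("P2", "c01", "+"), make_record("P2", "c02", "-"))))
  agg <- aggregate_over_controls(recs, "A", total_controls = 11)
  p1 <- agg[agg$pathway_id == "P1", ]
  expect_equal(p1$support, 9)
  expect_identical(p1$sign, "+")
  expect_false(p1$discordant)
  expect_equal(p1$total_controls, 11)
  # conflicting signs across control sets are flagged discordant
  p2 <- agg[agg$pathway_id == "P2", ]
  expect_true(p2$discordant)
  # never-significant pathways are simply absent; empty input, empty output
  expect_false("P99" %in% agg$pathway_id)
  expect_identical(nrow(aggregate_over_controls(recs[0, ], "A")), 0L)
})

test_that("random record sets aggregate like a brute-force tally", {
  set.seed(37)
  for (rep in 1:10) {
    recs <- do.call(rbind, lapply(1:60, function(i) {
      make_record(sample(sprintf("P%02d", 1:8), 1),
                  sample(sprintf("c%02d", 1:11), 1),
                  sample(c("+", "-"), 1))
    }))
    recs <- recs[!duplicated(recs[c("pathway_id", "control_id")]), ]
    agg <- aggregate_over_controls(recs, "A", total_controls = 11)
    for (pid in unique(recs$pathway_id)) {
      g <- recs[recs$pathway_id == pid, ]
      pos <- length(unique(g$control_id[g$sign == "+"]))
      neg <- length(unique(g$control_id[g$sign == "-"]))
      row <- agg[agg$pathway_id == pid, ]
      expect_equal(row$support_pos, pos)
      expect_equal(row$support_neg, neg)
      expect_equal(row$support, max(pos, neg))
    }
  }
})

test_that("consensus keeps pathways significant in both datasets with matching sign", {
  aggA <- aggregate_over_controls(rbind(
    make_record("SHARED", "c01", "+"), make_record("SHARED", "c02", "+"),
    make_record("ONLY_A", "c01", "+"),
    make_record("FLIP", "c01", "+")), "A", total_controls = 11)
  aggB <- aggregate_over_controls(rbind(
    make_record("SHARED", "d01", "+", dataset_id = "B"),
    make_record("FLIP", "d01", "-", dataset_id = "B")), "B",
    total_controls = 3)
  res <- intersect_datasets(aggA, aggB)
  expect_identical(res$consensus$pathway_id, "SHARED")
  expect_identical(res$consensus$sign, "+")
  expect_equal(res$consensus$support_A, 2)
  expect_equal(res$consensus$support_B, 1)
  # cross-dataset sign conflicts are reported, not silently dropped
  expect_identical(res$discordant$pathway_id, "FLIP")
  expect_match(res$discordant$reason, "cross-dataset")
  # without the sign requirement, FLIP enters the consensus
  res2 <- intersect_datasets(aggA, aggB, require_sign_match = FALSE)
  expect_setequal(res2$consensus$pathway_id, c("SHARED", "FLIP"))
})

test_that("within-dataset sign conflicts are excluded from the consensus", {
  aggA <- aggregate_over_controls(rbind(
    make_record("P1", "c01", "+"), make_record("P1", "c02", "-")), "A")
  aggB <- aggregate_over_controls(
    make_record("P1", "d01", "+", dataset_id = "B"), "B")
  res <- intersect_datasets(aggA, aggB)
  expect_identical(nrow(res$consensus), 0L)
  expect_match(res$discordant$reason, "within-dataset")
})

test_that("planted shared pathways are exactly the intersection", {
  shared <- sprintf("SH%d", 1:3)
  a_only <- sprintf("AO%d", 1:5)
  aggA <- aggregate_over_controls(
    do.call(rbind, lapply(c(shared, a_only),
                          function(p) make_record(p, "c01", "+"))), "A")
  aggB <- aggregate_over_controls(
    do.call(rbind, lapply(shared, function(p)
      make_record(p, "d01", "+", dataset_id = "B"))), "B")
  res <- intersect_datasets(aggA, aggB)
  expect_setequal(res$consensus$pathway_id, shared)
  # symmetry up to column labeling
  res_swap <- intersect_datasets(aggB, aggA)
  expect_setequal(res_swap$consensus$pathway_id, shared)
  expect_equal(res_swap$consensus$support_A, res$consensus$support_B)
  # consensus is a subset of each dataset's significant set
  expect_true(all(res$consensus$pathway_id %in% aggA$pathway_id))
  expect_true(all(res$consensus$pathway_id %in% aggB$pathway_id))
})

test_that("raising alpha never shrinks the consensus", {
  set.seed(41)
  n <- 10
  lines_a <- sprintf("A%02d", 1:n)
  lines_b <- sprintf("B%02d", 1:n)
  act_a <- rnorm(n); act_b <- rnorm(n)
  pas_a <- rbind(P1 = act_a, P2 = rnorm(n), P3 = rnorm(n))
  pas_b <- rbind(P1 = act_b, P2 = rnorm(n), P3 = rnorm(n))
  colnames(pas_a) <- lines_a; colnames(pas_b) <- lines_b
  ic_a <- make_ic50_table(setNames(act_a + rnorm(n, sd = 0.2) + 10, lines_a))
  ic_b <- make_ic50_table(setNames(act_b + rnorm(n, sd = 0.2) + 10, lines_b))
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5), function(alpha) {
    aggA <- aggregate_over_controls(
      screen_pathways(make_profile(pas_a), ic_a, alpha, dataset_id = "A"), "A")
    aggB <- aggregate_over_controls(
      screen_pathways(make_profile(pas_b), ic_b, alpha, dataset_id = "B"), "B")
    nrow(intersect_datasets(aggA, aggB)$consensus)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_gt(sizes[length(sizes)], 0)
})

test_that("duplicate (drug, pathway) rows are deduplicated before intersection", {
  aggA <- aggregate_over_controls(make_record("P1", "c01", "+"), "A")
  aggA2 <- rbind(aggA, aggA)   # duplicated entry, as seen in curated tables
  aggB <- aggregate_over_controls(
    make_record("P1", "d01", "+", dataset_id = "B"), "B")
  res <- intersect_datasets(aggA2, aggB)
  expect_identical(nrow(res$consensus), 1L)
})
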