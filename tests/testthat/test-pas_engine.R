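test_that("CNR is the case value over the control mean", {
  expect_equal(compute_cnr(10, c(5, 5)), 2)
  expect_equal(compute_cnr(7, c(6, 8, 7)), 1)
  set.seed(5)
  for (i in 1:20) {
    case <- runif(1, 1, 100)
    ctrl <- runif(sample(2:10, 1), 1, 100)
    expect_equal(compute_cnr(case, ctrl), case / mean(ctrl))
  }
  expect_error(compute_cnr(-1, c(1, 2)), "positive")
  expect_error(compute_cnr(1, c(2)), "at least 2")
})

test_that("BTIF needs both the tolerance-interval and the fold criterion", {
  ctrl <- c(99, 100, 101, 100, 99.5, 100.5)
  # CNR = 1 sits inside [0.66, 1.5]: never flagged however small p is
  expect_identical(compute_btif(100, ctrl)$btif, 0L)
  # 3x up-shift against tight controls: both criteria met
  r <- compute_btif(300, ctrl)
  expect_identical(r$btif, 1L)
  expect_lt(r$p_gene, 0.05)
  expect_equal(r$cnr, 3, tolerance = 1e-3)
  # large fold but no statistical support (wild controls)
  wild <- c(10, 500, 30, 800, 90, 250)
  r2 <- compute_btif(3 * mean(wild), wild)
  expect_identical(r2$btif, 0L)
  # zero-variance controls: p = 1 with a warning, no flag by default
  expect_warning(r3 <- compute_btif(300, c(100, 100, 100)), "zero-variance")
  expect_identical(r3$p_gene, 1)
  expect_identical(r3$btif, 0L)
})

test_that("a sweep across the thresholds matches the two-criteria oracle", {
  set.seed(21)
  ctrl <- rnorm(20, 100, 5)
  cases <- seq(50, 200, by = 1)
  got <- vapply(cases, function(cv) compute_btif(cv, ctrl)$btif, integer(1))
  want <- vapply(cases, function(cv) btif_oracle(cv, ctrl), integer(1))
  expect_identical(got, want)
  expect_gt(sum(got), 0)   # the sweep crosses into flagged territory
  expect_gt(sum(1L - got), 0)
  # literal polarity is the exact complement
  lit <- vapply(cases, function(cv)
    compute_btif(cv, ctrl, btif_polarity = "literal")$btif, integer(1))
  expect_identical(lit, 1L - got)
})

test_that("PAS is the ARR- and flag-weighted sum of log10 ratios", {
  gs <- function(genes, cnr, btif)
    data.frame(gene_symbol = genes, cnr = cnr, btif = btif)
  p1 <- pathway("P1", "A", 1)
  expect_equal(compute_pas(p1, gs("A", 10, 1L)), 1)
  expect_equal(compute_pas(p1, gs("A", 10, 0L)), 0)
  # activator and repressor with the same fold cancel exactly
  p2 <- pathway("P2", c("A", "B"), c(1, -1))
  expect_equal(compute_pas(p2, gs(c("A", "B"), c(100, 100), c(1L, 1L))), 0)
  # no member present: 0 with a coverage warning
  expect_warning(z <- compute_pas(p1, gs("ZZZ", 2, 1L)), "no member gene")
  expect_equal(z, 0)
})

test_that("random 30-gene pathways match a term-by-term summation oracle", {
  set.seed(33)
  for (rep in 1:100) {
    ng <- 30
    pw <- pathway("P", sprintf("G%02d", 1:ng),
                  sample(ARR_LEVELS, ng, replace = TRUE))
    stats_df <- data.frame(gene_symbol = sprintf("G%02d", 1:ng),
                           cnr = rlnorm(ng, 0, 1),
                           btif = sample(0:1, ng, replace = TRUE))
    oracle <- 0
    for (i in 1:ng) {
      oracle <- oracle + pw$members$arr[i] * stats_df$btif[i] *
        log10(stats_df$cnr[i])
    }
    got <- compute_pas(pw, stats_df)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("PAS properties: sign equivariance, monotonicity, permutation invariance", {
  set.seed(44)
  ng <- 15
  genes <- sprintf("G%02d", 1:ng)
  arr <- sample(ARR_LEVELS, ng, replace = TRUE)
  arr[1] <- 1
  stats_df <- data.frame(gene_symbol = genes, cnr = rlnorm(ng, 0, 1),
                         btif = rep(1L, ng))
  pw <- pathway("P", genes, arr)
  neg <- pathway("P", genes, -arr)
  expect_equal(compute_pas(neg, stats_df), -compute_pas(pw, stats_df))
  # raising the CNR of a flagged activator never decreases PAS
  base <- compute_pas(pw, stats_df)
  for (f in c(1.1, 2, 10)) {
    up <- stats_df
    up$cnr[1] <- up$cnr[1] * f
    expect_gte(compute_pas(pw, up), base)
  }
  # CNR = 1 contributes exactly 0: equivalent to removing the gene
  one <- stats_df
  one$cnr[1] <- 1
  expect_equal(compute_pas(pw, one),
               compute_pas(pathway("P", genes[-1], arr[-1]), stats_df))
  # permutation invariance in member order
  perm <- sample(ng)
  expect_equal(compute_pas(pathway("P", genes[perm], arr[perm]), stats_df),
               compute_pas(pw, stats_df))
})

test_that("profile computation composes the per-gene oracles", {
  set.seed(55)
  sc <- scenario(seed = 55, n_pathways = 5, genes_per_pathway = c(5L, 8L),
                 n_cell_lines = 4, n_control_sets = c(A = 1L, B = 1L),
                 n_background_genes = 10, planted_pathways = NULL)
  db <- gen_pathway_db(sc)
  ex <- gen_expression(sc, db, "A")
  ctrl <- ex$controls[[1]]
  prof <- compute_pas_profile(ex$cases, ctrl, db, pas_params())
  # independent composition: joint quantile normalization, then per-gene
  # CNR/BTIF via compute_btif, then per-pathway compute_pas
  joint <- quantile_normalize(cbind(ex$cases, ctrl$matrix))
  cs <- joint[, colnames(ex$cases)]
  ct <- joint[, colnames(ctrl$matrix)]
  for (s in colnames(cs)) {
    stats_df <- do.call(rbind, lapply(rownames(cs), function(g) {
      b <- compute_btif(cs[g, s], ct[g, ])
      data.frame(gene_symbol = g, cnr = b$cnr, btif = b$btif)
    }))
    for (pid in names(db)) {
      expect_equal(prof$pas[pid, s], compute_pas(db[[pid]], stats_df),
                   tolerance = 1e-10)
    }
  }
})

test_that("profiles behave at the design edges", {
  set.seed(66)
  genes <- sprintf("G%02d", 1:10)
  ctrlm <- matrix(rlnorm(10 * 6, 5, 0.05), 10, 6,
                  dimnames = list(genes, paste0("n", 1:6)))
  ctrl <- control_set("c1", ctrlm)
  db <- pathway_db(list(pathway("P1", genes[1:5], c(1, 1, 1, 0.5, 1))))
  # cases equal to the control means: everything unflagged, profile all zero
  cases0 <- matrix(rowMeans(ctrlm), 10, 2,
                   dimnames = list(genes, c("s1", "s2")))
  prof0 <- compute_pas_profile(cases0, ctrl, db, normalize = FALSE)
  expect_true(all(prof0$pas == 0))
  # uniform 4-fold up-shift on every activator gene: strictly positive PAS
  cases4 <- cases0
  cases4[1:5, "s1"] <- cases4[1:5, "s1"] * 4
  prof4 <- compute_pas_profile(cases4, ctrl, db, normalize = FALSE)
  expect_gt(prof4$pas["P1", "s1"], 0)
  expect_equal(prof4$pas["P1", "s2"], 0)
  # insufficient gene coverage is an error
  dbx <- pathway_db(list(pathway("PX", c("NOT1", "NOT2", "NOT3"), c(1, 1, 1))))
  expect_error(compute_pas_profile(cases0, ctrl, dbx), "coverage")
})

test_that("with thresholds collapsed to 1 and alpha 1, PAS is the unfiltered signed sum", {
  set.seed(77)
  genes <- sprintf("G%02d", 1:20)
  ctrlm <- matrix(rlnorm(20 * 8, 5, 0.3), 20, 8,
                  dimnames = list(genes, paste0("n", 1:8)))
  cases <- matrix(rlnorm(20 * 3, 5, 0.3), 20, 3,
                  dimnames = list(genes, paste0("s", 1:3)))
  arr <- sample(ARR_LEVELS, 20, replace = TRUE)
  db <- pathway_db(list(pathway("P1", genes, arr)))
  open <- pas_params(alpha_gene = 1, low_thresh = 1 - 1e-12,
                     high_thresh = 1 + 1e-12)
  prof <- compute_pas_profile(cases, control_set("c", ctrlm), db, open,
                              normalize = FALSE)
  mu <- rowMeans(ctrlm)
  for (s in colnames(cases)) {
    expect_equal(prof$pas["P1", s], sum(arr * log10(cases[, s] / mu)),
                 tolerance = 1e-10)
  }
})
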