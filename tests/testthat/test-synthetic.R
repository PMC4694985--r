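test_that("generators are pure functions of scenario and seed", {
  sc <- scenario(seed = 101, n_pathways = 8, n_cell_lines = 4,
                 n_control_sets = c(A = 2L, B = 1L), n_background_genes = 10)
  expect_equal(gen_pathway_db(sc), gen_pathway_db(sc))
  db <- gen_pathway_db(sc)
  e1 <- gen_expression(sc, db, "A")
  e2 <- gen_expression(sc, db, "A")
  expect_identical(e1$cases, e2$cases)
  expect_identical(e1$latent, e2$latent)
  # a different seed changes the draw
  e3 <- gen_expression(scenario(seed = 102, n_pathways = 8, n_cell_lines = 4,
                                n_control_sets = c(A = 2L, B = 1L),
                                n_background_genes = 10), db, "A")
  expect_false(identical(e1$cases, e3$cases))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_pathway_db(sc)); after <- runif(1)
  expect_identical(before, after)
})

test_that("pathway sizes and ARR role frequencies follow the configuration", {
  sc5 <- scenario(seed = 7, n_pathways = 20, genes_per_pathway = c(5L, 5L))
  db5 <- gen_pathway_db(sc5)
  expect_true(all(vapply(db5, function(p) nrow(p$members), integer(1)) == 5L))
  # frequencies over ~10^4 members stay inside a 99.9% binomial envelope
  probs <- c(0.15, 0.1, 0.1, 0.15, 0.5)
  sc <- scenario(seed = 8, n_pathways = 600, genes_per_pathway = c(15L, 18L),
                 arr_probs = probs)
  arr <- unlist(lapply(gen_pathway_db(sc), function(p) p$members$arr))
  n <- length(arr)
  expect_gt(n, 9000)
  for (i in seq_along(ARR_LEVELS)) {
    got <- mean(arr == ARR_LEVELS[i])
    half <- qnorm(0.9995) * sqrt(probs[i] * (1 - probs[i]) / n)
    # the all-zero guard perturbs frequencies by at most ~1/15 per pathway
    expect_lt(abs(got - probs[i]), half + 0.005)
  }
})

test_that("an unplanted scenario yields near-null PAS profiles", {
  sc <- scenario(seed = 9, n_pathways = 10, n_cell_lines = 6,
                 n_control_sets = c(A = 1L, B = 1L),
                 planted_pathways = NULL, n_background_genes = 20)
  db <- gen_pathway_db(sc)
  ex <- gen_expression(sc, db, "A")
  prof <- compute_pas_profile(ex$cases, ex$controls[[1]], db)
  # no systematic activation: scores hover near zero relative to a
  # planted pathway's scale (|PAS| ~ genes * log10(fold) ~ 5+)
  expect_lt(max(abs(prof$pas)), 2)
  expect_lt(abs(mean(prof$pas)), 0.2)
})

test_that("planted fold-shifts produce sign-correct PAS in activated lines", {
  sc <- scenario(seed = 10, n_pathways = 6, n_cell_lines = 8,
                 n_control_sets = c(A = 1L, B = 1L),
                 planted_pathways = data.frame(pathway_id = "PW001",
                                               effect = 4, target_r = 0.9),
                 expr_sdlog = 0.05, n_background_genes = 20)
  db <- gen_pathway_db(sc)
  ex <- gen_expression(sc, db, "A")
  prof <- compute_pas_profile(ex$cases, ex$controls[[1]], db)
  act <- ex$latent[, "PW001"]
  pas <- prof$pas["PW001", rownames(ex$latent)]
  # strongly activated lines score positive, strongly repressed negative
  expect_true(all(pas[act > 0.5] > 0))
  expect_true(all(pas[act < -0.5] < 0))
  # empirical PAS tracks the latent activation
  expect_gt(cor(act, pas), 0.8)
})

test_that("true IC50s realize the planted correlation with latent activation", {
  sc <- scenario(seed = 11, n_cell_lines = 400)
  lines <- sprintf("CL%03d", 1:400)
  latent <- paslink:::gen_latent_activation(sc, lines, offset = 1007L)
  ic50 <- gen_true_ic50(sc, latent)
  expect_true(all(ic50 >= 1 & ic50 <= 40))
  expect_equal(cor(latent[, 1], log10(ic50)), 0.95, tolerance = 0.05)
  # negative planting flips the slope
  scn <- scenario(seed = 11, n_cell_lines = 400,
                  planted_pathways = data.frame(pathway_id = "PW001",
                                                effect = 4, target_r = -0.95))
  icn <- gen_true_ic50(scn, latent)
  expect_lt(cor(latent[, 1], log10(icn)), -0.9)
})

test_that("a fixed-seed bundle writes byte-identical files", {
  sc <- scenario(seed = 13, n_pathways = 4, genes_per_pathway = c(5L, 6L),
                 n_cell_lines = 3, n_control_sets = c(A = 1L, B = 1L),
                 n_background_genes = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(gen_linked_dataset(sc), d1)
  write_bundle(gen_linked_dataset(sc), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in setdiff(f1, "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated files round-trip through the pipeline readers", {
  sc <- scenario(seed = 15, n_pathways = 4, genes_per_pathway = c(5L, 6L),
                 n_cell_lines = 3, n_control_sets = c(A = 2L, B = 1L),
                 n_background_genes = 5)
  b <- gen_linked_dataset(sc)
  d <- withr::local_tempdir()
  write_bundle(b, d)
  expect_equal(read_pathway_db(file.path(d, "pathways.tsv")), b$db)
  cases <- read_expression(file.path(d, "dataset_A", "cases.tsv"))
  expect_equal(cases, b$datasets$A$cases, tolerance = 1e-12)
  ctrl <- read_expression(file.path(d, "dataset_A", "ctrl_A_01.tsv"))
  expect_equal(ctrl, b$datasets$A$controls[[1]]$matrix, tolerance = 1e-12)
})
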