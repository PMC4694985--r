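#' Define a synthetic-data scenario
#'
#' A scenario fixes every knob of the ground-truth generator: the pathway
#' database shape, the cell-line panel, the control datasets used for
#' normalization, the planted pathway perturbations tied to drug response,
#' and the noise levels. All generators are pure functions of
#' (scenario, seed).
#'
#' The defaults mirror a two-dataset drug-screen at desk scale: 50
#' pathways of 10-20 genes, an 11-cell-line panel per dataset, 11
#' normalization control sets for dataset A and 3 for dataset B (4-10
#' normal samples each), one planted pathway whose activation drives IC50
#' with correlation 0.95, four-fold expression shifts on planted genes,
#' 10\% log-normal expression noise and 5\% Gaussian OD noise on
#' quadruplicate plates over the standard 8-dose ladder.
#'
#' @param seed Integer seed.
#' @param n_pathways Number of pathways in the generated database.
#' @param genes_per_pathway Length-2 inclusive range of member counts.
#' @param n_cell_lines Cell lines per dataset.
#' @param n_control_sets Named vector: control sets per dataset
#'   (default \code{c(A = 11, B = 3)}).
#' @param controls_per_set Length-2 range of normal samples per control set.
#' @param planted_pathways Data frame with columns \code{pathway_id},
#'   \code{effect} (fold shift applied as \code{effect^(arr * activation)}),
#'   \code{target_r} (planted PAS-IC50 correlation, sign included). Use
#'   \code{NULL} for an all-null scenario.
#' @param arr_probs Sampling weights over the ARR levels
#'   (-1, -0.5, 0, +0.5, +1).
#' @param expr_sdlog Log-normal expression noise (natural-log sd).
#' @param tissue_sdlog Per-control-set per-gene tissue offset (log sd).
#' @param od_sigma_frac Plate OD noise as a fraction of the control signal.
#' @param n_background_genes Genes outside every pathway.
#' @param hill True hill slope of simulated dose-response curves.
#' @param drug Drug label used throughout.
#' @param true_ic50s Optional named vector forcing cell-line IC50s (uM).
#' @return Object of class \code{"pas_scenario"}.
#' @export
scenario <- function(seed = 1L, n_pathways = 50L,
                     genes_per_pathway = c(10L, 20L),
                     n_cell_lines = 11L,
                     n_control_sets = c(A = 11L, B = 3L),
                     controls_per_set = c(4L, 33L),
                     planted_pathways = data.frame(
                       pathway_id = "PW001", effect = 4, target_r = 0.95),
                     arr_probs = c(0.15, 0.1, 0.1, 0.15, 0.5),
                     expr_sdlog = 0.1, tissue_sdlog = 0.05,
                     od_sigma_frac = 0.05, n_background_genes = 200L,
                     hill = 1, drug = "drugX", true_ic50s = NULL) {
  stopifnot(length(genes_per_pathway) == 2L,
            genes_per_pathway[1] >= 1L,
            length(arr_probs) == length(ARR_LEVELS),
            expr_sdlog >= 0, od_sigma_frac >= 0)
  if (!is.null(planted_pathways)) {
    stopifnot(all(c("pathway_id", "effect", "target_r") %in%
                    names(planted_pathways)),
              all(abs(planted_pathways$target_r) <= 1))
  } else {
    planted_pathways <- data.frame(pathway_id = character(),
                                   effect = numeric(), target_r = numeric())
  }
  structure(list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_control_sets = n_control_sets,
                 controls_per_set = as.integer(controls_per_set),
                 planted_pathways = planted_pathways,
                 arr_probs = arr_probs / sum(arr_probs),
                 expr_sdlog = expr_sdlog, tissue_sdlog = tissue_sdlog,
                 od_sigma_frac = od_sigma_frac,
                 n_background_genes = as.integer(n_background_genes),
                 hill = hill, drug = drug, true_ic50s = true_ic50s),
            class = "pas_scenario")
}

#' @export
print.pas_scenario <- function(x, ...) {
  cat("pas_scenario: ", x$n_pathways, " pathways, ", x$n_cell_lines,
      " cell lines, control sets [",
      paste(x$n_control_sets, collapse = ", "), "], ",
      nrow(x$planted_pathways), " planted pathway(s), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# draw one integer uniformly from an inclusive range (robust to a
# degenerate range, unlike sample(x, 1) on a scalar)
sample_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1L)
}

# run fn with a private RNG stream derived from (seed, offset), restoring
# the caller's RNG state afterwards
with_seed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + offset)
  fn()
}

#' Generate a synthetic pathway database
#'
#' Pathways with disjoint member-gene sets, ARR roles drawn from the
#' configured mixture over the discrete level set, and mixed
#' signaling/metabolic kinds. Deterministic given the scenario seed.
#'
#' @param sc A \code{\link{scenario}}.
#' @return A \code{\link{pathway_db}}.
#' @export
gen_pathway_db <- function(sc) {
  stopifnot(inherits(sc, "pas_scenario"))
  with_seed(sc$seed, 101L, function() {
    pws <- lapply(seq_len(sc$n_pathways), function(i) {
      ng <- sample_range(sc$genes_per_pathway)
      arr <- sample(ARR_LEVELS, ng, replace = TRUE, prob = sc$arr_probs)
      if (all(arr == 0)) arr[1L] <- 1  # guarantee the pathway can score
      pathway(sprintf("PW%03d", i),
              genes = sprintf("G%03d_%02d", i, seq_len(ng)),
              arr = arr,
              kind = if (i %% 2L == 1L) "signaling" else "metabolic")
    })
    pathway_db(pws)
  })
}

# latent per-line activation of each planted pathway, standard normal
gen_latent_activation <- function(sc, lines, offset) {
  with_seed(sc$seed, offset, function() {
    matrix(stats::rnorm(length(lines) * nrow(sc$planted_pathways)),
           nrow = length(lines),
           dimnames = list(lines, sc$planted_pathways$pathway_id))
  })
}

#' Generate case and control expression matrices
#'
#' Control intensities are log-normal per gene around a gene-specific
#' baseline, with a small per-control-set tissue offset. Case cell lines
#' share the baseline; each gene of a planted pathway is shifted by
#' \code{effect^(arr * activation)} where \code{activation} is the cell
#' line's latent activation of that pathway, so that strongly activated
#' lines push their member genes beyond the fold-change flag thresholds
#' while near-zero activations stay inside them.
#'
#' @param sc A \code{\link{scenario}}.
#' @param db Database from \code{\link{gen_pathway_db}}.
#' @param dataset_id \code{"A"} or \code{"B"}; selects the control-set
#'   count and decorrelates the two datasets' random draws.
#' @param latent Optional pre-drawn activation matrix (lines x planted
#'   pathways); drawn internally when \code{NULL}.
#' @return List with \code{cases} (genes x lines matrix), \code{controls}
#'   (list of \code{\link{control_set}}), \code{latent}.
#' @export
gen_expression <- function(sc, db, dataset_id = "A", latent = NULL) {
  stopifnot(inherits(sc, "pas_scenario"), inherits(db, "pathway_db"))
  ds_off <- 1000L * match(dataset_id, names(sc$n_control_sets))
  if (is.na(ds_off)) stop("unknown dataset_id '", dataset_id, "'")
  genes <- c(pathway_genes(db),
             if (sc$n_background_genes > 0)
               sprintf("BG%04d", seq_len(sc$n_background_genes)))
  lines <- sprintf("CL%s%02d", dataset_id, seq_len(sc$n_cell_lines))
  if (is.null(latent)) latent <- gen_latent_activation(sc, lines, ds_off + 7L)
  # baseline means are a property of the gene, shared by the two datasets
  meanlog <- with_seed(sc$seed, 11L, function() {
    stats::setNames(stats::rnorm(length(genes), mean = log(200), sd = 1), genes)
  })
  # per-gene multiplicative shift per line from planted perturbations
  shift <- matrix(0, length(genes), length(lines),
                  dimnames = list(genes, lines))
  for (k in seq_len(nrow(sc$planted_pathways))) {
    pid <- sc$planted_pathways$pathway_id[k]
    if (!pid %in% names(db))
      stop("planted pathway '", pid, "' not in the generated database")
    m <- db[[pid]]$members
    lef <- log(sc$planted_pathways$effect[k])
    shift[m$gene_symbol, ] <- shift[m$gene_symbol, , drop = FALSE] +
      outer(m$arr, latent[, pid]) * lef
  }
  cases <- with_seed(sc$seed, ds_off + 23L, function() {
    noise <- matrix(stats::rnorm(length(genes) * length(lines),
                                 sd = sc$expr_sdlog),
                    length(genes), length(lines))
    exp(meanlog + shift + noise)
  })
  dimnames(cases) <- list(genes, lines)
  n_sets <- sc$n_control_sets[[dataset_id]]
  controls <- with_seed(sc$seed, ds_off + 31L, function() {
    lapply(seq_len(n_sets), function(ci) {
      m <- sample_range(sc$controls_per_set)
      tissue <- stats::rnorm(length(genes), sd = sc$tissue_sdlog)
      vals <- exp(meanlog + tissue +
                    matrix(stats::rnorm(length(genes) * m, sd = sc$expr_sdlog),
                           length(genes), m))
      dimnames(vals) <- list(genes,
                             sprintf("N%s%02d_S%02d", dataset_id, ci, seq_len(m)))
      control_set(sprintf("ctrl_%s_%02d", dataset_id, ci), vals)
    })
  })
  list(cases = cases, controls = controls, latent = latent)
}

#' Generate true IC50 values tied to planted pathway activation
#'
#' log10(IC50) is centered mid-ladder and linear in the first planted
#' pathway's latent activation, so that cor(activation, log10 IC50)
#' equals \code{target_r} in expectation; a negative \code{target_r}
#' flips the slope (the drug works better the more active the pathway).
#' The log scale is the natural scale for IC50 (real panels report
#' log-normal IC50 spreads of an order of magnitude). With no planted
#' pathway, IC50s are drawn log-uniform within the ladder. Values are
#' kept inside [1, 40] uM so the default scenario stays uncensored.
#'
#' @param sc A \code{\link{scenario}}.
#' @param latent Activation matrix from \code{\link{gen_expression}}.
#' @param offset RNG offset (decorrelates datasets).
#' @return Named vector of IC50s (uM) per cell line.
#' @export
gen_true_ic50 <- function(sc, latent, offset = 47L) {
  lines <- rownames(latent)
  if (!is.null(sc$true_ic50s)) return(sc$true_ic50s[lines])
  with_seed(sc$seed, offset, function() {
    v <- if (nrow(sc$planted_pathways) > 0) {
      r <- sc$planted_pathways$target_r[1L]
      act <- latent[, 1L]
      eps <- stats::rnorm(length(lines))
      10^(log10(5) + 0.3 * (r * act + sqrt(1 - r^2) * eps))
    } else {
      10^stats::runif(length(lines), log10(1), log10(40))
    }
    stats::setNames(pmin(pmax(v, 1), 40), lines)
  })
}

#' Generate dose-response plates from a 4PL forward model
#'
#' For every cell line, treated-well ODs follow
#' \code{OD = blank + span * v(c)/100 + noise} where \code{v} is the true
#' 4PL curve (top 100, bottom 0, configured hill, the line's true IC50)
#' over the standard dose ladder, in quadruplicate, with Gaussian noise of
#' sd \code{od_sigma_frac * span}. Untreated control and no-cell blank
#' wells are included with the same noise.
#'
#' @param sc A \code{\link{scenario}}.
#' @param true_ic50s Named vector of true IC50s (uM) per cell line.
#' @param offset RNG offset.
#' @param n_replicates Treated replicates per dose (default 4).
#' @return List of \code{\link{dose_response}} objects, one per cell line.
#' @export
gen_dose_response <- function(sc, true_ic50s, offset = 53L,
                              n_replicates = 4L) {
  lines <- names(true_ic50s)
  blank0 <- 0.1; span <- 1.0   # control OD 1.1, blank OD 0.1
  doses <- DOSE_LADDER_UM
  with_seed(sc$seed, offset, function() {
    lapply(lines, function(cl) {
      v <- 100 / (1 + (doses / true_ic50s[[cl]])^sc$hill)
      od_mean <- blank0 + span * v / 100
      sdev <- sc$od_sigma_frac * span
      od <- matrix(stats::rnorm(n_replicates * length(doses),
                                mean = rep(od_mean, each = n_replicates),
                                sd = sdev),
                   nrow = n_replicates)
      dose_response(sc$drug, cl, doses, od,
                    od_untreated = stats::rnorm(8L, blank0 + span, sdev),
                    od_blank = stats::rnorm(4L, blank0, sdev))
    })
  })
}

#' Generate a complete two-dataset linked bundle
#'
#' Emits everything the end-to-end pipeline consumes: the pathway
#' database, and for each of two independent datasets (distinct cell-line
#' panels, independent noise draws, their own control sets) the case
#' expression matrix, the normalization control sets, dose-response
#' plates, and the underlying truth (latent activations, true IC50s).
#' Latent pathway activation drives both the planted expression shifts
#' and the true IC50s, so the pipeline should recover the planted
#' pathways in the consensus with the planted correlation sign.
#'
#' @param sc A \code{\link{scenario}}.
#' @return Object of class \code{"pas_bundle"}: list with \code{scenario},
#'   \code{db}, \code{datasets} (named list; each has \code{dataset_id},
#'   \code{cases}, \code{controls}, \code{plates}, \code{true_ic50},
#'   \code{latent}).
#' @export
gen_linked_dataset <- function(sc) {
  stopifnot(inherits(sc, "pas_scenario"))
  db <- gen_pathway_db(sc)
  datasets <- lapply(names(sc$n_control_sets), function(ds) {
    off <- 1000L * match(ds, names(sc$n_control_sets))
    ex <- gen_expression(sc, db, dataset_id = ds)
    ic50 <- gen_true_ic50(sc, ex$latent, offset = off + 47L)
    plates <- gen_dose_response(sc, ic50, offset = off + 53L)
    list(dataset_id = ds, cases = ex$cases, controls = ex$controls,
         plates = plates, true_ic50 = ic50, latent = ex$latent)
  })
  names(datasets) <- names(sc$n_control_sets)
  structure(list(scenario = sc, db = db, datasets = datasets),
            class = "pas_bundle")
}

#' Write a bundle to disk in the pipeline's file formats
#'
#' Writes the pathway database (extended GMT dialect), per-dataset case
#' expression TSVs, control-set TSVs, plate CSVs, true IC50 CSVs, and a
#' \code{config.yaml} that \code{\link{run_pipeline}} can consume.
#'
#' @param bundle A \code{\link{gen_linked_dataset}} bundle.
#' @param dir Output directory (created if needed).
#' @return The config file path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pas_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pathway_db(bundle$db, file.path(dir, "pathways.tsv"))
  cfg_datasets <- list()
  for (ds in names(bundle$datasets)) {
    d <- bundle$datasets[[ds]]
    ddir <- file.path(dir, paste0("dataset_", ds))
    dir.create(ddir, showWarnings = FALSE)
    write_expression(d$cases, file.path(ddir, "cases.tsv"))
    ctrl_paths <- vapply(d$controls, function(cs) {
      p <- file.path(ddir, paste0(cs$control_id, ".tsv"))
      write_expression(cs$matrix, p)
      p
    }, character(1))
    names(ctrl_paths) <- vapply(d$controls, `[[`, character(1), "control_id")
    plate_rows <- do.call(rbind, lapply(d$plates, function(pl) {
      tr <- expand.grid(replicate = seq_len(nrow(pl$od_treated)),
                        concentration_uM = pl$concentrations)
      rbind(
        data.frame(drug = pl$drug, cell_line = pl$cell_line,
                   concentration_uM = tr$concentration_uM,
                   replicate = tr$replicate,
                   od = as.vector(pl$od_treated), well_type = "treated"),
        data.frame(drug = pl$drug, cell_line = pl$cell_line,
                   concentration_uM = 0,
                   replicate = seq_along(pl$od_untreated),
                   od = pl$od_untreated, well_type = "control"),
        data.frame(drug = pl$drug, cell_line = pl$cell_line,
                   concentration_uM = 0, replicate = seq_along(pl$od_blank),
                   od = pl$od_blank, well_type = "blank"))
    }))
    utils::write.csv(plate_rows, file.path(ddir, "plates.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(drug = bundle$scenario$drug, cell_line = names(d$true_ic50),
                 ic50_uM = unname(d$true_ic50)),
      file.path(ddir, "true_ic50.csv"), row.names = FALSE, quote = FALSE)
    cfg_datasets[[ds]] <- list(cases = file.path(ddir, "cases.tsv"),
                               controls = as.list(ctrl_paths),
                               plates = file.path(ddir, "plates.csv"))
  }
  cfg <- list(pathway_db = file.path(dir, "pathways.tsv"),
              datasets = cfg_datasets,
              out_dir = file.path(dir, "out"),
              params = list(alpha_gene = 0.05, low_thresh = 0.66,
                            high_thresh = 1.5, btif_polarity = "perturbed"),
              alpha_corr = 0.05, log10_ic50 = FALSE,
              min_support = 1L, require_sign_match = TRUE,
              seed = bundle$scenario$seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
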