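#' Build and validate a pipeline configuration
#'
#' @param pathway_db Path to the pathway database file.
#' @param datasets Named list (one entry per dataset); each entry a list
#'   with \code{cases} (expression TSV), \code{controls} (named list of
#'   control expression TSVs) and either \code{plates} (plate CSV to fit)
#'   or \code{ic50} (pre-computed IC50 CSV).
#' @param out_dir Output directory.
#' @param params PAS parameter block (see \code{\link{pas_params}}).
#' @param alpha_corr Significance threshold of the correlation screen.
#' @param log10_ic50 Correlate on log10(IC50).
#' @param min_support,require_sign_match Consensus settings
#'   (see \code{\link{intersect_datasets}}).
#' @param seed Integer seed recorded in the run log (the pipeline stages
#'   themselves are deterministic).
#' @return Validated config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(pathway_db, datasets, out_dir,
                            params = list(), alpha_corr = 0.05,
                            log10_ic50 = FALSE, min_support = 1L,
                            require_sign_match = TRUE, seed = 1L) {
  params <- do.call(pas_params, params)
  if (!(params$low_thresh > 0 && params$low_thresh < 1 &&
          params$high_thresh > 1))
    stop("invalid thresholds: need 0 < low_thresh < 1 < high_thresh")
  if (!(params$alpha_gene > 0 && params$alpha_gene < 1))
    stop("alpha_gene must lie in (0, 1)")
  if (!(alpha_corr > 0 && alpha_corr < 1))
    stop("alpha_corr must lie in (0, 1)")
  if (length(datasets) < 1L) stop("at least one dataset required")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list")
  for (ds in names(datasets)) {
    d <- datasets[[ds]]
    if (is.null(d$cases) || is.null(d$controls))
      stop("dataset '", ds, "': cases and controls are required")
    if (is.null(d$plates) && is.null(d$ic50))
      stop("dataset '", ds, "': either plates or ic50 input is required")
  }
  structure(list(pathway_db = pathway_db, datasets = datasets,
                 out_dir = out_dir, params = params,
                 alpha_corr = alpha_corr, log10_ic50 = log10_ic50,
                 min_support = as.integer(min_support),
                 require_sign_match = isTRUE(require_sign_match),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file as written by \code{\link{write_bundle}}.
#' @return A validated \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(pathway_db = y$pathway_db, datasets = y$datasets,
                  out_dir = y$out_dir,
                  params = if (is.null(y$params)) list() else y$params,
                  alpha_corr = if (is.null(y$alpha_corr)) 0.05 else y$alpha_corr,
                  log10_ic50 = isTRUE(y$log10_ic50),
                  min_support = if (is.null(y$min_support)) 1L else y$min_support,
                  require_sign_match = !isFALSE(y$require_sign_match),
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

# analyse one dataset held in memory: IC50 (fit or as given) -> PAS per
# control set -> correlation screen -> aggregation over control sets
analyse_dataset <- function(dataset_id, cases, controls, plates = NULL,
                            ic50 = NULL, db, params, alpha_corr = 0.05,
                            log10_ic50 = FALSE) {
  if (is.null(ic50)) {
    fits <- lapply(plates, fit_dose_response)
    ic50 <- ic50_table(fits)
  }
  records <- do.call(rbind, lapply(controls, function(cs) {
    prof <- compute_pas_profile(cases, cs, db, params)
    screen_pathways(prof, ic50, alpha = alpha_corr,
                    dataset_id = dataset_id, log10_ic50 = log10_ic50)
  }))
  rownames(records) <- NULL
  list(dataset_id = dataset_id, ic50 = ic50, records = records,
       aggregate = aggregate_over_controls(records, dataset_id,
                                           total_controls = length(controls)))
}

#' Run the linked analysis on an in-memory bundle
#'
#' Convenience end-to-end driver over a \code{\link{gen_linked_dataset}}
#' bundle: fits IC50s from the simulated plates, computes PAS profiles
#' against every control set, screens correlations, aggregates over
#' control sets per dataset, and intersects the two datasets.
#'
#' @param bundle A \code{pas_bundle}.
#' @param params PAS parameters (default \code{\link{pas_params}()}).
#' @param alpha_corr Correlation significance threshold.
#' @param log10_ic50 Correlate on log10(IC50).
#' @param min_support,require_sign_match Consensus settings.
#' @param use_true_ic50 Skip curve fitting and use the bundle's true IC50s
#'   (default \code{FALSE}).
#' @return List with \code{consensus}, \code{discordant},
#'   \code{per_dataset} (each dataset's ic50 table, records, aggregate).
#' @export
run_linked_analysis <- function(bundle, params = pas_params(),
                                alpha_corr = 0.05, log10_ic50 = FALSE,
                                min_support = 1L, require_sign_match = TRUE,
                                use_true_ic50 = FALSE) {
  stopifnot(inherits(bundle, "pas_bundle"))
  per <- lapply(bundle$datasets, function(d) {
    ic50 <- if (use_true_ic50) {
      data.frame(drug = bundle$scenario$drug,
                 cell_line = names(d$true_ic50),
                 ic50_uM = unname(d$true_ic50), censored = FALSE,
                 stringsAsFactors = FALSE)
    } else NULL
    analyse_dataset(d$dataset_id, d$cases, d$controls, plates = d$plates,
                    ic50 = ic50, db = bundle$db, params = params,
                    alpha_corr = alpha_corr, log10_ic50 = log10_ic50)
  })
  ids <- names(per)
  res <- intersect_datasets(per[[ids[1]]]$aggregate, per[[ids[2]]]$aggregate,
                            require_sign_match = require_sign_match,
                            min_support = min_support)
  c(res, list(per_dataset = per))
}

#' Run the full file-based pipeline
#'
#' Stages: read inputs, estimate IC50 (4PL fit of plate data, or ingest a
#' pre-computed table), compute PAS profiles against every control set,
#' screen PAS-IC50 correlations, aggregate support over control sets per
#' dataset, and intersect datasets into the consensus. All intermediates
#' are written under \code{out_dir}; a run log records parameters and
#' per-control gene coverage. Output is identical for identical inputs
#' and configuration. Any stage failure raises an error naming the stage.
#'
#' @param config A \code{\link{pipeline_config}} or path to a YAML config.
#' @return Invisibly, the list from \code{\link{intersect_datasets}} plus
#'   per-dataset intermediates.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("paslink pipeline run")
  logf("seed\t", config$seed)
  for (p in names(config$params)) logf("param ", p, "\t", config$params[[p]])
  logf("alpha_corr\t", config$alpha_corr)
  logf("log10_ic50\t", config$log10_ic50)
  logf("min_support\t", config$min_support)

  db <- stage("read_pathway_db", read_pathway_db(config$pathway_db))
  logf("pathways\t", length(db))

  per <- list()
  for (ds in names(config$datasets)) {
    dcfg <- config$datasets[[ds]]
    ddir <- file.path(config$out_dir, paste0("dataset_", ds))
    dir.create(ddir, showWarnings = FALSE)
    cases <- stage("read_expression", read_expression(dcfg$cases))
    controls <- stage("read_controls", {
      ids <- names(dcfg$controls)
      if (is.null(ids)) ids <- paste0("ctrl_", seq_along(dcfg$controls))
      mapply(function(p, id) control_set(id, read_expression(p)),
             dcfg$controls, ids, SIMPLIFY = FALSE)
    })
    ic50 <- if (!is.null(dcfg$ic50)) {
      stage("read_ic50", read_ic50_csv(dcfg$ic50))
    } else {
      stage("fit_ic50", {
        fits <- lapply(read_plate_csv(dcfg$plates), fit_dose_response)
        ic50_table(fits)
      })
    }
    utils::write.csv(ic50, file.path(ddir, "ic50.csv"), row.names = FALSE,
                     quote = FALSE)
    records <- stage("pas_and_correlate", {
      do.call(rbind, lapply(controls, function(cs) {
        prof <- compute_pas_profile(cases, cs, db, config$params)
        logf("coverage ", ds, " ", cs$control_id, "\t",
             format(mean(prof$coverage), digits = 4))
        write_pas_profile(prof, file.path(ddir, paste0("pas_", cs$control_id,
                                                       ".tsv")))
        screen_pathways(prof, ic50, alpha = config$alpha_corr,
                        dataset_id = ds, log10_ic50 = config$log10_ic50)
      }))
    })
    rownames(records) <- NULL
    write_correlation_tsv(records, file.path(ddir, "correlations.tsv"))
    agg <- stage("aggregate",
                 aggregate_over_controls(records, ds,
                                         total_controls = length(controls)))
    utils::write.table(agg, file.path(ddir, "aggregate.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    per[[ds]] <- list(dataset_id = ds, ic50 = ic50, records = records,
                      aggregate = agg)
  }
  if (length(per) >= 2L) {
    ids <- names(per)
    res <- stage("intersect",
                 intersect_datasets(per[[ids[1]]]$aggregate,
                                    per[[ids[2]]]$aggregate,
                                    require_sign_match = config$require_sign_match,
                                    min_support = config$min_support))
    write_consensus_tsv(res, file.path(config$out_dir, "consensus.tsv"))
  } else {
    res <- list(consensus = NULL, discordant = NULL)
  }
  logf("consensus_pathways\t",
       if (is.null(res$consensus)) NA else nrow(res$consensus))
  invisible(c(res, list(per_dataset = per)))
}
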