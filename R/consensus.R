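#' Aggregate significant correlation records over normalization control sets
#'
#' Within one dataset and one drug, counts for every pathway how many
#' control sets yielded a significant correlation, split by sign. A
#' pathway significant with conflicting signs across control sets is
#' flagged sign-discordant.
#'
#' @param records Data frame of significant records (output of
#'   \code{\link{screen_pathways}} over one or more control sets), all from
#'   one dataset.
#' @param dataset_id Dataset label; defaults to the label on the records.
#' @param total_controls Number of control sets evaluated; defaults to the
#'   number of distinct \code{control_id} values seen.
#' @return Data frame with one row per (pathway, drug):
#'   \code{pathway_id}, \code{drug}, \code{dataset_id}, \code{support}
#'   (control sets significant with the majority sign), \code{support_pos},
#'   \code{support_neg}, \code{total_controls}, \code{sign},
#'   \code{discordant}.
#' @export
aggregate_over_controls <- function(records, dataset_id = NULL,
                                    total_controls = NULL) {
  if (nrow(records) == 0L)
    return(data.frame(pathway_id = character(), drug = character(),
                      dataset_id = character(), support = integer(),
                      support_pos = integer(), support_neg = integer(),
                      total_controls = integer(), sign = character(),
                      discordant = logical(), stringsAsFactors = FALSE))
  if (is.null(dataset_id)) dataset_id <- records$dataset_id[1L]
  if (!all(records$dataset_id == dataset_id))
    stop("records span more than one dataset_id")
  if (is.null(total_controls))
    total_controls <- length(unique(records$control_id))
  groups <- split(records, list(records$pathway_id, records$drug), drop = TRUE)
  out <- do.call(rbind, lapply(unname(groups), function(g) {
    pos <- length(unique(g$control_id[g$sign == "+"]))
    neg <- length(unique(g$control_id[g$sign == "-"]))
    disc <- pos > 0 && neg > 0
    data.frame(pathway_id = g$pathway_id[1L], drug = g$drug[1L],
               dataset_id = dataset_id,
               support = max(pos, neg), support_pos = pos, support_neg = neg,
               total_controls = total_controls,
               sign = if (pos >= neg) "+" else "-",
               discordant = disc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$drug, out$pathway_id), , drop = FALSE]
}

#' Intersect significant pathways across two independent datasets
#'
#' Consensus pathways: significant (with at least \code{min_support}
#' supporting control sets) in both datasets for the same drug, and — when
#' \code{require_sign_match} — with the same correlation sign in both.
#' Pathways that are sign-discordant within either dataset are excluded
#' from the consensus and returned separately for diagnostics, as are
#' cross-dataset sign conflicts.
#'
#' @param aggA,aggB Aggregates from \code{\link{aggregate_over_controls}}
#'   for the two datasets.
#' @param require_sign_match Require the same sign in both datasets
#'   (default \code{TRUE}).
#' @param min_support Minimum supporting control sets per dataset
#'   (default 1).
#' @return List with \code{consensus} (data frame: \code{drug},
#'   \code{pathway_id}, \code{sign}, \code{support_A}, \code{support_B},
#'   \code{total_controls_A}, \code{total_controls_B}) and
#'   \code{discordant} (excluded pathways with a \code{reason} column).
#' @export
intersect_datasets <- function(aggA, aggB, require_sign_match = TRUE,
                               min_support = 1L) {
  key <- function(a) paste(a$drug, a$pathway_id, sep = "\r")
  a <- aggA[!duplicated(key(aggA)) & aggA$support >= min_support, , drop = FALSE]
  b <- aggB[!duplicated(key(aggB)) & aggB$support >= min_support, , drop = FALSE]
  m <- merge(a, b, by = c("drug", "pathway_id"), suffixes = c("_A", "_B"))
  empty_cons <- data.frame(drug = character(), pathway_id = character(),
                           sign = character(), support_A = integer(),
                           support_B = integer(),
                           total_controls_A = integer(),
                           total_controls_B = integer(),
                           stringsAsFactors = FALSE)
  empty_disc <- data.frame(drug = character(), pathway_id = character(),
                           sign_A = character(), sign_B = character(),
                           reason = character(), stringsAsFactors = FALSE)
  if (nrow(m) == 0L)
    return(list(consensus = empty_cons, discordant = empty_disc))
  within_disc <- m$discordant_A | m$discordant_B
  cross_disc <- require_sign_match & (m$sign_A != m$sign_B)
  keep <- !within_disc & !cross_disc
  consensus <- if (any(keep)) {
    data.frame(drug = m$drug[keep], pathway_id = m$pathway_id[keep],
               sign = m$sign_A[keep], support_A = m$support_A[keep],
               support_B = m$support_B[keep],
               total_controls_A = m$total_controls_A[keep],
               total_controls_B = m$total_controls_B[keep],
               stringsAsFactors = FALSE)
  } else empty_cons
  drop <- within_disc | cross_disc
  discordant <- if (any(drop)) {
    data.frame(drug = m$drug[drop], pathway_id = m$pathway_id[drop],
               sign_A = m$sign_A[drop], sign_B = m$sign_B[drop],
               reason = ifelse(within_disc[drop], "within-dataset sign conflict",
                               "cross-dataset sign mismatch"),
               stringsAsFactors = FALSE)
  } else empty_disc
  o <- order(consensus$drug, consensus$pathway_id)
  list(consensus = consensus[o, , drop = FALSE], discordant = discordant)
}

#' Write consensus (and diagnostics) tables as TSV
#'
#' @param result List from \code{\link{intersect_datasets}}.
#' @param path Consensus TSV path; diagnostics go to
#'   \code{<path>.discordant.tsv} when non-empty.
#' @export
write_consensus_tsv <- function(result, path) {
  utils::write.table(result$consensus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(result$discordant) > 0L)
    utils::write.table(result$discordant,
                       paste0(sub("\\.tsv$", "", path), ".discordant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
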