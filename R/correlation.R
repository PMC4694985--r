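#' Pearson correlation of PAS with IC50 across cell lines
#'
#' Pairs are aligned by name when both vectors are named; pairs with a
#' missing value on either side (e.g. a censored IC50 excluded upstream)
#' are dropped. The two-sided p-value comes from the t-transform
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} with \code{n - 2} degrees of
#' freedom.
#'
#' @param pas_by_line Numeric vector of PAS values, one per cell line.
#' @param ic50_by_line Numeric vector of IC50 values for the same lines.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
correlate_pas_ic50 <- function(pas_by_line, ic50_by_line) {
  if (!is.null(names(pas_by_line)) && !is.null(names(ic50_by_line))) {
    shared <- intersect(names(pas_by_line), names(ic50_by_line))
    pas_by_line <- pas_by_line[shared]
    ic50_by_line <- ic50_by_line[shared]
  }
  if (length(pas_by_line) != length(ic50_by_line))
    stop("vectors must be aligned on cell-line id")
  ok <- stats::complete.cases(pas_by_line, ic50_by_line)
  x <- pas_by_line[ok]; y <- ic50_by_line[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete (PAS, IC50) pairs (n = ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one of the vectors: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Screen all pathways of a PAS profile against an IC50 table
#'
#' For each (pathway, drug), correlates the pathway's PAS across cell
#' lines with that drug's IC50 values and keeps the records with
#' \code{p < alpha}. Censored IC50s are excluded pairwise; constant
#' (zero-variance) pathways are skipped with a warning.
#'
#' @param pas_profile A \code{\link{compute_pas_profile}} result (columns
#'   named by cell line).
#' @param ic50_table Data frame with columns \code{drug}, \code{cell_line},
#'   \code{ic50_uM} and optional \code{censored}.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @param dataset_id Label recorded on every output row.
#' @param log10_ic50 Correlate against log10(IC50) instead of the raw scale
#'   (default \code{FALSE}).
#' @param adjust_p Apply Benjamini-Hochberg adjustment per drug before
#'   thresholding (default \code{FALSE}; the default screen uses raw p).
#' @return Data frame of significant records: \code{pathway_id},
#'   \code{drug}, \code{dataset_id}, \code{control_id}, \code{n}, \code{r},
#'   \code{p}, \code{sign}.
#' @export
screen_pathways <- function(pas_profile, ic50_table, alpha = 0.05,
                            dataset_id = "dataset", log10_ic50 = FALSE,
                            adjust_p = FALSE) {
  stopifnot(inherits(pas_profile, "pas_profile"), alpha >= 0, alpha <= 1)
  pas <- pas_profile$pas
  if (!"censored" %in% names(ic50_table)) ic50_table$censored <- FALSE
  out <- list()
  for (drug in unique(ic50_table$drug)) {
    tab <- ic50_table[ic50_table$drug == drug & !ic50_table$censored, ]
    ic50 <- stats::setNames(tab$ic50_uM, tab$cell_line)
    if (log10_ic50) ic50 <- log10(ic50)
    shared <- intersect(colnames(pas), names(ic50))
    if (length(shared) == 0L)
      stop("no shared cell lines between PAS profile and IC50 table for drug '",
           drug, "'")
    if (length(shared) < 3L)
      stop("fewer than 3 shared cell lines for drug '", drug, "'")
    y <- ic50[shared]
    res <- lapply(rownames(pas), function(pid) {
      x <- pas[pid, shared]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
      ct <- stats::cor.test(x, y, method = "pearson")
      data.frame(pathway_id = pid, drug = drug,
                 dataset_id = dataset_id,
                 control_id = pas_profile$control_id,
                 n = length(shared), r = unname(ct$estimate),
                 p = ct$p.value, stringsAsFactors = FALSE)
    })
    skipped <- sum(vapply(res, is.null, logical(1)))
    if (skipped > 0)
      warning(skipped, " constant pathway(s) skipped for drug '", drug, "'")
    res <- do.call(rbind, res)
    if (is.null(res)) next
    if (adjust_p) {
      res$p <- stats::p.adjust(res$p, method = "BH")
    }
    out[[drug]] <- res[res$p < alpha, , drop = FALSE]
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), drug = character(),
                      dataset_id = character(), control_id = character(),
                      n = integer(), r = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$sign <- ifelse(out$r > 0, "+", "-")
  out
}

#' Write correlation records as TSV
#'
#' @param records Data frame from \code{\link{screen_pathways}}.
#' @param path Output path.
#' @export
write_correlation_tsv <- function(records, path) {
  cols <- c("pathway_id", "drug", "dataset_id", "control_id", "n", "r", "p",
            "sign")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
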