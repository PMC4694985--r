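#' Default PAS engine parameters
#'
#' \describe{
#'   \item{alpha_gene}{Significance level of the per-gene tolerance-interval
#'     test (default 0.05).}
#'   \item{low_thresh, high_thresh}{Fold-change bounds on the case-to-normal
#'     ratio; a gene with CNR inside \code{[low_thresh, high_thresh]} is
#'     considered essentially normal (defaults 0.66 and 1.5).}
#'   \item{btif_polarity}{\code{"perturbed"} (default) flags genes whose
#'     expression is significantly perturbed; \code{"literal"} inverts the
#'     flag (see the methods vignette for why the default is the sensible
#'     reading).}
#'   \item{min_coverage}{Minimum fraction of database genes that must be
#'     present in the expression matrix (default 0.5).}
#'   \item{size_normalize}{Divide each pathway score by its member count
#'     (default \code{FALSE}; the scoring formula has no size term).}
#' }
#'
#' @param alpha_gene,low_thresh,high_thresh,btif_polarity,min_coverage,size_normalize
#'   See description.
#' @return Named list of parameters.
#' @export
pas_params <- function(alpha_gene = 0.05, low_thresh = 0.66, high_thresh = 1.5,
                       btif_polarity = c("perturbed", "literal"),
                       min_coverage = 0.5, size_normalize = FALSE) {
  btif_polarity <- match.arg(btif_polarity)
  stopifnot(alpha_gene > 0, alpha_gene <= 1,
            low_thresh > 0, low_thresh < 1, high_thresh > 1)
  list(alpha_gene = alpha_gene, low_thresh = low_thresh,
       high_thresh = high_thresh, btif_polarity = btif_polarity,
       min_coverage = min_coverage, size_normalize = size_normalize)
}

#' Case-to-normal expression ratio (CNR)
#'
#' Ratio of a gene's expression in the case sample to its mean expression
#' across the control samples.
#'
#' @param case_value Positive case intensity (vectorized over genes).
#' @param control_values Numeric vector of positive control intensities
#'   (length >= 2), or, when \code{case_value} is a vector, a matrix with
#'   one row per gene.
#' @return CNR value(s), strictly positive.
#' @export
compute_cnr <- function(case_value, control_values) {
  if (is.matrix(control_values)) {
    if (ncol(control_values) < 2L) stop("need at least 2 control samples")
    if (any(control_values <= 0) || any(case_value <= 0))
      stop("CNR requires strictly positive intensities")
    return(case_value / rowMeans(control_values))
  }
  if (length(control_values) < 2L) stop("need at least 2 control samples")
  if (any(control_values <= 0) || any(case_value <= 0))
    stop("CNR requires strictly positive intensities")
  case_value / mean(control_values)
}

# two-sided p of one case observation against the control sample:
# t = (x - mean) / (sd * sqrt(1 + 1/n)), df = n - 1 (prediction-style
# tolerance check for a single new observation)
tolerance_p <- function(case_value, ctrl_mean, ctrl_sd, n) {
  p <- rep(1, length(case_value))
  pos <- ctrl_sd > 0
  if (any(pos)) {
    z <- (case_value[pos] - ctrl_mean[pos]) /
      (ctrl_sd[pos] * sqrt(1 + 1 / n))
    p[pos] <- 2 * stats::pt(-abs(z), df = n - 1)
  }
  p
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' Flags a gene as significantly perturbed in the case sample: the flag is
#' 1 when the case value falls outside the tolerance interval of the
#' control distribution (two-sided p < \code{alpha_gene}) AND the CNR lies
#' beyond the fold-change bounds (below \code{low_thresh} or above
#' \code{high_thresh}); otherwise 0. With
#' \code{btif_polarity = "literal"} the flag is inverted, preserving a
#' word-for-word reading of the original description.
#'
#' Controls with zero variance cannot support the statistical criterion;
#' their p is reported as 1 with a warning, so such genes are never flagged
#' under the default polarity.
#'
#' @param case_value Positive case intensity.
#' @param control_values Numeric vector of positive control intensities.
#' @param alpha_gene,low_thresh,high_thresh,btif_polarity See
#'   \code{\link{pas_params}}.
#' @return List with elements \code{btif} (0/1), \code{p_gene}, \code{cnr}.
#' @export
compute_btif <- function(case_value, control_values, alpha_gene = 0.05,
                         low_thresh = 0.66, high_thresh = 1.5,
                         btif_polarity = c("perturbed", "literal")) {
  btif_polarity <- match.arg(btif_polarity)
  cnr <- compute_cnr(case_value, control_values)
  n <- length(control_values)
  s <- stats::sd(control_values)
  if (s == 0) warning("zero-variance control vector: p_gene set to 1")
  p <- tolerance_p(case_value, mean(control_values), s, n)
  flag <- as.integer(p < alpha_gene & (cnr < low_thresh | cnr > high_thresh))
  if (btif_polarity == "literal") flag <- 1L - flag
  list(btif = flag, p_gene = p, cnr = cnr)
}

#' Pathway activation strength of one pathway in one sample
#'
#' The signed single-sample score: the sum over member genes of
#' \code{arr * btif * log10(cnr)} — each significantly perturbed gene
#' contributes its log10 fold-change weighted by its activator/repressor
#' role; unperturbed genes and genes absent from the matrix contribute 0.
#' A positive score means the pathway is up-activated relative to the
#' normal controls.
#'
#' @param pw A \code{\link{pathway}}.
#' @param gene_stats Data frame with columns \code{gene_symbol},
#'   \code{cnr}, \code{btif} (as produced gene-by-gene by
#'   \code{\link{compute_btif}}).
#' @param size_normalize Divide by the member count (default \code{FALSE}).
#' @return Signed scalar score.
#' @export
compute_pas <- function(pw, gene_stats, size_normalize = FALSE) {
  stopifnot(inherits(pw, "pathway"), is.data.frame(gene_stats))
  idx <- match(pw$members$gene_symbol, toupper(gene_stats$gene_symbol))
  present <- !is.na(idx)
  if (!any(present)) {
    warning("pathway '", pw$pathway_id,
            "': no member gene present in the matrix; PAS = 0")
    return(0)
  }
  terms <- pw$members$arr[present] * gene_stats$btif[idx[present]] *
    log10(gene_stats$cnr[idx[present]])
  pas <- sum(terms)
  if (size_normalize) pas <- pas / nrow(pw$members)
  pas
}

#' Pathway activation profile against one control set
#'
#' For every case sample: case and control columns are quantile-normalized
#' jointly on their shared gene universe, per-gene CNR and BTIF are
#' computed against the control set, and every pathway is scored. The
#' whole grid is deterministic given its inputs.
#'
#' @param cases Genes x case-samples matrix of positive linear intensities.
#' @param control A \code{\link{control_set}}.
#' @param db A \code{\link{pathway_db}}.
#' @param params Parameter list from \code{\link{pas_params}}.
#' @param normalize Quantile-normalize the joint matrix first
#'   (default \code{TRUE}).
#' @return Object of class \code{"pas_profile"}: list with \code{control_id},
#'   \code{pas} (pathways x case-samples matrix), \code{params},
#'   \code{coverage} (per-pathway fraction of members present).
#' @export
compute_pas_profile <- function(cases, control, db, params = pas_params(),
                                normalize = TRUE) {
  stopifnot(inherits(control, "control_set"), inherits(db, "pathway_db"))
  j <- join_on_genes(cases, control$matrix)
  genes <- rownames(j$cases)
  dbg <- pathway_genes(db)
  cov_total <- mean(dbg %in% genes)
  if (cov_total < params$min_coverage)
    stop(sprintf("gene coverage %.1f%% below the required %.1f%% (%d of %d database genes present)",
                 100 * cov_total, 100 * params$min_coverage,
                 sum(dbg %in% genes), length(dbg)))
  if (normalize) {
    joint <- quantile_normalize(cbind(j$cases, j$controls))
    cs <- joint[, seq_len(ncol(j$cases)), drop = FALSE]
    ct <- joint[, -seq_len(ncol(j$cases)), drop = FALSE]
  } else {
    cs <- j$cases
    ct <- j$controls
  }
  n <- ncol(ct)
  mu <- rowMeans(ct)
  sdev <- apply(ct, 1L, stats::sd)
  if (any(sdev == 0))
    warning(sum(sdev == 0), " gene(s) with zero-variance controls: p_gene set to 1")
  cnr <- cs / mu
  pmat <- matrix(1, nrow(cs), ncol(cs), dimnames = dimnames(cs))
  pos <- sdev > 0
  if (any(pos)) {
    z <- (cs[pos, , drop = FALSE] - mu[pos]) / (sdev[pos] * sqrt(1 + 1 / n))
    pmat[pos, ] <- 2 * stats::pt(-abs(z), df = n - 1)
  }
  btif <- (pmat < params$alpha_gene) &
    (cnr < params$low_thresh | cnr > params$high_thresh)
  if (params$btif_polarity == "literal") btif <- !btif
  contrib <- btif * log10(cnr)   # per-gene signed contribution before ARR
  pas <- matrix(0, length(db), ncol(cs),
                dimnames = list(names(db), colnames(cs)))
  coverage <- stats::setNames(numeric(length(db)), names(db))
  for (k in seq_along(db)) {
    m <- db[[k]]$members
    idx <- match(m$gene_symbol, genes)
    present <- !is.na(idx)
    coverage[k] <- mean(present)
    if (!any(present)) next
    w <- m$arr[present]
    block <- contrib[idx[present], , drop = FALSE]
    pas[k, ] <- colSums(block * w)
    if (params$size_normalize) pas[k, ] <- pas[k, ] / nrow(m)
  }
  if (any(coverage == 0))
    warning(sum(coverage == 0),
            " pathway(s) with no member gene in the matrix scored 0")
  structure(list(control_id = control$control_id, pas = pas,
                 params = params, coverage = coverage),
            class = "pas_profile")
}

#' @export
print.pas_profile <- function(x, ...) {
  cat("pas_profile vs control '", x$control_id, "': ",
      nrow(x$pas), " pathways x ", ncol(x$pas), " case samples\n", sep = "")
  invisible(x)
}

#' Write a PAS profile as TSV plus a key-value sidecar
#'
#' The matrix goes to \code{path}; control id and parameters go to
#' \code{<path>.meta} as \code{key<TAB>value} lines.
#'
#' @param profile A \code{pas_profile}.
#' @param path Output TSV path.
#' @export
write_pas_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pas_profile"))
  write_expression(profile$pas, path, id_col = "pathway_id")
  meta <- c(control_id = profile$control_id,
            lapply(profile$params, as.character))
  writeLines(paste(names(meta), unlist(meta), sep = "\t"),
             paste0(path, ".meta"))
  invisible(NULL)
}
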