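#' Read an expression matrix, optionally collapsing probes to genes
#'
#' Reads a tab-delimited genes-or-probes x samples table of linear-scale
#' intensities (first column the probe/gene id, header row the sample ids).
#' If a probe map is supplied, probe rows are mapped to gene symbols and
#' rows hitting the same gene are collapsed by their mean; unmapped probes
#' are dropped with a message. Intensities at or below the floor
#' \code{floor_eps} are clamped to it so that downstream log-ratios stay
#' finite.
#'
#' @param path Path to the TSV matrix.
#' @param probe_map Optional path to a two-column TSV
#'   \code{probe<TAB>gene_symbol} (no header required; a header line whose
#'   first field is \code{"probe"} is skipped).
#' @param floor_eps Positive floor applied to all intensities
#'   (default \code{1e-6}).
#' @return Numeric matrix, gene symbols (upper-cased) as row names, sample
#'   ids as column names.
#' @export
read_expression <- function(path, probe_map = NULL, floor_eps = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(path, ": need a header row and at least one data row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  widths <- lengths(fields[-1L])
  if (any(widths != length(header)))
    stop(path, ": ragged row at line ",
         which(widths != length(header))[1L] + 1L,
         " (expected ", length(header), " fields)")
  ids <- vapply(fields[-1L], `[[`, character(1), 1L)
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(fields[-1L], `[`, -1L)))),
    ncol = length(samples), byrow = TRUE,
    dimnames = list(ids, samples))
  if (anyNA(vals)) stop(path, ": non-numeric intensity value")
  if (!is.null(probe_map)) {
    map <- utils::read.delim(probe_map, header = FALSE,
                             colClasses = "character")
    if (ncol(map) < 2L) stop(probe_map, ": expected two columns probe, gene")
    if (tolower(map[1, 1]) == "probe") map <- map[-1L, , drop = FALSE]
    vals <- collapse_probes(vals, stats::setNames(map[[2L]], map[[1L]]))
  } else {
    rownames(vals) <- toupper(rownames(vals))
    if (anyDuplicated(rownames(vals)))
      vals <- collapse_probes(vals, stats::setNames(rownames(vals), rownames(vals)))
  }
  clamp_floor(vals, floor_eps)
}

# group probe rows by mapped gene symbol and average; drops unmapped probes
collapse_probes <- function(vals, probe2gene) {
  genes <- toupper(unname(probe2gene[rownames(vals)]))
  keep <- !is.na(genes) & nzchar(genes)
  if (!any(keep)) stop("no probe mapped to a gene symbol")
  if (sum(!keep) > 0)
    message(sum(!keep), " unmapped probe(s) dropped")
  vals <- vals[keep, , drop = FALSE]
  genes <- genes[keep]
  out <- rowsum(vals, group = genes) / as.vector(table(genes)[sort(unique(genes))])
  out[order(match(rownames(out), genes)), , drop = FALSE]
}

clamp_floor <- function(vals, floor_eps) {
  stopifnot(is.numeric(floor_eps), floor_eps > 0)
  vals[vals <= floor_eps] <- floor_eps
  vals
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param id_col Name of the first (identifier) column.
#' @export
write_expression <- function(mat, path, id_col = "gene") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a control set
#'
#' A control set is one normal-tissue expression dataset used as the
#' normalization reference when computing case-to-normal ratios. At least
#' two samples are required so that a control mean and dispersion exist.
#'
#' @param control_id Identifier of the control dataset.
#' @param matrix Genes x samples numeric matrix of positive intensities.
#' @return Object of class \code{"control_set"}.
#' @export
control_set <- function(control_id, matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (ncol(matrix) < 2L)
    stop("control set '", control_id, "': at least 2 samples required")
  if (any(matrix <= 0))
    stop("control set '", control_id, "': non-positive intensities")
  rownames(matrix) <- toupper(rownames(matrix))
  structure(list(control_id = as.character(control_id), matrix = matrix,
                 n_samples = ncol(matrix)),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat("control_set '", x$control_id, "': ", nrow(x$matrix), " genes x ",
      x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the identical empirical
#' distribution: the vector of row-wise means of the sorted columns,
#' reassigned within each column by rank. Tied values receive the mean of
#' the candidate normalized values at their tied ranks. Case and control
#' samples intended for case-to-normal comparison should be passed jointly
#' so that both end up on a common scale.
#'
#' @param mat Numeric genes x samples matrix with at least 2 columns.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs at least 2 samples")
  if (nrow(mat) < 1L) stop("empty gene set")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Join case and control matrices on their shared gene universe
#'
#' Inner join by (upper-cased) gene symbol, as needed when matrices come
#' from different array platforms; unmatched genes are dropped with a
#' message reporting the count.
#'
#' @param cases Genes x case-samples matrix.
#' @param controls Genes x control-samples matrix.
#' @return List with elements \code{cases} and \code{controls}, row-aligned
#'   on the common gene set.
#' @export
join_on_genes <- function(cases, controls) {
  rownames(cases) <- toupper(rownames(cases))
  rownames(controls) <- toupper(rownames(controls))
  shared <- intersect(rownames(cases), rownames(controls))
  if (length(shared) == 0L) stop("empty gene intersection between matrices")
  dropped <- (nrow(cases) - length(shared)) + (nrow(controls) - length(shared))
  if (dropped > 0)
    message(dropped, " gene row(s) outside the shared universe dropped")
  list(cases = cases[shared, , drop = FALSE],
       controls = controls[shared, , drop = FALSE])
}
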