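#' @keywords internal
"_PACKAGE"

#' Discrete activator/repressor role (ARR) levels
#'
#' The signed weight attached to each pathway member gene: -1 (repressor),
#' -0.5 (weak repressor), 0 (neutral), +0.5 (weak activator), +1 (activator).
#'
#' @format Numeric vector of length 5.
#' @export
ARR_LEVELS <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway definition
#'
#' A pathway is a named gene set in which every member gene carries a
#' discrete signed activator/repressor role (ARR). Gene symbols are
#' case-normalized to upper case so that matrices from different array
#' platforms can be joined on a common key.
#'
#' @param pathway_id Unique pathway identifier.
#' @param genes Character vector of member gene symbols.
#' @param arr Numeric vector of roles, same length as \code{genes}; each
#'   value must belong to \code{arr_levels}.
#' @param kind Pathway class, \code{"signaling"} or \code{"metabolic"}.
#' @param name Human-readable name; defaults to \code{pathway_id}.
#' @param arr_levels Allowed ARR alphabet (default the five-level
#'   \code{\link{ARR_LEVELS}}; pass \code{c(-1, 0, 1)} for the strict
#'   three-level scheme).
#' @return An object of class \code{"pathway"}.
#' @export
pathway <- function(pathway_id, genes, arr, kind = c("signaling", "metabolic"),
                    name = pathway_id, arr_levels = ARR_LEVELS) {
  kind <- match.arg(kind)
  stopifnot(is.character(genes), is.numeric(arr), length(genes) == length(arr))
  if (length(genes) < 1L)
    stop("pathway '", pathway_id, "': at least one member gene is required")
  genes <- toupper(genes)
  if (anyDuplicated(genes))
    stop("pathway '", pathway_id, "': duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (any(!nzchar(genes)))
    stop("pathway '", pathway_id, "': empty gene symbol")
  bad <- !arr %in% arr_levels
  if (any(bad))
    stop("pathway '", pathway_id, "': ARR value(s) ",
         paste(unique(arr[bad]), collapse = ", "),
         " outside the discrete set {", paste(arr_levels, collapse = ", "), "}")
  structure(
    list(pathway_id = as.character(pathway_id),
         name = as.character(name),
         kind = kind,
         members = data.frame(gene_symbol = genes, arr = as.numeric(arr),
                              stringsAsFactors = FALSE)),
    class = "pathway")
}

#' Construct a pathway database
#'
#' @param pathways List of \code{\link{pathway}} objects.
#' @return Object of class \code{"pathway_db"}: a list of pathways named by
#'   their ids.
#' @export
pathway_db <- function(pathways) {
  stopifnot(is.list(pathways))
  ok <- vapply(pathways, inherits, logical(1), what = "pathway")
  if (!all(ok)) stop("all elements must be 'pathway' objects")
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate pathway_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pathways) <- ids
  structure(pathways, class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  kinds <- vapply(x, function(p) p$kind, character(1))
  sizes <- vapply(x, function(p) nrow(p$members), integer(1))
  cat("pathway_db with ", length(x), " pathways (",
      sum(kinds == "signaling"), " signaling, ",
      sum(kinds == "metabolic"), " metabolic); ",
      "members per pathway: ", if (length(x)) min(sizes) else 0, "-",
      if (length(x)) max(sizes) else 0, "\n", sep = "")
  invisible(x)
}

#' @export
print.pathway <- function(x, ...) {
  cat("pathway '", x$pathway_id, "' (", x$kind, "), ",
      nrow(x$members), " member genes\n", sep = "")
  invisible(x)
}

# format an ARR value the way the file dialect writes it: +1, +0.5, 0, -0.5, -1
format_arr <- function(a) {
  s <- vapply(a, function(x) format(x, trim = TRUE, scientific = FALSE),
              character(1))
  ifelse(a > 0, paste0("+", s), s)
}

parse_arr <- function(s, arr_levels, where) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stop(where, ": unparseable ARR value '", s[which(is.na(v))[1]], "'")
  bad <- !v %in% arr_levels
  if (any(bad))
    stop(where, ": ARR value ", v[which(bad)[1]],
         " outside the discrete set {", paste(arr_levels, collapse = ", "), "}")
  v
}

#' Read a pathway database from the extended GMT dialect
#'
#' One pathway per line, tab-separated:
#' \code{pathway_id<TAB>kind<TAB>gene:arr<TAB>gene:arr...} where \code{kind}
#' is \code{signaling} or \code{metabolic} and \code{arr} is written as
#' \code{+1}, \code{+0.5}, \code{0}, \code{-0.5} or \code{-1}.
#'
#' @param path File path.
#' @param arr_levels Allowed ARR alphabet.
#' @return A \code{\link{pathway_db}} (empty file gives an empty database).
#' @export
read_pathway_db <- function(path, arr_levels = ARR_LEVELS) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(pathway_db(list()))
  pws <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    where <- paste0(path, " line ", i)
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(where, ": expected at least 3 tab-separated fields, got ", length(f))
    if (!f[2] %in% c("signaling", "metabolic"))
      stop(where, ": unknown pathway kind '", f[2], "'")
    toks <- strsplit(f[-(1:2)], ":", fixed = TRUE)
    nf <- vapply(toks, length, integer(1))
    if (any(nf != 2L))
      stop(where, ": malformed gene:arr token '", f[-(1:2)][which(nf != 2L)[1]], "'")
    pws[[i]] <- pathway(
      pathway_id = f[1],
      genes = vapply(toks, `[[`, character(1), 1L),
      arr = parse_arr(vapply(toks, `[[`, character(1), 2L), arr_levels, where),
      kind = f[2])
  }
  pathway_db(pws)
}

#' Write a pathway database in the extended GMT dialect
#'
#' Inverse of \code{\link{read_pathway_db}}: reading the written file
#' reproduces the database exactly.
#'
#' @param db A \code{\link{pathway_db}}.
#' @param path Output file path.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(db, function(p) {
    paste(c(p$pathway_id, p$kind,
            paste0(p$members$gene_symbol, ":", format_arr(p$members$arr))),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(unname(lines), con)
  invisible(NULL)
}

#' Read a plain GMT gene-set file
#'
#' Standard GMT (\code{id<TAB>description<TAB>gene<TAB>gene...}); every
#' member receives the default role \code{+1} and kind \code{"signaling"},
#' for interoperability with unsigned gene-set collections.
#'
#' @param path File path.
#' @param default_arr Role assigned to every gene (default \code{+1}).
#' @return A \code{\link{pathway_db}}.
#' @export
read_gmt <- function(path, default_arr = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  pws <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(path, " line ", i, ": expected at least 3 fields")
    genes <- unique(toupper(f[-(1:2)]))
    pathway(f[1], genes, rep(default_arr, length(genes)),
            kind = "signaling", name = f[2])
  })
  pathway_db(pws)
}

#' All genes referenced by a pathway database
#' @param db A \code{\link{pathway_db}}.
#' @return Character vector of unique gene symbols.
#' @export
pathway_genes <- function(db) {
  unique(unlist(lapply(db, function(p) p$members$gene_symbol), use.names = FALSE))
}
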