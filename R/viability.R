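#' Percent viability of one treated well
#'
#' MTT-style viability:
#' \code{(OD_treated - OD_blank) / (mean OD_control - OD_blank) * 100},
#' where blank wells contain no cells and control wells are untreated.
#' The raw value is returned unclipped, so it may exceed 100 or fall
#' below 0 with noisy optical densities.
#'
#' @param od_treated_well Optical density of the treated well (vectorized).
#' @param od_blank_mean Mean OD of the blank (no-cell) wells.
#' @param od_control_mean Mean OD of the untreated control wells; must
#'   exceed \code{od_blank_mean}.
#' @return Percent viability.
#' @export
compute_viability <- function(od_treated_well, od_blank_mean, od_control_mean) {
  if (od_control_mean <= od_blank_mean)
    stop("assay failure: control OD (", od_control_mean,
         ") does not exceed blank OD (", od_blank_mean, ")")
  (od_treated_well - od_blank_mean) / (od_control_mean - od_blank_mean) * 100
}

#' Default drug concentration ladder (micromolar)
#'
#' The eight-point dose grid used throughout: 0 (untreated anchor) plus
#' seven two-fold-spaced doses up to 50 uM.
#'
#' @format Numeric vector of length 8.
#' @export
DOSE_LADDER_UM <- c(0, 0.8, 1.56, 3.1, 6.25, 12.5, 25, 50)

#' Construct a dose-response experiment
#'
#' One drug on one cell line: a concentration ladder, a replicates x
#' concentrations grid of treated-well ODs, untreated control ODs, and
#' no-cell blank ODs.
#'
#' @param drug,cell_line Identifiers.
#' @param concentrations Non-negative doses in uM; strictly increasing once
#'   the 0-dose anchor is removed, with at least 3 distinct nonzero doses.
#' @param od_treated Replicates x concentrations matrix of ODs (columns
#'   aligned with \code{concentrations}).
#' @param od_untreated Vector of untreated control-well ODs.
#' @param od_blank Vector of blank-well ODs.
#' @return Object of class \code{"dose_response"}.
#' @export
dose_response <- function(drug, cell_line, concentrations, od_treated,
                          od_untreated, od_blank) {
  stopifnot(is.numeric(concentrations), all(concentrations >= 0))
  nz <- sort(unique(concentrations[concentrations > 0]))
  if (length(nz) < 3L)
    stop("at least 3 distinct nonzero concentrations required for fitting")
  cpos <- concentrations[concentrations > 0]
  if (is.unsorted(cpos, strictly = TRUE))
    stop("nonzero concentrations must be strictly increasing")
  od_treated <- as.matrix(od_treated)
  if (ncol(od_treated) != length(concentrations))
    stop("od_treated must have one column per concentration")
  structure(list(drug = as.character(drug), cell_line = as.character(cell_line),
                 concentrations = as.numeric(concentrations),
                 od_treated = od_treated,
                 od_untreated = as.numeric(od_untreated),
                 od_blank = as.numeric(od_blank),
                 n_replicates = nrow(od_treated)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("dose_response: ", x$drug, " on ", x$cell_line, ", ",
      length(x$concentrations), " doses x ", x$n_replicates,
      " replicates\n", sep = "")
  invisible(x)
}

#' Mean percent viability per concentration
#'
#' @param exp A \code{\link{dose_response}}.
#' @return Data frame with columns \code{concentration} and
#'   \code{viability} (mean over replicates).
#' @export
viability_curve <- function(exp) {
  stopifnot(inherits(exp, "dose_response"))
  blank <- mean(exp$od_blank)
  ctrl <- mean(exp$od_untreated)
  v <- compute_viability(exp$od_treated, blank, ctrl)
  data.frame(concentration = exp$concentrations,
             viability = colMeans(v))
}

# 4PL on the linear-dose parameterization: v(c) = bottom +
# (top - bottom) / (1 + (c / ic50)^hill); fitted on log10 dose via
# the log10(ic50) parameter for numerical stability
fourpl <- function(conc, top, bottom, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log_ic50)))
}

#' Fit a four-parameter logistic dose-response curve and estimate IC50
#'
#' Least-squares fit of
#' \code{v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)} to the mean
#' viability per nonzero concentration (the 0-dose wells anchor the
#' viability normalization only and are excluded from the logistic fit).
#' Initialization is a fixed deterministic multi-start grid: hill in
#' \{0.5, 1, 2\} crossed with ic50 at every interior dose; the start with
#' the best residual sum of squares wins.
#'
#' The reported \code{ic50} is the fitted inflection parameter (relative
#' IC50); \code{abs_ic50} is the dose at which the fitted curve crosses
#' 50\% viability. The result is censored (\code{censored = TRUE},
#' \code{ic50 = max dose}) when the fitted IC50 exceeds the highest tested
#' dose or the fitted curve never reaches 50\% within the tested range.
#'
#' @param exp A \code{\link{dose_response}}.
#' @return Object of class \code{"ic50_result"}: list with \code{drug},
#'   \code{cell_line}, \code{ic50} (uM), \code{censored}, \code{hill_slope},
#'   \code{top}, \code{bottom}, \code{abs_ic50}, \code{rss},
#'   \code{converged}.
#' @export
fit_dose_response <- function(exp) {
  stopifnot(inherits(exp, "dose_response"))
  curve <- viability_curve(exp)
  fit <- fit_fourpl(curve$concentration, curve$viability)
  structure(c(list(drug = exp$drug, cell_line = exp$cell_line), fit),
            class = "ic50_result")
}

#' Fit a 4PL curve to mean viability values
#'
#' Workhorse behind \code{\link{fit_dose_response}}; also usable directly
#' on a pre-averaged (dose, viability) table. A dose-0 row, when present,
#' enters the fit as the drug-free anchor (the model evaluates to
#' \code{top} at zero concentration), which pins the upper asymptote of
#' the control-normalized curve.
#'
#' @param conc Non-negative doses (uM), at least 3 distinct nonzero values.
#' @param viability Mean percent viability at each dose.
#' @return List with \code{ic50}, \code{censored}, \code{hill_slope},
#'   \code{top}, \code{bottom}, \code{abs_ic50}, \code{rss},
#'   \code{converged}.
#' @export
fit_fourpl <- function(conc, viability) {
  stopifnot(length(conc) == length(viability), all(conc >= 0))
  nz <- sort(conc[conc > 0])
  if (length(unique(nz)) < 3L) stop("fewer than 3 nonzero doses")
  o <- order(conc)
  conc <- conc[o]; viability <- viability[o]
  dmin <- min(nz); dmax <- max(nz)
  df <- data.frame(conc = conc, v = viability)
  interior <- nz[-c(1L, length(nz))]
  starts <- expand.grid(hill = c(0.5, 1, 2), log_ic50 = log10(interior))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        v ~ fourpl(conc, top, bottom, log_ic50, hill), data = df,
        start = list(top = max(viability),
                     bottom = max(min(viability, 0), -30),
                     log_ic50 = starts$log_ic50[i], hill = starts$hill[i]),
        lower = c(top = 50, bottom = -30,
                  log_ic50 = log10(dmin / 10), hill = 0.1),
        upper = c(top = 150, bottom = 110,
                  log_ic50 = log10(dmax * 10), hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = f, rss = rss)
  }
  if (is.null(best)) {
    return(list(ic50 = dmax, censored = TRUE, hill_slope = NA_real_,
                top = NA_real_, bottom = NA_real_, abs_ic50 = NA_real_,
                rss = NA_real_, converged = FALSE))
  }
  p <- as.list(stats::coef(best$fit))
  ic50 <- 10^p$log_ic50
  # absolute IC50: dose where the fitted curve crosses 50% viability
  abs_ic50 <- if ((p$top - 50) * (p$bottom - 50) < 0) {
    ic50 * ((p$top - 50) / (50 - p$bottom))^(1 / p$hill)
  } else NA_real_
  censored <- ic50 > dmax ||
    !any(fourpl(conc, p$top, p$bottom, p$log_ic50, p$hill) < 50)
  list(ic50 = if (censored) dmax else ic50, censored = censored,
       hill_slope = p$hill, top = p$top, bottom = p$bottom,
       abs_ic50 = abs_ic50, rss = best$rss, converged = TRUE)
}

#' @export
print.ic50_result <- function(x, ...) {
  cat("ic50_result: ", x$drug, " on ", x$cell_line, ": IC50 ",
      if (x$censored) paste0("> ", format(x$ic50)) else format(x$ic50),
      " uM (hill ", format(x$hill_slope, digits = 3), ", converged ",
      x$converged, ")\n", sep = "")
  invisible(x)
}

#' Read a plate-layout CSV into dose-response experiments
#'
#' Expected columns: \code{drug, cell_line, concentration_uM, replicate,
#' od, well_type} with \code{well_type} in \{treated, control, blank\}.
#' Blank and control wells are shared per (drug, cell line) group.
#'
#' @param path CSV path.
#' @return List of \code{\link{dose_response}} objects.
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "cell_line", "concentration_uM", "replicate", "od",
            "well_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  groups <- split(d, list(d$drug, d$cell_line), drop = TRUE)
  lapply(unname(groups), function(g) {
    tr <- g[g$well_type == "treated", ]
    conc <- sort(unique(tr$concentration_uM))
    reps <- sort(unique(tr$replicate))
    od <- matrix(NA_real_, length(reps), length(conc))
    for (i in seq_len(nrow(tr)))
      od[match(tr$replicate[i], reps), match(tr$concentration_uM[i], conc)] <-
        tr$od[i]
    dose_response(g$drug[1], g$cell_line[1], conc, od,
                  od_untreated = g$od[g$well_type == "control"],
                  od_blank = g$od[g$well_type == "blank"])
  })
}

#' Write fitted IC50 results as CSV
#'
#' Columns: drug, cell_line, ic50_uM, censored, hill, top, bottom, rss,
#' converged.
#'
#' @param results List of \code{ic50_result} objects.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_ic50_csv <- function(results, path) {
  df <- ic50_table(results)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Collect IC50 results into a table
#'
#' @param results List of \code{ic50_result} objects.
#' @return Data frame with one row per (drug, cell line).
#' @export
ic50_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(drug = r$drug, cell_line = r$cell_line, ic50_uM = r$ic50,
               censored = r$censored, hill = r$hill_slope, top = r$top,
               bottom = r$bottom, rss = r$rss, converged = r$converged,
               stringsAsFactors = FALSE)
  }))
}

#' Read a pre-computed IC50 table
#'
#' Accepts external (e.g. public drug-screen) IC50 tables directly: a CSV
#' with columns \code{drug, cell_line, ic50} (or \code{ic50_uM}) and an
#' optional \code{censored} column. Values are stored as provided; the
#' declared \code{unit} is carried along rather than guessed.
#'
#' @param path CSV path.
#' @param unit Declared unit of the ic50 column (default \code{"uM"}).
#' @return Data frame with columns drug, cell_line, ic50_uM, censored and
#'   attribute \code{unit}.
#' @export
read_ic50_csv <- function(path, unit = "uM") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"ic50_uM" %in% names(d)) {
    if (!"ic50" %in% names(d)) stop(path, ": no ic50 or ic50_uM column")
    d$ic50_uM <- d$ic50
  }
  if (!"censored" %in% names(d)) d$censored <- FALSE
  miss <- setdiff(c("drug", "cell_line"), names(d))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  out <- d[, c("drug", "cell_line", "ic50_uM", "censored")]
  attr(out, "unit") <- unit
  out
}
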