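# shared builders for small in-code fixtures

# wrap a pathways x cell-lines matrix as a pas_profile
make_profile <- function(pas, control_id = "ctrl1", params = pas_params()) {
  structure(list(control_id = control_id, pas = pas, params = params,
                 coverage = stats::setNames(rep(1, nrow(pas)), rownames(pas))),
            class = "pas_profile")
}

# simple ic50 table for one drug
make_ic50_table <- function(values, drug = "drugX", censored = FALSE) {
  data.frame(drug = drug, cell_line = names(values), ic50_uM = unname(values),
             censored = censored, stringsAsFactors = FALSE)
}

# a correlation record row as screen_pathways emits it
make_record <- function(pathway_id, control_id, sign, drug = "drugX",
                        dataset_id = "A", p = 0.01) {
  data.frame(pathway_id = pathway_id, drug = drug, dataset_id = dataset_id,
             control_id = control_id, n = 10L,
             r = if (sign == "+") 0.8 else -0.8, p = p, sign = sign,
             stringsAsFactors = FALSE)
}

# independent sort/average/unsort quantile-normalization oracle
# (valid for matrices without ties)
qn_oracle <- function(m) {
  mu <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) mu[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(m)
  out
}

# independent two-criteria flag oracle: single-observation t check plus
# fold-change bounds, applied separately
btif_oracle <- function(case, controls, alpha = 0.05, low = 0.66, high = 1.5) {
  n <- length(controls)
  tt <- (case - mean(controls)) / (sd(controls) * sqrt(1 + 1 / n))
  p <- 2 * pt(-abs(tt), df = n - 1)
  cnr <- case / mean(controls)
  as.integer((p < alpha) & (cnr < low | cnr > high))
}

# noise-free viability from the 4PL model
fourpl_viability <- function(conc, ic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}
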