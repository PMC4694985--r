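---
title: "Linking pathway activation to drug sensitivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking pathway activation to drug sensitivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paslink)
```

## The problem

A drug's half-maximal inhibitory concentration (IC50) varies widely across
cancer cell lines, and single-gene expression markers explain that
variation poorly: genes act inside signaling and metabolic pathways, and
different member genes can be perturbed in different lines with the same
net effect on pathway output. `paslink` implements a pathway-level
analysis: it scores the activation of each pathway in each cell line from
its pre-treatment transcriptome, estimates each line's IC50 from
dose–response viability plates, screens every (pathway, drug) pair for
correlation between the two, and keeps only pathways whose correlation
replicates — with the same sign — in two independent datasets.

## Pathway activation strength

For a case sample and a set of normal control samples, each gene $n$ gets a
*case-to-normal ratio*

$$\mathrm{CNR}_n = \frac{x_n^{\text{case}}}{\overline{x}_n^{\text{control}}},$$

the ratio of its (linear-scale) expression to its mean expression in the
controls, after the case and control columns have been quantile-normalized
jointly on their shared gene universe. A Boolean *beyond-tolerance-interval
flag* gates each gene's contribution:

$$\mathrm{BTIF}_n = 1 \iff p_n < \alpha_{\text{gene}} \;\wedge\;
  (\mathrm{CNR}_n < \theta_{\text{low}} \vee \mathrm{CNR}_n > \theta_{\text{high}}),$$

so a gene counts only when it is both statistically outside the control
tolerance interval and changed by a substantial fold. The score of pathway
$p$ is then the signed sum

$$\mathrm{PAS}_p = \sum_{n \in p} \mathrm{ARR}_{np} \cdot \mathrm{BTIF}_n
  \cdot \lg \mathrm{CNR}_n,$$

where $\mathrm{ARR}_{np} \in \{-1, -0.5, 0, +0.5, +1\}$ encodes the gene
product's activator/repressor role in the pathway and $\lg$ is $\log_{10}$.
A positive PAS means the pathway is up-activated relative to normal tissue.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `alpha_gene` | 0.05 | per-gene tolerance-interval significance |
| `low_thresh`, `high_thresh` | 0.66, 1.5 | fold-change window of "essentially normal" CNR |
| `btif_polarity` | `"perturbed"` | flag perturbed genes (see below) |
| `alpha_corr` | 0.05 | raw-p threshold of the correlation screen |
| `min_support` | 1 | control sets needed for "significant in a dataset" |
| floor $\varepsilon$ | $10^{-6}$ | intensity clamp keeping $\lg(\mathrm{CNR})$ finite |

The verbal definition of the flag in the literature can be read either
way ("equals zero when … passed the two criteria that demark significantly
perturbed expression" — while also calling the criteria *within* the
tolerance interval). We flag *perturbed* genes: under the opposite reading
only unperturbed genes would contribute, and the score of a strongly
perturbed pathway would tend to zero, contradicting the method's purpose.
The literal inverse remains available as `btif_polarity = "literal"`.

The five-level ARR alphabet (strong/weak activator, neutral, weak/strong
repressor) follows the original pathway-scoring method; a strict
three-level scheme can be enforced via `arr_levels = c(-1, 0, 1)`.

### The tolerance-interval test

The original description names no test. We use the standard check of a
single new observation against a reference sample: $t = (x -
\bar{x}_c)/(s_c\sqrt{1 + 1/n})$ with $n - 1$ degrees of freedom, two-sided.
Controls with zero variance (possible after quantile normalization assigns
identical values) get $p = 1$ and a warning, so they can never be flagged
through the statistical criterion.

### Multi-control normalization

The choice of normal reference shifts every CNR, so PAS is computed
independently against each of several control datasets (different normal
tissues; by default 11 for one dataset and 3 for the other, 4–33 samples
each). Cases are quantile-normalized *jointly* with each control set — a
deliberate choice the source method leaves open — so that CNR compares
values on a single common scale and is invariant to each platform's overall
intensity scale. Normalization is done on linear intensities; genes are
joined across platforms by upper-cased symbol, with unmatched genes dropped
and counted. No per-pathway size normalization is applied (the score's
definition has none); `size_normalize = TRUE` divides by member count for
users who want comparable magnitudes across pathways.

## IC50 estimation

Viability of a treated well is
$(\mathrm{OD} - \mathrm{OD}_{\text{blank}}) / (\overline{\mathrm{OD}}_{\text{control}} -
\mathrm{OD}_{\text{blank}}) \times 100\%$, unclipped. Mean viabilities per
dose are fitted with the four-parameter logistic

$$v(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}
  {1 + (c/\mathrm{IC50})^{\text{hill}}}$$

by Levenberg–Marquardt least squares over a deterministic multi-start grid
(hill $\in \{0.5, 1, 2\}$ crossed with IC50 at every interior dose; best
RSS wins), on the 8-point ladder 0, 0.8, 1.56, 3.1, 6.25, 12.5, 25, 50 µM
in quadruplicate. Two numerical choices matter:

* **The 0-dose anchor enters the fit.** At $c = 0$ the model evaluates
  exactly to `top`, and the drug-free wells are a genuine measurement of
  it. With only seven nonzero doses and a free `top`, the upper asymptote
  is weakly identified under realistic OD noise and IC50 recovery degrades
  severely; anchoring restores it.
* **Bounded parameters.** top $\in [50, 150]$, bottom $\in [-30, 110]$,
  hill $\in [0.1, 10]$, IC50 within [lowest dose/10, highest dose × 10] —
  sane ranges for control-normalized viability that keep noisy fits from
  wandering into degenerate optima.

The reported IC50 is the fitted inflection (relative IC50); the dose at
which the curve crosses 50% (absolute IC50) is reported alongside. A fit
whose IC50 exceeds the highest tested dose, or whose curve never drops
below 50% in the tested range, is *censored* and reported as "> max dose"
rather than extrapolated. Censored values are excluded pairwise from
correlations, never imputed. Pre-computed IC50 tables are ingested as
given, with their declared unit carried along.

## Correlation screen and consensus

For each pathway and drug, Pearson's product-moment correlation is
computed between PAS and IC50 across cell lines (≥ 3 complete pairs), with
the two-sided p from the usual t-transform. Records with $p < 0.05$ (raw,
per the source procedure; Benjamini–Hochberg optional) are kept. A
*positive* sign means higher pathway activation accompanies a higher IC50
— a less effective drug; a *negative* sign means the drug works better
when the pathway is active. Correlations use IC50 on the scale provided;
`log10_ic50 = TRUE` is available and statistically preferable, but off by
default for fidelity to the source procedure.

Per dataset, a pathway's *support* is the number of control sets under
which it was significant, split by sign; pathways significant with both
signs within a dataset are excluded from consensus and written to a
diagnostics table (the source procedure never discusses this case). The
consensus keeps pathways with support ≥ 1 in *both* datasets and matching
sign; cross-dataset sign conflicts are likewise reported separately rather
than silently dropped. Duplicate (drug, pathway) rows are deduplicated.

## What the synthetic generator emulates

Every stage is testable against planted ground truth without any
downloads. The generator draws, deterministically from a seed:

* a pathway database with disjoint member sets and ARR roles from a
  configurable mixture (default 50 pathways of 10–20 genes);
* log-normal linear-scale intensities (baseline sd 0.1 on the natural log)
  with a per-control-set tissue offset (sd 0.05), 4–33 samples per
  control set, 11 control sets for dataset A and 3 for dataset B;
* case cell lines (11 per dataset, disjoint panels) in which every gene of
  a planted pathway is shifted by $\text{effect}^{\mathrm{ARR} \cdot a_s}$,
  where $a_s \sim N(0,1)$ is the line's latent activation — strongly
  activated lines push member genes beyond the BTIF thresholds while
  near-zero activations stay inside them;
* true IC50s linear in the latent activation on the $\log_{10}$ scale
  (centre 5 µM, slope 0.3, clamped to [1, 40] µM), so that
  $\mathrm{cor}(a_s, \lg \mathrm{IC50}) = $ `target_r` (0.95 by default;
  a negative value flips the slope). The log scale mirrors the log-normal
  IC50 spreads of real panels (an order of magnitude between sensitive
  and resistant lines) and keeps every line inside the measurable part of
  the dose ladder; on the strictly linear scale the same spread either
  drowns in curve-fitting noise or collides with the censoring boundary;
* 4PL plates (hill 1, top 100, bottom 0) with Gaussian OD noise of 5% of
  the control signal, in quadruplicate, plus noisy control and blank wells.

The two datasets use independent cell-line panels, noise draws and
control sets, so a null pathway's chance of entering the consensus is
approximately the product of its per-dataset false-positive rates.

What the generator does **not** emulate: probe-level chemistry, batch and
platform effects beyond a smooth tissue offset, gene–gene correlation
outside planted pathways, overlapping pathway membership, heteroscedastic
plate noise, and drug-specific curve shapes. Passing tests therefore
demonstrate the pipeline's internal correctness and statistical
calibration under its own model — not robustness to the artifacts of any
particular array platform.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run the full pipeline at the
default desk scale: 50 pathways × 11 cell lines × (11 + 3) control sets
per seed, 25–50 seeds for recovery and false-positive estimates, 200
noisy plates for IC50 recovery, and a 1000-pathway null for screen
calibration — sizes chosen so the whole suite completes in minutes on a
laptop while leaving the binomial envelopes tight enough to detect a
miscalibrated screen.

## Known limitations

* The tolerance-interval test assumes approximately normal control
  intensities per gene; heavy-tailed platform noise will mis-calibrate
  the per-gene p slightly (the fold-change criterion then dominates).
* With `min_support = 1`, the per-dataset false-positive rate exceeds the
  nominal per-control α whenever control sets disagree, because any one
  of several partially dependent screens may fire; the two-dataset
  intersection is what keeps the consensus clean.
* Raw-scale Pearson correlation with log-normally spread IC50s gives
  outlying resistant lines high leverage; `log10_ic50 = TRUE` mitigates
  this.
* Censored IC50s are dropped, which biases screens for drugs that are
  inactive in most lines toward the sensitive minority.
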