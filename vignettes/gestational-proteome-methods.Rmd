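---
title: "Methods: cross-species gestational-age analysis of multi-plex isobaric-label proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species gestational-age analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestprot)
```

# What this package models

Amniotic fluid surrounds the developing fetus and its protein composition
reorganizes substantially over gestation. Studying that reorganization
longitudinally requires repeated amniocentesis, feasible in a rhesus macaque
model (term ~168 days, sampled at gestational days 85/110/135) but not in
humans, where cross-sectional samples are matched to the rhesus windows by
percent completed gestation (term ~280 days; matched ages ~140, 178.5 and
220.5 days). Proteins are quantified by multi-plex isobaric labeling (TMT):
samples are pooled into plexes, each contributing reporter-ion intensities
per channel, with pooled-reference channels shared by every plex.

`gestprot` implements the full quantitative chain for such a design —
harmonization, normalization, per-protein gestational-age modelling,
cross-species ortholog concordance, enrichment, and trajectory
summarization — and pairs it with a synthetic-data generator with known
ground truth, so that every stage's statistical behaviour (error control,
parameter recovery, closure of planted signals) is testable without any
external download.

# The generative model

For protein $g$ in sample $i$ of one species the generator draws

$$\log_2 x_{gi} = \mu_g + \beta_g \, a_i + u_{g,s(i)} + b_{g,p(i)} + \varepsilon_{gi},
\qquad \varepsilon_{gi} \sim N(0, \sigma_\varepsilon^2),$$

where $a_i$ is gestational age in days, $\beta_g$ the per-day log2 slope,
$u_{g,s}$ a protein-specific subject random intercept
($N(0, \sigma_{\text{subject}}^2)$) and $b_{g,p}$ a protein-specific plex
effect ($N(0, \sigma_{\text{plex}}^2)$). Reference-pool channels carry, per
plex, the arithmetic log2 mean of all biological channel means of that
species — a common pooled aliquot — plus the plex effect and noise.
Intensities are emitted on the raw scale ($2^{\log_2}$).

Two modelling choices deserve emphasis:

* **Random effects are protein-specific.** A subject or plex effect that is
  a single per-sample scalar is a pure sample-level offset; total-intensity
  (library) scaling removes it entirely, which would make within-subject
  correlation vanish after normalization and leave internal reference
  scaling with nothing to correct that TMM does not already fix. Protein-level
  plex effects are precisely the batch structure IRS exists for, and
  protein-level subject intercepts are the model underlying
  consensus-correlation blocking.
* **Ortholog pairs share their drift flag and direction** (slope magnitudes
  are drawn independently per species), and shared orthologs share a baseline
  abundance up to a species offset (`sigma_species`, default 0.7 log2). The
  offset keeps the expected cross-species abundance correlation below 1 and
  in the high-0.8s, the regime reported for primate amniotic-fluid proteomes;
  flag sharing gives cross-species concordance a well-defined ground truth.

Default study conditions (`sim_config()`): 1300 proteins per species, 7
longitudinal rhesus subjects at days 85/110/135, cross-sectional humans
7/10/7 per matched window, 3 plexes per species with 2 reference-pool
channels each, 20% of proteins drifting up and 20% down with per-day slopes
$\pm|N(0.04, 0.01^2)|$ log2/day (the scale of reported top coefficients,
~0.03–0.07/day), $\sigma_{\text{subject}} = \sigma_\varepsilon = 0.3$,
$\sigma_{\text{plex}} = 0.5$, baselines $N(20, 2^2)$ log2. Human sampling
ages sit exactly at the window-matched midpoints; real cohorts scatter
within a window, a feature the generator deliberately omits (slopes are
identified by the cross-window spread, which dominates).

The tissue-atlas generator plants, per tissue, genes whose expression in
that tissue exceeds the expressed threshold and is at least `fold` (≥5,
default 10) times the maximum over other tissues, against a background of
below-threshold and broadly expressed genes; planted sets are exactly
recoverable by the classification rule, giving a closure test. Optionally a
tissue's planted genes can be fixed to chosen symbols (e.g. gestationally
rising orthologs), emulating tissue signatures that track development.

# Harmonization and normalization

**Internal reference scaling (IRS).** Per protein $g$ and plex $p$, the
geometric mean $R_{gp}$ of the reference-pool intensities estimates the
plex's measurement scale; every channel of plex $p$ is multiplied by
$f_{gp} = \bar G_g / R_{gp}$, with $\bar G_g$ the geometric mean of the
$R_{gp}$. After scaling, per-plex reference geometric means agree across
plexes to machine precision for proteins observed in all plex pools —
exactness is a property of the construction and is asserted in the tests.
Geometric means ignore zeros and missing values; a protein absent from a
plex's pools has no defined scale there and its values in that plex are set
missing rather than guessed. Single-plex data are returned unchanged.
Geometric (rather than arithmetic) pooling was chosen because the effects
being removed are multiplicative.

**TMM + library scaling + log transform.** Sample scaling uses the
canonical trimmed-mean-of-M-values definition: reference column selected by
the upper-quartile/library-size heuristic, M- and A-values over proteins
positive in both samples, double trimming (30% on M, 5% on A), and a
precision-weighted mean under the binomial variance approximation, with
factors rescaled to geometric mean 1. The implementation is checked
bit-for-bit against edgeR's on positive data. The reported `rel_scale`
column is the combined per-sample divisor $L_i t_i$ rescaled to geometric
mean 1 — the quantity by which samples actually differ after TMM plus
library scaling (a globally doubled sample has `tmm` 1 but `rel_scale`
$\sqrt 2$). Log expression is
$\log_2(x \cdot 10^6 / (L_i t_i) + c)$ with a per-million offset $c = 2$,
finite at zero and variance-stabilizing at low intensity.

**QC.** The per-protein coefficient of variation (SD/mean on IRS-scaled raw
intensities) is summarized as the median percent per species × window over
biological channels.

*Known limitation — compositional drift.* When a large fraction of the
proteome drifts with age and the library is dominated by a few
high-abundance proteins, the trimmed mean cannot perfectly separate null
from drifting mass: a small age-correlated scale error (of order 10% of the
planted slope at 60% drifting proteins) survives normalization, is shared
by all proteins of a sample, and — because ortholog drift is shared across
species — produces *concordant* false positives. This is a property of
global scaling itself (edgeR's TMM behaves identically), visible here only
because the generator provides ground truth. Recovery checks therefore
average a few replicate experiments, and results at extreme drift fractions
should be read with this bias in mind.

# Differential abundance with gestational age

Each protein is fit with a linear model, intercept + age in days, on the
log2 matrix; the coefficient (`logFC`) is the log2 change per day of
gestation and `AveExpr` the mean log2 intensity. For the longitudinal
species, repeated measures are handled by generalized least squares under
block compound symmetry: a single consensus intra-subject correlation
$\rho$, shared by all proteins, whitens each subject block
($\Sigma = (1-\rho)I + \rho J$ has the closed-form inverse square root
$aI + bJ$). The consensus is the hyperbolic tangent of the 30%-trimmed mean
of per-protein $\mathrm{atanh}(\hat\rho_g)$, where $\hat\rho_g$ is a moment
estimator from the OLS residuals (mean within-subject cross-product over
mean squared residual), clipped to $(-0.99, 0.99)$. The estimator carries a
small attenuation (~0.05 at $\rho = 0.5$, $n = 21$) from residual
projection; it is well inside the recovery tolerance and GLS efficiency is
flat near the optimum.

Residual variances are moderated empirically: the scaled-F prior
$(d_0, s_0^2)$ is estimated by matching the mean and variance of
$\log s_g^2$ through the digamma/trigamma equations, inverting the trigamma
function by Newton iteration (tolerance $10^{-8}$); posterior variances
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ feed moderated
t-statistics on $d_g + d_0$ degrees of freedom. When the observed
log-variance dispersion does not exceed chi-square sampling noise the prior
degrees of freedom are infinite and all variances pool to their mean.
Results agree with limma's `lmFit`/`eBayes` chain to numerical precision on
complete data; limma is used only as a cross-check, never as the
implementation. Multiplicity is controlled by Benjamini–Hochberg step-up
adjustment (own implementation, verified against both a brute-force
evaluation of the definition and `stats::p.adjust`), with direction called
at adjusted p < 0.05.

# Cross-species concordance

Species are joined on uniquely mapping (1:1) orthologs only; ambiguous
pairs are excluded. Mean-abundance and effect-size agreements are Pearson
correlations with Fisher-z intervals ($\pm 1.96/\sqrt{n-3}$, omitted for
$n \le 3$). Each ortholog is classified as significant in both species with
the same or opposite direction, in one species only, or neither; the
overlap of significant sets is tested with the exact upper-tail
hypergeometric probability. The universe for that test is the set of joined
1:1 orthologs analyzed in both species — the only universe the species
share; a larger universe would overstate enrichment. Comparison against an
external protein list reports identification, overlap (with the same exact
test over the internally quantified genes) and directional consistency.

# Enrichment

Tissue-enriched genes follow the Human Protein Atlas convention: expressed
above 1 TPM-like unit in the top tissue and at least five-fold above the
*maximum* of all other tissues ("compared to all other tissues" is
ambiguous between mean and max; the max reading is the HPA definition and
guarantees each gene at most one tissue). Over-representation uses the
exact hypergeometric upper tail with the standard $(N, K, n, k)$ counts,
BH-adjusted within each collection × direction family. Redundant terms are
collapsed greedily in ascending-p order when the Jaccard index of their
overlap gene sets exceeds 0.7; an overlap-based similarity stands in for
semantic similarity, which would require an ontology graph (out of scope
here), and the smallest-p term is never dropped.

# Summaries

PCA row-centers the log matrix and decomposes by SVD (scores = sample
projections, percent variance = squared singular values). Hierarchical
clustering of samples defaults to 1 − Pearson distance with average
linkage; both are configurable and recorded in the output, since heatmap
conventions vary. Longitudinal trajectories standardize each protein
against the earliest gestational window (sample mean and $n-1$ SD of the
reference group; zero-SD proteins are excluded and reported) and average
Z-scores over the proteins enriched for a tissue, per window — by the
centering identity the reference-window trajectory is exactly zero in the
reference samples and near zero in expectation. Volcano tables cap
$-\log_{10} p$ at 320 to avoid plotting infinities at numeric underflow.

# Orchestration and reproducibility

`run_pipeline()` executes simulate → normalize → differential →
cross-species → enrichment → summaries from a single validated
configuration, echoes the configuration into the output directory, writes
every stage's tables as TSV (so any stage can be re-entered standalone),
and emits a JSON run summary whose counts equal the corresponding table row
counts. All randomness flows from one top-level seed fanned out to stages
by fixed offsets; the same configuration and seed reproduce all numeric
artifacts bit-identically. A failing stage leaves a `FAILED` marker naming
the stage, with partial outputs kept. The numbered scripts under
`analysis/` run the same chain stage by stage with narrative output.

Problem sizes used in the shipped checks — 250–1300 proteins, the 21 + 24
sample study design, 400 null replicates for false-discovery calibration,
3 replicate experiments for concordance recovery, 20 seeded atlas runs —
were chosen as the smallest sizes at which Monte-Carlo error is clearly
inside each tolerance.

# What passing the synthetic checks does and does not show

The generator emulates the study design, the batch/subject/noise structure,
ortholog sharing and tissue signatures, but not peptide-level rollup,
missingness mechanisms beyond complete data, isotopic impurity, outlier
samples, or within-window age scatter. Passing checks therefore demonstrate
that the statistical machinery is correct and well calibrated under the
stated model — not that any particular biological dataset satisfies that
model. Values reported by `scripts/acceptance.R` are computed fresh from
synthetic data at run time and will differ in detail from any real-data
analysis.
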