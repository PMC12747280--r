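---
title: "From placental cell types to maternal circulation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From placental cell types to maternal circulation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Preeclampsia (PE) is a hypertensive disorder of pregnancy diagnosed after 20
weeks of gestation, conventionally split by onset: early-onset disease (EOPE,
diagnosed and delivered before 34 weeks) and late-onset disease (LOPE, at or
after 34 weeks). The placenta drives the disease, so transcriptional states
of individual placental cell types — trophoblasts (CTB, EVT, STB), decidual
and stromal cells, NK cells, macrophages — are natural sources of candidate
biomarkers. `placentrace` implements a complete analysis chain for this
idea:

1. **Derive** cell-type-specific mRNA signatures from placental single-cell
   RNA-seq by pseudo-bulk differential expression against gestational-age
   (GA) matched controls, separately for whole PE, EOPE, LOPE, and an
   EOPE-vs-LOPE interaction.
2. **Project** circulating measurements (longitudinal whole-blood
   microarrays, cross-sectional diagnosis-time arrays, aptamer-based plasma
   proteomics) onto a common Z-score scale: reference-anchored
   standardization, GA detrending fitted on controls, and probe/aptamer to
   gene collapsing.
3. **Score** each sample by the mean standardized expression of each
   signature's genes.
4. **Infer**: global GA trend tests (mixed models), diagnosis-window
   ROC/AUC with confidence intervals, and per-window case–control t-tests.

Because the corresponding clinical datasets are access-restricted, the
package ships a first-class synthetic-data module that generates data with
the statistical structure each stage assumes, with planted ground truth, so
every stage is testable end to end.

# Pseudo-bulk differential expression

## Aggregation and filters

Counts of all cells sharing a (cell type, sample) pair — a *combination* —
are summed into one pseudo-bulk column; sums are exact, so total counts are
conserved. Two filters with deliberate boundary semantics follow:

* cells with **fewer than 200 detected genes** are removed (a cell with
  exactly 200 is retained), as are cells whose mitochondrial read fraction
  **exceeds 25%** (exactly 25% is retained);
* combinations need **strictly more than 20 cells**, and a cell type must be
  observed in **at least 3 samples in each arm** of a contrast, otherwise it
  is dropped for that contrast.

The filters commute: applying the cell-count filter and then the
sample-count filter equals joint application.

## Model

Within each retained cell type, each gene is fitted with a negative binomial
GLM (log link) on the pseudo-bulk counts:

$$
y_{gs} \sim \mathrm{NB}(\mu_{gs},\ \alpha_g),\qquad
\log \mu_{gs} = \log s_s + \beta_0 + \beta_1\,\mathrm{case}_s + \text{library}_s,
$$

with $\mathrm{Var}(y) = \mu + \alpha\mu^2$. Size factors $s_s$ are
median-of-ratios over genes with positive geometric mean. The library
(batch) factor is dropped automatically when it has a single level. The
interaction contrast fits `case * onset` on all samples and tests the
interaction coefficient — the difference between the EOPE and LOPE case
effects.

Dispersion is estimated per gene in two stages: a method-of-moments start on
normalized counts (falling back to the median dispersion across genes when
the moment estimate is non-positive), then a Pearson-moment re-estimate
around the GLM-fitted means with an $n/(n-p)$ degrees-of-freedom correction,
followed by one refit. The second stage matters: moments taken around a
single grand mean absorb group and batch structure into the dispersion and
make the test markedly conservative. There is deliberately no
empirical-Bayes shrinkage — acceptance of this module is calibration and
recovery, not agreement with any particular package's coefficients. Wald
statistics on the refitted model are referred to the standard normal; on
null simulations at the package's default design this yields a raw-p
fraction below 0.05 of 0.04–0.05.

P-values are adjusted by Benjamini–Hochberg within each cell type × contrast
stratum; genes that fail to converge are flagged and excluded from the BH
denominator; all-zero genes are skipped. DEGs are `fdr < 0.1`.

Signatures are the DEGs passing the cutoff with the requested fold-change
sign, named `<cellType>_<contrast>`. The default direction is `up`
(up-regulated in cases), which preserves the downstream assumption that
circulating signature scores are higher in cases; `down` and `both` (with
per-gene direction labels) are available because the direction convention of
published signature tables is not universal.

Q-Q summaries of the per-cell-type p-value distributions rank cell types by
the mean gap between observed and expected $-\log_{10} p$ — a simple,
monotone measure of transcriptional perturbation used to pick out the most
affected cell types.

# Projection into circulating measurements

Three detrending dialects share one goal: remove the gestational-age trend
*estimated in controls only*, so that a case–control location shift at fixed
GA is preserved in expectation.

* **Anchored Z-scores** (`anchor_zscore`): each feature is standardized by
  the mean and SD (n−1) of a designated anchor set — control samples at or
  before 11 weeks for the longitudinal arrays, first-window (T1) controls
  for proteomics. The inclusive "≤ 11.0 weeks" reading was chosen (the
  boundary wording is ambiguous in common usage) and is configurable.
  Features constant over the anchor set are excluded and logged. Anchoring
  is idempotent.
* **Longitudinal mixed-model detrending** (`detrend_longitudinal`): per
  gene, a linear mixed model with degree-2 B-spline fixed effects of GA and
  a random intercept per subject is fitted on control samples; the fitted
  fixed-effect trend is subtracted from all samples. The spline basis has no
  interior knots by default, and its boundary knots span the *full* observed
  GA range (cases included) so evaluation never extrapolates. A gene whose
  mixed fit fails falls back to a fixed-effects-only spline, and is logged.
* **Cross-sectional residual detrending** (`detrend_crosssectional`): per
  gene, a linear regression on GA (degree 1 by default — "regression on
  gestational age" is read literally; the degree is configurable) fitted in
  controls; all samples become residuals relative to the control fit,
  divided by the control residual SD. Genes exactly collinear with GA (zero
  residual SD) are excluded. A `strata` argument supports detrending within
  a <34 / ≥34-week control split when controls are matched to EOPE and LOPE
  cases separately.
* **GAM detrending** (`detrend_gam`): per protein, an *unpenalized* cubic
  regression spline of GA with basis dimension 3–6 (enforced) fitted on
  controls; the trend is subtracted everywhere and the result anchored to T1
  controls. A fixed-degrees-of-freedom fit was chosen over penalized
  smoothing because it is deterministic and the quantity that matters
  downstream is trend removal, not smoothing-parameter selection.

**Feature collapsing** maps probes/aptamers to genes and keeps, per gene,
the feature with the highest coefficient of variation (microarray rule) or
the highest variance (proteomic rule), computed on the matrix as provided
(the raw-vs-log scale for CV is not standardized across platforms, so it is
left to the caller and recorded in provenance). Features mapping to several
genes — protein complexes, semicolon-separated symbols — are excluded when
`drop_multigene` is set. Ties break lexicographically by feature id, making
the result independent of input order.

# Scoring and inference

A **signature score** is the unweighted mean of the gene-level Z-scores over
the signature genes present on the platform. Signatures with fewer than 3
genes on a platform are flagged as missing — the minimum-coverage rule is
this package's choice, since partial platform coverage is unavoidable and a
1–2-gene "signature" score is mostly noise. For signatures holding both up-
and down-regulated genes the default score is (mean of up) − (mean of
down), preserving the higher-in-cases convention; a plain mean is available.
Missing values are handled by pairwise deletion per sample, with the number
of genes actually used reported.

**Trend test**: for one signature's longitudinal scores, a likelihood-ratio
test (ML fits) compares GA-spline fixed effects + random subject intercept
against intercept + random intercept, with as many degrees of freedom as
spline terms — a global test for any change across gestation. Singular
random-effect fits trigger a flagged fixed-effects-only refit. Zero-variance
scores are a degenerate-input error.

**ROC/AUC**: the AUC is the Mann–Whitney probability
$P(\text{case} > \text{control}) + \tfrac12 P(\text{tie})$ computed by pair
counting; the direction is fixed (cases higher) and never auto-flipped, so
AUC < 0.5 is reported as such. The 95% CI is DeLong's placement-value
interval; when either class has fewer than 5 members a seeded stratified
bootstrap (2000 replicates, percentile interval) substitutes. A signature
*discriminates* when the CI lower bound exceeds 0.5. Diagnosis-window
analysis restricts to samples at 32–34 weeks and keeps one sample per
patient — the earliest in-window visit by default (configurable to latest;
the choice of visit is not standardized in this literature).

**Window t-tests**: Welch two-sample t-tests of case vs control scores
within each gestational window — T1 [15, 22), T2 [22, 30), T3 [30, 42]
weeks. The half-open convention resolves the boundary weeks 22 and 30, which
would otherwise belong to two windows. Welch rather than pooled variance is
used for robustness. No multiplicity correction is applied across the
signature panel by default (per-signature results are reported side by
side); a BH flag can be applied by the caller on the tidy report.

# The synthetic-data generator

`simulate_single_cell_study()` emulates a 78-sample-scale design: EOPE and
LOPE case strata with GA-matched control strata (GA 28–34 weeks for the
EOPE stratum, 34–40 for LOPE), NB counts with $\mathrm{Var}=\mu+\alpha\mu^2$
(matching the DE model), log-normal gene baselines and per-cell depth,
mild cell-type expression profiles, per-library log2 batch offsets balanced
across groups, planted DEGs per cell type (effect applied in cases, optional
EOPE-only effects for the interaction contrast), optional per-cell-type
case/control abundance ratios (composition effects), and deliberate sparse
corners: a decaying abundance series, one rare cell type present in only two
samples per group, and combinations at or under 20 cells — fodder for the
filters.

`simulate_blood_longitudinal()` and `simulate_proteomics()` generate
feature-level values as `quadratic GA trend + subject intercept + noise`,
with case samples gaining a planted shift on signature genes once GA reaches
the onset (default 20 weeks, the definitional boundary of the disease).
Subject intercepts are drawn independently per gene, matching the per-gene
mixed models fitted downstream; with `subject_sd = 0` the closed-form AUC
$\Phi(\delta\sqrt{m}/(\sigma\sqrt{2}))$ for an $m$-gene signature is exact
and is used as a test oracle. The planted shift is expressed in Z units
(units of $\sqrt{\sigma_{subj}^2+\sigma_\epsilon^2}$). The shift is applied
only to genes *exclusive* to the planted signatures: cell-type signatures
share genes, and planting shared genes would leak signal into nominally null
signatures, making "flags exactly the planted signatures" ill-defined.
Visits are evenly spaced with small jitter over 8–41 weeks, so every
subject has an early (≤ 11 weeks) visit for anchoring and one visit inside
the 32–34-week diagnosis window. Proteomic sampling draws one sample per
subject per window. Feature maps include duplicated-gene probes and a
multi-gene aptamer so collapsing rules are exercised.

All randomness flows from a single root seed through deterministic,
stage-named substreams; identical configuration and seed give bit-identical
output.

What the generator does **not** emulate: raw reads, doublets and ambient
RNA, genotype demultiplexing, dropout/missingness patterns of real probes
and aptamers (matrices are complete — the real datasets' missingness is not
publicly characterized), platform normalization artifacts, or correlated
gene–gene structure beyond the planted effects. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not robustness to every pathology of real clinical data.

# Numerical and testing choices

* Dispersion estimates are clamped to $[10^{-8}, 100]$; non-convergent genes
  are excluded from the BH denominator rather than assigned p = 1.
* Q-Q expected quantiles use $(i-\tfrac12)/n$.
* Test problem sizes are scaled for tight feedback loops: null calibration
  uses 2,000 genes at 10 vs 10 samples; recovery uses 800 genes at 10 per
  group; trend/window calibration uses 500 replicates; the end-to-end run
  uses 2,000 genes × 8 cell types × 40 samples (~50k cells) with a
  49-control/13-case blood cohort. These sizes are the package's chosen
  operating points for its own verification.
* Quantities estimated from a single simulated study (a recovered AUC at
  50/50 samples has Monte-Carlo SD ≈ 0.05; a recovered composition fold at
  12+12 samples has SD ≈ 0.13) are verified as means over a few replicate
  studies at the *same* study size, which controls Monte-Carlo error without
  loosening the comparison.
* The CI-lower-bound > 0.5 discrimination rule falsely flags a truly null
  signature in ~2.5% of draws by construction; tests treat this as the
  method's own property (bounding false-flag counts by their binomial tail)
  rather than something to suppress.

# Known limitations

* The NB Wald test has slightly elevated tail mass at very small p-values in
  some draws at n = 10 per group (realized FDR at the 0.1 cutoff averages
  ~0.12); empirical-Bayes dispersion shrinkage would reduce this at the cost
  of a dependency on its prior — out of scope here.
* `detrend_longitudinal` fits one mixed model per gene and is the slowest
  projection step; for thousands of genes prefer the cross-sectional dialect
  or score-level detrending.
* The pipeline driver is sequential and single-threaded by design
  (determinism over speed).
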