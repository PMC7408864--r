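---
title: "Methods: consensus kinase co-expression signatures and their survival evaluation"
author: "kinsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus kinase co-expression signatures and their survival evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsig)
```

## The scientific problem

Chronic lymphocytic leukemia (CLL) is clinically heterogeneous: some
patients never need treatment while others progress rapidly. Enhanced
B-cell-receptor (BcR) signaling drives the aggressive phenotype, but no
single kinase is a reliable marker — ZAP70, the classical surrogate of
IGHV-unmutated disease, is discordant with outcome in a sizeable
fraction of patients. The premise of this package is that genes
co-expressed with *several* BcR-signaling kinases (ZAP70, AKT1, AKT2,
BTK, MAPK1, MAPK3, PIK3CD) integrate the activity of the whole
signaling network and therefore make better biomarkers than any one
kinase. `kinsig` implements that screening strategy end to end and —
because the original expression collections and validation cohort
cannot be bundled — ships a synthetic-data module that generates every
input with planted ground truth, so each stage is verifiable against a
known answer.

## Robust correlation screening

Per dataset, each candidate gene is correlated with each panel kinase
using the biweight midcorrelation. For a vector $x$ the deviations are
scaled by the unscaled median absolute deviation,

$$u_i = \frac{x_i - \mathrm{med}(x)}{9\,\mathrm{MAD}(x)}, \qquad
a_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1],$$

the weighted deviations $\tilde x_i = (x_i - \mathrm{med}(x))\,a_i$ are
normalized to unit length, and
$r = \sum_i \tilde x_i \tilde y_i / (\lVert\tilde x\rVert\,\lVert\tilde
y\rVert)$. Samples beyond nine MADs get zero weight, which is what makes
the estimate resistant to the gross outliers that survive imperfect
microarray normalization. Numerical edge cases are handled explicitly:
if either vector has zero MAD (more than half its values tied at the
median), the pair falls back to the Pearson correlation and is flagged;
constant vectors are an error; missing values are removed pairwise with
a minimum overlap of 8 complete pairs, below which a robust estimate is
not meaningful.

## Consensus selection

Correlations are computed separately in every dataset and thresholded
at $|r| \ge 0.5$ (both signs count: an absolute threshold). A gene's
*support* for a kinase is the number of datasets passing the threshold.
Selection proceeds in two stages around an anchor kinase (ZAP70 by
default):

* **stage 1** — support $\ge 5$ datasets for the anchor *and* for at
  least one other panel kinase;
* **stage 2** — support $\ge 5$ datasets for the anchor and for at
  least two other kinases.

Support is counted per kinase independently; whether the supporting
datasets must coincide across kinases is genuinely ambiguous in this
kind of design, so a `same_datasets` switch implements the stricter
reading without making it the default. Genes are ranked by total
support summed over kinases, ties broken alphabetically, so the
ordering is deterministic. Kinase genes themselves are excluded from
the candidate universe (their mutual correlation would pass trivially),
and the legacy panel spelling `PI3KCD` is aliased to the HGNC symbol
`PIK3CD`.

## Survival evaluation

The prognostic value of a gene set is measured on a cohort with two
endpoints — time to treatment (TTT) and overall survival (OS). A Cox
proportional-hazards model over the signature genes yields the
prognostic index $\mathrm{PI}_i = \sum_g \beta_g x_{ig}$; samples are
ranked and split at the median of the PI into two equal-sized risk
groups (ties broken by a stable sort on value then sample id, so equal
group sizes are guaranteed, which a value threshold cannot do), and the
reported hazard ratio is the exponentiated Cox coefficient of the
binary group indicator, with a Wald interval and log-rank p-value.
Single genes are evaluated the same way with the median split applied
to expression directly. Gene-level importance is assessed two ways:
individually (per-gene HR) and by leave-one-out contribution, defined
as the drop in the combined HR when the gene is removed from the pool —
the strongest contributors are the genes whose removal hurts the most.
A planted dual-endpoint driver should then be the unique gene common to
the four top-k lists (individual and leave-one-out, per endpoint),
which is the package's end-to-end recovery property.

Cox fitting, the Kaplan–Meier estimator and the log-rank test are
delegated to the `survival` package (Efron tie correction, convergence
tightened to `eps = 1e-9`, 100 iterations); the test suite
independently verifies the fits against a brute-force Efron
partial-likelihood maximizer on exhaustively scripted small instances.
Two numerical behaviors are worth knowing. First, a monotone partial
likelihood (e.g. a covariate that perfectly orders the failures) has no
finite maximizer; such fits are returned flagged (`converged = FALSE`)
rather than as silent large coefficients. Second, the Efron correction
is *not* invariant to replicating every subject (Breslow is); the
brute-force oracle confirms the small shift is correct behavior, not a
bug.

The multivariate clinical model adjusts the median-split gene indicator
for IGHV mutational status and 17p13 deletion; samples with unknown
IGHV are excluded listwise (no imputation). Note that dichotomizing a
continuous planted effect attenuates coefficients (non-collapsibility),
so parameter-recovery checks are run on the correctly specified
continuous model, while the dichotomized model is checked for
significance and sign. No multiple-testing correction is applied across
the per-gene HRs; the per-gene table is a ranking device, not a set of
confirmatory tests, and this is a documented limitation.

## qPCR stage contrasts

Ct values are converted to reference-normalized relative expression by
the single-delta doubling model $2^{\mathrm{Ct_{ref}} -
\mathrm{Ct_{target}}}$ (100% amplification efficiency; no calibrator
sample is involved, so the double-delta form is not computable).
Stage-group differences use Welch's unequal-variance t-test with the
three standard risk contrasts: Rai 0 vs III–IV, Rai I–II vs III–IV, and
Binet A vs B∪C; other pairs are available behind a flag. Contrasts are
computed on the log2 relative-expression scale (equivalently on
delta-Ct values) by default: Ct noise is additive, so relative
expression is lognormal, and a null-calibration simulation showed the
raw-scale Welch test anticonservative at the smallest stratum (four
samples) while the log scale holds its nominal level — which is also
where qPCR group comparisons are standardly performed. The raw scale
remains available via `log2_transform = FALSE`.

## Enzyme activity and drug combinations

Kinetic fluorescence traces (readings every 60 s over 30 min) are
reduced to a slope over the contiguous window maximizing $R^2$ — the
"linear portion" — in fluorescence units per minute; flat traces yield
a flagged zero slope. The inhibitor activity score is
$((\mathrm{RFI_{DI}} - \mathrm{RFI_u})/(\mathrm{RFI_u} -
\mathrm{RFI_{Zn}})) \times 100\%$; inhibition therefore yields negative
scores, and because reporting conventions differ, both the signed score
and its magnitude are returned.

Dose–response curves follow the median-effect model $f_a/f_u =
(D/D_m)^m$, fitted by the exact log-linear regression of
$\log(f_a/(1-f_a))$ on $\log D$; points with $f_a$ at exactly 0 or 1
carry no information on that scale and are excluded with a warning. The
Chou–Talalay combination index uses the non-constant-ratio,
mutually-exclusive two-term form $\mathrm{CI} = d_1/D_{x1} +
d_2/D_{x2}$, each observed point evaluated at its own dose pair — the
appropriate form when one drug is held fixed while the other is
titrated. CI below 1 is synergy, 1 additivity, above 1 antagonism; the
additivity band used for labeling (±0.05) is a reporting convention,
not part of the computation.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the pipeline
relies on, with one pseudo-random stream per generator split from the
master seed so outputs are individually reproducible.

* **Expression collection** (default 14 datasets, 2000 genes, 30–200
  samples each, log2 scale): panel kinases share a latent
  signaling-activity factor (pairwise correlation 0.6) — without such
  sharing, genes correlated with several kinases at once could not
  exist. Each planted positive gene (default 100) tracks the anchor
  plus two random other kinases (target correlation 0.85) in 6 of the
  14 datasets; background genes are independent. When a gene tracks a
  single kinase its population correlation equals the configured rho
  exactly; with several kinases the per-kinase correlation is
  attenuated to rho times the kinase–target correlation (about 0.73 at
  the defaults), still comfortably above the 0.5 threshold. An
  `outlier_fraction` option replaces samples with draws from a
  10-fold-wider distribution to exercise the robustness of the
  correlation.
* **Survival cohort** (default 107 samples): expression standard normal
  on the log2 scale; event times exponential with hazard
  $h_0\exp(\mathrm{PI})$ per endpoint (default $h_0 = 0.01$/month),
  independent uniform censoring on 120 months; the two endpoints share
  covariates but draw independent noise. IGHV status (48% mutated / 45%
  unmutated / 7% unknown) and 17p13 deletion (8%) carry their own
  planted log-hazards. Proportional hazards hold by construction and
  are verified by Schoenfeld-type checks in the tests.
* **qPCR table** (default 34 samples; Rai strata 20/10/4; Binet 29/5
  with the advanced labels on the highest-risk samples): the planted
  target log2 expression rises by `stage_effect` (default 1, a 2-fold
  change) per risk stratum; reference and target Ct carry independent
  Gaussian noise (default 0.3 cycles), so at zero noise the relative
  expression inverts exactly to the planted fold change.
* **Dose–response tables**: exact median-effect curves on a geometric
  grid around each drug's $D_m$, and combination points constructed so
  the true CI equals the configured synergy factor at every point
  (1 = Loewe additive).

Real data differ in ways the generators deliberately do not model:
probe-level artifacts, batch and platform effects, non-proportional
hazards, informative censoring, amplification-efficiency drift, and
biological correlation structure among background genes. Passing tests
therefore demonstrate that the machinery is correct and calibrated
under its stated model, not that the biological conclusions of any
particular study are reproduced.

## Problem sizes and defaults used in validation

The test suite and the acceptance script run at the scale of the study
design they emulate: the full 14-dataset, 2000-gene screen; a
107-sample cohort for the end-to-end demonstration, with n = 500
cohorts and 50–100 replicate seeds for the statistical recovery
properties (coefficient bias, SE calibration, hazard-ratio coverage,
log-rank and Welch type-I error at 2000–5000 null replicates); and a
20-replicate emergence rate for the dual-endpoint driver. In the
end-to-end pipeline the combined survival analyses use the top 32
ranked stage-2 genes, keeping the multi-gene Cox fit well-posed
relative to a ~107-sample cohort — the signature-to-cohort ratio the
design is built around. With roughly a third as many covariates as
samples, the combined fit overfits by construction (the same is true of
any 32-gene signature on 107 patients); the combined hazard ratios are
therefore demonstration outputs, and the controlled simulations above
are where calibration is actually established. A run of the whole suite
takes on the order of a minute.

## Known limitations

* Consensus counting treats datasets as exchangeable; no weighting by
  sample size or platform.
* The leave-one-out contribution is a marginal measure; correlated
  genes share credit, and removing one of a duplicated pair shows
  little contribution even when the pair is a strong driver.
* HRs from median splits discard within-group gradation; they are the
  field's presentation convention, not the most efficient estimator.
* The multivariate model supports only the two clinical covariates of
  the design (IGHV, del17p); arbitrary adjustment sets are out of
  scope.
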