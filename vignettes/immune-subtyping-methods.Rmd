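---
title: "Methods: immune subtyping of melanoma from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune subtyping of melanoma from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melsubtype)
```

# The problem and the model

Melanoma tumors fall into three immune microenvironment subtypes defined
by where tumor-infiltrating lymphocytes (TILs) sit: **desert** tumors have
essentially no TILs, **excluded** tumors trap TILs in a dense reactive
stroma, and **inflamed** tumors have TILs in direct contact with cancer
cells. Because TIL content and stromal activation leave a strong imprint
on the bulk transcriptome, the subtype can be estimated from expression
data alone. The package's core artifact is a *two-step decision rule* on
robust per-gene scores:

1. **Step 1 — is there any meaningful immune infiltrate?** A small set of
   genes elevated outside the desert state is averaged,
   $S_1 = \tfrac1k \sum_g s_g z_g$; a sample with $S_1$ below a cutoff is
   called desert. In the published seven-gene model the genes are CD53,
   TNFAIP6, CD2, IRF1 (all weighted $+1$) with cutoff $-0.44$.
2. **Step 2 — is the infiltrate excluded or inflamed?** A signed sum
   opposes stromal markers to immune effector markers,
   $S_2 = z_{COL5A2} + z_{INHBA} - z_{CD8B} - z_{IRF1}$; non-desert
   samples with $S_2$ at or above a cutoff (published: $0.13$) are called
   excluded, the rest inflamed.

The underlying score is the **modified z-score**
$z = 0.6745\,(x - \mathrm{median})/\mathrm{MAD}$, whose median/MAD basis
tolerates the heavy tails of expression data; the constant makes it
comparable to an ordinary z-score under normality. When a gene's MAD is
zero we fall back to the mean absolute deviation with constant 0.7979,
and a fully constant gene scores zero — degenerate inputs never produce
infinities.

The decision sequence assumes (i) the z-scores are computed on a cohort
(or against frozen reference medians/MADs from a training cohort), so a
score of 0 means "at the population median"; (ii) the marker genes behave
monotonically in the infiltrate (no non-monotone dose effects); and
(iii) step 2 is only meaningful after step 1, since its contrast is
between two infiltrated states.

## Cutoff and class orientation

Cutoffs are placed where Youden's $J = \text{sensitivity} +
\text{specificity} - 1$ is maximal, scanning the midpoints between
consecutive distinct scores plus $\pm\infty$; ties go to the smallest
cutoff, so results are reproducible. Step 1's ROC treats *non-desert* as
the positive class (its four genes rise with infiltration, so desert sits
below the cutoff); step 2 treats *excluded* as positive (stromal genes
weighted $+$). Boundary handling is `<` for the desert call and `>=` for
the excluded call. The published cutoffs are reproduced by
`published_classifier()`; rebuilt models carry their own Youden-optimal
cutoffs.

# Rebuilding the classifier from a cohort

`two_step_classifier()` reproduces the whole construction pipeline:

1. **Filtering** (`preprocess_expression()`): genes with missing values
   are removed, then genes with coefficient of variation below a
   threshold (default 5%, computed on the raw values with the $n-1$
   standard deviation — CV is conventionally defined on untransformed
   positive data). Removed genes are reported with their CVs so the
   accounting is auditable.
2. **Marker ranking**: per gene, a group-means model with one coefficient
   per subtype and no intercept is fit on $\log_2(x+1)$ expression; the
   residual variances are shrunk by empirical Bayes. We estimate the
   prior degrees of freedom $d_0$ and prior variance $s_0^2$ by matching
   the mean and variance of $\log s^2$ to a scaled-$F$ hierarchy
   (digamma/trigamma inversion); the posterior variance is the
   df-weighted average $(d_0 s_0^2 + d\,s^2)/(d_0 + d)$, and one-vs-rest
   contrasts (subtype minus the mean of the other two) are tested with
   $t$ on $d_0 + d$ degrees of freedom (normal when $d_0 = \infty$; when
   the log-variance spread does not exceed its sampling noise the
   $d_0=\infty$ branch is used). Genes are ranked by raw p-value — the
   ranking is a screening step, so no multiplicity correction is applied
   — with ties broken by $|t|$ and then gene id. Top 10 per subtype enter
   the search.
3. **Combination search** (`search_combinations()`): every subset of the
   candidate pool up to size 4 is scored with empirically signed
   z-combinations (average for step-1-style scores, sum for
   step-2-style), ranked by AUC with ties broken by fewer genes then
   lexicographic ids. The search is exhaustive rather than greedy: at 30
   candidates and size ≤ 4 that is ~32,000 combinations, which runs in
   seconds and removes any path dependence.
4. **Freezing**: the winning gene sets, signs and Youden cutoffs are
   stored together with per-gene training medians/MADs, so single new
   samples can be scored on the training scale
   (`predict(fit, x, type = "expression")`).

## Which scale is z-scored

All RNA-seq z-scores in the pipeline are computed on $\log_2(x+1)$
expression. Three reasons: expression noise is multiplicative, so
location/scale statistics are meaningful on the log scale; the raw-scale
modified z of log-normal data has extreme right tails that destabilize
Euclidean k-means (lowest-inertia solutions isolate outliers) and distort
silhouette-based model selection; and the qPCR route z-scores
$\log_2$ relative quantities by construction, so the two assays feed the
classifier on the same scale. `zscore_matrix()` itself is scale-agnostic
— it standardizes whatever matrix it receives.

# Consensus subtype discovery

Discovery labels a cohort without histology. Two independent labelings of
the samples, both on the z-scores of a 40-gene
angiogenesis/stroma/immune signature, are intersected:

- **Rule labeling**: per sample, the three category scores are the mean
  z over the signature genes of each program; the sample takes the
  subtype whose hallmark program wins (angiogenesis → desert,
  stroma → excluded, immune → inflamed). Exact ties are labeled
  `unassigned` rather than broken arbitrarily.
- **k-means labeling**: samples are clustered at $k=3$ (Euclidean,
  k-means++ seeding, best of 50 restarts, seed recorded); clusters are
  translated to subtype names by the bijection (of the six possible)
  that maximizes agreement with the rule labeling, with a warning on
  ties.

Samples on which the two methods disagree become `unassigned` and are
excluded from classifier training. The number of clusters is chosen by
maximal mean silhouette width over $k = 2..k_{\max}$ (default 10); the
distortion elbow (maximal second forward difference) is computed as a
cross-check and a disagreement is reported, silhouette winning. All-
singleton clusterings ($k=n$) have undefined widths and are scored 0.

# qPCR quantification

Triplicate Ct values are collapsed to their **median** (robust to one
failed well); replicate spreads above 0.5 cycles are flagged but not
altered, and fully undetermined wells are treated as missing — never
imputed at 40 cycles, which would silently inflate desert calls. With
per-gene amplification efficiency $E \in (1, 2.2]$ (fold per cycle,
default 2), each gene's quantity is $E^{-Ct}$ and relative expression
divides by the **geometric mean** of the reference-gene quantities
(RPL13A, GAPDH) of the same sample — the standard multi-reference
convention; with all $E = 2$ this is exactly
$2^{\overline{Ct}_{ref} - Ct_g}$. A global per-sample amplification delay
cancels through the references. Cohort modified z-scores of
$\log_2$ relative expression then feed `classify_samples()` directly,
mirroring how a validation cohort is scored in practice (within-cohort
standardization, not frozen training statistics).

# Performance reporting

`evaluate_binary()` reports confusion counts, sensitivity, specificity,
accuracy, PPV and NPV with 95% **Wilson score** intervals — chosen
because the score interval, unlike Clopper–Pearson, reproduces printed
intervals such as (83.0%, 94.9%) for 86/95 — plus Youden's $J$ and the
clinical utility indices. We compute the CUIs by their conventional
formulas, $\mathrm{CUI}^+ = \text{sensitivity}\times\text{PPV}$ and
$\mathrm{CUI}^- = \text{specificity}\times\text{NPV}$, and label them by
formula, since published positive/negative labels for these indices are
not used consistently in the field. Grade bands: CUI ≥ 0.81 excellent,
≥ 0.64 good, ≥ 0.49 fair, ≥ 0.36 poor, else very poor; accuracy ≥ 0.85
excellent, ≥ 0.70 good, ≥ 0.55 fair, else poor. Metrics with an empty
margin (e.g. PPV with no positive calls) are reported as undefined
(`NA`), never as zero. AUC is computed as the Mann–Whitney statistic with
tied pairs counted ½, which equals the trapezoid area under the
empirical ROC.

Survival separation is assessed with the Kaplan–Meier product-limit
estimator (median = smallest time with $S(t) \le 0.5$, reported as "not
reached" when the curve stays above one half) and the standard log-rank
test with the hypergeometric variance and the common-risk-set convention
for ties; after a three-group test, pairwise comparisons are reported
unadjusted and Holm-adjusted. Both are delegated to the `survival`
package behind the package's interfaces, with brute-force risk-table
oracles in the test suite.

# The synthetic cohort generator

`generate_expression()` emulates the *structure* the analysis assumes,
not any particular dataset: three latent subtypes with default sizes
95 desert / 75 excluded / 176 inflamed (the consensus-cohort
composition), a 40-gene signature (13 angiogenesis, 13 stroma, 14
immune) plus 300 background genes, log-normal expression with per-gene
baselines uniform on $\log_2 \in [3, 10]$, and block-structured subtype
effects of size $\delta$ (default 2 log2 units): desert shifts immune by
$-\delta$ and stroma by $-\delta/2$; excluded shifts stroma by $+\delta$
and angiogenesis by $+\delta/2$; inflamed shifts immune by $+\delta$
while its stroma genes get doubled residual variance (stromal content in
inflamed tumors is heterogeneous). Baselines are gene-intrinsic — drawn
from their own fixed stream so that independently seeded cohorts share a
gene universe and frozen reference statistics transfer, as they must for
train/validate designs.

Genes of one program co-vary because they share the subtype shifts. The
`rho` parameter (default 0.5) fixes the shared program-activity variance
$\rho/(1-\rho)\,\sigma^2$ that would produce within-program correlation
$\rho$ in an unstructured cohort; a shared per-sample program factor
supplies only what the block structure does not already provide. At the
default $\delta = 2$ the blocks exceed that level, so no extra correlated
noise is injected; at $\delta = 0$ the null cohort exhibits correlation
$\rho$ exactly. We deliberately do **not** stack a full compound-symmetric
noise factor on top of the block structure: doing so double-counts
program co-regulation (the blocks *are* the co-regulation) and provably
destroys the category-score margins — with $\delta/2 = 1$ log2-unit
margins against a shared factor of standard deviation
$\sqrt{0.5}\,\sigma \approx 0.7$, every class boundary incurs ~17%
assignment error, which contradicts the discovery behavior the generator
exists to exercise.

Survival times are exponential per subtype with default medians 66
(inflamed) / 47 (excluded) / 35 (desert) months, with uniform independent
censoring whose horizon is solved so the expected censoring fraction is
0.30 for the label mix at hand. At these sample sizes the
excluded-vs-desert median gap is within sampling noise for an
appreciable fraction of seeds — single-seed median *orderings* between
those two groups are not a stable property, and the tests assert the
ordering on seed-averaged medians (plus inflamed above both per seed).
The qPCR read-out follows $Ct = 35 - \log_2(\text{expr}) +
\mathcal N(0, 0.3^2)$ per replicate (triplicates, efficiency 2), with
reference genes drawn stable (sd 0.25 log2 units, no subtype effect).

**What passing tests do and do not show.** The generator produces clean
block effects, independent Gaussian log-noise, perfectly stable
references and exactly exponential survival. Real cohorts add batch
effects, subtype-impure samples, non-monotone markers, FFPE RNA
degradation and reference-gene drift; recovery rates on the generator
are therefore upper bounds on real-data behavior, and the package's
numerical agreement checks (oracle equivalences, calibration of the
moderated test) are the results that transfer unconditionally.

# Numerical conventions and edge cases

- Medians use the standard even-$n$ midpoint rule throughout.
- `modified_zscore()` errors on non-finite input; constant vectors score 0.
- `moderate_variances()` requires ≥ 10 genes, errors when all residual
  variances are zero, and maps exact-fit genes ($s^2 = 0$) to a tiny
  positive value for the log-moment fit only; a `df_prior = 0` object
  reproduces the ordinary $t$ exactly.
- Exact ties: rule scores → `unassigned`; cluster mapping → first optimal
  permutation with a warning; gene rankings → $|t|$ then lexicographic;
  combination search → fewer genes then lexicographic; Youden → smallest
  cutoff.
- Model JSON is written with 17 significant digits, so a
  write/read round trip is bit-exact; expression TSVs round-trip to at
  least 12 significant digits.
- All randomized stages take explicit integer seeds, and reruns with the
  same inputs and seeds are byte-identical.

# Problem sizes used by the test suite

Unit tests run on matrices of tens to hundreds of genes; the
parameter-recovery suites use the default 346-sample cohort over 20 seeds
for consensus discovery and 5 train/validate seed pairs for classifier
rebuild and qPCR validation; the null-calibration check pools ten
5,000-gene null cohorts. These sizes give stable averages for the
properties tested while keeping a full run in about a minute; the same
computations at larger sizes are a matter of changing the loop bounds.

# Known limitations

- The discovery rule's category → subtype mapping scores angiogenesis as
  the desert hallmark; in data where excluded tumors also elevate
  angiogenesis the desert/excluded boundary is the least certain call,
  and the consensus filter exists precisely to remove such samples from
  training.
- The classifier emits hard labels; samples near a cutoff get no
  uncertainty quantification.
- The qPCR route assumes the reference genes are unaffected by subtype;
  violated references bias all relative quantities of a sample.
- Step 2 of the published model shares IRF1 with step 1, so a single
  aberrant IRF1 measurement moves both scores.
- No batch correction is included; cohorts must be normalized upstream.
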