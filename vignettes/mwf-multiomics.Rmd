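---
title: "Validating a myelin water fraction biomarker with multi-omics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a myelin water fraction biomarker with multi-omics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mwfomics` asks a simple question with four independent instruments: does a
myelin water fraction (MWF) imaging measure behave like a *myelin-specific*
biomarker? The package implements the statistical machinery of each
instrument — a proteome-wide association scan, cell-type specificity
calls, gene-set over-representation, and an imaging-transcriptomics
regional correlation — together with a synthetic-data generator that makes
the whole chain testable by parameter recovery. This vignette documents
the models, the tunable parameters, the numerical choices, and the places
where the design was genuinely open.

## The proteome-wide association scan

For each aptamer $j$ the scan fits, by ordinary least squares,

$$\mathrm{MWF}_i = \beta_0 + \beta_j \log_2 A_{ij} + \gamma_1\,
\mathrm{age}_i + \gamma_2\, \mathrm{age}_i^2 + \gamma_3\, \mathrm{sex}_i +
\gamma_4\, \mathrm{eGFR}_i + \varepsilon_{ij},$$

where $A_{ij}$ is the linear-scale abundance of aptamer $j$ in subject
$i$. The quadratic age term absorbs the nonlinear lifespan trajectory of
MWF; eGFR adjusts plasma protein levels for kidney clearance; sex is coded
0/1. The model is cross-sectional OLS throughout — no mixed effects, no
interactions. Standard errors use the unbiased residual variance and
p-values the t distribution on $n - k$ degrees of freedom.

**Regression direction.** With MWF as response and log2 abundance as
predictor, the covariates read naturally as adjustments of the MWF age
trajectory. The shared-term t statistic and p-value are identical under
the swapped orientation (log2 abundance as response); only the $\beta$
scale changes. `run_scan(..., swap_direction = TRUE)` reproduces the
alternative, so the choice is a reporting convention, not a modeling
commitment.

**Age covariate.** Where a cohort carries separate ages at protein and at
image acquisition, the scan uses age at protein measurement — the
covariate set adjusts the protein side of the association.

**Hits.** A gene enters the positive (negative) hit list when any of its
aptamers has unadjusted $p < \alpha$ (default 0.05) with positive
(negative) $\beta$. Aptamers are collapsed to genes only at the list
stage, because panels are aptamer-level and collapsing earlier would
discard multi-aptamer information. Benjamini–Hochberg q-values are emitted
alongside but do not gate the lists: the unadjusted threshold is the
analysis's stated selection rule, and the q-values let a user apply a
stricter one. A gene significant in both directions (possible with
multiple aptamers, not observed in practice) is assigned to the direction
of its smallest-p significant aptamer so the lists stay disjoint.

**Degenerate fits.** Noise-free simulated data produce designs where an
abundance column is *exactly* collinear with the covariates (a null
protein whose only variation is its covariate loading) or where the fit is
exact. `fit_ols()` raises a singular-design error naming the aliased
columns — which the scan catches per aptamer and records as
`direction = "null"` — and detects exact fits by
$\mathrm{RSS} \le 10^{-13} \sum y_i^2$, reporting $p = 0$ for clearly
nonzero coefficients. Both rules only matter in the noiseless limit; at
any realistic noise level they are never triggered.

## Cell-type specificity

Expression levels across cell types are heavy-tailed, so a gene's nTPM
profile is standardized on the log scale: with pseudocount $\epsilon$,

$$z_c = \frac{\ln(x_c + \epsilon) - \overline{\ln(x + \epsilon)}}
{\mathrm{sd}\,\ln(x + \epsilon)},$$

the z-score of the log values — equivalently the log-ratio to the
geometric mean scaled by the log geometric standard deviation. Choices
fixed here: natural log (z-scores are base-invariant; fixed for
reproducibility), sample ($n-1$) standard deviation (matching common
z-scoring convention, and what the test oracles recompute),
$\epsilon = 0.1$ nTPM (nTPM can be exactly 0; 0.1 is small against the
conventional 1 nTPM detection cutoff), and all available cell types —
brain and peripheral alike — enter the mean and SD. An all-equal profile
has zero spread and is defined to return all-zero z-scores rather than an
error.

A gene's enriched set is the *brain-related* cell types with $z \ge 2$
(ties at exactly 2.0 count); peripheral types never enter the set however
large their z. Categories partition every profile: `none` (empty set),
`single`, `oligoMultiCell` (two or more enriched types including
oligodendrocytes or OPCs), `multiCell` (two or more, no oligo lineage).
The default brain-related list — oligodendrocyte, OPC, astrocyte,
microglia, excitatory neuron, inhibitory neuron, endothelial — is a
defensible default rather than a canonical standard, and is fully
overridable via `cell_type_vocabulary()` / a vocabulary YAML.

**Why the default panel has 24 cell types.** The z-score of $k$ jointly
enriched types among $n$ is bounded above (even with an infinite
expression boost) by

$$z_{\max}(k, n) = \frac{(1 - k/n)\sqrt{n-1}}
{\sqrt{k(1-k/n)^2 + (n-k)k^2/n^2}},$$

which for $k = 2$ gives 1.90 at $n = 10$ but 3.25 at $n = 24$. A small
cell-type panel therefore *cannot represent* multi-cell-type enrichment at
the $z \ge 2$ threshold at all; 24 types (the scale of single-cell
expression atlases) leaves a wide margin. For the same reason the
generator plants at most two enriched types per gene: at $k = 3$, $n = 24$
the ceiling drops to 2.59 and recovery becomes noise-limited.

## Gene-set over-representation

The right-tail Fisher exact test is computed directly,
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
accumulated in log space via `lchoose` and log-sum-exp so it is stable at
panel-scale $N$; when $k$ is at the distribution's lower support bound the
function returns exactly 1. Only the enrichment (greater) tail is tested —
depletion is not the question being asked.

The background is the set of genes assayed on the protein panel, not the
genome: a query drawn from a panel can only ever contain panel genes, and
a genome-wide background would overstate every overlap. An explicit
`background` argument overrides this. Genes outside the background are
dropped from both query and sets (with a logged count); sets empty within
the background are omitted. The reporting rule per library is
`min(top_k, #{p < alpha})` rows of the p-sorted table, defaults 5 and
0.05, with ties broken by descending overlap then set name. Rank-based
"combined scores" that some enrichment services add on top of Fisher p
are out of scope — the Fisher p reproduces the ranking semantics.

## Spatial transcriptomics

Four operations reproduce the atlas stage:

* **Assignment.** A sample belongs to the region of the voxel it falls in;
  otherwise to the nearest labeled voxel *center* within `max_dist_mm`
  (default 2 mm), else it is unassigned. Distance-to-center rather than
  distance-to-boundary keeps the rule honest at atlas resolution and
  exhaustively checkable; ties break by smaller region id, then
  lexicographic voxel index. Enlarging the tolerance can only assign
  previously unassigned samples, never change an in-voxel call.
* **Profiles.** Per donor and region, the mean expression of a probe over
  the donor's assigned samples.
* **Differential stability.** A probe's DS is the mean Spearman
  correlation (midranks for ties) of its regional profile over all
  unordered donor pairs, computed on the regions present in both donors'
  profiles. Pairs with fewer than 3 common regions are skipped with a
  warning; a probe with no valid pair gets `NA` and is never selected; DS
  ties break by probe id order. DS is invariant to monotone transforms of
  a probe's values, which is exactly why it is the right probe-selection
  criterion for arrays with probe-specific gains and offsets.
* **Correlation.** Donor-level regional means are averaged with equal
  donor weight (donor-first aggregation, so densely sampled donors do not
  dominate), then regional mean MWF is regressed on regional mean
  expression. The headline statistic is the Pearson r with its two-sided
  p from $t = r\sqrt{(n-2)/(1-r^2)}$ — for simple OLS the regression
  delivers exactly this r — and the Spearman alternative is always emitted
  alongside, since with a dozen regions the two can differ materially.
  Fewer than 3 common regions or a zero-variance axis is an error, not a
  silent NA.

## The synthetic-data generator

`simulate_study()` draws every input the pipeline consumes, from one
`sim_config()`. One master seed spawns fixed-offset child seeds per
component, so each component is independently reproducible and the whole
study is byte-identical under a repeated seed.

What it emulates, and the defaults:

* **Cohort** (85 subjects): age uniform on [22, 94] years (mean 58), sex
  Bernoulli(0.56, male), eGFR log-normal around 75 mL/min/1.73m². Global
  MWF follows an inverted-U quadratic age trend (0.22 at the age-45 peak,
  curvature $2\times10^{-5}$ per year², so roughly 0.17–0.22 across the
  age range), plus a between-subject biological deviation
  (`mwf_subject_sd` = 0.02) plus measurement noise (`mwf_noise_sd` =
  0.005). Regional MWF rescales the subject's global level by each
  region's latent myelin.
* **Proteome** (500 aptamers; the assay-scale thousands are a config
  choice, not a different code path): log2 abundance is intercept +
  planted effect × standardized MWF + small random age/sex/eGFR loadings
  + N(0, 1) residual. The planted effect defaults to 3× the detectable
  standardized slope at the cohort size
  ($3(z_{0.975}+z_{0.8})/\sqrt{n} \approx 0.91$ at $n=85$) — large enough
  that recovery failures indicate bugs, not power.
* **nTPM** (24 cell types): log-normal baselines with 0.5 log-scale
  scatter; planted enriched types get a +5 log boost (~150-fold, the
  order of magnitude of canonical cell-type markers).
* **Atlas**: 6 white-matter regions (latent myelin uniform on
  [0.55, 0.90]) and 6 deep-gray regions ([0.10, 0.35]) as disjoint
  4-voxel cubes on a 24³ grid of 2 mm voxels — geometry is irrelevant to
  the statistics, so boxes keep the NIfTI affine handling real while
  staying trivially checkable.
* **Donors** (6 × 60 samples): samples cycle over regions, land on a
  random labeled voxel center, and are jittered by 1.5 mm per axis — so
  some fall outside their region but within the 2 mm tolerance and a few
  beyond it, deliberately exercising the assignment rule. Probe
  expression is offset + gain × slope × regional myelin + noise, with the
  stable probe at SD 0.1 and the others at 0.5 (1:5). The MBP-like gene
  carries the maximal slope.
* **Gene sets**: one pathway enriched for planted-positive genes, one for
  planted-negative genes, and 10 uniform decoys of size 20.

Two deliberate conventions deserve emphasis. First, `zero_noise()` zeroes
every *measurement* noise scale but keeps `mwf_subject_sd`: the
between-subject MWF deviation is the biological signal the planted
proteins respond to, and without it MWF is an exact function of age, which
makes the covariate-adjusted regression degenerate for every protein. The
noiseless limit is "perfect instruments", not "no biology". Second, the
planted stable probe is always the first probe label of each gene: in the
noiseless limit all probes reach DS = 1 and selection falls to the
deterministic probe-id tie-break, which must then still pick the planted
probe. Probe labels are arbitrary, so this costs no generality.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: assay chemistry and batch effects,
non-Gaussian noise (all noise is Gaussian on the modeling scale: log2 for
proteins, identity for MWF — the simplest model consistent with the linear
analyses; the true across-subject noise structure of MWF is unknown, so
this is a stand-in, not an inference), realistic anatomy and spatial
autocorrelation of expression, donor-specific normalization of atlas
intensities, and hemisphere asymmetries. The permutation null in the tests
is a raw permutation; spatial-autocorrelation-preserving nulls are out of
scope.

## Numerical choices, collected

* OLS via QR; aliased columns named in the singular-design error;
  exact-fit threshold $10^{-13}\sum y^2$.
* Fisher tail in log space; exact 1 at the support bound.
* Geometric z-scores: natural log, $n-1$ SD, $\epsilon = 0.1$; all-equal
  rows return zeros.
* Assignment ties: smaller region id, then lexicographic voxel index;
  distance comparisons use a $10^{-9}$ mm² slack so float noise cannot
  flip a tie.
* DS ties: probe id order; Spearman with midranks.
* Label volumes written as uncompressed int16 NIfTI-1 (sform code 2), so
  repeated runs are byte-identical; no output table carries a timestamp.

## Problem sizes in the test suite

The packaged tests run the generator at two scales: the full default study
(85 subjects × 500 aptamers, 12 regions, 6 donors) for the calibration,
recovery, and determinism checks — 20 seeds for the null-calibration and
planted-recovery sweeps, 200 seeds for the classifier and probe-selection
recovery rates at a reduced panel (40 genes) whose noise and boost
parameters are the defaults — and a miniature configuration (40 subjects ×
60 aptamers) for unit-level checks. These sizes are the package's choice
of desk-scale study conditions; every threshold the tests assert
(recovery ≥ 90%, stable-probe selection ≥ 95%, type-I error inside the
exact binomial 99% interval) is evaluated at those conditions.

## Known limitations

* Complete-case handling per aptamer; no imputation.
* One nTPM matrix per run; no consensus across single-cell references.
* The enrichment stage tests over-representation only, with raw p driving
  the reporting rule.
* The spatial stage handles one gene per run (the myelin marker of
  interest); genome-wide imaging-transcriptomics preprocessing
  (cross-donor intensity normalization, gene filtering, mirroring) is out
  of scope.
* Real-mode regional MWF is a per-region table; a voxelwise MWF map can
  be aggregated over the label volume, but no registration is performed.
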