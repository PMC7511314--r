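---
title: "Methods: co-expression modules and polytranscript risk scores for dimensional child psychopathology"
author: "ptrsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and polytranscript risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analytical problem

`ptrsnet` implements a blood-transcriptome analysis of *dimensional* child
psychopathology. The phenotypes are the eight syndrome scales of the Child
Behavior Checklist (CBCL) — anxious/depressed, withdrawn/depressed, somatic
complaints, social problems, thought problems, attention problems,
rule-breaking, aggressive behavior — reported as age- and sex-normed t-scores
with a hard floor at 50. The molecular data are gene-level RNA-seq counts from
whole blood in a cohort of school-age children drawn from two matched groups
(children with parent-reported psychiatric concerns and typically developing
children).

The pipeline asks, stage by stage:

1. which leukocyte mixture underlies each bulk blood sample (deconvolution);
2. which hidden technical factors confound the expression matrix (surrogate
   variable analysis, SVA);
3. which co-expressed gene modules exist, summarized by their eigengenes
   (weighted co-expression network analysis);
4. whether module eigengenes, and then individual member genes, associate with
   CBCL scales under negative-binomial regression with covariate adjustment;
5. whether module members over-represent annotated gene sets; and
6. how much CBCL variance a *polytranscript risk score* (PTRS) — a linear
   composite of expression weighted by per-gene effect sizes — explains out of
   sample.

Because the motivating cohort is controlled-access, every stage is exercised
against a synthetic cohort generator that plants the exact structures the
analysis is designed to recover.

# Models and procedures

## Negative-binomial regression of t-scores

CBCL t-scores are bounded-below counts; the package models them directly with
an NB2 generalized linear model, log link:

$$y_i \sim \mathrm{NB}(\mu_i, \phi), \qquad \log \mu_i = x_i^\top\beta, \qquad
\mathrm{Var}(y_i) = \mu_i + \phi\,\mu_i^2 .$$

`fit_nb_glm()` alternates Fisher-scoring IRLS for $\beta$ with a profile
optimization of $\phi$ on the log scale, stopping when the log-likelihood
changes by less than `1e-8` (at most 100 outer iterations). When $\hat\phi$
collapses below `1e-6` — t-scores are frequently *under*-dispersed relative to
Poisson because of the floor — the Poisson-limit fit is reported with
$\phi = 0$. Wald standard errors come from the Fisher (expected) information
at the optimum; this matches the `MASS::glm.nb` convention, which the test
suite uses as an independent oracle, and differs from the observed information
by $O(1/n)$. Two-sided p-values use the normal approximation
$p = 2\Phi(-|\beta/\mathrm{SE}|)$.

The scores are modeled on their natural scale (not shifted by the floor of
50); `shift_floor = TRUE` in the association functions provides the shifted
variant as a sensitivity analysis.

Variance explained is Nagelkerke's pseudo-$R^2$,
$R^2_N = \frac{1 - e^{(2/n)(\ell_0-\ell_1)}}{1 - e^{(2/n)\ell_0}}$,
computed against the covariate-only null fit of the same response.

## Covariates and surrogate variables

All association and PTRS models adjust for age, sex, race, and RIN (RNA
integrity number), plus any surrogate variables. `estimate_num_sv()` selects
the number of SVs by a permutation null (Buja–Eyuboglu style): the expression
matrix is residualized on the protected covariates, each gene's residuals are
permuted independently and re-residualized (preserving the degrees of freedom
absorbed by the design), and a component is kept while its share of residual
variance exceeds the 95th permutation percentile. This replaces the
asymptotic "leek" selection with a distribution-free, directly testable
criterion — a deliberate substitution.

`estimate_svs()` is an iteratively re-weighted SVD. Gene weights are
$(1-\mathrm{lfdr}(p_{\text{SV}}))\cdot\mathrm{lfdr}(p_{\text{cov}})$ — an
empirical probability of being affected by the SVs but not by the protected
covariates — with moderated F p-values from `limma` and a histogram-based
local FDR (so that a batch affecting all genes equally drives all weights to
one and the procedure reduces to the plain residual SVD). Convergence is
declared when the principal angle between successive SV subspaces falls below
`1e-6` (cap 50 iterations; non-convergence returns the last iterate with a
flag, never an error).

One caveat discovered and documented here: a permutation criterion counts
*any* reproducible latent structure, including genuine co-expression factors.
On data with strong modules it therefore reports many "surrogate variables"
that are biology, not artefact. The pipeline consequently (a) builds the
network from covariate-residualized data *without* SV removal, and (b) caps
the SVs carried into the association design (`sva$max_sv`, default 1,
configurable). `estimate_num_sv()` itself is left uncapped.

## Leukocyte deconvolution

`estimate_proportions()` implements signature-based iterative least squares:
per sample, expression over the genes shared with the signature matrix is
regressed on the signature columns; while any coefficient is negative, the
most negative cell type is dropped (ties broken toward the lower column
index, for determinism) and the fit repeated; residual negatives are clamped
and the result normalized to proportions. Deconvolution runs on linear-scale
expression because mixing is linear in abundance; log-scale input is refused.
No reference signature is bundled — the appropriate signature set is a user
decision — but `simulate_signature()` provides a clearly-synthetic
marker-block signature for tests and demonstrations.

## Co-expression network and module eigengenes

The network follows the weighted co-expression framework with Pearson
correlation and an **unsigned** adjacency $a_{ij} = |r_{ij}|^\beta$ (the
signed variant is available; the choice of network type is configurable
because the reference analysis does not state it). `pick_soft_threshold()`
selects $\beta$ as the smallest candidate whose connectivity distribution
achieves scale-free model fit $R^2 \ge 0.8$ with negative slope, regressing
$\log_{10} p(k)$ on $\log_{10} k$ over 10 connectivity bins.

Topological overlap is
$\mathrm{TOM}_{ij} = \frac{\sum_{u\ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}}$, and $1-\mathrm{TOM}$ the clustering
dissimilarity.

`detect_modules()` deliberately does **not** reproduce the dynamic hybrid
tree cut. It applies, in order:

* average-linkage hierarchical clustering, cut statically at 0.99 of the
  maximum merge height;
* recursive two-way splits of clusters when both branches reach
  `min_module_size` (default 30, conservative relative to the smallest module
  the reference analysis reports) and are separated by a merge-height gap of
  at least `gap_min = 0.02` (aggressive splitting is safe because the merge
  step below re-joins over-split modules);
* core filters requiring an eigengene variance share of at least 0.25 and
  per-gene $|kME| \ge 0.3$ (genes failing it are pruned to label 0);
* an external-connectivity guard: a cluster whose eigengene correlates above
  the $kME$ threshold with more than
  $\max(0.05,\; 3 \times \text{null rate at this } n)$ of the genes *outside*
  it is dissolved. A genuine co-expression module is locally connected; only
  a matrix-wide factor (a batch artefact strong enough that its most-affected
  genes form a cluster) shows that diffuse signature. Without this guard the
  planted-batch simulations reliably produce one spurious "batch module".
  The guard presumes the input carries no per-sample common mode: CPM
  normalization divides every gene by the library size, leaking a mixture of
  the dominant expression factors into all genes, which mimics exactly the
  diffuse signature the guard looks for. `center_samples()` removes that
  common mode and the pipeline applies it to the network input. On very
  small gene panels (a module comprising a sixth of all genes) the module's
  own factor dominates the common mode and centering cannot fully separate
  the two — a documented limitation; the reference scale (3,000 genes,
  largest module 8%) is unaffected;
* merging of modules whose eigengenes correlate above `1 - merge_height`
  (default correlation 0.85), then relabelling `1..M` by decreasing size.

The acceptance surface of this simplified algorithm is truth recovery: on the
default generator it must reassemble the planted partition (adjusted Rand
index $\ge 0.8$ in at least 18 of 20 seeds), which the test suite verifies.

A module eigengene is the first right singular vector of the standardized
module submatrix, scaled to unit variance, signed so that its correlation
with the module's mean standardized expression is nonnegative, and reported
with its variance share.

## Association and multiple testing

`associate_modules()` tests every scale-by-eigengene pair: NB2 fit of the
t-score on eigengene + covariates (+ SVs) against the covariate-only null;
the eigengene's Wald $\beta$, SE, $Z$, $p$ and the Nagelkerke increment are
recorded, with Benjamini–Hochberg FDR applied jointly across the full
scale-by-module grid. `associate_genes()` then restricts attention to the
member genes of significant modules, testing only the scales with at least
one significant module and applying BH across exactly those tests — the test
count is a checked contract.

## Gene-set over-representation

`enrich_module()` performs one-sided hypergeometric over-representation of a
module against a GMT collection, with the retained post-pruning gene list as
universe, sets intersected with the universe first, set-size bounds
[5, 2000], and BH-FDR within each module. Rank-based GSEA variants are out of
scope.

## Polytranscript risk scores

`train_weights()` regresses, gene by gene, the scale's t-score on the
standardized expression plus covariates within the training samples; the
per-gene coefficient and p-value become the weight table. `score_samples()`
builds $s_i = \sum_{g\,:\,p_g \le \tau} \beta_g z_{ig}$ over a fixed grid of
six p-value thresholds $\tau \in \{0.001, 0.01, 0.05, 0.1, 0.5, 1.0\}$ (the
reference analysis corrected six tests per scale without printing its grid;
these values span polygenic-score convention and are configurable). The
standardization statistics always come from the training samples only; the
inclusive bound ($p \le \tau$) makes $\tau = 1$ the all-genes score.

`crossvalidate_ptrs()` runs stratified (by group) 5-fold cross-validation,
pools the withheld-fold scores, and evaluates each threshold by the NB2 fit
of the t-score on score + covariates versus the null, reporting Nagelkerke
$R^2$, Wald $p$, and BH-FDR across the six thresholds per scale
(`pooled = FALSE` gives the per-fold-average alternative with
Fisher-combined p-values). `external_ptrs()` scores the whole cohort with
externally derived disorder weight tables — 8 scales × 6 thresholds = 48
tests per disorder, BH within disorder — reporting the gene-intersection
size per table.

Information leakage is guarded twice: structurally (per-fold weights can be
recomputed from the training folds alone and compared, which a test does) and
statistically (under permuted phenotypes the cross-validated $R^2$ must stay
at its null level).

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions with full ground truth. Its
defaults *are* the reference conditions of the test suite.

| Parameter | Default | Rationale |
|---|---|---|
| `n_samples` | 100 | two matched groups, near the motivating cohort's 95–96 |
| `n_genes`, `n_modules` | 3000, 10 | desk-scale network with 1500 module genes (sizes 60–240) and 1500 background genes |
| `factor_loading_sd` | 1.0 | log-scale module signal SD; with NB noise this yields within-module correlations around 0.8 |
| `nb_dispersion` | 0.2 | NB2 $\phi$ typical of bulk RNA-seq after normalization |
| `dirichlet_alpha` | (22, 12, 3.2, 2, 0.8) | blood-like mean proportions (neutrophils > lymphocytes > monocytes > eosinophils > basophils) |
| `batch_effect_sd`, `batch_gene_fraction` | 0.5, 0.30 | one hidden batch factor, multiplicative on the log scale, touching 30% of genes — partial affectedness is what makes SVA non-trivial |
| `phenotype_noise_sd` | 12 | latent (pre-floor) t-score noise; after flooring this realizes a t-score SD near 7, typical of clinically enriched CBCL samples, and keeps the floored scores' variance near their mean so the NB model is sensible |
| `phenotype_covariate_effects` | age 0.2/yr, sex 1.0, group 4.0 | small demographic effects plus the expected case–control elevation |
| `t_floor` | 50 | the CBCL t-score floor |

Covariates are drawn to match the reference cohort's marginals: age uniform
on 6–12 years, sex and race balanced binaries, RIN normal (8.75, 0.5)
truncated to (6, 10). Module loadings have magnitude
`factor_loading_sd · |N(1, 0.25)|` and are positive with probability 0.8 —
module genes are mostly co-regulated in one direction, which is what gives
the eigengene a meaningful orientation. Counts are NB2 draws with log-mean
`baseline + loading·factor + batch·effect + RIN·effect`. Phenotypes are
`max(50, round(50 + Σ effect·factor + covariate terms + noise))`: the floor
is applied as a max after rounding, because the floor is the only documented
constraint on how sub-threshold scores arise.

Planted phenotype effects default to attention problems ← module 1 and
aggression ← module 2, sized by the analytic mapping
`effect_for_target_r2()`: $e = \sqrt{\frac{R^2}{1-R^2}(\sigma^2_\varepsilon +
\sigma^2_{\text{cov}})}$ with latent targets 0.15 and 0.10. Flooring and the
pseudo-$R^2$ attenuate the *realized* oracle Nagelkerke $R^2$ to roughly
0.07–0.10 at these settings; recovery is therefore always judged relative to
the measured oracle (the in-sample NB fit on the true factor), not to the
latent target.

What the generator does **not** emulate — so what passing tests do not show
about real data: library-size variation and GC/length biases (normalization
is exercised only lightly); the empirical inter-scale correlation structure
of the CBCL (effects can be shared across scales via the configuration, but
no claim is made to match the real correlation matrix); cell-proportion
effects on gene expression (proportions are recorded truth, and enter counts
only through the optional appended signature-gene block used by the pipeline
smoke path); overlapping or nested modules; and count artefacts such as
zero-inflation.

# Numerical and design choices

* **Determinism.** Every stochastic function takes or derives a seed; the
  pipeline fans one base seed out to per-stage seeds through a fixed counter
  scheme, so stage-level reruns reproduce in isolation and identical
  configurations yield byte-identical run manifests (no timestamps are
  written).
* **Tie-breaks.** Deconvolution drops the lower column index among equally
  negative coefficients; module relabelling breaks size ties by first gene
  index; eigengene and SV signs are fixed by explicit conventions.
* **Degenerate inputs.** Constant genes are an error in network construction
  and eigengene computation (they carry no correlation information), a
  flagged zero-weight in PTRS training, and a flagged NA in proportion
  testing. Empty filter results and empty significant-pair sets warn or
  return empty tables rather than erroring.
* **Problem sizes.** The test suite runs the recovery and calibration studies
  at the reference sizes (20 seeds at 100×3000 for module recovery; 500
  null cohorts at n=95 for association calibration; 50 permutation cohorts
  and 20 recovery cohorts for PTRS); the acceptance script reports the same
  quantities from moderately fewer replicates, a deliberate precision/effort
  trade-off stated in its output (`n` per quantity).
* **Open points resolved.** Predictor-vs-response direction for eigengenes
  (eigengene as predictor of the t-score, the alternative noted); binary race
  coding; pooled rather than per-fold-averaged CV evaluation (the per-fold
  average of Nagelkerke $R^2$ on 19-sample folds carries a much larger
  small-sample bias); normalization fixed to log2-CPM as the documented
  stand-in for an unspecified upstream pipeline.

# Known limitations

* The simplified tree cut is validated by truth recovery, not by agreement
  with any particular published clustering implementation; on real data its
  partitions will differ in detail from dynamic hybrid cutting.
* Wald p-values from pooled cross-validated scores are slightly optimistic
  because pooled predictions are not independent of the outcomes; the null
  calibration tests quantify this and the per-fold mode avoids it at a power
  cost.
* The permutation SV count is honest about *structure* but agnostic about
  *provenance*; distinguishing artefact factors from biology requires either
  protected-covariate knowledge or the downstream cap described above.
* NB regression of floored t-scores is a pragmatic reading of the reference
  analysis; for strongly under-dispersed scales the Poisson-limit fit is
  conservative.
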