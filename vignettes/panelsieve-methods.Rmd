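---
title: "Methods: stability-selected mutation signatures and survival cutpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected mutation signatures and survival cutpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsieve)
```

`panelsieve` discovers a gene-panel mutation signature predictive of benefit
from immune checkpoint inhibition (ICI) in a randomized two-arm trial, and
evaluates it against tumor mutational burden (TMB). This vignette is the
package's own account of the statistical machinery: the models, the tunable
parameters and their defaults, what the synthetic generator does and does not
emulate, the numerical conventions, and the design decisions that were
genuinely open.

## 1. The data model

The central container (`cohort_dataset`) joins a strictly binary patient ×
gene mutation matrix with per-patient clinical outcomes: arm
(`treated`/`control`), PFS and OS (months, each with a 0/1 event indicator),
RECIST best response (CR/PR/SD/PD/NE), baseline sum of longest diameters
(SLD, mm), and optionally a precomputed TMB (mutations/Mb). Mutation
presence is binary per (patient, gene) regardless of variant multiplicity:
the benefit score counts *genes*, not variants. `pfs_time <= os_time` is
deliberately not enforced — real trial exports violate it. When no TMB
column is supplied, TMB is approximated as total mutated genes / 1.1 Mb
(the target region of a 391-gene commercial assay); this is a documented
approximation, since the assay counts variants while the matrix counts
genes.

## 2. Panel selection

### Base learner

The classifier is a gradient-boosted tree ensemble with a logistic
objective in the second-order formulation: with per-observation gradient
$g_i = p_i - y_i$ and hessian $h_i = p_i(1-p_i)$, a split of node $N$ into
$(L, R)$ scores
$$\mathrm{gain} = \tfrac12\left(\frac{G_L^2}{H_L+\lambda} +
\frac{G_R^2}{H_R+\lambda} - \frac{G_N^2}{H_N+\lambda}\right),$$
and a leaf takes weight $-G/(H+\lambda)$, shrunk by the learning rate.
Because every feature is binary there is exactly one candidate split per
gene, so greedy search is exact, cheap, and fully deterministic (gain ties
break on gene order). Defaults: 200 rounds, depth 3, learning rate 0.1,
$\lambda = 1$, minimum child hessian 1. No published hyperparameters exist
for the procedure this emulates; these are conventional values for sparse
binary features, all exposed via `base_learner_params`. No GBDT library on
the supported platform provides this with the determinism the stability
procedure needs, so the learner is compiled in the package (`src/gbt.cpp`);
it is deliberately minimal (no subsampling, no column sampling), which also
makes repetition-level variation attributable solely to the random
train/validation split.

### Label

The training label is the only genuinely undefined ingredient of the
procedure. The default is the RECIST responder (CR/PR = 1, SD/PD = 0, NE
masked), the one binary outcome a trial export always defines; a
`pfs_ge_m` alternative labels patients by whether PFS reached `m` months
(censored-before-`m` patients masked). Only treated-arm patients are
labeled: the signature should capture benefit *under ICI*, not prognosis.

### Importance

Default importance is held-out permutation importance: the drop in
validation AUC, averaged over `n_permutation_shuffles = 5` random shuffles
of one gene's column. Genes the forest never splits on receive exactly 0
without prediction work (shuffling a column the trees ignore cannot change
predictions). Native total split gain is available as
`importance = "native_gain"`. Ranks order by (importance desc, gene asc);
permutation importance can be negative by sampling noise, and such genes
rank after the zero block.

### Aggregation across repetitions

Each of `n_repetitions` (default 350) repetitions contributes its top-`k`
set (default `top_k = 150` for a ~400-gene universe; the stability trace is
the diagnostic for choosing it). Two aggregation modes exist:

* `mode = "frequency"` (default): keep genes in the top-k of at least
  `freq_threshold = 0.8` of repetitions — the conventional
  stability-selection threshold.
* `mode = "intersection"`: the strict intersection of all top-k sets.

The strict intersection was the first-choice design, but it is fragile in a
way implementation made measurable: on the planted-signal benchmark (400
genes, 20 causal with per-gene odds ratio 4 and frequency ≥ 0.15, ~800
treated patients, `top_k = 60`), causal genes sit in the top-60 of roughly
75–100% of repetitions — held-out permutation importance on ~160 validation
patients is noisy enough to occasionally push a truly predictive gene to
zero or below. One such excursion removes the gene from a strict
intersection permanently, and over 50 repetitions the intersection collapses
to one or two genes. The frequency rule at $q = 0.8$ recovers 17–20 of the
20 causal genes with ≤ 15% false discoveries on the same worlds. The running
intersection is still computed for every run (it is non-increasing by
construction) and a plateau is declared when it is unchanged for
`stability_window = 25` consecutive repetitions.

A caveat the chance-overlap tests encode: top-k inclusion under a null
label is only uniform across genes when genes are exchangeable. Unequal
mutation frequencies systematically favor common genes (they are more
splittable), and on a single fixed dataset chance gene–label correlations
persist across repetitions because the 80% training splits overlap heavily.
Stability selection controls split-to-split variance, not dataset-level
confounding.

## 3. Scoring and the cutpoint

The ICI-benefit score of a patient is the number of distinct mutated
signature genes. For each candidate cutoff $c \in \{1, \dots, \max s\}$ the
treated-arm PFS Cox model of the dichotomized score $1[s \ge c]$ yields a
hazard ratio and the Wald statistic $(\hat\beta/\mathrm{se})^2$. Cutoffs
where either stratum has fewer than `min_group_size = 20` patients or fewer
than `min_events = 5` events are skipped (tail-of-grid fits are unstable);
fewer than 3 surviving cutoffs aborts the curve.

Structural breaks of the Wald-vs-cutoff curve are located by the Chow test:
OLS lines fitted to the pooled curve and to the two segments around each
admissible break (≥ 3 points per side),
$$F = \frac{(RSS_p - RSS_1 - RSS_2)/2}{(RSS_1 + RSS_2)/(n-4)} \sim
F(2,\,n-4)$$
under the no-break null. The selected cutoff is the maximum-F break with
$p < 0.05$; with no significant break the raw-Wald-maximum cutoff is
returned, flagged. The elbow range is the contiguous run of breaks with
$F \ge F_{\max}/2$. A perfectly linear curve has $F = 0$ by convention, and
$F$ is invariant to affine rescaling of the Wald values.

The break search runs on the **raw** curve by default. The original design
smoothed first (LOESS, span 0.80) and a smoothed search remains available
(`smooth = TRUE`), but on planted hazard steps the smoothing is
counterproductive and measurably so: a step at score ≥ 3 produces a sharp
tent-shaped Wald peak over the dozen-odd candidate cutoffs, span-0.8 LOESS
over so few points flattens the tent into a near-monotone curve, and the
max-F break slides 2–4 cutoffs downstream (simulations: smoothed search
selected 7–9 where the truth was 3 in 10/10 replicates; the raw search
selected 3 in 10/10). Smoothed Wald and HR values are always emitted with
the curve for plotting. The LOESS itself is local-linear with tricube
weights over the `floor(span·n)` nearest neighbors — the standard
definition, verified against an independent implementation to machine
precision — and degrades to a weighted mean where the local design is
singular.

Cox ties use the Efron approximation throughout.

## 4. Evaluation

The report computes, for each arm × endpoint (PFS, OS) × marker (score,
TMB): the continuous-covariate Cox contrast, the dichotomized contrast, and
treated-vs-control contrasts within each marker stratum; Kaplan–Meier
coordinates with log-rank p-values; ORR tables (responder = CR or PR, NE
and missing excluded from denominators — the RECIST convention) with
absolute ORR differences; responder AUC per marker (Mann–Whitney with 0.5
tie credit; percentile bootstrap CI over patients, 2000 seeded replicates —
chosen over DeLong because it is trivially verifiable against an
independent implementation); and Spearman correlations of score with TMB
and SLD (Pearson on mid-ranks, t-approximation p). KM medians are the first
time survival reaches 0.5 or below and are reported as "not reached"
(`NA`), never as the last observed time. Degenerate strata and missing arms
are flagged in the report, not silently dropped. The TMB-high threshold
defaults to 10 mutations/Mb — the only conventional dichotomization — and
is required explicit config for any TMB-stratified result.

## 5. The synthetic trial generator

`simulate_cohort` draws the world the test suite reasons about:

* ~1:1 randomization (`arm_ratio = 0.5`), default 850 patients and 400
  genes with 20 planted benefit genes;
* per-gene Bernoulli mutation rates uniform in `mutation_freq_range`
  (default 0.02–0.25, the spread seen on targeted panels);
* exponential PFS and OS with hazard
  $h_0 \exp(a\beta_{trt} + a\,s\,\beta_{trt/mut} + (1-a)\,s\,\beta_{ctl/mut})$,
  where $s$ counts planted-gene mutations: each benefit mutation improves
  the treated-arm hazard (default $e^{\beta} = 0.8$) and slightly worsens
  the control arm (1.05). Constant baseline hazards (defaults: median PFS 4
  months, median OS 10 months, typical of second-line NSCLC) keep
  proportional hazards exactly true, so Cox recovery is an exact oracle;
* administrative censoring uniform on (0, 30) months, independent of
  covariates;
* responder status from
  $\mathrm{logit}\,P = \alpha + a\,s\,\beta_{resp}$, emitted as PR/PD
  labels. For planted-signal benchmarks the intercept is set to
  $-\mathbb{E}[s]\,\beta_{resp}$ so the responder rate is balanced: an
  early pilot with a fixed 10% intercept saturated the label (90%
  responders) and destroyed the per-gene odds ratios the benchmark is
  supposed to plant;
* SLD normal (75 ± 30 mm, truncated at 10); TMB derived from the matrix.

PFS and OS are independent given covariates (no copula) — the pipeline
never uses their joint law. Identical configs are bit-identical
(`set.seed` on the config seed; the caller's RNG state is restored).

What the generator does **not** emulate — and therefore what a green test
does not establish: variant-level allele frequencies and subclonality
(mutations are gene-level Bernoulli), co-mutation correlation structure
(genes are independent), non-proportional hazards, informative censoring,
PD-L1 expression, and the gene-count/variant-count gap in derived TMB. The
planted-step cutpoint benchmarks use an over-dispersed count score with
appreciable mass at zero (about half of real patients carry no signature
mutation); a score distribution concentrated above zero silently removes
the leftmost cutoffs from the grid and with them any admissible break
around a low threshold.

## 6. Reproducibility and the pipeline

`run_pipeline` chains simulate/load → select → score → cutpoint → evaluate,
writing every stage artifact plus a resolved-config snapshot that
reproduces the run byte-identically. One global seed deterministically
derives stage seeds (`seed · 7919 + offset mod 2³¹−1`), repetition seeds are
drawn once from the selection seed, and the AUC bootstrap is seeded, so
standalone stage reruns match pipeline runs. All filter counts — dropped
patients, off-panel genes, skipped cutoffs, degenerate strata — are logged:
stratification claims are only auditable if the exclusions are.

## 7. Known limitations

* The training label behind the published 88-gene signature, its top-k, and
  its stopping rule are not public; `panelsieve` exposes all three and
  makes no claim to reproduce that exact gene list without the original
  export.
* Strict-intersection aggregation should be used only with few repetitions
  (see §2); the default frequency rule answers a slightly different
  question (high-probability top-k membership) than the published wording
  (all-repetition intersection).
* The cutpoint procedure assumes a univariate, monotone-in-score hazard
  contrast; it is not a maximally-selected-rank-statistics method and does
  not adjust its p-values for the cutoff search.
* With heavy censoring or small arms the HR curve loses grid points from
  both ends; `min_group_size` trades curve length against per-point
  stability.
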