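# panelsieve

Stability-selected mutation-count signatures for predicting benefit from
immune checkpoint inhibition (ICI), with a survival-driven cutpoint and a
head-to-head evaluation against tumor mutational burden (TMB).

## The problem

TMB — the somatic mutation count per megabase of sequenced coding region —
is a blunt predictor of immunotherapy benefit: it counts every gene on a
targeted panel, predictive or not. `panelsieve` implements the alternative:
learn *which* panel genes carry predictive signal from a randomized two-arm
trial (ICI vs chemotherapy), score each patient by the number of mutated
signature genes, and stratify at a data-driven score threshold.

The pipeline has four statistical stages, each exposed as an R function and
a CLI subcommand:

1. **Panel selection** (`select_panel`). On the treated arm, repeat
   `n_repetitions` times: draw a stratified 8/2 train/validation split, fit
   a gradient-boosted tree classifier (logistic objective, depth-3 trees,
   exact greedy splits on the binary gene matrix) of a binary benefit label
   (RECIST responder by default), and rank genes by held-out permutation
   importance — the mean drop in validation AUC when a gene's column is
   shuffled. The signature is the set of genes ranked in the top *k* in at
   least a fraction *q* of repetitions (default *q* = 0.8); the running
   top-*k* intersection is traced as the stability diagnostic.
2. **Scoring** (`ici_benefit_score`). A patient's benefit score is the
   count of distinct mutated signature genes; TMB is mutations / 1.1 Mb.
3. **Cutpoint** (`hr_curve`, `select_cutoff`). For each candidate cutoff
   *c*, fit the Cox model λ(t | s ≥ c) = λ₀(t) · exp(β·1[s ≥ c]) on
   treated-arm PFS and record the Wald statistic (β/se)². Structural breaks
   of the Wald-vs-cutoff curve are located by the Chow test
   F = [(RSS_p − RSS₁ − RSS₂)/2] / [(RSS₁+RSS₂)/(n−4)], and the maximum-F
   significant break is the selected threshold (LOESS span-0.8 smoothing of
   the curve is available for plotting and as an alternative search mode).
4. **Evaluation** (`build_report`). Stratified and continuous Cox hazard
   ratios per arm and endpoint, Kaplan–Meier curves with log-rank tests,
   objective response rate tables (responder = CR/PR), responder AUC with a
   bootstrap CI, and Spearman correlations of the score with TMB and
   baseline tumor burden (SLD) — each computed side-by-side for the
   signature and for TMB.

Because trial exports with mutation calls cannot be bundled, the package
ships a synthetic randomized-trial simulator (`simulate_cohort`) with a
planted benefit-gene panel: exponential PFS/OS with a treatment × score
hazard interaction, a logistic responder model with a treatment × score
interaction, administrative censoring, and realistic per-gene mutation
frequencies. Every stage is tested against that generator and against
independent oracles (closed-form OLS, exhaustive pairwise AUC,
`stats::loess`, partial-likelihood consistency).

## Worked example

```r
library(panelsieve)

cohort <- simulate_cohort(simulation_config(
  n_patients = 500, n_genes = 60, n_benefit_genes = 10,
  mutation_freq_range = c(0.15, 0.30),
  response_intercept = -10 * 0.225 * log(4),   # centres the responder logit
  response_score_by_arm_slope = log(4), seed = 313))

sel <- select_panel(cohort, selection_config(
  n_repetitions = 25, top_k = 20, freq_threshold = 0.5,
  stability_window = 10, seed = 42))
sel
#> <panel_selection> 16 genes after 25 repetitions (mode: frequency)
#>   mean validation AUC: 0.85
#>   plateau at repetition: not reached

scores <- ici_benefit_score(cohort, sel$panel)
cut <- select_cutoff(hr_curve(cohort, scores, min_group_size = 12,
                              min_events = 3))
cut
#> <cutpoint_result> selected cutoff: score >= 3
#>   no significant structural break; cutoff taken at raw Wald maximum

report <- build_report(cohort, sel$panel, score_cutoff = cut$cutoff,
                       n_bootstrap = 500, seed = 1)
report
#> <evaluation_report> 24 survival contrasts
#> score_group_pfs_treated: HR 0.564 (95% CI 0.397-0.803), P=0.00146 [n=239, events=163]
#> score_group_pfs_control: HR 1.217 (95% CI 0.914-1.620), P=0.179 [n=261, events=221]
#> tmb_group_pfs_treated: HR 0.867 (95% CI 0.591-1.271), P=0.465 [n=239, events=163]
#> tmb_group_pfs_control: HR 1.196 (95% CI 0.856-1.669), P=0.294 [n=261, events=221]
#>   responder AUC (score): 0.780 (0.728-0.836)
#>   responder AUC (tmb): 0.632 (0.569-0.701)
```

Reading the numbers: 16 of the panel's genes survived stability selection
(all 10 planted genes among them). Patients with ≥ 3 mutated signature
genes have roughly half the progression hazard on immunotherapy
(HR 0.564) but *no* benefit — a trend toward harm — on chemotherapy
(HR 1.217): the signature is treatment-specific, which is exactly what
separates a predictive from a prognostic marker. TMB stratification on the
same cohort separates neither arm, and the signature discriminates
responders better than TMB (AUC 0.78 vs 0.63).

Real data enter through `read_mutations()` (MAF or long-format TSV),
`read_clinical()` (TSV with `sample_id`, `arm`, `pfs_time`, `pfs_event`,
`os_time`, `os_event`, optionally `response`/`sld`/`tmb`) and
`build_dataset()`, optionally restricted to a panel file of gene symbols
(e.g. a 391-gene targeted assay). `restrict_panel()` maps a signature onto
another assay's gene universe.

## Command line

```sh
inst/cli/panelsieve simulate --out-prefix cohort --n 850 --seed 1
inst/cli/panelsieve select   --mutations cohort_mutations.tsv \
    --clinical cohort_clinical.tsv --reps 350 --top-k 150 --seed 1 --out panel.txt
inst/cli/panelsieve cutpoint --mutations ... --clinical ... --panel panel.txt
inst/cli/panelsieve run      --config inst/extdata/demo_config.json
```

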