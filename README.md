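# prsmed

Does the genetic risk for Alzheimer's dementia reach into late-life motor
decline, and through which molecular systems? `prsmed` implements the full
inference chain for that question in older-adult cohort data: it builds a
polygenic risk score (PRS) for Alzheimer's dementia from external GWAS
summary statistics, constructs composite motor phenotypes (a global
parkinsonism score and a global motor score), scans them for PRS
associations with covariate adjustment, screens hundreds of molecular
endophenotypes (brain pathologies, omics module eigengenes, miRNAs,
proteins) in two Bonferroni-controlled stages, quantifies how much of the
PRS effect each endophenotype explains by exact LMG variance decomposition,
learns a tier-constrained Bayesian network over {PRS, endophenotypes, motor
outcome}, and runs GREAT-style enrichment of histone-peak modules.

Because the cohort data this kind of analysis targets are access-controlled,
the package ships a first-class synthetic cohort generator with a *planted*
mediation structure, so every stage — and the whole pipeline — is testable
against known ground truth.

The package is aimed at statistical geneticists and computational
neuroscientists who want a transparent, dependency-light reference
implementation of this analysis chain, or a calibrated sandbox for method
development on genotype → endophenotype → phenotype cascades.

## The model in brief

**PRS.** For SNP set `S(t) = {j : p_j ≤ t}` after allele harmonization and
greedy LD clumping (keep the most significant SNP, drop neighbors with
`r² > 0.1` within 2000 kb),

```
PRS_i = (1/|S|) Σ_{j∈S} β_j · dosage_ij
```

standardized over the cohort. Sample overlap with the GWAS is removed by
inverse-variance subtraction: `β_adj = (w_m β_m − w_o β_o)/(w_m − w_o)`,
`se_adj = (w_m − w_o)^{−1/2}`, with `w = 1/se²` — the exact inverse of an
inverse-variance-weighted meta-analysis.

**Association.** Continuous outcomes are residualized on age, sex,
education and three genotyping PCs, then regressed on the standardized PRS;
binary diagnoses use a logistic model whose covariate coefficients are fit
once and then frozen as an offset term.

**Screen.** Stage 1 keeps endophenotypes associated with a motor outcome at
`p < α/m₁` (Bonferroni over all variables, e.g. `0.05/560 = 8.9×10⁻⁵`);
stage 2 keeps stage-1 hits associated with the PRS at `p < α/m₂` (m₂ =
realized hit count, e.g. `0.05/13 = 0.0038`).

**Mediation.** With LMG relative importance (the average sequential R²
contribution over all predictor orderings, computed exactly by subset
enumeration), the proportion of the PRS effect explained by endophenotype E
is

```
1 − LMG_PRS({PRS, E}) / R²(outcome ~ PRS)
```

clipped to [0, 1]; the joint version enters all candidate mediators at once.

**Network.** Greedy hill-climbing on the linear-Gaussian BIC score with
add/delete/reverse moves, random restarts, tier constraints (PRS is a
source, the motor outcome a sink), bootstrap edge frequencies, and per-edge
annotation (sign, incremental R², Wald p).

## Worked example

```r
library(prsmed)

spec   <- simulation_spec(n_individuals = 1000, n_snps = 1000, seed = 42)
geno   <- simulate_genotypes(spec)
gwas   <- simulate_gwas(geno, spec)
cohort <- simulate_cohort(geno, gwas, spec)

stats <- harmonize(gwas, geno)
stats <- ld_clump(stats, geno, r2_threshold = 0.1, window_kb = 2000)
#> [prscore] clump: 980 -> 298 SNPs (r2 > 0.1 within 2000 kb removed)
prs   <- compute_prs(stats, geno, p_thresholds = c(0.05, 0.5))

scores <- score_motor(cohort$phenotypes)
covs   <- cohort$phenotypes[, c("age", "sex", "educ", "pc1", "pc2", "pc3")]
prs_scan(prs, scores["global_parkinsonism"], covs)
#>   threshold             outcome    n estimate         se            p signed_log10p significant
#> 1      0.05 global_parkinsonism 1000 1.101781 0.05628522 1.823579e-72      71.73908        TRUE
#> 2      0.50 global_parkinsonism 1000 1.096446 0.05638951 1.162441e-71      70.93463        TRUE

ry  <- residualize(scores$global_parkinsonism, covs)
med <- mediate(ry, prs_vector(prs, 0.5),
               cohort$endophenotypes$values[, names(spec$mediation_weights)],
               outcome_id = "global_parkinsonism")
med
#> mediation_result for 'global_parkinsonism' (lmg metric)
#>      endophenotype r2_prs_marginal proportion
#>   pathology_tangle           0.275      0.143
#>  pathology_arterio           0.275      0.111
#>          acetyl_m1           0.275      0.130
#>         express_m1           0.275      0.129
#>            mirna_1           0.275      0.138
#>          protein_1           0.275      0.129
#>   jointly explained: 0.545
true_mediated_fraction(spec)
#> [1] 0.6
```

Reading: the scan row says a 1-SD increase in PRS predicts a 1.10-unit
worse residualized parkinsonism score (p ≈ 10⁻⁷²; the signed −log10 p
carries the direction). Each planted mediator individually explains
11–14% of the PRS effect, and all six jointly explain 54.5% — close to the
generator's true mediated fraction of 0.6 (the gap is sampling noise at
n = 1000 plus GWAS noise in the score weights).

The whole chain, including the bootstrap network and enrichment stages, can
be run from one config:

```r
run_pipeline(pipeline_config(), out_dir = "out", seed = 1)
```

or from a shell via the thin CLI at `inst/scripts/prs-mediate.R`
(`run`, `simulate`, `score`, `motorscore` subcommands); single-stage
operations (`scan`, `screen`, `mediate`, `network`, `enrich`) are one-call
wrappers of the exported functions shown above.

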