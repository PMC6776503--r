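---
title: "Methods: from polygenic risk to motor impairment through molecular endophenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from polygenic risk to motor impairment through molecular endophenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`prsmed` implements an inference chain linking the polygenic risk of
Alzheimer's dementia to late-life motor impairment through molecular
endophenotypes measured in brain tissue. This vignette documents the
statistical model behind each stage, the parameters that matter and their
defaults, the synthetic cohort that the test suite is calibrated on, and
the numerical and design choices a maintainer should know about.

## 1. Composite motor phenotypes

Two composites summarize motor function in aging cohorts.

*Global parkinsonism.* Four clinician-rated signs (parkinsonian gait,
bradykinesia, rigidity, tremor), each on a 0–100 severity scale, are
averaged over whatever subset is present and square-root transformed (the
sign distributions are strongly right-skewed, with a mass at zero).
Parkinsonian gait is additionally carried forward sqrt-transformed on its
own; bradykinesia and rigidity are dichotomized at presence (`score > 0`
— ties are impossible because absence is coded exactly 0), and tremor is
left untransformed. An individual with all four signs missing gets a
missing composite, never an error.

*Global motor score.* Ten performance tests (grip, pinch, pegboard,
tapping, walk time and steps, turn time and steps, leg-stand and toe-stand
times) are z-scaled over the scoring cohort and averaged over available
items, then sign-reversed so that higher means more impaired, consistent
with the parkinsonism composite. Domain scores (strength = 2 tests,
dexterity = 2, gait = 4) are formed the same way; no balance composite is
formed because stand tests are often unattempted in practice. Two
conventions deserve note:

- **Item orientation.** Grip, pinch, pegboard, tapping and the stand times
  count "higher raw = better performance"; walk/turn times and step counts
  count "higher = worse" and are negated *before* z-averaging. The
  composite-level reversal alone would not make the average meaningful, so
  per-item orientation is applied first; this is the conventional reading.
- **Missing items.** The composite is the mean over available items. The
  alternative (complete-case) would discard most of the cohort for a
  single unattempted stand test.

The z-scaling is computed over exactly the table passed in, and the number
of individuals used is recorded as an attribute, so a caller can decide
whether to scale in the full cohort or an analysis subsample.

## 2. PRS construction

Summary statistics (per-SNP effect `beta` on the counted allele `A1`,
standard error, p-value) are first *harmonized* to the genotype panel:
effects are re-oriented when the panel tracks the other allele (beta
negated, alleles swapped), strand-ambiguous SNPs (A/T, C/G) are removed
because their orientation cannot be verified without strand information,
and allele-pair mismatches are dropped. Counts of every disposition are
logged.

*Sample-overlap adjustment.* When the scoring cohort contributed to the
GWAS meta-analysis, its signal is removed by inverse-variance subtraction
(`adjust_overlap`). With precisions `w = 1/se²`,
`beta_adj = (w_m beta_m − w_o beta_o)/(w_m − w_o)` and
`se_adj = (w_m − w_o)^{-1/2}`. This is the canonical decomposition because
fixed-effect meta-analysis is itself inverse-variance weighted: the
operation is exactly invertible, which the test suite exploits as a
round-trip identity at 1e-10. SNPs where the overlap precision is not
smaller than the meta precision are impossible under that model and are
dropped with a warning (configurable to an error).

*LD clumping.* Greedy: sort by p ascending (total order: p, chromosome,
position, id — so the output is invariant to input row order), take the
best remaining SNP as index, and remove all SNPs on the same chromosome
within `window_kb` whose squared dosage correlation with the index exceeds
`r2_threshold`. Defaults `r2_threshold = 0.1`, `window_kb = 2000` follow
standard practice for Alzheimer's PRS construction. LD is estimated in the
scoring cohort itself (squared Pearson correlation of mean-imputed
dosages); zero-variance SNPs yield an undefined correlation which is
treated as 0 (no removal).

*Scoring.* For each inclusion threshold `t`, the raw score is the average
of counted-allele dosages weighted by beta over
`S(t) = {p ≤ t} ∖ exclude ∩ restrict_to`. Division is by `|S|`
(SNP count); a `denominator = "alleles"` flag divides by `2|S|` instead
for the allele-count convention. Missing dosages are mean-imputed per SNP
so `|S|` is constant across individuals. Scores are standardized to mean
0, SD 1 over the scored cohort; a zero-variance score (e.g. all-zero
weights) keeps its raw values and reports missing standardized scores with
a warning rather than failing. Locus exclusion/restriction accepts 1-based
inclusive regions (BED input is converted from 0-based half-open on read),
supporting e.g. ApoE/TOMM40-free scores and ApoE/TOMM40-only scores. The
default threshold series is {5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1.0},
with 0.5 the conventional headline.

## 3. Covariate handling and the two-stage screen

Continuous outcomes are residualized once on age at assessment (years),
sex, education (years) and the first three genotyping principal
components, by OLS with intercept; association tests then regress the
residuals on the raw standardized predictor. This is mildly conservative
relative to a joint fit; the two coincide exactly when the predictor is
orthogonal to the covariates (Frisch–Waugh–Lovell), which the suite
verifies to 1e-8. Rank-deficient covariate designs are an error naming the
collinear columns.

Binary outcomes (clinical diagnoses) use *offset-term logistic
regression*: the covariate model is fit once per outcome, and its linear
predictor enters subsequent single-predictor fits as a fixed offset. This
keeps covariate adjustment identical across the hundreds of predictors
tested against one outcome. With no covariates the procedure reduces
exactly to ordinary logistic regression. Apparent separation (predictor
coefficient diverging) is an error; penalized fits are out of scope.

The endophenotype screen is two-staged, Bonferroni-corrected within each
stage: stage 1 tests every variable against each motor outcome at
`p < α/m₁` (m₁ = number of variables; at the reference scale of 560
variables and α = 0.05 this is 8.9×10⁻⁵ at two significant figures);
stage 2 tests the stage-1 hits against the PRS at `p < α/m₂` with m₂ the
*realized* stage-1 hit count (13 hits give 0.0038). Stage-2 variables are
residualized on the same covariates before testing, mirroring stage 1.
Exact thresholds are used in comparisons; the two-significant-figure
values are display attributes only. P-values are two-sided Wald throughout
and are floored at 1e-300 to keep signed −log10(p) finite.

## 4. Mediation by variance decomposition

The mediation question is operationalized as variance explained, not as a
counterfactual estimand: how much of the outcome variance attributed to
the PRS is absorbed once an endophenotype enters the model. The
attribution uses the LMG relative-importance metric — predictor k's
average sequential increase in R² over all orderings of the predictors —
computed exactly by enumerating predictor subsets with combinatorial
weights from a single covariance matrix (O(2^p) small solves; p ≤ 12
enforced, which covers the intended use of one PRS plus up to eleven
screened mediators). Subset R² uses a pseudoinverse so exactly collinear
predictors (duplicated variables) remain well defined and split their
contribution symmetrically.

The per-endophenotype proportion is
`1 − LMG_PRS({PRS, E}) / R²(outcome ~ PRS)`, the joint proportion the same
with all mediators entered together. Sampling noise can push the ratio
slightly outside [0, 1], so the reported value is clipped and the raw
value kept alongside. When the marginal PRS R² is below 1e-6 the
proportion is undefined (missing) rather than a 0/0 artifact. A simpler
semipartial-R² variant (`1 − (R²_both − R²_E)/R²_PRS`) is available behind
a flag for sensitivity analysis; LMG is the default because it matches the
relative-importance framework this analysis convention is built on.

For a planted chain `g → E → motor` with unit-variance variables, path
algebra gives closed-form correlations (`cor(g,E) = a`, `cor(E,m) ≈ b`,
`cor(g,m) = ab + c`), from which the LMG proportion follows in closed
form; at `a = b = 0.5, c = 0` it equals exactly 0.5. The suite checks
recovery against this value at n = 5000 within ±0.1, and against the
generator's implied mediated fraction end to end.

## 5. Tier-constrained network learning

Structure learning is score-based: greedy hill-climbing over add, delete
and reverse moves on the linear-Gaussian BIC score
(`loglik − (k/2)·log n` per node, parameters = coefficients + intercept +
residual variance), with moves rejected when they form a cycle or violate
the tier constraints (no edge into the PRS source, none out of the motor
sink; endophenotype–endophenotype edges free). Data are continuous and
complete-case (missing values are a hard error instructing filtering), and
n > 5× the node count is required. Scores are computed from the MLE
covariance matrix, so each candidate move costs one small linear solve;
residual variances are floored at 1e-12 to keep near-deterministic
relationships finite. Restarts: the first climb starts from the empty
graph, subsequent ones from random DAGs (edge probability 0.25 under a
random topological order); the best final score wins. Defaults are 10
restarts for one-shot learning and 2 per bootstrap resample (the bootstrap
already averages over data perturbations, so deep restarting per resample
buys little).

Edge confidence comes from learning on bootstrap resamples of the rows
(default 100; fewer than 10 is an error) and keeping edges with selection
frequency ≥ 0.5. Frequencies are directed, so a cycle in the consensus is
possible; any cycle is broken by dropping its lowest-frequency edge, and
the repaired graph is re-checked. Consensus edges are annotated by
regressing each child on its consensus parents: coefficient sign,
incremental R² of the edge given the other parents, and the Wald p-value.
`direct_regulators()` returns the parents of an outcome sorted by
frequency (ties by label, so output is deterministic).

Discretization-based or sampling-based structure learning was rejected:
the variables are continuous and approximately Gaussian after
residualization, and the linear-Gaussian score matches the per-edge linear
regression annotation. The method is validated by an exhaustive-search
oracle on 3 nodes (all 25 DAGs) and by chain-recovery simulations, not by
agreement with any published network topology.

## 6. GREAT-style enrichment

Histone-peak modules are assigned to genes through basal-plus-extension
cis-regulatory domains: a strand-aware basal domain (5 kb upstream, 1 kb
downstream of the TSS by default) extended in each direction to the
nearest neighboring basal domain or 1 Mb, whichever is closer (so
neighboring extensions abut at basal boundaries). A peak maps to every
gene whose domain contains its midpoint (a flag switches to any-overlap).
Two tests are provided, because region-based and gene-based nulls answer
slightly different questions: a gene-based hypergeometric upper tail
(universe = genes hit by any peak, draws = genes hit by the module) and a
region-based binomial upper tail (per-peak success probability = fraction
of all peaks hitting the term). Fold enrichment is observed/expected.
Benjamini–Hochberg q-values are computed across terms within each method;
terms with no genes in the universe are skipped with a warning. No gene
ontology is shipped; gene sets come in as GMT.

## 7. The synthetic cohort

The generator exists so that every stage has a ground truth. What it
emulates:

- **Genotypes.** Haplotypes from a blocked AR(1) latent Gaussian:
  adjacent SNPs within a block have latent correlation `rho` (default
  0.8), blocks and chromosomes reset it to zero. Thresholding at the
  allele-frequency quantile and summing two independent haplotypes gives
  hard-call dosages with blockwise LD — enough structure to make clumping
  windows and thresholds consequential. At allele frequency 1/2 the
  implied dosage correlation has the closed tetrachoric form
  `(asin rho)/(2π) · 4`, which the suite uses as a Monte-Carlo oracle.
  Panel layout: 500 SNPs per chromosome at 5 kb spacing; allele
  frequencies uniform in (0.05, 0.45); 2% of SNPs get strand-ambiguous
  allele pairs so harmonization's filter has work.
- **External GWAS.** A random causal subset (default 50 of 5000 SNPs)
  receives normal effects scaled so the causal SNPs explain
  `h2_liability = 0.3` of liability variance; reported effects add noise
  with `SE = 1/sqrt(gwas_n · 2·maf·(1−maf))` (default `gwas_n` = 50,000,
  the scale of consortium GWAS) and Wald p-values. `gwas_n = Inf` gives
  the noiseless limit used in tests.
- **Cascade.** Liability `g` (standardized true-effect score) drives each
  endophenotype `E_j = a_j g + √(1−a_j²) ε`; the motor outcome is
  `c·g + Σ b_j E_j + covariates + noise`, with residual noise chosen so
  the non-covariate part has unit variance (a spec with structural
  variance above 1 is rejected as an inconsistent budget). Defaults: six
  mediators spread over the endophenotype categories with `a = 0.3,
  b = 0.2` each and direct effect `c = 0.24`, giving a true mediated
  fraction `Σab/(c+Σab) = 0.6` — the magnitude this analysis framework is
  designed to detect — plus 100 pure-noise endophenotypes as screening
  background. Covariate effects default to age 0.3, sex 0.1, education
  −0.1 SD per SD.
- **Raw items.** The ten performance tests are back-generated linearly
  from the outcome with item noise (SD 0.5 on the standardized scale) and
  realistic units and orientations; the four signs are logistic
  transforms with a floor producing genuine zeros, so dichotomization has
  both classes.

All randomness flows from one integer seed through named streams (one per
operation), so adding a downstream stage never perturbs upstream draws,
and equal seeds give byte-identical pipeline outputs.

What it does *not* emulate: realistic human LD maps or recombination
hotspots, imputation uncertainty, population structure beyond synthetic
PCs, the empirical marginal distributions or cross-correlations of real
pathology and omics variables, and selection/attrition in aging cohorts.
A green suite therefore demonstrates correctness of the algorithms and
calibration under the generative model, not robustness to everything real
data can do.

## 8. Problem sizes and reproducibility

The default pipeline configuration simulates 2000 individuals × 5000 SNPs
and completes in about a minute on one CPU; the test suite uses n up to
5000 for mediation recovery, 200 simulations for screen calibration, and
100 datasets/seeds for the network oracle and recovery checks — sizes at
which the Monte-Carlo tolerances quoted above are comfortably resolved.
Two runs with the same configuration and seed produce byte-identical TSV
and VCF outputs; each stage writes a JSON manifest (parameters, seeds,
input checksums) and is skipped on re-runs when its outputs are newer than
its inputs under an unchanged configuration.

## 9. Known limitations

- Mediation is variance-explained, not causal mediation; no confidence
  intervals are attached to the proportions (the bootstrap network carries
  the uncertainty story instead).
- Exact LMG is limited to 12 predictors; sampling approximations for
  larger models are deliberately out of scope.
- The VCF interface covers hard-call biallelic GT records only; dosage
  (imputed) formats reduce to mean imputation of missing hard calls.
- Offset-logistic inference ignores the sampling error of the frozen
  covariate coefficients, as the convention dictates; with strongly
  informative covariates and small n the predictor SE is slightly
  optimistic.
- Module *detection* (co-methylation/co-acetylation/co-expression
  clustering) is out of scope; module assignments are an input, and only
  the eigengene summarization (first PC, unit variance, orientation by
  mean member correlation, deterministic tie-break on the first feature)
  is implemented.
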