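# ykincohort

Kin-cohort association analysis of Y-chromosome (MSY) haplogroups against
cardiovascular phenotypes.

## What problem this solves, and for whom

The male-specific region of the Y chromosome is inherited father-to-son
without recombination, so every man carries one of a phylogeny of
patrilineal lineages (haplogroups). Claims that these lineages affect
coronary artery disease (CAD), blood pressure or mortality are hard to
test credibly, because Y lineages are extremely geographically structured
and because adjusting for heritable risk factors can *create* spurious
associations (collider bias). This package is for genetic
epidemiologists who want to run such analyses properly in large cohorts
with family-history questionnaires:

- haplogroup assignment from haploid Y-SNP genotypes on a user-supplied
  phylogeny (Newick + SNP map), with panel QC and composite/paragroup
  indicator construction;
- cardiovascular phenotype construction from measurements, medication
  flags and ICD/OPCS-coded records (iterative Tukey outlier removal,
  +15/+10 mm Hg and /0.7, /0.8 medication corrections, code-list CAD
  classification);
- per-haplogroup association models `Y = Xβ + Zγ + ε` (linear), logistic
  and Cox, under a population-structure-robust covariate set
  (coordinates and deprivation at assessment and birth, genetic PCs,
  batch — and no heritable covariates);
- a PCA-based effective number of independent tests for multiplicity
  (the smallest m components explaining 95% of indicator variance;
  threshold α/m);
- kin-cohort validation: father disease as replication (fathers share
  the lineage), mother disease as negative control (mothers cannot),
  with an explicit verdict rule;
- genetic father–son pair inference (kinship > 0.2 plus a ±6-month
  date-of-birth interval) and a bootstrap estimate of how accurately
  "father heart disease" proxies father CAD;
- a seeded synthetic cohort generator that emulates all of the above —
  geographically structured lineage frequencies, geography-correlated
  confounders, effects shared father–son, mothers independent of the
  lineage, coded health records, Gompertz survival — so the entire
  pipeline is testable without access-controlled cohort data.

## Worked example

Simulate a cohort of 20,000 men in which the IJK lineage raises mean
arterial pressure by 0.93 mm Hg, call haplogroups from the emitted
genotypes, build phenotypes, and run the blood-pressure battery:

```r
library(ykincohort)

sim <- simulate_cohort(sim_config(
  n_subjects = 20000, seed = 1,
  effect_map = list(list(haplogroup = "IJK-S137", outcome = "map",
                         effect = 0.93))))
panel  <- qc_snps(sim$panel)
asn    <- assign_haplogroups(sim$tree, panel)
ind    <- build_indicator_matrix(asn, sim$tree, ykc_fixture_groups())
cohort <- build_cohort_phenotypes(sim)
res    <- run_association(cohort, ind, outcome = "map", family = "linear")
attr(res, "n_eff"); attr(res, "threshold")
head(res[order(res$p_raw), c("haplogroup","gamma","se","ci_lo","ci_hi",
                             "p_raw","p_adj","n")], 5)
```

Output from this exact run:

```
qc_snps: 26 in, 0 removed (call rate < 0.95), 0 removed (monomorphic), 26 retained
filter_groups: retained 22 of 25 groups
n_eff: 17  threshold: 0.0029
 haplogroup  gamma    se   ci_lo  ci_hi  p_raw p_adj     n
   R1a-M420  0.538 0.258  0.0324 1.0435 0.0370 0.629 20000
     Q-M242 -1.441 0.777 -2.9637 0.0808 0.0635 1.000 20000
   IJK-S137  0.429 0.392 -0.3390 1.1961 0.2738 1.000 20000
     I-M170 -0.399 0.371 -1.1265 0.3277 0.2817 1.000 20000
    J2-M172  0.355 0.334 -0.2998 1.0103 0.2878 1.000 20000
```

Reading it: 22 of 25 groups have at least 100 carriers; their indicator
correlation matrix collapses to 17 independent components, so the
Bonferroni-style threshold is 0.05/17 ≈ 0.0029 and each raw P is
multiplied by 17. Nothing clears the threshold in this single cohort —
with ~400 carriers the IJK-S137 standard error is 0.39 mm Hg, so its CI
(−0.34, 1.20) comfortably covers the simulated +0.93 but a lone cohort of
this size is underpowered for so small an effect; the recovery *across
200 replicates* (mean estimate ≈ 0.93, |bias| < 0.1) is what the
acceptance checks assert. The two top rows are chance rankings of null
lineages, which is exactly what the multiplicity correction is for.

The kin-cohort side (`run_kin_battery`) fits the same model on the
subject, father and mother phenotypes per haplogroup and returns a
verdict per lineage (`validated` / `not_supported` / `inconclusive`);
`infer_father_son_pairs` + `proxy_accuracy` reproduce the
father-son-pair accuracy analysis (e.g. with 26 of 37 reported-HD
fathers meeting CAD criteria among 301 pairs, the estimate is 70.3% with
a bootstrap 95% CI of roughly 55–85%).

A full pipeline run with all stages and a reproducible manifest:

```r
run_pipeline(simulate = TRUE, seed = 1, outdir = "ykc_results")
# or: Rscript inst/cli/run_pipeline.R --simulate --seed 1 --outdir ykc_results
```

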