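---
title: "Kin-cohort analysis of Y-chromosome haplogroups: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-cohort analysis of Y-chromosome haplogroups: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ykincohort)
```

## The scientific problem

The male-specific region of the Y chromosome (MSY) does not recombine and
is transmitted essentially unchanged from father to son. Every man
therefore carries one of a tree of patrilineal lineages — haplogroups —
defined by derived SNP alleles on the branches of the Y phylogeny. Whether
these lineages influence cardiovascular risk has been debated for two
decades, with conflicting small-cohort reports.

Testing the question properly is hard for two reasons that this package is
built around:

1. **Population structure.** Y lineages are among the most geographically
   structured parts of the human genome. Any phenotype that also varies
   with geography or socioeconomic deprivation (blood pressure does) will
   confound a naive haplogroup association. The package's *robust*
   covariate set therefore adjusts for coordinates at assessment and
   birth, area deprivation at both, a large number of genetic principal
   components, and genotyping batch — and deliberately **not** for
   heritable risk factors.
2. **Collider bias.** A heritable risk factor used as a covariate can
   manufacture an association where none exists. If a lineage Z influences
   a risk factor R, and an unmeasured cause U influences both R and the
   disease, then conditioning on R opens the non-causal path
   Z → R ← U → disease. The package demonstrates this with a dedicated
   simulation scenario (below).

The kin-cohort idea supplies an internal validation that no autosomal
study design has: fathers share the son's Y lineage, mothers cannot carry
it. A real lineage effect on disease must therefore *replicate* in
subject-reported father disease and must be *absent* from mother disease —
the mother is a negative-control outcome whose only route to significance
is bias.

## The models

For each haplogroup g (carrier indicator Z), the association model is

- linear: `Y = Xβ + Zγ + ε` for blood pressure and lipid traits,
- logistic: `logit P(Y=1) = Xβ + Zγ` for CAD and hypertension,
- Cox: `h(t) = h0(t) exp(Xβ + Zγ)` on the age timescale for all-cause
  mortality, with entry at assessment age and a fixed cohort censoring
  date (2021-11-01).

γ is reported with a Wald standard error, a 95% CI of γ ± 1.96·se, and a
two-sided normal P value. One model is fitted per haplogroup; each
haplogroup is contrasted against all other lineages pooled (non-carriers,
including "unassigned" men, form the reference group). Estimation is
delegated to `stats::glm.fit()` and `survival::coxph()`; the package's
contract is the estimate and its SE, not the optimiser.

### Covariate sets

- `robust` — (parent) age, age², north/east coordinates at assessment and
  birth, area deprivation at assessment and birth, all genetic PC columns
  present, genotyping batch. Age terms are dropped for Cox models, which
  already run on the age scale.
- `minimal` — age, PCs, batch: a sensitivity set with no explicit
  geography.
- `eales` — age, BMI, the first 5 PCs, batch, plus heritable/lifestyle
  covariates present in the cohort (hypertension, a generic
  `risk_factor`, family history). It reproduces the *style* of earlier
  analyses whose vulnerabilities the robust set is designed to avoid; it
  is included to demonstrate those vulnerabilities, not for inference.

### Multiplicity

Haplogroup indicators are strongly correlated through the phylogeny
(a composite or ancestor column largely duplicates its members), so raw
Bonferroni over-corrects. `effective_tests()` eigendecomposes the Pearson
correlation matrix of the indicator columns on the complete-case analysis
sample and returns the smallest m whose top-m eigenvalues reach 95% of the
trace. P values are multiplied by this count (and by an analogous count
over phenotypes within a category) and capped at 1; the significance
threshold is α divided by the same product. Because complete cases differ
per outcome, the effective count can legitimately differ between, say, the
CAD battery and the blood-pressure battery. A small numerical tolerance
(1e-9) is applied at the cumulative-variance boundary so that an exact
fraction (identity correlation at m/k = 0.95) is not lost to eigenvalue
round-off.

### Kin validation verdicts

`kin_verdict()` is a pure decision rule. A subject association with raw
P < 0.10 is *suggestive*; it is **validated** if the father estimate has
the same sign *and* the mother 95% CI spans zero; **not_supported** if
either kin check fails; **inconclusive** otherwise. "Directionally
consistent" is operationalised as sign agreement, and the maternal null as
CI coverage of zero — deliberate, stricter operationalisations of
criteria that are often applied visually to forest plots. Kin estimates
are treated as independent when combining verdicts; shared-environment
correlation between family members' phenotypes would call for SE
inflation, which is intentionally not performed (the shared-environment
knob in the simulator exists precisely so users can see how much this
matters).

## Haplogroup calling

`assign_haplogroups()` scores every node of the phylogeny by the number of
derived calls on its root-to-node path and assigns each man the
best-supported node. Ties are resolved by parsimony:

1. fewer observed-*ancestral* calls on the candidate path — a candidate
   contradicted by its own defining SNPs loses;
2. fewer *missing* calls on the path — the caller never descends into a
   branch for which no evidence was observed;
3. fewer derived calls off the path;
4. greater depth;
5. lexicographic label.

Rules 1–2 are what make the caller exact on clean data: a man whose
lineage stops at an internal node ties on the derived-path score with
every descendant reachable without further derived calls, and only the
consistency rules separate them. Rule 4 then settles genuine conflicts in
which two branches carry equal observed evidence, favouring the more
derived claim. Men with zero derived calls map to the root; men with no
observed calls at all are `"unassigned"` and are retained in the cohort
with all-zero indicators (they contribute to every model's reference
group). Heterozygous diploid genotypes on the Y are treated as missing:
the male Y is haploid, so a het call is an artifact.

SNP QC removes markers with call rate below 0.95 and then markers
monomorphic among the survivors' observed calls, in that fixed order —
a SNP whose only variable calls are missing counts as monomorphic.

## Phenotype construction

- **Outlier removal** uses an iterative modified Tukey rule: values
  strictly beyond 3 IQR outside the quartiles are removed, quartiles are
  recomputed on the survivors, and the rule is repeated to a fixed point.
  Quartiles use the default linear-interpolation convention (type 7),
  which the underlying rule does not specify.
- **Blood pressure**: technical replicates are averaged first; treated
  individuals then get +15/+10 mm Hg (SBP/DBP), the standard correction
  for antihypertensive use. Hypertension is classified on *measured*
  values (medication ≥, SBP ≥ 140, or DBP ≥ 90): treated individuals are
  cases regardless, so the adjusted-versus-measured question only arises
  for the untreated, whose values are identical either way.
- **MAP**: the default is the standard formula DBP + (SBP − DBP)/3. A
  `"printed"` mode computing DBP + (DBP + SBP)/3 is provided for
  comparison with sources that print that expression; it exceeds SBP for
  physiological inputs and is flagged as implausible whenever used.
- **Lipids**: LDL/0.7 and total cholesterol/0.8 for treated individuals,
  log-transformed triglycerides (non-positive values become missing), and
  the Tukey filter per trait.
- **CAD** is classified from coded health records by prefix matching
  against configurable code lists (MI by ICD-9/ICD-10, PCI and CABG by
  OPCS, CAD death codes, angina and anti-anginal medications as
  exclusions). Ranges such as I21–I23 are expanded at load time and dots
  are ignored, so I21 covers every I21.x subcode. The partition
  case/control/excluded is exhaustive and exclusive.
- **Parental phenotypes** come from the subject questionnaire: "heart
  disease" → parent CAD-proxy case, "high blood pressure" → parent
  hypertension case, any other answered selection → control, "prefer not
  to answer" → missing. Parent survival uses reported age and vital
  status at the subject's assessment on the age scale with delayed entry
  at 40; reported deaths before 40 are excluded (accident and injury
  dominate there), which is also why entry is placed at 40.

## Father–son pair inference and proxy accuracy

Pairs of men with genetic kinship strictly above 0.2 (the
parent–offspring kinship coefficient expectation is 0.25) are oriented by
dates of birth: subtracting the reported father age from the subject's
assessment date gives an implied father date of birth, and a closed
interval of ±183 days (six months) around it must contain exactly one
member's DOB — that member is the father; pairs matching in both
directions are ambiguous and dropped. The half-width and the
year-to-days conversion (round(age × 365.25)) are the package's own
calendar conventions.

`proxy_accuracy()` estimates how often a son-reported "father heart
disease" corresponds to a father meeting CAD criteria: the proportion of
CAD cases among reported-HD fathers, with a percentile bootstrap CI over
resamples of the full pair list. Because the proportion depends only on
the category counts (HD∩CAD, HD∖CAD, rest), the resampling is drawn as
multinomial counts, which is exactly equivalent to resampling pairs and
much faster at 100 000 iterations.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, so the whole pipeline can be exercised without access-controlled
data:

- Birth/assessment coordinates on a ~1000 × 700 km grid; deprivation and
  the outcome confounding follow the (scaled) north axis.
- Lineage assignment from base frequencies (defaults roughly matching a
  British cohort: R1b ≈ 47%, I1 ≈ 13%, a tail of rarer lineages,
  including men stopping at internal nodes) tilted per location by
  per-node log-frequency gradients, sampled by the Gumbel-max trick so a
  seed fully determines the draw.
- Y genotypes emitted along the tree path with configurable per-call
  error and missingness; the packaged fixture tree has 22 nodes, 26
  branch SNPs, two composites and one paragroup.
- Ten genetic-PC surrogates by default, the first two loaded 0.7 on the
  north/east axes. The simulated structure is two-dimensional, so a
  handful of noisy surrogates spans it; analyses of real array data would
  use many more (the robust covariate set simply consumes whatever PC
  columns are present).
- Blood pressure as latent linear models plus noise; antihypertensive
  treatment is assigned independently of BP and shifts measured values
  down by exactly 15/10 mm Hg. This makes the standard +15/+10 correction
  exactly unbiasing *within the simulation* — a deliberate idealisation:
  in real data treatment is indicated by high BP and has heterogeneous
  effects, so passing recovery tests here demonstrates correctness of the
  machinery, not of the clinical correction itself.
- A lineage effect on "map" shifts SBP and DBP equally, so MAP moves by
  the stated amount under either MAP formula's difference structure.
- CAD is produced by *emitting ICD/OPCS-coded records* (plus angina and
  medication exclusions), so the classification algorithm itself is on
  the test path, not bypassed by a convenience flag.
- Survival is Gompertz (shape 0.09, rate 5e-5: median age at death near
  80) with proportional-hazards lineage and geography effects folded into
  the rate; parents' deaths are drawn conditional on surviving to the age
  at the subject's birth. A Cox fit is agnostic to the baseline, so any
  smooth parametric baseline would do; Gompertz gives realistic parental
  age-at-death distributions.
- Fathers share the son's lineage and therefore its binary-outcome
  effects (same log-odds); mothers are generated with no dependence on
  the lineage whatsoever; an optional shared-household effect correlates
  family members' outcomes without touching the lineage.
- The collider scenario rewires generation to Z → R ← U → CAD with *no*
  causal path from lineage to CAD: the lineage raises the risk factor,
  an unmeasured cause raises both the risk factor and CAD. Conditioning
  on R (the `eales` set) then induces a systematically negative lineage
  coefficient, while the robust set — which never adjusts heritable
  covariates — stays null. Note the marginal lineage–CAD association is
  null by construction here; a scenario in which the risk factor also
  causes CAD would give the lineage a real mediated effect that an
  unadjusted model *should* detect, which is why the demonstration uses
  this DAG.

What the generator does **not** emulate: linkage structure beyond the
tree (the MSY does not recombine, so none is needed), recurrent or back
mutation, mosaic loss of Y, real UK geography or area codes, indication
bias in treatment, and autosomal genotypes beyond the PC surrogates.
Passing tests on this cohort therefore shows the estimators and decision
rules are correct under the assumed structure; it cannot certify the
clinical adjustments themselves.

## Problem sizes and numerical choices

The packaged test and acceptance workloads use sizes chosen to make the
Monte-Carlo assertions sharp at desk scale: 1 000 noise-free individuals
for the caller round trip; 200 replicates of n = 20 000 for recovery of a
+0.93 mm Hg MAP effect (the Monte-Carlo SE of the mean estimate is
≈ 0.03 mm Hg, so a 0.1 mm Hg bias bound is a meaningful check); 500
replicates of n = 2 000 for the maternal negative-control calibration
(≈ 3 400 tests); 500 replicates of n = 5 000 for the collider contrast;
10 000–100 000 bootstrap iterations for the proxy-accuracy CI.
Property tests that need detectable confounding (e.g. the minimal-set
inflation check) construct deliberately strong confounding scenarios via
the generator's `confounding` and `geo_gradient` arguments rather than
relying on the milder defaults.

Degenerate inputs are handled explicitly: fewer than four non-missing
values skip outlier filtering with a warning; a carrier-free haplogroup,
a separated logistic fit, or a failed Cox fit returns a flagged result
with `NA` estimates (excluded from multiplicity accounting) rather than
disappearing silently; zero-variance indicator columns are dropped with a
warning before the eigendecomposition; an empty group filter result is
permitted and logged.

## Known limitations

- The verdict rule treats kin estimates as independent; no SE inflation
  for shared environment is applied.
- The mother-null check is CI coverage of zero, which is conservative
  when mother samples are small.
- Proxy-accuracy inference conditions on the inferred pair list; pair
  misidentification is not propagated.
- The fixture phylogeny is a ~20-node caricature of the real tree; full
  ISOGG-scale trees are supported by the data structures but not shipped.
- `prevalence_by_area()` excludes individuals whose area fails the
  minimum-n rule at every supplied level (with a log message) rather than
  reporting them in an undersized area.
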