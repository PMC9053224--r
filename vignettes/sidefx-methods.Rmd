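---
title: "Models and methods behind sidefx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sidefx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sidefx` studies the aetiology of self-reported antidepressant side
effects: given per-medication binary endorsements of a 23-item side-effect
checklist, it quantifies co-occurrence across medications, separates
general from drug-class-specific liability, and tests whether polygenic
risk for related traits predicts specific side effects. This vignette
explains the models, the tunable parameters, the synthetic world used for
testing, and the numerical choices — including the places where the design
was genuinely open and what we chose.

## 1. Data model

A cohort row carries `sex`, `age`, ten exposure indicators
(`taken_<drug>`) and 250 endorsement columns (`se_<drug>_<effect>`) with
tri-state coding: `NA` = medication never taken, `0` = taken without the
side effect, `1` = taken with it. This mirrors the questionnaire logic:
only people who took a medication can report its side effects, so
missingness is *structural*, driven by exposure. Two invariants are
enforced at every read: endorsement is `NA` iff exposure is 0, and a
"no side effects" report excludes checklist endorsements for that drug.
Participants missing sex or age are dropped with a logged count (how the
source study handled them is undocumented; dropping keeps the analysis
complete-case and auditable).

Drug classes: SSRIs (sertraline, escitalopram, fluoxetine, citalopram,
paroxetine), SNRIs (venlafaxine, desvenlafaxine, duloxetine), and
other (mirtazapine, amitriptyline).

## 2. Descriptive statistics

Prevalence cells use the Wilson score interval. The source material does
not name its CI method; Wilson is the standard choice for prevalence
plots because it is well-behaved at small counts and never leaves
[0, 1]. The unit tests pin it to a brute-force inversion of the score
test at 10⁻⁶ grid resolution.

Sex differences use the pooled-variance two-sample Z proportion test
*without* continuity correction: recomputing the published demographic
table from its printed counts reproduces all printed p-values to two
significant figures only under this variant, which settles the
convention empirically. Age comparisons default to the Student
pooled-variance t test (Welch is available); at these group sizes the
two are indistinguishable, and the printed values are reproduced within
the rounding of the printed means.

## 3. Tetrachoric co-occurrence and clustering

For two binary endorsements the tetrachoric correlation is the `ρ` of a
latent bivariate normal dichotomized at thresholds matching the margins.
We use the two-step estimator — thresholds from marginal quantiles, then
`ρ` by maximizing the 2×2 multinomial likelihood — rather than joint
trivariate ML: it matches common psychometric practice and is far more
stable over the ~26,000 pairs of a full 230-column matrix. Zero cells
receive a 0.5 continuity correction (a standard remedy the source does
not specify); a table with an empty *raw* margin carries no correlation
information and is flagged undefined. The bivariate normal CDF is
evaluated by 64-node Gauss–Legendre integration over the correlation
parameter (checked against `mvtnorm` at ~1e-15 in the tests).

Pairs are evaluated on pairwise-complete observations, i.e. participants
exposed to both medications; pairs with fewer than `min_pair_n = 30`
such participants are flagged. The distance transform is `d = 1 − ρ`
(the simpler of the common choices; the alternative
`sqrt(2(1 − ρ))` is a one-line change and the choice is recorded in
output metadata). Undefined distances are imputed to the median defined
distance with a logged count. Clustering uses the Ward minimum-variance
criterion via the Lance–Williams recurrence on squared dissimilarities
(the same convention as `hclust(method = "ward.D2")`), with ties broken
deterministically by lowest label index. No positive-semidefinite repair
is applied before clustering because dissimilarities are all the
algorithm needs.

## 4. Bifactor liability-threshold models

Per side effect, the ten per-medication endorsements are manifests of a
liability model: manifest `j` is endorsed iff
`λg_j F + λc_j C_class(j) + e_j > τ_j`, with `F`, `C_SSRI`, `C_SNRI`
orthogonal standard normal and `Var(e_j)` fixed by the unit-total-
variance constraint (the standard identification for binary manifests).
Four model classes are fit — full, SSRI-only, SNRI-only, common-only —
and reductions are judged by AIC and the likelihood-ratio test with
degrees of freedom equal to the number of removed loadings (no boundary
correction: loadings, unlike variances, are two-sided).

The likelihood marginalizes the factors by Gauss–Hermite quadrature.
Conditional on `F`, the SSRI and SNRI blocks are independent, so the
three-dimensional integral factorizes into nested one-dimensional sums,
costing `O(nodes²)` rather than `O(nodes³)`. Participants are collapsed
to unique response patterns, and analytic gradients make each fit a few
hundred milliseconds even at n = 2,000. Internally the optimizer works
on the unconstrained slope/intercept (item-response) parameterization
`a = λ/σ`, `d = τ/σ`, which removes the residual-variance boundary
entirely; estimates are reported on the standardized loading scale.
Participants exposed to a single medication still contribute (their
single-manifest likelihood informs the thresholds), which is the
"full information" treatment of exposure-driven missingness.

Numerical facts worth knowing:

* **Quadrature accuracy.** 21 nodes per dimension (the default) is
  converged to ~1e-9 for loadings up to 0.7 but only to ~1e-3 at 0.8;
  42 nodes restores 1e-6 there. The tests assert exactly this profile,
  and the oracle comparison against adaptive integration is run at 31
  nodes where convergence is ~1e-12. Gauss–Legendre alternatives were
  measured and are substantially worse.
* **Weak identification under near-zero correlations.** When the data
  carry no factor signal, individual loadings are poorly identified: the
  ML can trade one large loading against many tiny ones while implying
  the same near-zero correlations, and genuinely does (we observed
  λ̂ ≈ 0.98 with a +10 log-likelihood gain over independence on null
  data at n = 1,500). A tiny L2 pull (1e-4) on the slopes selects the
  minimum-norm point of such flat ridges without affecting identified
  parameters; reported log-likelihoods are unpenalized, and recovery
  tests assert the identified quantities (implied correlations and
  thresholds) rather than raw loadings.
* **Multi-start.** Five jittered starts by default under a fixed seed;
  ties broken by best log-likelihood then lowest start index.
  Slightly negative LRT statistics within 1e-3 (optimizer noise) are
  clamped to zero with a log note.

## 5. Polygenic scoring

The clumping-and-thresholding arm is implemented in full: QC removes
variants with imputation r² strictly below 0.6 and strand-ambiguous
(A/T, C/G) pairs; effect alleles are harmonized to the panel's alt
dosage (flip = negate); greedy clumping sorts by ascending p (ties by
position), takes each best remaining variant as an index, and removes
remaining variants within 10,000 kb with squared dosage correlation
above 0.1, computed in the target panel itself (the source used the
genotyped cohort for LD; reference panels are out of scope). Scores are
`Σ β_v · dosage_v` at the eight standard thresholds with strict "<"
(as printed); pre-computed shrinkage weights can be supplied as a
summary-statistics-shaped file with p = 0, bypassing thresholding.
Scores are standardized by default (the source's odds ratios are
consistent with per-SD scaling) and the flag is recorded. Principal
components come from the column-standardized dosage matrix with a
deterministic sign convention. Bayesian shrinkage weighting itself
(the source's primary method) is explicitly out of scope.

## 6. Association and variance explained

Logistic regressions adjust for sex, age (linear, untransformed) and 20
PCs on complete cases; the null model drops only the PRS term, so
Nagelkerke's R² isolates the PRS contribution. Wald intervals are used,
matching how PRS odds ratios are conventionally reported. Separation
and non-convergence yield flagged `NA` rows, never silent drops. The
pooled outcome collapses to participant level: endorsed on ≥1 medication
taken vs exposed-never-endorsed (the source's pooling is not
operationally defined; per-medication stacking would need cluster-robust
errors and is intentionally not the default). Bonferroni families:
0.05/25 (one PRS across side effects), 0.05/10 (per-drug tests),
0.05/80 (eight thresholds × ten drugs).

## 7. The synthetic world

The generator's defaults state one cohort and do not move: 20,941
participants, 75.6% female, age 43 (sd 15.3); exposure probabilities
declining from 0.55 (sertraline) to 0.12 (paroxetine); endorsement
prevalences per side effect matching the published sex-pooled margins
(0.40 for reduced sexual desire down to 0.015 for rash); general
loadings 0.75 everywhere; class loadings 0.35 on the class-specific
effects (SNRI: sweating, insomnia, suicidality, dizziness,
constipation; SSRI: nausea, vomiting, drowsiness, dizziness,
constipation); liability-scale genetic paths γ ≤ 0.15 linking BMI to
weight gain, insomnia and headache scores to their side effects, and a
depression score to suicidality/anxiety; small sex shifts (e.g. +0.3
female on nausea, −0.12 on reduced sexual desire).

Three structural choices deserve explanation:

* **Partially shared general factors.** Each side effect has its own
  general factor `F_s = √w·F_common + √(1−w)·u_s` with `w = 0.47`, and
  its own class factors. Endorsements of the same side effect then
  correlate at `λg² ≈ 0.57` across medications while different side
  effects share only `w·λg² ≈ 0.27` — the published within/across
  ordering. A single global factor would make all columns equally
  correlated and erase the clustering signal the analyses look for.
* **Genotypes.** Haplotypes arise from compound-symmetric latent
  Gaussians per block, dichotomized at the allele-frequency threshold;
  the latent correlation is calibrated by tetrachoric inversion so the
  realized *dosage* correlation equals `block_rho`. Blocks share one
  MAF each (uniform over `maf_range`) because a common within-block
  dosage correlation is otherwise unattainable. Imputation quality is
  drawn with 10% of mass below 0.6 so QC filters always have work.
* **GWAS realism.** True effects hit a random 10% of variants and are
  rescaled so the genetic value explains `h2_trait = 0.01` of variance
  in the panel. At the default discovery size (100,000) this puts
  causal-variant chi-squares near 30 — comparable to real GWAS loci —
  so the eight-threshold ladder selects meaningfully different variant
  sets instead of saturating. Marginal effects are computed against the
  panel (so LD partners of causal variants carry signal) with
  `se = 1/√(2·maf·(1−maf)·n)` noise and Wald p-values.

What a green test does **not** establish: the generator has no
population structure beyond the block model, no relatedness, no
attrition, no dependence of medication choice on liability (a
confounding knob exists, default off, because the real-world magnitude
is unknown), and age affects exposure only. Agreement on this world
means the *machinery* is correct, not that the published effect sizes
are recovered — those require the restricted cohort.

## 8. Calibration evidence

The acceptance suite demonstrates, per run: tetrachoric estimates equal
a 1e-4-resolution grid-search oracle and recover true ρ with mean
absolute error < 0.03 at n = 50,000 over a ρ × thresholds grid; Ward
merges equal a brute-force minimum-variance agglomerator and cluster a
general-factor cohort by side effect with purity > 0.8; the bifactor
likelihood matches adaptive integration to 1e-8, recovers loadings with
mean absolute error < 0.1 at n = 2,000 over a 3×3 loading grid, and its
LRT rejects a true common-only null at 3–8% (500 replicates); clumping
equals an independent brute-force implementation on 100 random
fixtures; the PRS logistic fit covers the pseudo-true slope (an
M-estimation quadrature oracle — probit-generated data have no exact
logistic "true OR") in ≥ 90% of 100 cohorts with 3–8% type-I error
under γ = 0; and Nagelkerke's formula evaluates exactly (0.2265 on the
worked inputs). The packaged demo reruns byte-for-byte under its fixed
seed.

## 9. Known limitations

Tetrachoric estimation near |ρ| → 1 relies on a continuity-corrected
boundary search and is reported at the optimizer's resolution; the SEM
stage fits ten manifests per side effect and does not scale to
arbitrary item counts without revisiting the quadrature budget;
exposure-driven missingness is assumed ignorable given exposure
(missing-at-random), which the single-drug sensitivity subset probes
but cannot prove; and the pipeline emits tables, not figures — the
published clustergram and forest plots are presentation-layer work that
the exported matrices support directly.
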