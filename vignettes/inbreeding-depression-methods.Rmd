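---
title: "Pedigree and genomic inbreeding, and how ibdep validates its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and genomic inbreeding, and how ibdep validates its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibdep)
```

## The problem

Inbreeding depression — the decline of fitness-related traits with the
inbreeding coefficient *F* — is classically estimated from pedigrees. A
pedigree gives the *expected* fraction of the genome identical by descent
(IBD), but field pedigrees are incomplete (unassigned fathers, unobserved
grandmothers), which biases F&#95;ped toward zero, and even a perfect pedigree
ignores the variation of *realized* IBD around its expectation created by
Mendelian segregation and recombination. Dense SNP panels offer genomic
alternatives, and in species with extended maternal care the mother's
inbreeding can depress offspring traits in its own right. `ibdep`
implements the full analysis — estimators, QC, identity disequilibrium,
and mixed-model regressions of traits and fitness on individual *and*
maternal F — together with a simulator that knows the truth, so each claim
the analysis makes can be checked against known realized autozygosity.

## The four estimators

* **F_ped** — kinship of the parents, computed by the tabular method on the
  topologically sorted pedigree (`kinship_matrix()`, `f_ped()`). Unknown
  parents are treated as unrelated founders, reproducing the downward bias
  under study. Ancestry completeness is classified into nested tiers
  (`classify_ancestry()`): both parents known; both parents plus at least
  one maternal grandparent; all four grandparents.
* **F_hom** — the fraction of successfully genotyped loci that are
  homozygous. Scale depends on the panel's allele frequencies.
* **F_GRM** — the allele-frequency-weighted single-SNP estimator averaged
  over loci, `[x^2 - (1+2p)x + 2p^2] / [2p(1-p)]`. It estimates the
  correlation between uniting gametes, weights minor-allele homozygotes
  more, and can be negative.
* **F_ROH** — summed length of runs of homozygosity divided by the assayed
  genome length. ROH are called by a scanning-window algorithm
  (`detect_roh()`) with the conventional chip parameters: 5-SNP windows
  (no heterozygote, at most 2 missing calls), segments of at least 15 SNPs
  and 5 Mb, split at gaps over 1 Mb, at most 275 kb per SNP. The length of
  a segment descending from a single ancestor *g* generations back is
  exponential with mean 1/(2g) Morgans, i.e. 100/(2g) Mb at 1 cM per Mb
  (`expected_roh_length_mb()`), so a 5 Mb threshold targets loops within
  roughly 10 generations. The caller expects MAF-filtered (>= 0.05),
  LD-pruned input so that long homozygous stretches reflect autozygosity
  rather than chance; `ld_prune_vif()` provides sliding-window variance
  inflation factor pruning (VIF = 1/(1-R^2) <= 10, approximately r^2 <= 0.9).

Genotype QC (`qc_filter()`) mirrors chip practice: individuals with call
rate <= 95% first, then loci with MAF < 0.01, call rate < 99%, or exact
Hardy–Weinberg *P* < 1e-5. The HWE test (`hwe_exact_test()`) is the exact
conditional two-sided test (probability-ordering rule, no mid-p), which
stays calibrated at the extreme threshold where a chi-square would not.

Identity disequilibrium (`g2_estimate()`) measures whether heterozygosity
covaries across loci within individuals — the footprint of variance in
inbreeding that makes heterozygosity-fitness correlations interpretable.
We compute g2 as the ratio of within- to between-individual mean two-locus
heterozygosity minus one, in ratio-of-sums form so that missing calls drop
out of numerator and denominator pairwise and the estimator is O(nL);
uncertainty comes from bootstrapping individuals and significance from
permuting each locus column independently (upper tail).

## The simulator and what it emulates

`sim_config()` / `simulate_pedigree()` / `gene_drop()` build a synthetic
study system resembling a small, polygynous, overlapping-generation
ungulate population:

* ~10 cohorts; dams drawn from living adult females; sires drawn with
  lognormal quality weights calibrated so the top 20% of males father ~80%
  of offspring; with probability `close_mating_rate` (default 0.08, chosen
  so that a few percent of matings are between close kin, giving the
  observed scatter of F&#95;ped values up to 0.25+) the mate is drawn among
  the dam's relatives with kinship >= 0.125. With the rate at 0 close kin
  are avoided, which gives clean null populations.
* Gene dropping: founders draw two distinct haplotypes from a finite pool;
  meioses place crossovers as a Poisson process on the cM map (Haldane, no
  interference — consistent with the exponential ROH-length expectation);
  founder-allele labels are tracked alongside the alleles, so realized IBD
  is measured exactly as the fraction of map length where the two labels
  coincide. This is the ground truth all estimators are judged against.
* LD: pool haplotypes are mosaics of 3 ancestral templates (switch rate
  0.4/cM, per-locus mutation 0.002). These values were calibrated once
  against the target of mean adjacent-marker r^2 ~ 0.3 at chip density
  while keeping template-sharing from masquerading as autozygosity
  (measured: r^2 = 0.29 and ~0 spurious ROH segments among 200 unrelated
  founders). More templates or mutation weaken LD; the generator does not
  reproduce a full coalescent LD decay, only its short-range behaviour.
* Genome: the default map is 26 autosomes totalling 400 cM carrying 6000
  SNPs — a genome scaled down with its marker panel so that density
  (~15 SNPs/cM, ~180-250 kb spacing after pruning) matches the real chip
  and the fixed ROH parameters remain meaningful. A shorter map inflates
  the variance of realized IBD around F&#95;ped relative to a full genome;
  tests exploit this (more signal per individual) and it is the main
  respect in which passing tests understate real-data precision.
* Traits (`simulate_traits()`): phenotype = mean + beta_ind * F(i) +
  beta_mat * F(dam) + sex + additive genetic + maternal genetic + maternal
  environment + year + residual. The genetic effects descend the pedigree
  by Mendelian-sampling recursion, so relatives covary by the numerator
  relationship matrix. Default means/SDs (2.08 (0.60) kg birthweight,
  13.18 (2.76) kg August weight, 159.48 (10.49) mm hindleg) and slopes
  (e.g. -8.36 individual and -7.89 maternal for weight) are the study
  conditions the recovery tests target; variance proportions (additive
  0.25, maternal genetic 0.10, maternal environment 0.10, year 0.15) are
  typical of juvenile ungulate body size. Each trait draws independent
  genetic effects (no cross-trait covariance).
* Fitness (`simulate_fitness()`): first-year survival and annual survival
  are Bernoulli on a logit scale, annual breeding success Poisson on a log
  scale, with sex-specific intercepts and F slopes (default male
  first-year slope -22.66), year and mother/individual random intercepts.
  Adult observation spans are geometric; no density dependence, selection,
  or X chromosome.

Everything is seeded; identical seed and configuration give bit-identical
output.

## The models

Body-size traits use the animal model: fixed individual and maternal F
(plus sex), random year, additive genetic, maternal genetic and maternal
environment effects, the two genetic terms structured by the pedigree
relationship matrix. `fit_lmm_reml()` fits this by REML through lme4's
modular interface after post-multiplying the random-effect design by the
Cholesky factor of each relationship matrix — numerically the same REML
criterion as the explicit mixed-model-equation formulation, with lme4's
optimizer handling boundary variances. Fixed effects are tested with Wald
statistics (z, and F = z^2 on 1 df). Fitness components use
Laplace-approximation GLMMs (`fit_glmm()`, binomial-logit or Poisson-log)
with iid random intercepts; this deliberately replaces MCMC posterior
sampling with a frequentist fit of the same fixed/random structure — the
validation currency here is slope recovery on synthetic data, not
posterior reproduction, and Wald intervals stand in for credible
intervals. Birthweight is pre-corrected by the residuals of a cubic of
capture weight on capture age, using only captures within 10 days of birth
(`correct_birthweight_for_age()`; at least 8 records required for the
cubic).

Slopes are made comparable across traits by
`pct_change_per_deltaF()` (percent change of the trait mean per 0.1
increase in F) and, for logit slopes, `odds_reduction_per_deltaF()`
(100 * (1 - exp(0.1 * slope))).

## Numerical choices and edge cases

* Kinship: recursion with an incremental tabular update; unknown parents
  contribute zero; relationship matrices get a 1e-8 diagonal ridge before
  Cholesky.
* VIF pruning: windows of 50 SNPs stepping by 5 within chromosome (window
  sizes are a convention, not printed anywhere authoritative; both are
  arguments); exact duplicates and ties drop the later marker, making the
  result deterministic in input order; the final window is anchored to the
  chromosome end so the tail is always covered.
* ROH: a SNP is in a run iff at least 5% of the scanning windows covering
  it are homozygous; windows truncate at chromosome ends; segment length
  is the bp span between its first and last SNP.
* g2: loci with zero observed heterozygotes are dropped with a warning;
  datasets where all individuals share one heterozygosity pattern are
  flagged degenerate; permutation p-values use the (1 + exceedances)/(1 +
  permutations) convention, so they are never zero.
* GLMM separation: fits whose slopes and standard errors explode (|b|,
  SE > 25) are flagged rather than raised.
* REML convergence: bobyqa with a coarse-to-fine trust region
  (rhobeg 0.4, rhoend 1e-5); non-convergence flags the fit instead of
  erroring.

## What the test suite establishes (and at what scale)

The suite runs entirely on synthetic data, sized for a desktop: gene-drop
unbiasedness uses 300 replicate drops of a fixed multi-loop pedigree
(every mean realized IBD within 3 Monte-Carlo SE of F&#95;ped); the
damaged-pedigree comparison uses 6 replicate populations of ~700
individuals with 3750 SNPs and 30% of links deleted (F_GRM and F_ROH
correlate with truth at least as well as F&#95;ped, genomic estimators
inter-correlate above their correlation with F&#95;ped, and the
F&#95;ped-genomic correlation rises under the four-grandparent restriction);
ROH calling is exact (100% recall, 0 false positives) on constructed
genotypes with implanted autozygous segments, and gene-dropped segment
lengths pass a KS check against the exponential tail; calibration uses
500 null g2 datasets (n = 200, L = 500), 400 null LMM fits and 200 null
GLMM fits (type-I error within two binomial SE of 5%, uniform Wald
p-values); and slope recovery uses 35 replicate populations of ~400
individuals (CI coverage of the individual, maternal and male-survival
slopes within binomial bounds of 95%). The real study's sample sizes are
roughly 4-10x larger per analysis; nothing in the methods depends on the
scaling.

## Known limitations

* The LD generator is two-level (templates -> pool -> founders), so
  long-range LD is weaker and flatter than a coalescent model would give;
  g2 and HH correlations on simulated data are somewhat larger than the
  tiny values typical of real dense panels, because the scaled map has
  fewer independently segregating segments.
* Maternal genetic and direct genetic effects are simulated and fitted as
  uncorrelated; cross-trait and direct-maternal covariances are out of
  scope.
* The GLMMs use Laplace approximation and Wald intervals; with few year
  levels the year variance is imprecise, which the calibration tests
  bound but do not eliminate.
* Pedigree F is computed for every individual, but with one known parent
  it is 0 by construction; analyses that need accurate F&#95;ped should
  restrict by ancestry tier, as the comparison functions do.
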