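---
title: "FST-based SNP preselection for genomic prediction: models and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FST-based SNP preselection for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-density SNP panels and sequence-level genotypes put far more markers
into a whole-genome regression than there are phenotyped animals. The
resulting over-parameterization and co-linearity dilute each QTL's signal
across many correlated markers, and Bayesian variable-selection machinery
(BayesB, BayesC) must spend its statistical budget discovering which
markers matter. In a livestock population under sustained directional
selection there is, however, a cheap external signal: markers linked to
selected QTL shift in allele frequency. `fstprior` implements a
prioritization scheme that exploits this — animals of one genotyped
generation are split on phenotype into extreme tails, Nei's fixation index
is computed per SNP between the tails, and only SNPs in the upper tail of
the FST-score distribution enter the prediction model — together with the
full simulation apparatus needed to study the scheme's behavior against
BayesB and BayesC.

## Population simulation

`run_simulation()` reproduces a classical livestock design:

1. **Historical phase** (`run_historical`). All candidate loci start at
   allele frequency 0.5 in linkage equilibrium; a closed population of
   `hist_size` animals mates at random for `hist_generations` discrete
   generations, then grows linearly to `expand_size_end` over
   `expand_generations` generations. Drift in the finite population is the
   only source of LD; recurrent biallelic mutation (allele flips at
   `mutation_rate` = 1e-4 per locus per gamete per generation) maintains
   segregation. At the end, the marker panel is drawn from candidates with
   MAF >= 0.01 (evenly thinned to `n_markers`) and the QTL from candidates
   with MAF >= 0.05; candidates are oversampled so both draws succeed. QTL
   positions are uniform and never coincide with marker positions.
2. **Founders (G0)** (`found_population`). `n_males` + `n_females` animals
   sampled from the final historical generation, mated at random with no
   selection.
3. **Selection phase (G1-G4)** (`ebv_and_select`). One progeny per dam, 50%
   sex ratio. Parents are truncation-selected on EBVs from a single-trait
   pedigree animal-model BLUP with the known variance ratio
   `lambda = (1 - h2)/h2`, solved by Jacobi-preconditioned conjugate
   gradients to a relative residual of 1e-8 (a `selection = "phenotypic"`
   fallback ranks on own phenotype). Each generation, 50% of the sires and
   20% of the dams are culled and replaced by the top young animals of the
   matching sex. Animals of generations 3 and 4 are flagged genotyped: G3
   supplies the FST scan and the training set, G4 the validation set.

Meiosis follows the Haldane model: per chromosome, a Poisson(map length in
Morgans) crossover count, uniform crossover positions, no interference,
uniform starting strand. Positions in cM are treated directly as genetic
distance.

### Trait architecture

One hundred biallelic QTL (40 at desk scale) carry additive effects under
one of two architectures:

* **gamma** — |effect| ~ gamma(shape 0.4), random sign, rescaled so the
  Hardy-Weinberg variance `sum(2*p*q*a^2)` equals `sigma2_g` = 0.4. A few
  QTL dominate (the largest typically explains >10% of the genetic
  variance).
* **predefined** — per-QTL variance fractions ~ U(0.005, 0.015),
  renormalized; every QTL explains roughly 0.5-1.5% of the variance, a
  deliberately flat architecture.

Phenotypes add a normal residual to the TBV. Under the default
`rescale_to_realized_h2` policy the residual variance is set from the
*realized* founder TBV variance, `sigma2_e = Var(tbv)*(1 - h2)/h2`, so
heritability is held at 0.4 whatever LD among QTL did to the genetic
variance; the `nominal` policy uses `sigma2_e` = 0.6 as given. The
residual variance is fixed once on the founder cohort and reused in later
generations; realized h2 is therefore defined (and measured by
`realized_h2_pct`) on the unselected G0 cohort — later generations are
under selection, where the Bulmer effect deflates the genetic variance.

### Desk scale and LD calibration

The full design (10 chromosomes, 200K/400K markers, 8000 animals for 300 +
15 generations, 16,500 founders) is the documented default of
`sim_config()` but is not meant to run on a desktop. `scaled_sim_config()`
is the desk-scale counterpart used by the tests: 2 chromosomes of 100 cM,
a 4000-SNP panel, 40 QTL, 250 sires x 2500 dams, so G3 supports 2000
training animals and 5% phenotype tails of 125 animals each, and G4 a
1000-animal validation set. The historical phase (45 animals for 150
generations, expanding to ~2830) was calibrated so that mean adjacent-
marker r2 at G0 sits near 0.65-0.70 — the dense-chip LD regime the study
targets; `ld_regime = "low"` multiplies the historical size by 4 to weaken
adjacent r2 to roughly 0.3. Scaling choices keep marker *density* (SNPs
per cM) and tail *fractions* faithful; they cannot keep every ratio at
once (see "Limitations").

## The FST scan

Within the genotyped G3 animals, `split_by_phenotype()` takes equal-sized
phenotype tails by rank (S1 lowest, S2 highest; 750 + 750 at full scale,
5% per side in general), deterministic under ties. For each SNP,
`nei_fst()` computes

> FST = (H_T - H_S) / H_T,  H_Si = 2 p_Si q_Si,
> H_S = (H_S1 n_S1 + H_S2 n_S2) / (n_S1 + n_S2),  H_T = 2 p q,

with p the size-weighted pooled frequency of the two tails (S0 animals do
not enter the scores). Conventions chosen where the estimator is silent:
loci monomorphic across both tails score 0 (keeps NaN out of the quantile
step; such loci carry no differentiation signal); the selection threshold
is the empirical quantile (0.975/0.99/0.995) of the score distribution
over *all* loci, with ties at the threshold included, so selected counts
can exceed `(1-q)*n`. `fst_scan()` wires these together and, given a
stratum factor, scores within stratum — the recommended mode for admixed
populations, where pooled scans confound selection signatures with
between-breed frequency differences; combining prioritized sets across
strata is left to the user.

## Bayesian whole-genome regression

All three fitted models share

> y_i = mu + sum_j X_ij beta_j gamma_j + e_i

with X the 0/1/2 dosage, centered by twice the training allele frequency
(validation reuses the training centers). `gwr_fit()` runs a single-site
Gibbs sampler (Rcpp):

* **fst_preselect** — the proposed method: the design holds only the
  FST-selected SNPs, every gamma_j = 1, and each SNP has its own effect
  variance with a scaled-inverse-chi-square prior (a BayesA-style model on
  a prioritized panel).
* **bayesB** — point mass at zero with prior exclusion probability
  `pi_zero`, locus-specific variances; the indicator is sampled with the
  effect integrated out of its full conditional (no Metropolis step), and
  excluded loci refresh their variance from the prior.
* **bayesC** — as bayesB but one effect variance common to all included
  SNPs. `pi_zero` is fixed, not estimated; the study grid is
  {0.90, 0.95, 0.98, 0.99}.

Priors: scaled-inverse-chi-square with scales set to the true simulation
variances (genetic 0.4, residual 0.6) and degrees of freedom 1 (genetic)
and 4 (residual). The genetic-variance scale is partitioned per locus as
`prior_scale_g / ((1 - pi_zero) * m * mean(2pq))`, so the genetic variance
implied by the expected number of included SNPs matches the prior scale;
at `pi_zero = 0` this is the plain equal-partition rule. Default chain:
11,000 iterations, 1,000 burn-in, thinning 10. At the desk-scale design
sizes (<= 4000 SNPs, 2000 records) chains of 2,500 iterations with 500
burn-in give accuracies indistinguishable from 8,000-iteration chains
(checked directly), and the test suite uses such chains; posterior means
over kept samples are reported, and every fit is deterministic given its
seed. A note on notation: GenSel-style reports often label their columns
"(1-pi)" while pairing "(1-pi) = 0.90" with 10% of the SNPs in the model;
the package's `pi_zero` (prior *exclusion* probability) maps onto such
columns directly.

`predict_gebv()` computes GEBV_i = sum_j z_ij beta_hat_j on training-
centered validation dosages, matching columns by SNP id.

## Evaluation

`genomic_accuracy()` is the Pearson correlation of GEBV with TBV in
validation; `phenotype_accuracy()` correlates GEBV with phenotypes
adjusted for the fitted overall mean (the only systematic effect).
`tag_qtl()` calls a QTL tagged when its squared dosage correlation
(composite r2 — no phasing needed, the convention in this literature) with
at least one selected SNP exceeds 0.7, computed in the G3 training
animals, and reports the Hardy-Weinberg share of genetic variance carried
by tagged QTL (single-locus 2pqa^2 sums; QTL-QTL LD covariance is ignored,
an approximation). `run_experiment()` drives the full grid — within a
replicate all methods analyze the same simulated data, so comparisons are
paired — and emits per-replicate rows, means with standard errors, and a
percentage-difference table (100*(other - proposed)/proposed, negative
meaning worse than the proposed method).

## Numerical and design choices

* **EBV engine.** QMSim-style breeding designs select on "EBVs" without
  pinning down the estimator; pedigree BLUP with the true variance ratio
  is the standard reading and the default here, solved iteratively (CG,
  tol 1e-8).
  Henderson's A-inverse rules ignore inbreeding in the Mendelian-sampling
  variances — the usual fast approximation.
* **Replicate structure.** Each replicate re-simulates the population from
  a fresh child seed (rather than only re-sampling training/validation
  splits); every stage derives its own seed from the master seed and all
  seeds land in the run manifest.
* **Founder sampling** is without replacement when the historical
  generation is large enough, with replacement (documented in the
  manifest) otherwise.
* **Quantile of the FST distribution** is computed over all loci, not only
  polymorphic ones; monomorphic loci score 0 and only shift the threshold
  infinitesimally at the quantiles used.
* **Missing genotypes** (real-data mode): VCF half-calls are missing;
  multi-allelic records are rejected with a count; loci above 10%
  missingness are dropped and the rest mean-imputed at model entry
  (`impute_dosages`); fractional dosages automatically take the sampler's
  double-precision path instead of the byte fast path.
* **Degenerate inputs.** Constant phenotypes make the tail split an error;
  zero-variance TBV makes the rescale policy an error; monomorphic QTL are
  excluded from effect sampling and from the tagged-variance denominator;
  monomorphic SNP columns keep effect 0.

## What the generator does and does not emulate

The simulator reproduces drift-generated LD, selection response, family
structure under truncation selection, and the few-large/many-small QTL
architectures — the features the prioritization method feeds on. It does
not emulate dominance or epistasis, genotyping error, real chip
ascertainment bias, variable recombination rates or crossover
interference, multi-trait selection, or overlapping generations. Passing
tests therefore show the method behaves as designed under its own
assumptions, not that it will match these numbers on real bovine data.

## Limitations

Desk-scale replication compresses the design unevenly: the panel shrinks
50-fold while QTL count shrinks 2.5-fold and records 5-fold. Two
consequences matter. First, the all-SNP reference model is only mildly
over-parameterized (4000 SNPs on 2000 records, against 20:1 at full
scale), so the penalty that preselection removes is much smaller. Second,
a fixed FST quantile selects SNPs in proportion to the panel, leaving
~2.5 selected SNPs per QTL at the 97.5% quantile where the full-scale
design has ~49, and the phenotype tails are 6x smaller, making the scores
noisier. The preselection advantage over the all-SNP model is accordingly
attenuated and replicate-dependent at desk scale, even though the
enrichment of selected SNPs around large QTL is robust there. Full-scale
behavior should be assessed with the full `sim_config()` defaults on
appropriate hardware.
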