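---
title: "Comparing SNP-based and haplotype-based GWAS in a closed multigenerational pedigree"
author: "SnpHapPower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SNP-based and haplotype-based GWAS in a closed multigenerational pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`SnpHapPower` reconstructs, as a tested pipeline, a simulation comparison of
two association-mapping strategies in a purebred livestock line bred as one
closed family over seven generations: a per-SNP linear mixed-model Wald scan
(LD-based mapping) and a haplotype-cluster score test (linkage/LD-based
mapping). Because the underlying genotypes of such populations are rarely
deposited, the package ships a first-class synthetic-population module that
emulates the study design — 836 animals in seven generations, array-density
SNP genotypes whose average r² decays to about 0.20 at 1 Mb, array-style
missingness and quality control — so every downstream stage is reproducible
from a single seed.

# The statistical models

## Animal model and adjusted phenotypes

Phenotypes are pre-adjusted with the single-trait animal model

$$ y = Xb + u + e,\qquad u \sim N(0, A\sigma_u^2),\quad e \sim N(0, I\sigma_e^2), $$

where `X` codes sex (boar/barrow/gilt) and generation (seven classes) as
fixed effects and `A` is the pedigree numerator relationship matrix. The
adjusted phenotype is the exact affine residual \(y_{adj} = y - X\hat b\).
Variance components come from REML. Because the model has a single random
effect, the restricted likelihood profiled over \(b\) and the total variance
is a smooth one-dimensional function of the variance ratio
\(\lambda = \sigma_u^2/\sigma_e^2\) on the spectral decomposition of `A`
(`eigenRelationship()`); `fitAnimalModel()` maximises it by Brent search on
\(\log\lambda\) (tolerance `1e-10`, search range `1e-6`–`1e4`, explicit
comparison against the \(\sigma_u^2 = 0\) boundary). This is exact for this
model class — a deliberate design choice over iterative AI-REML, whose
updates can leave the parameter space and whose convergence then needs
monitoring; on these problems the two coincide to the optimiser tolerance.
A small diagonal jitter (at most `1e-8`) is added only if `A` is numerically
singular.

## Per-SNP mixed-model scan

Each SNP is tested with
\(y_{adj} = \beta_i w_i + u + e'_i\) (intercept included), re-optimising the
variance ratio per SNP on the shared spectral decomposition — the exact-LMM
strategy of GEMMA-style software. The per-SNP profile REML is evaluated on a
61-point log-spaced grid of \(\lambda \in [10^{-5}, 10^5]\) with parabolic
refinement; \(\hat\beta\), its standard error and the 1-df chi-square Wald
p-value follow from weighted least squares in rotated coordinates. Missing
dosages are mean-imputed per SNP before testing; monomorphic SNPs are
flagged `NA`. A fast mode (`perSnpLambda = FALSE`) fixes \(\lambda\) at the
null-model optimum. The per-SNP variance proportion is
\(2p_i(1-p_i)\hat\beta_i^2 / V_P\) with \(V_P = \mathrm{var}(y_{adj})\)
(the report caps it at 1 with a warning).

## Haplotype-cluster model and score test

`fitHaplotypeHMM()` fits a fastPHASE-style hidden Markov model with
`K = 20` ancestral haplotype states: locus-specific emission probabilities
\(\theta_{jk}\) (alt-allele probability of state `k` at locus `j`),
uniform state weights, and per-interval cluster-switch probabilities
\(1 - e^{-\rho d}\) with \(\rho = 20\) switches/Morgan on the 1 Mb = 1 cM
map. The diploid likelihood is the exact product of two gamete chains with
factorising transitions, so every forward–backward update costs `O(K²)` per
locus. EM updates the emissions only (with a `1e-6` pseudo-count), which
keeps the log-likelihood trace provably non-decreasing; state weights and
\(\rho\) stay fixed. Default 25 iterations, seeded random initialisation
around the sample allele frequencies, optional restarts keeping the best
likelihood. The fit returns, per position, the `n × K` table `H` of
posterior expected ancestral-state copies (rows sum exactly to 2) and the
panel with missing genotypes imputed by the posterior-mode genotype.

The association test is the two-step score test: the intercept-only animal
model on \(y_{adj}\) yields residuals \(r = y_{adj} - 1\mu - \hat u\)
(`glascowResiduals()`), reused across positions, and each position is scored
with

$$ T = \tfrac12\, r' H_i H_i' r . $$

Under the null the distribution of `T` is approximated per position by a
gamma distribution fitted by moment matching to the permutation distribution
of `r` across animals. `gammaNullPvalue()` offers two estimators of those
moments: random permutations (`n_perm` ≥ 100, default 1000), and an
analytic mode that evaluates the exact permutation mean and variance of the
quadratic form in closed form from six invariants of \(B = H_iH_i'\) and the
power sums of `r` (verified in the test suite against exhaustive
enumeration of all permutations at small `n`). Scans default to the
analytic moments: they are the infinite-permutation limit of the same
estimator, cost `O(nK)` per position after a one-off pass, and remove all
Monte-Carlo error from the null fit. p-values are floored at the machine
tail and a degenerate null (zero variance, e.g. `K = 1`) reports p = 1.

Two caveats are worth stating. First, the gamma fit matches two moments;
its extreme tail is an extrapolation, which is exactly why genome-wide
inference uses the Bonferroni threshold rather than the nominal tail.
Second, permuting residuals across animals treats them as exchangeable;
in a deeply related pedigree the residual vector retains some family
structure, so the test is conservative there (we observe about 1–2% of
null positions below p = 0.05 at study scale). Both behaviours depress the
haplotype scan's power relative to a perfectly calibrated test, consistent
with the low power this method family shows for rare variants.

# The synthetic population

## Pedigree

`generatePedigree()` builds the closed line with the study's generation
sizes (16/22, 19/40, 42/47, 67/86, 73/86, 71/86, 80/101 males/females;
836 animals), marking the recorded numbers of sib-tested males as barrows.
The breeding programme's selection index is out of scope; mating is random
with two constraints a breeder would impose to slow inbreeding: full-sib
and parent–offspring matings are avoided whenever an alternative sire
exists, and litters are spread evenly over the previous generation's dams.
Founders (generation 1) carry unknown parents; inbreeding then accumulates
to a mean of about 0.07 by generation 7.

## Founder LD and gene dropping

Founder haplotypes are Poisson mosaics (switch rate per Morgan) of a small
pool of ancestral haplotypes. Pool alleles are generated from a latent
circular uniform per haplotype that persists along the chromosome
(exponential survival with scale `persistCM`): SNP `j` is an arc of length
\(p_j\) on that circle. With probability `phaseAlignProb` the arc anchors to
a persistent local "clade phase" — such SNPs tag the same haplotype
background and provide the high-r² proxies real arrays contain — otherwise
the arc is placed independently, as distinct mutation events are. This
mixture matters: anchoring *all* SNPs to one phase makes neighbouring SNPs
literal duplicates (median best proxy r² = 1), which inflates masked-QTL
detection power and even inverts the MAF ordering; fully independent arcs
remove high-LD proxies entirely and flatten the decay curve. Gene dropping
transmits one recombinant gamete per parent under the Haldane model
(Poisson crossovers on the cM scale, 1 Mb = 1 cM, no interference).

The defaults — `nAnc = 14`, `switchRate = 5`/Morgan, `persistCM = 6`,
`phaseAlignProb = 0.7`, two 100 Mb autosomes with 1667 SNPs each (≈60 kb,
the post-QC density of a 60K array on a 2.3 Gb autosomal genome) — were
fixed once by a pilot grid search against the population's stated LD
anchor, chromosome-averaged r² ≈ 0.20 at 1 Mb (observed 0.199–0.215 across
seeds), with a realistic short-range level (r² ≈ 0.30 at 50 kb) and MAF
spectrum (≈14% of segregating SNPs in the 0.01–0.10 class). They are study
conditions, not tuning knobs.

What the generator does *not* emulate: array ascertainment bias beyond the
uniform target-frequency draw, coverage gaps and density heterogeneity of a
real chip, genotyping error, sex chromosomes, selection on breeding values,
and litter/maternal structure. Power measured here therefore characterises
the methods on an idealised panel with the right LD scale, not on any
particular real dataset.

# The power study

`simulateBasePhenotype()` draws the null polygenic phenotype down the
pedigree: founders \(u_j \sim N(0, \sigma_u^2)\); non-founders
\(u_j \sim N\!\big(\tfrac12(u_{Sj}+u_{Dj}),\;
\tfrac12(1-\tfrac12(F_{Sj}+F_{Dj}))\sigma_u^2\big)\) using the parents'
Meuwissen–Luo inbreeding coefficients; \(e_j \sim N(0, \sigma_e^2)\);
\(\sigma_u^2 = 0.30\), \(\sigma_e^2 = 0.70\), \(V_P = 1\).

Each replicate picks one SNP uniformly from the configured MAF class on the
imputed panel, assigns \(\beta = \pm\sqrt{\sigma^2_{QTL}/2p(1-p)}\) (random
sign; \(\sigma^2_{QTL}\) equals the QTL heritability since \(V_P = 1\)),
adds the effect, and masks the QTL from the analysis panel. The wording
"an error value was also added" admits two readings; the default
(`qtl_error_mode = "rescale"`) scales the base phenotype by
\(\sqrt{1-h^2_{QTL}}\) before adding the effect, so the new phenotype keeps
\(V_P = 1\), the realised QTL variance equals its nominal value and the
polygenic-to-residual ratio is unchanged; `"additive"` adds the effect
without rescaling (total variance \(1 + h^2_{QTL}\)). At the heritabilities
studied the two differ by a multiplicative \(\le 0.93\) on the non-QTL part
and lead to very similar power.

Both scans are then run on sex+generation-adjusted phenotypes, and the
minimum p-value is recorded in three disjoint windows around the masked
QTL: ±0.5 Mb, ±0.5–1.0 Mb and ±1.0–2.0 Mb (annuli, so their union is
±2 Mb). Power per cell is the fraction of replicates whose window minimum
beats the genome-wide threshold \(P = 1.31\times10^{-6}\) — the Bonferroni
5% level for 38,128 tests, kept at the study's value regardless of the
reduced panel size so that power is comparable; the suggestive level is
\(5\times10^{-5}\). `callRegions()` merges significant SNPs within 1 Mb
into regions labelled by their top SNP.

## Problem sizes

The default study design used by the acceptance script and the end-to-end
tests is the 836-animal pedigree on two 100 Mb autosomes (3,334 SNPs before
QC): large enough to preserve the LD structure and the multi-generation
relatedness that drive both tests, small enough that a hundred replicates
of the full two-scan protocol complete on a desktop core. Heritability
recovery uses 50 replicates; SNP-scan power 100 replicates per MAF class at
QTL heritability 0.05; the haplotype bound 25 replicates per heritability.
The full 18-autosome, 38k-SNP design is supported by the same functions
(`makeMarkerMap(18, ...)`), only slower.

# Numerical choices and degenerate inputs

* Forward/backward probabilities below `1e-150` are flushed to zero after
  normalisation; subnormal arithmetic is dramatically slower and the mass
  involved is far below posterior relevance.
* The exact HWE test sums genotype-table probabilities conditional on
  allele counts, with a `1 + 1e-12` relative guard on the "as extreme"
  comparison; monomorphic input returns p = 1.
* `ldR2()` excludes incomplete pairs pairwise and reports `NA` (never 0)
  for monomorphic or <2-pair cases; decay-curve bins with no pairs are
  `NA`, not zero.
* Region calling breaks p-value ties towards the smaller position.
* All stochastic operations take explicit seeds; replicate `r` of a study
  derives its seed from the base seed and the cell/replicate index, so any
  replicate can be reproduced in isolation and identical seeds give
  bit-identical results. Seeded code restores the caller's RNG state.

# Known limitations

* The haplotype-cluster model updates emissions only; cluster weights and
  the switch rate are fixed. This is enough for dosage construction and
  imputation (accuracy ≈0.99 on masked entries of the calibrated panel,
  versus ≈0.62 for the major-allele guess), but it is not a full phasing engine,
  and no pedigree information enters the phasing — unlike the linkage-aware
  tools it stands in for.
* The score test's permutation null ignores residual relatedness (above);
  its power figures are for the test as defined, conservativeness included.
* In the clade-phase pool, rare SNPs that anchor to a persistent clade sit
  exactly on one haplotype background, so the K = 20 cluster model tags
  their carriers perfectly and the score test can detect a large rare QTL
  (power up to ~0.3 at QTL heritability 0.15 in the default design). Real
  array data appear far less cluster-taggable for rare alleles; treat the
  haplotype scan's rare-variant power here as an upper bound for this
  population class, not an estimate.
* The synthetic panel's best proxy within ±0.5 Mb of a masked SNP is
  somewhat stronger than on a real array with the same 1 Mb LD anchor, so
  masked-QTL power for the SNP scan runs a tenth or so above what the
  matching field study reports at the same QTL heritability.
* Half-known parentage, repeated records per animal, dominance and maternal
  effects are unsupported by design.
* With two chromosomes, genome-wide null scans cross the 38,128-test
  Bonferroni threshold less often than a 18-chromosome genome would; the
  threshold is kept at the study's printed value deliberately, because the
  power windows are local and the threshold is part of the protocol under
  comparison.
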