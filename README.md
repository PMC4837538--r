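# SnpHapPower

Power comparison of SNP-based and haplotype-based genome-wide association
scans in closed multigenerational livestock populations, with a fully
synthetic, seed-reproducible study population.

Local breeding programmes keep purebred lines (pigs, in the motivating
design) as a single closed family over many generations. QTL mapped in such
lines can drive marker-assisted selection, and two mapping strategies
compete: testing each SNP with a linear mixed model (LD-based mapping), or
testing ancestral haplotype dosages with a score test (linkage/LD-based
mapping). `SnpHapPower` implements both, plus everything needed to measure
their QTL-detection power on a population whose structure and linkage
disequilibrium match a seven-generation closed line of 836 animals
genotyped at array density. It is aimed at quantitative geneticists who
want a transparent, testable reimplementation of this comparison rather
than a black-box toolchain.

## Models

**Adjusted phenotypes.** The animal model
*y* = *Xb* + *u* + *e*, *u* ~ N(0, **A**σ²ᵤ), *e* ~ N(0, **I**σ²ₑ), with sex
and generation as fixed effects and **A** the pedigree numerator
relationship matrix (Meuwissen–Luo inbreeding on the diagonal), is fitted
by exact profiled REML on the spectral decomposition of **A**; the scans
use *y*adj = *y* − *X**b̂*.

**SNP-based scan.** Per SNP *i*: *y*adj = βᵢ*w*ᵢ + *u* + *e*′ᵢ with
dosages *w*ᵢ ∈ {0,1,2}; the variance ratio is re-optimised per SNP on the
shared eigen-decomposition (exact-LMM, GEMMA-style) and βᵢ is tested by a
1-df Wald chi-square. Per-SNP variance explained: 2*p*ᵢ(1−*p*ᵢ)βᵢ²/*V*P.

**Haplotype-based scan.** A fastPHASE-style hidden Markov model with
K = 20 ancestral haplotype states yields, per position, the n × K table
**H**ᵢ of expected ancestral-haplotype copies (rows sum to 2) and imputes
missing genotypes. The two-step score test uses the null-model residuals
*r* = *y*adj − **1**μ − *û* and the statistic

> T = ½ · *r*′ **H**ᵢ **H**ᵢ′ *r*,

whose null distribution is approximated per position by a gamma fitted by
moment matching to the permutation distribution of *r* (closed-form exact
moments by default; sampled permutations optionally).

**Power study.** Per replicate, a base phenotype (h² = 0.30, *V*P = 1) is
gene-dropped down the pedigree with the inbreeding-adjusted Mendelian
sampling rule, a QTL drawn from a MAF class gets effect
±√(σ²QTL / 2*p*(1−*p*)) and is masked, both scans run, and power is the
fraction of replicates with *P* < 1.31 × 10⁻⁶ (Bonferroni 5% for 38,128
tests) within ±0.5 Mb (and the ±0.5–1.0 / ±1.0–2.0 Mb annuli) of the QTL.

## Worked example

A reduced single-chromosome run (the default study design uses two 100 Mb
chromosomes; everything is seed-reproducible):

```r
library(SnpHapPower)

ped <- generatePedigree(seed = 1)            # the 7-generation closed line
#> Pedigree: 836 animals, 7 generations (38 founders)
#>   per generation: G1=38, G2=59, G3=89, G4=153, G5=159, G6=157, G7=181

panel <- simulateGenotypePanel(ped,
  map = makeMarkerMap(nChrom = 1, chromLengthBp = 4e7,
                      nSnpsPerChrom = 700, seed = 2), seed = 3)
qc <- qcFilter(maskMissing(panel, 0.01, seed = 4))
qc$report
#> QCReport: 639/700 SNPs kept, 836/836 animals kept
#>   thresholds: MAF >= 0.01, SNP call rate >= 0.95, HWE p >= 0.001, animal call rate >= 0.95

ldAt(ldDecayCurve(panel, maxDist = 2e6), 1e6)   # calibrated useful-LD anchor
#> [1] 0.195

hmm <- fitHaplotypeHMM(qc$panel, K = 20, nEmIter = 15, seed = 5)
ids <- animalIds(hmm$imputed)
eigenA <- eigenRelationship(relationshipMatrix(ped)[ids, ids])

# plant a masked QTL explaining 10% of variance on a null polygenic trait
y <- simulateBasePhenotype(ped, h2 = 0.30, seed = 6)[ids]
inj <- injectQtl(y, hmm$imputed, mafClass = c(0.10, 0.5), qtlH2 = 0.10, seed = 7)
#> planted QTL snp_c1_21271494 at 21.27 Mb, MAF 0.38, beta -0.460

pedDf <- as.data.frame(ped); rownames(pedDf) <- pedDf$id
fit <- fitAnimalModel(inj$y,
  fixed = data.frame(sex = factor(pedDf[ids, "sex"]),
                     generation = factor(pedDf[ids, "generation"])),
  eigenA = eigenA)

snp <- snpScan(fit@yAdj, panel = inj$panel, eigenA = eigenA)
snp[which.min(snp$p), c("snp_id", "pos", "beta", "se", "p", "proportion")]
#>           snp_id      pos   beta     se        p proportion
#>  snp_c1_19808371 19808371 -0.368 0.0707 1.97e-07     0.0484

hap <- hapScan(fit@yAdj, dosages = hmm$dosages, eigenA = eigenA,
               exclude = inj$qtl$snp_id)
hap[which.min(hap$p), c("snp_id", "pos", "T", "p")]
#>           snp_id      pos   T       p
#>  snp_c1_21392104 21392104 680 0.00628

callRegions(snp)
#>  chrom    start      end n_snps         top_snp    top_p       level
#>      1 19808371 23363501     18 snp_c1_19808371 1.97e-07 significant
#>      1 24406583 24568842      2 snp_c1_24406583 1.72e-05  suggestive
```

Both scans localise the masked QTL: the SNP scan's top hit sits 1.5 Mb from
the planted locus at genome-wide significance (a proxy SNP in strong LD;
the QTL itself is masked) and explains ~5% of the phenotypic variance; the
haplotype scan's top position lands 0.12 Mb away but, at this effect size,
does not reach the genome-wide threshold — the qualitative pattern the
power study quantifies. `runPowerGrid()` repeats this protocol over
replicates, MAF classes and QTL heritabilities; `runPipeline()` drives the
whole chain from a YAML/list configuration and writes TSVs plus a manifest.

## Layout

* `R/` — pedigree and genotype simulation, QC/LD, kinship, REML, both
  scans, power study, PLINK and CSV IO, pipeline.
* `src/` — Rcpp kernels: haplotype-cluster EM, per-SNP exact-LMM scan,
  banded LD binning.
* `vignettes/power-comparison.Rmd` — models, assumptions, calibration and
  design decisions.
* `tests/testthat/` — unit, property and end-to-end suites.
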