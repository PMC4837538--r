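# Founder-LD simulation and gene dropping.
#
# Genetic map convention used throughout: 1 Mb = 1 cM, Haldane map function
# (no interference); coordinates are 1-based bp on autosomes.

#' Ancestral haplotype pool
#'
#' A small pool of ancestral haplotypes from which founder haplotypes are
#' built as Poisson mosaics. Pool alleles come from a latent circular
#' uniform per haplotype that persists along the chromosome (redrawn with an
#' exponential survival over `persistCM`): SNP `j` carries the alt allele on
#' haplotype `a` when the latent value falls inside the SNP's arc of length
#' `p_j` on the unit circle. Arc positions mimic the two ways real variants
#' relate to the local genealogy: with probability `phaseAlignProb` a SNP's
#' arc is anchored to a slowly varying local clade phase (variants on a
#' shared haplotype background, giving the high-LD proxies seen on arrays),
#' otherwise the arc position is independent (distinct mutation events,
#' sharing carriers only through chance overlap). The persistence length and
#' the mosaic switch rate set the LD decay scale.
#'
#' @slot alleles integer matrix (nAnc x m), 0/1 alt-allele indicators.
#' @slot switchRate numeric, expected mosaic switches per Morgan.
#' @slot persistCM numeric, latent persistence length (cM) used to build the pool.
#' @slot freq numeric, realised pool alt-allele frequencies per SNP.
#' @slot map data.frame marker map.
#' @export
setClass("HaplotypePool", representation(
  alleles = "matrix", switchRate = "numeric", persistCM = "numeric",
  freq = "numeric", map = "data.frame"
))

setValidity("HaplotypePool", function(object) {
  msg <- character()
  if (nrow(object@alleles) < 1L) msg <- c(msg, "pool must contain at least one haplotype")
  if (!all(object@alleles %in% 0:1)) msg <- c(msg, "pool alleles must be 0/1")
  if (object@switchRate < 0) msg <- c(msg, "switchRate must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypePool", function(object) {
  cat(sprintf("HaplotypePool: %d ancestral haplotypes x %d SNPs, switch rate %.1f /Morgan\n",
              nrow(object@alleles), ncol(object@alleles), object@switchRate))
})

#' Simulate a marker map
#'
#' Places SNPs uniformly at random along each autosome (sorted, deduplicated),
#' giving approximately exponential inter-marker spacings, as on a genotyping
#' array after quality control.
#'
#' @param nChrom Number of autosomes.
#' @param chromLengthBp Chromosome length in bp (recycled over chromosomes).
#' @param nSnpsPerChrom SNPs per chromosome (recycled).
#' @param seed Integer seed.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
makeMarkerMap <- function(nChrom = 2L, chromLengthBp = 1e8, nSnpsPerChrom = 1667L,
                          seed = NULL) {
  len <- rep_len(as.numeric(chromLengthBp), nChrom)
  nsn <- rep_len(as.integer(nSnpsPerChrom), nChrom)
  withSeed(seed, {
    pieces <- lapply(seq_len(nChrom), function(ch) {
      pos <- sort(sample.int(len[ch], nsn[ch]))
      data.frame(chrom = ch, pos = pos)
    })
    map <- do.call(rbind, pieces)
    map$snp_id <- sprintf("snp_c%d_%07d", map$chrom, map$pos)
    map$ref <- "A"; map$alt <- "B"
    map[, c("snp_id", "chrom", "pos", "ref", "alt")]
  })
}

# cM positions under the 1 Mb = 1 cM rule
.mapCM <- function(map) map$pos / 1e6

#' Build an ancestral haplotype pool
#'
#' @param nAnc Number of ancestral haplotypes (>= 1).
#' @param map Marker map (see [makeMarkerMap()]).
#' @param switchRate Mosaic switches per Morgan used later by
#'   [generateFounderHaplotypes()].
#' @param persistCM Persistence length (cM) of the latent uniform that
#'   correlates pool alleles along the chromosome (also used for the local
#'   clade phase).
#' @param phaseAlignProb Probability that a SNP's arc anchors to the local
#'   clade phase rather than an independent random position.
#' @param freqRange Range from which per-SNP target allele frequencies are
#'   drawn uniformly.
#' @param seed Integer seed.
#' @return A [HaplotypePool-class].
#' @export
makeHaplotypePool <- function(nAnc, map, switchRate = 5, persistCM = 6,
                              phaseAlignProb = 0.7,
                              freqRange = c(0.03, 0.97), seed = NULL) {
  nAnc <- as.integer(nAnc)
  if (nAnc < 1L) stop("'nAnc' must be >= 1")
  m <- nrow(map)
  cm <- .mapCM(map)
  withSeed(seed, {
    p <- runif(m, freqRange[1], freqRange[2])
    # local clade phase: persists along the chromosome like the latent z
    clade <- numeric(m)
    clade[1] <- runif(1)
    z <- matrix(NA_real_, nAnc, m)
    z[, 1] <- runif(nAnc)
    for (j in seq_len(m)[-1]) {
      newChrom <- map$chrom[j] != map$chrom[j - 1L]
      surv <- if (newChrom) 0 else exp(-(cm[j] - cm[j - 1L]) / persistCM)
      keep <- runif(nAnc) < surv
      z[, j] <- ifelse(keep, z[, j - 1L], runif(nAnc))
      clade[j] <- if (runif(1) < surv) clade[j - 1L] else runif(1)
    }
    aligned <- runif(m) < phaseAlignProb
    phase <- ifelse(aligned, clade, runif(m))
    u <- (z + rep(phase, each = nAnc)) %% 1
    alleles <- matrix(as.integer(u < rep(p, each = nAnc)), nAnc, m)
    new("HaplotypePool", alleles = alleles, switchRate = switchRate,
        persistCM = persistCM, freq = colMeans(alleles), map = map)
  })
}

# Piecewise-constant source index along one chromosome: Poisson(rate/Morgan)
# switch points, uniform new source at each switch.
.mosaicSources <- function(cmPos, nSources, ratePerMorgan) {
  L <- (max(cmPos) - min(cmPos)) / 100  # Morgans spanned
  nSw <- if (ratePerMorgan > 0) rpois(1L, ratePerMorgan * L) else 0L
  src0 <- sample.int(nSources, 1L)
  if (nSw == 0L) return(rep(src0, length(cmPos)))
  sw <- sort(runif(nSw, min(cmPos), max(cmPos)))
  srcs <- c(src0, sample.int(nSources, nSw, replace = TRUE))
  srcs[findInterval(cmPos, sw) + 1L]
}

#' Generate founder haplotypes as mosaics of the pool
#'
#' Each founder haplotype copies alleles from a single active pool haplotype,
#' switching to a uniformly chosen pool haplotype at points of a Poisson
#' process with rate `switchRate` per Morgan (restarted on each chromosome).
#'
#' @param pool A [HaplotypePool-class].
#' @param nFounders Number of founder animals (each receives two haplotypes).
#' @param seed Integer seed.
#' @return list with 0/1 integer matrices `h1`, `h2` (SNPs x founders).
#' @export
generateFounderHaplotypes <- function(pool, nFounders, seed = NULL) {
  if (nrow(pool@alleles) < 1L) stop("empty haplotype pool")
  map <- pool@map
  m <- nrow(map)
  cm <- .mapCM(map)
  chromIdx <- split(seq_len(m), map$chrom)
  nAnc <- nrow(pool@alleles)
  withSeed(seed, {
    draw <- function() {
      hap <- integer(m)
      for (ii in chromIdx) {
        src <- .mosaicSources(cm[ii], nAnc, pool@switchRate)
        hap[ii] <- pool@alleles[cbind(src, ii)]
      }
      hap
    }
    h1 <- vapply(seq_len(nFounders), function(i) draw(), integer(m))
    h2 <- vapply(seq_len(nFounders), function(i) draw(), integer(m))
    list(h1 = h1, h2 = h2)
  })
}

# One recombinant gamete from a parent's two haplotypes (Haldane model:
# Poisson crossovers on the Morgan scale, random start strand, per chromosome).
.gamete <- function(h1, h2, cm, chromIdx) {
  g <- integer(length(h1))
  for (ii in chromIdx) {
    cpos <- cm[ii]
    L <- (max(cpos) - min(cpos)) / 100
    nX <- rpois(1L, L)
    start <- sample.int(2L, 1L)
    if (nX == 0L) {
      strand <- rep(start, length(ii))
    } else {
      xo <- sort(runif(nX, min(cpos), max(cpos)))
      strand <- 1L + (start - 1L + findInterval(cpos, xo)) %% 2L
    }
    g[ii] <- ifelse(strand == 1L, h1[ii], h2[ii])
  }
  g
}

#' Drop founder haplotypes through a pedigree
#'
#' Every non-founder inherits one recombinant gamete from each parent
#' (Haldane map on the 1 Mb = 1 cM scale). Dosage is the sum of the two
#' inherited alt-allele indicators; the returned panel is phased.
#'
#' @param pedigree A [Pedigree-class]; animals with exactly one known parent
#'   are rejected.
#' @param founderHaps Output of [generateFounderHaplotypes()] with one column
#'   pair per founder, in pedigree founder order.
#' @param map Marker map.
#' @param seed Integer seed.
#' @return A phased [GenotypePanel-class] for all pedigree animals.
#' @export
geneDrop <- function(pedigree, founderHaps, map, seed = NULL) {
  fndr <- isFounder(pedigree)
  nF <- sum(fndr)
  if (ncol(founderHaps$h1) != nF)
    stop("founderHaps must provide two haplotypes for each of the ", nF, " founders")
  m <- nrow(map)
  cm <- .mapCM(map)
  chromIdx <- split(seq_len(m), map$chrom)
  n <- length(pedigree)
  idx <- setNames(seq_len(n), pedigree@id)
  withSeed(seed, {
    H1 <- matrix(0L, m, n); H2 <- matrix(0L, m, n)
    fi <- 0L
    for (a in seq_len(n)) {
      if (fndr[a]) {
        fi <- fi + 1L
        H1[, a] <- founderHaps$h1[, fi]
        H2[, a] <- founderHaps$h2[, fi]
      } else {
        s <- idx[[pedigree@sire[a]]]
        d <- idx[[pedigree@dam[a]]]
        H1[, a] <- .gamete(H1[, s], H2[, s], cm, chromIdx)
        H2[, a] <- .gamete(H1[, d], H2[, d], cm, chromIdx)
      }
    }
    GenotypePanel(dosage = H1 + H2, map = map, animalIds = pedigree@id,
                  hap1 = H1, hap2 = H2)
  })
}

#' Mask genotypes as missing
#'
#' Sets dosage entries to `NA` independently at the given per-SNP rate,
#' emulating array no-calls; the input panel is not modified. Gamete assays
#' are dropped from the masked copy (a panel with missing dosages is
#' unphased by construction).
#'
#' @param panel A [GenotypePanel-class].
#' @param ratePerSnp Missingness rate in `[0, 1)`; scalar or one value per SNP.
#' @param seed Integer seed.
#' @return A new [GenotypePanel-class] with missing entries.
#' @export
maskMissing <- function(panel, ratePerSnp, seed = NULL) {
  m <- nSnps(panel); n <- nAnimals(panel)
  rate <- rep_len(ratePerSnp, m)
  if (any(rate < 0) || any(rate >= 1)) stop("'ratePerSnp' must lie in [0, 1)")
  d <- dosages(panel)
  withSeed(seed, {
    mask <- matrix(runif(m * n) < rate, m, n)  # rate recycles down columns = per SNP
    d[mask] <- NA_integer_
    GenotypePanel(dosage = d, map = markerMap(panel), animalIds = animalIds(panel))
  })
}

#' Simulate a complete genotype panel for a pedigree
#'
#' Convenience wrapper: builds the ancestral pool, draws founder mosaics and
#' gene-drops them through the pedigree. The default `nAnc`, `switchRate` and
#' `persistCM` were fixed once by a pilot grid search so that the
#' chromosome-averaged r-squared of the default seven-generation panel decays
#' to about 0.20 at 1.0 Mb, the useful-LD extent of the population the
#' package emulates.
#'
#' @param pedigree A [Pedigree-class].
#' @param map Marker map; defaults to [makeMarkerMap()] (2 autosomes x 100 Mb,
#'   2000 SNPs each) built from the same seed.
#' @param nAnc,switchRate,persistCM,phaseAlignProb Pool and mosaic
#'   parameters (see [makeHaplotypePool()]).
#' @param seed Integer seed.
#' @return A phased [GenotypePanel-class].
#' @export
simulateGenotypePanel <- function(pedigree, map = NULL, nAnc = 14L,
                                  switchRate = 5, persistCM = 6,
                                  phaseAlignProb = 0.7, seed = NULL) {
  if (is.null(map)) map <- makeMarkerMap(seed = childSeed(seed, 1L))
  pool <- makeHaplotypePool(nAnc, map, switchRate = switchRate,
                            persistCM = persistCM,
                            phaseAlignProb = phaseAlignProb,
                            seed = childSeed(seed, 2L))
  fh <- generateFounderHaplotypes(pool, sum(isFounder(pedigree)),
                                  seed = childSeed(seed, 3L))
  geneDrop(pedigree, fh, map, seed = childSeed(seed, 4L))
}
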