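#' Pedigree of a closed multigenerational population
#'
#' Records one animal per entry with its sire, dam, sex and discrete
#' generation. Founders have both parents unknown (`NA`) and are confined to
#' the base generation(s); every known parent precedes its offspring and
#' belongs to an earlier generation.
#'
#' @slot id character, unique animal identifiers in topological order.
#' @slot sire,dam character, parent identifiers (`NA` if unknown).
#' @slot sex character, one of `"male"`, `"female"`, `"castrate"`.
#' @slot generation integer, 1-based generation number.
#' @export
setClass("Pedigree", representation(
  id = "character", sire = "character", dam = "character",
  sex = "character", generation = "integer"
))

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  if (anyDuplicated(object@id)) msg <- c(msg, "animal ids must be unique")
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@sex) != n || length(object@generation) != n)
    msg <- c(msg, "slot lengths differ")
  if (!all(object@sex %in% c("male", "female", "castrate")))
    msg <- c(msg, "sex must be 'male', 'female' or 'castrate'")
  idx <- seq_len(n)
  pos <- setNames(idx, object@id)
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    if (any(known)) {
      pp <- pos[p[known]]
      if (anyNA(pp)) { msg <- c(msg, "parent id not present in pedigree"); break }
      if (any(pp >= idx[known])) { msg <- c(msg, "parents must precede offspring"); break }
      if (any(object@generation[pp] >= object@generation[known]))
        { msg <- c(msg, "offspring generation must exceed parent generation"); break }
    }
  }
  fndr <- is.na(object@sire) & is.na(object@dam)
  half <- xor(is.na(object@sire), is.na(object@dam))
  if (any(half)) msg <- c(msg, "animals with exactly one known parent are not supported")
  if (n > 0L && !any(fndr)) msg <- c(msg, "pedigree must contain founders")
  if (length(msg)) msg else TRUE
})

#' Genotype panel (animals x SNPs with a marker map)
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose `"dosage"`
#' assay holds SNP-major dosages (rows = SNPs, columns = animals) coded 0/1/2
#' with `NA` for missing. `rowData` carries the marker map (`chrom`, `pos`,
#' `ref`, `alt`); phased panels additionally carry `"hap1"` and `"hap2"`
#' 0/1 assays (alt-allele indicator on each gamete).
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object))) return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% 0:2)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  rd <- rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  else {
    if (any(rd$pos < 1L)) msg <- c(msg, "positions must be >= 1 (1-based bp)")
    for (ch in unique(rd$chrom)) {
      p <- rd$pos[rd$chrom == ch]
      if (any(diff(p) <= 0)) { msg <- c(msg, "positions must be strictly increasing within chromosome"); break }
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique SNP ids (rownames) are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique animal ids (colnames) are required")
  if (length(msg)) msg else TRUE
})

#' Genotype quality-control report
#'
#' @slot snpStats data.frame with per-SNP `maf`, `call_rate`, `hwe_p`, `kept`.
#' @slot animalStats data.frame with per-animal `call_rate`, `kept`.
#' @slot thresholds named list of the filter thresholds applied.
#' @export
setClass("QCReport", representation(
  snpStats = "data.frame", animalStats = "data.frame", thresholds = "list"
))

#' Animal-model REML fit
#'
#' Variance components, fixed-effect solutions, polygenic BLUPs and adjusted
#' phenotypes from the single-trait animal model
#' \eqn{y = Xb + u + e}, \eqn{u \sim N(0, A\sigma_u^2)},
#' \eqn{e \sim N(0, I\sigma_e^2)}.
#'
#' @slot sigma2u,sigma2e numeric variance components (>= 0).
#' @slot h2 numeric, \eqn{\sigma_u^2 / (\sigma_u^2 + \sigma_e^2)}.
#' @slot bHat named numeric, GLS fixed-effect solutions.
#' @slot uHat named numeric, BLUP of polygenic effects for phenotyped animals.
#' @slot yAdj numeric, \eqn{y - X\hat b}.
#' @slot logLik numeric, restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot trace data.frame of profiled restricted log-likelihood evaluations.
#' @export
setClass("AnimalModelFit", representation(
  sigma2u = "numeric", sigma2e = "numeric", h2 = "numeric",
  bHat = "numeric", uHat = "numeric", yAdj = "numeric",
  logLik = "numeric", converged = "logical", trace = "data.frame"
))

setValidity("AnimalModelFit", function(object) {
  if (object@sigma2u < 0 || object@sigma2e < 0) "variance components must be >= 0" else TRUE
})

#' Ancestral haplotype-cluster model
#'
#' A fastPHASE-style hidden Markov model with `K` ancestral haplotype states:
#' locus-specific emission probabilities `theta[j, k]` (probability that state
#' `k` carries the alt allele at locus `j`), state weights `alpha`, and a
#' cluster-switch rate `rho` (expected switches per Morgan) converted to
#' per-interval jump probabilities on the 1 Mb = 1 cM map.
#'
#' @slot K integer number of ancestral states.
#' @slot theta numeric matrix (SNPs x K) of alt-allele emission probabilities.
#' @slot alpha numeric length-K state weights (rows normalise to 1).
#' @slot rho numeric, cluster-switch rate per Morgan.
#' @slot logLik numeric vector, EM log-likelihood trace (non-decreasing).
#' @slot map data.frame marker map of the fitted loci.
#' @export
setClass("HaplotypeModel", representation(
  K = "integer", theta = "matrix", alpha = "numeric", rho = "numeric",
  logLik = "numeric", map = "data.frame"
))

setValidity("HaplotypeModel", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (any(object@theta < 0 | object@theta > 1)) msg <- c(msg, "theta must lie in [0, 1]")
  if (abs(sum(object@alpha) - 1) > 1e-8 || any(object@alpha < 0))
    msg <- c(msg, "alpha must be a probability vector")
  if (length(msg)) msg else TRUE
})

#' Per-position ancestral dosage panel
#'
#' For each tested position `i`, the n x K table `H_i` of posterior expected
#' copies (0 to 2) of each ancestral haplotype carried by each animal; every
#' row sums to 2 (both gametes fully attributed). Stored as an array with
#' dimensions (animal, state, position). `permMoments` caches, per position,
#' the matrix invariants of `B = H_i H_i'` needed for the closed-form
#' permutation moments of the score statistic.
#'
#' @slot H numeric array, dim (n animals, K states, m positions).
#' @slot animalIds character.
#' @slot map data.frame with `snp_id`, `chrom`, `pos` of the positions.
#' @slot K integer.
#' @slot permMoments numeric matrix (m x 6), columns
#'   `D1, D2, SB, C, F2, P2` (see [hapScan()]).
#' @export
setClass("DosagePanel", representation(
  H = "array", animalIds = "character", map = "data.frame",
  K = "integer", permMoments = "matrix"
))

setValidity("DosagePanel", function(object) {
  d <- dim(object@H)
  msg <- character()
  if (length(d) != 3L) return("H must have dim (animals, states, positions)")
  if (d[1] != length(object@animalIds)) msg <- c(msg, "animal dimension mismatch")
  if (d[2] != object@K) msg <- c(msg, "state dimension mismatch")
  if (d[3] != nrow(object@map)) msg <- c(msg, "position dimension mismatch")
  if (length(msg)) msg else TRUE
})

#' QTL-detection power grid
#'
#' Power estimates of the SNP-based and haplotype-based scans indexed by
#' (method, MAF class, QTL heritability, distance window), with the
#' underlying replicate-level records (selected QTL, true effect, minimum
#' p-value per window).
#'
#' @slot grid data.frame with columns `method`, `maf_class`, `qtl_h2`,
#'   `window`, `n_rep`, `n_detected`, `power`.
#' @slot replicates data.frame of per-replicate records.
#' @slot config list, the [simulationConfig()] used.
#' @export
setClass("PowerGrid", representation(
  grid = "data.frame", replicates = "data.frame", config = "list"
))
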