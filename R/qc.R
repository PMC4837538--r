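# Genotype quality control: MAF, call rate, exact Hardy-Weinberg test.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (the usual genotype-count exact test, as applied by PLINK by default).
#' Monomorphic input returns 1 by convention.
#'
#' @param nAA,nAa,naa Genotype counts (non-negative; total >= 1).
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # perfectly proportionate, p = 1
#' hweExactTest(50, 0, 50)    # no heterozygotes, p << 0.001
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # heterozygote counts compatible with the allele counts share rare's parity
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Genotype and animal quality control
#'
#' Applies the panel exclusion rules: animals with call rate below
#' `animal_call_rate_min` are removed first; then SNPs with minor allele
#' frequency below `maf_min`, call rate below `call_rate_min`, or exact
#' Hardy-Weinberg p-value below `hwe_p_min` (all computed on non-missing
#' calls of the retained animals) are removed. Filtering a filtered panel
#' changes nothing.
#'
#' @param panel A [GenotypePanel-class].
#' @param maf_min,call_rate_min,hwe_p_min,animal_call_rate_min Thresholds;
#'   defaults are the standard array-QC rules (MAF < 0.01, call rate < 0.95,
#'   HWE p < 0.001 excluded).
#' @return list with elements `panel` (filtered [GenotypePanel-class]) and
#'   `report` (a [QCReport-class]). An error is raised if no SNP survives.
#' @export
qcFilter <- function(panel, maf_min = 0.01, call_rate_min = 0.95,
                     hwe_p_min = 0.001, animal_call_rate_min = 0.95) {
  if (nSnps(panel) == 0L || nAnimals(panel) == 0L) stop("empty panel")
  d <- dosages(panel)
  animal_cr <- 1 - colMeans(is.na(d))
  keepA <- animal_cr >= animal_call_rate_min
  animalStats <- data.frame(animal_id = colnames(d), call_rate = animal_cr,
                            kept = keepA, row.names = NULL)
  d2 <- d[, keepA, drop = FALSE]
  nA <- ncol(d2)
  call_rate <- 1 - rowMeans(is.na(d2))
  n2 <- rowSums(d2 == 2L, na.rm = TRUE)
  n1 <- rowSums(d2 == 1L, na.rm = TRUE)
  n0 <- rowSums(d2 == 0L, na.rm = TRUE)
  tot <- n0 + n1 + n2
  pAlt <- ifelse(tot > 0, (2 * n2 + n1) / (2 * tot), NA_real_)
  maf <- pmin(pAlt, 1 - pAlt)
  hwe <- vapply(seq_along(tot), function(i) {
    if (tot[i] == 0) return(1)
    hweExactTest(n0[i], n1[i], n2[i])
  }, numeric(1))
  keepS <- !is.na(maf) & maf >= maf_min & call_rate >= call_rate_min & hwe >= hwe_p_min
  snpStats <- data.frame(snp_id = rownames(d), maf = maf, call_rate = call_rate,
                         hwe_p = hwe, kept = keepS, row.names = NULL)
  report <- new("QCReport", snpStats = snpStats, animalStats = animalStats,
                thresholds = list(maf_min = maf_min, call_rate_min = call_rate_min,
                                  hwe_p_min = hwe_p_min,
                                  animal_call_rate_min = animal_call_rate_min))
  if (!any(keepS)) stop("quality control removed every SNP")
  map <- markerMap(panel)[keepS, , drop = FALSE]
  out <- GenotypePanel(dosage = d2[keepS, , drop = FALSE], map = map,
                       animalIds = colnames(d2))
  list(panel = out, report = report)
}
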