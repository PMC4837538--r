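# Haplotype-cluster model fitting, ancestral dosages, and the GLASCOW-style
# score test with a gamma-approximated permutation null.

#' Fit the ancestral haplotype-cluster HMM
#'
#' Fits a fastPHASE-style hidden Markov model with `K` ancestral haplotype
#' states to unphased genotypes by EM (forward-backward on the product of
#' two gamete chains), returning the fitted model, the per-position panel of
#' posterior expected ancestral-state copies `H` (each animal's row sums to
#' 2), and the panel with missing genotypes imputed by the posterior-mode
#' genotype. Emission probabilities are locus-specific and updated by EM;
#' state weights are uniform and the cluster-switch rate `rho` is fixed, so
#' the EM log-likelihood trace is non-decreasing. A zero-iteration call
#' returns the (seeded) initialisation.
#'
#' @param panel A QC-passed [GenotypePanel-class].
#' @param K Number of ancestral states (default 20).
#' @param nEmIter EM iterations (default 25).
#' @param rho Cluster-switch rate per Morgan on the 1 Mb = 1 cM map.
#' @param nRestarts Independent EM starts; the best final likelihood is kept.
#' @param seed Integer seed for the random initialisation.
#' @param computeDosages Compute the [DosagePanel-class] (needed for scans).
#' @param hardAssign Report integer posterior-mode state copies in `H`
#'   instead of posterior expectations (sensitivity-analysis mode; rows
#'   still sum to 2).
#' @return list with `model` ([HaplotypeModel-class]), `dosages`
#'   ([DosagePanel-class] or `NULL`), `imputed` ([GenotypePanel-class]).
#' @export
fitHaplotypeHMM <- function(panel, K = 20L, nEmIter = 25L, rho = 20,
                            nRestarts = 1L, seed = NULL, computeDosages = TRUE,
                            hardAssign = FALSE) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > 2L * nAnimals(panel)) stop("K exceeds twice the number of animals")
  map <- markerMap(panel)
  m <- nrow(map)
  G <- dosages(panel)  # m x n
  cm <- map$pos / 1e6
  jump <- numeric(m)
  newChrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
  jump[-1] <- 1 - exp(-rho * diff(cm) / 100)
  blockStart <- c(which(newChrom) - 1L, m)  # 0-based starts for C++
  phat <- rowMeans(G, na.rm = TRUE) / 2
  phat[is.na(phat)] <- 0.5
  alpha <- rep(1 / K, K)

  fitOnce <- function(sd) {
    theta0 <- withSeed(sd, {
      th <- matrix(pmin(pmax(phat + runif(m * K, -0.4, 0.4), 0.02), 0.98), m, K)
      th
    })
    hmm_fit_cpp(G, jump, as.integer(blockStart), theta0, alpha,
                as.integer(nEmIter), computeDosages, TRUE, hardAssign)
  }
  best <- NULL
  for (r in seq_len(max(1L, nRestarts))) {
    fit <- fitOnce(childSeed(seed %||% 0L, r))
    if (is.null(best) || tail(fit$logLik, 1) > tail(best$logLik, 1)) best <- fit
  }
  model <- new("HaplotypeModel", K = K, theta = best$theta, alpha = alpha,
               rho = rho, logLik = as.numeric(best$logLik), map = map)
  dos <- NULL
  if (computeDosages) {
    inv <- perm_invariants_cpp(best$H)
    dos <- new("DosagePanel", H = best$H, animalIds = animalIds(panel),
               map = map[, c("snp_id", "chrom", "pos")], K = K,
               permMoments = inv)
  }
  imp <- GenotypePanel(dosage = best$imputed, map = map,
                       animalIds = animalIds(panel))
  list(model = model, dosages = dos, imputed = imp)
}

#' Null-model residuals for the score test
#'
#' First step of the two-step (GLASCOW-style) haplotype association: fit the
#' intercept-only animal model to the adjusted phenotypes and return
#' \eqn{r = y_{adj} - 1\mu - \hat u}, reused across all tested positions.
#'
#' @param yAdj Adjusted phenotype vector.
#' @param pedigree,A,eigenA Relationship information (see
#'   [fitAnimalModel()]).
#' @return Numeric residual vector with attribute `"fit"` (the
#'   [AnimalModelFit-class]).
#' @export
glascowResiduals <- function(yAdj, pedigree = NULL, A = NULL, eigenA = NULL) {
  fit <- fitAnimalModel(yAdj, fixed = NULL, pedigree = pedigree, A = A,
                        eigenA = eigenA)
  r <- drop(yAdj - fit@bHat[1] - fit@uHat)
  attr(r, "fit") <- fit
  r
}

#' Haplotype score statistic
#'
#' \eqn{T = 0.5\, r' H_i H_i' r = 0.5 \lVert H_i' r\rVert^2}, the sum over
#' ancestral states of squared group deviations between observed and
#' expected phenotypes.
#'
#' @param r Residual vector (see [glascowResiduals()]).
#' @param H n x K ancestral dosage matrix at the tested position.
#' @return Non-negative scalar.
#' @examples
#' scoreStatistic(c(1, -1), diag(2))  # 1
#' @export
scoreStatistic <- function(r, H) {
  H <- as.matrix(H)
  stopifnot(nrow(H) == length(r))
  0.5 * sum(drop(crossprod(H, r))^2)
}

# Exact first two moments of q = x' B x when x is a uniformly random
# permutation of r, from the B invariants (D1, D2, SB, C, F2, P2) and the
# power sums of r. T = q / 2.
.permGammaMoments <- function(inv, r) {
  n <- length(r)
  p1 <- sum(r); p2 <- sum(r^2); p3 <- sum(r^3); p4 <- sum(r^4)
  n2 <- n * (n - 1); n3 <- n2 * (n - 2); n4 <- n3 * (n - 3)
  M11 <- p1^2 - p2
  M22 <- p2^2 - p4
  M31 <- p3 * p1 - p4
  M211 <- p2 * p1^2 - 2 * p1 * p3 - p2^2 + 2 * p4
  M1111 <- p1^4 - 6 * p1^2 * p2 + 3 * p2^2 + 8 * p1 * p3 - 6 * p4
  D1 <- inv[, "D1"]; D2 <- inv[, "D2"]; SB <- inv[, "SB"]
  C <- inv[, "C"]; F2 <- inv[, "F2"]; P2 <- inv[, "P2"]
  SO <- SB - D1
  FO <- F2 - D2
  P2O <- P2 - 2 * C + D2
  Eq <- D1 * p2 / n + SO * M11 / n2
  Eq2 <- D2 * p4 / n + (D1^2 - D2) * M22 / n2 +
    2 * ((D1 * SO - 2 * (C - D2)) * M211 / n3 + 2 * (C - D2) * M31 / n2) +
    (SO^2 - 4 * P2O + 2 * FO) * M1111 / n4 +
    4 * (P2O - FO) * M211 / n3 + 2 * FO * M22 / n2
  cbind(mean = Eq / 2, var = pmax(Eq2 - Eq^2, 0) / 4)
}

# Gamma tail p-value from (mean, var) moment matching; degenerate null
# (variance ~ 0) yields p = 1.
.gammaTail <- function(Tobs, m, v) {
  bad <- !is.finite(v) | v <= 1e-12 * pmax(m^2, 1e-12) | m <= 0
  shape <- ifelse(bad, NA_real_, m^2 / v)
  scale <- ifelse(bad, NA_real_, v / m)
  p <- ifelse(bad, 1, pgamma(Tobs, shape = shape, scale = scale, lower.tail = FALSE))
  p <- pmax(p, 1e-300)
  data.frame(T = Tobs, gamma_shape = shape, gamma_scale = scale, p = pmin(p, 1))
}

#' Gamma-approximated null p-value for the score statistic
#'
#' The null distribution of `T` at a position (no haplotype variance) is
#' approximated by a gamma distribution whose parameters are estimated per
#' position by moment matching (shape = m^2/v, scale = v/m). With
#' `method = "permutation"` the moments come from `nPerm` random
#' permutations of the residuals across animals; with `method = "analytic"`
#' the exact mean and variance of the permutation distribution are computed
#' in closed form (the infinite-permutation limit of the same estimator).
#' The p-value is the upper gamma tail of the observed `T`, floored at the
#' machine tail (never exactly 0); a degenerate null sample yields p = 1.
#'
#' @param Tobs Observed score statistic.
#' @param r Residual vector.
#' @param H n x K ancestral dosage matrix at the position.
#' @param nPerm Number of permutations (>= 100) for
#'   `method = "permutation"`.
#' @param seed Integer seed for the permutations.
#' @param method `"permutation"` (default) or `"analytic"`.
#' @return One-row data.frame with `T`, `gamma_shape`, `gamma_scale`, `p`.
#' @export
gammaNullPvalue <- function(Tobs, r, H, nPerm = 1000L, seed = NULL,
                            method = c("permutation", "analytic")) {
  method <- match.arg(method)
  H <- as.matrix(H)
  stopifnot(nrow(H) == length(r))
  if (method == "permutation") {
    if (nPerm < 100L) stop("'nPerm' must be >= 100")
    Tnull <- withSeed(seed, {
      R <- vapply(seq_len(nPerm), function(i) sample(r), numeric(length(r)))
      0.5 * colSums(crossprod(H, R)^2)
    })
    m <- mean(Tnull)
    v <- var(Tnull)
  } else {
    B <- tcrossprod(H)
    inv <- matrix(c(sum(diag(B)), sum(diag(B)^2), sum(B),
                    sum(diag(B) * rowSums(B)), sum(B^2), sum(rowSums(B)^2)),
                  1, 6, dimnames = list(NULL, c("D1", "D2", "SB", "C", "F2", "P2")))
    mv <- .permGammaMoments(inv, r)
    m <- mv[1, "mean"]; v <- mv[1, "var"]
  }
  .gammaTail(Tobs, m, v)
}

#' Haplotype-cluster score-test scan
#'
#' Second step of the two-step association: computes the score statistic and
#' its gamma-approximated null p-value at every tested position (all SNP
#' positions of the dosage panel). Residuals are taken from
#' [glascowResiduals()] unless supplied directly.
#'
#' @param yAdj Adjusted phenotype vector (ignored when `r` is given).
#' @param dosages A [DosagePanel-class].
#' @param pedigree,A,eigenA Relationship information for the null model.
#' @param r Optional pre-computed residual vector.
#' @param method Gamma-null moment estimation: `"analytic"` (default; exact
#'   permutation moments) or `"permutation"`.
#' @param nPerm,seed Permutation settings for `method = "permutation"`.
#' @param exclude Optional SNP ids or indices to drop from the results.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `T`, `gamma_shape`,
#'   `gamma_scale`, `p`.
#' @export
hapScan <- function(yAdj = NULL, dosages, pedigree = NULL, A = NULL,
                    eigenA = NULL, r = NULL, method = c("analytic", "permutation"),
                    nPerm = 1000L, seed = NULL, exclude = NULL) {
  method <- match.arg(method)
  if (is.null(r)) {
    if (is.null(yAdj)) stop("supply 'yAdj' or 'r'")
    r <- glascowResiduals(yAdj, pedigree = pedigree, A = A, eigenA = eigenA)
  }
  stopifnot(length(r) == nAnimals(dosages))
  Tvec <- hap_scan_T_cpp(dosages@H, as.numeric(r))
  if (method == "analytic") {
    mv <- .permGammaMoments(dosages@permMoments, as.numeric(r))
    res <- .gammaTail(Tvec, mv[, "mean"], mv[, "var"])
  } else {
    m <- dim(dosages@H)[3]
    res <- do.call(rbind, lapply(seq_len(m), function(j) {
      gammaNullPvalue(Tvec[j], as.numeric(r), dosages@H[, , j], nPerm = nPerm,
                      seed = childSeed(seed %||% 0L, j), method = "permutation")
    }))
  }
  out <- cbind(dosages@map, res)
  rownames(out) <- NULL
  if (!is.null(exclude)) {
    drop_ <- if (is.character(exclude)) out$snp_id %in% exclude
             else seq_len(nrow(out)) %in% exclude
    out <- out[!drop_, , drop = FALSE]
  }
  out
}
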