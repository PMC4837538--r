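# Per-SNP mixed-model association on adjusted phenotypes.

#' Prepare the rotated design for repeated SNP scans
#'
#' Rotates the (mean-imputed) SNP dosage matrix and the intercept onto the
#' eigenbasis of the relationship matrix once, so that many scans on the
#' same panel (e.g. power-study replicates) reuse the expensive matrix
#' product.
#'
#' @param panel A QC-passed [GenotypePanel-class].
#' @param A Relationship matrix for the panel animals (ignored when
#'   `eigenA` is given).
#' @param eigenA Optional [eigenRelationship()] result.
#' @return An opaque list used by [snpScan()].
#' @export
prepareSnpScan <- function(panel, A = NULL, eigenA = NULL) {
  if (is.null(eigenA)) {
    if (is.null(A)) stop("supply 'A' or 'eigenA'")
    if (!is.null(rownames(A))) A <- A[animalIds(panel), animalIds(panel)]
    eigenA <- eigenRelationship(A)
  }
  W <- dosages(panel, transpose = TRUE)  # n x m
  # per-SNP mean imputation of missing dosages (GEMMA convention)
  cm <- colMeans(W, na.rm = TRUE)
  nas <- which(is.na(W))
  if (length(nas)) W[nas] <- cm[(nas - 1L) %/% nrow(W) + 1L]
  eaf <- cm / 2
  mono <- apply(W, 2L, function(col) all(col == col[1]))
  U <- eigenA$vectors
  list(UtW = crossprod(U, W), Ut1 = drop(colSums(U)), U = U,
       d = eigenA$values, eaf = eaf, mono = mono, map = markerMap(panel),
       n = nrow(W))
}

#' Per-SNP mixed-model Wald scan
#'
#' Tests each SNP with the model
#' \eqn{y_{adj} = \beta_i w_i + u + e'_i}, \eqn{u \sim N(0, A\sigma_u^2)},
#' re-optimising the variance ratio per SNP by profiled REML on a shared
#' spectral decomposition of A (exact-LMM, as in GEMMA), with an intercept
#' included. Missing dosages are mean-imputed per SNP. The Wald statistic
#' \eqn{(\hat\beta/se)^2} is referred to chi-square with 1 df. The per-SNP
#' proportion of phenotypic variance \eqn{2p(1-p)\beta^2/V_P} uses
#' \eqn{V_P = var(y_{adj})}.
#'
#' @param yAdj Adjusted phenotype vector (animals in panel order).
#' @param panel A QC-passed [GenotypePanel-class] (or `NULL` when
#'   `rotation` is supplied).
#' @param A,eigenA Relationship matrix or its eigen-decomposition.
#' @param rotation Optional [prepareSnpScan()] result (overrides
#'   `panel`/`A`/`eigenA`).
#' @param perSnpLambda `FALSE` fixes the variance ratio at the null-model
#'   optimum instead of re-optimising per SNP (fast approximate mode).
#' @param lambdaGrid Candidate variance ratios for the per-SNP profile.
#' @param exclude Optional SNP ids or indices to drop from the results
#'   (e.g. a masked QTL).
#' @return data.frame with `snp_id`, `chrom`, `pos`, `effect_allele`, `eaf`,
#'   `beta`, `se`, `p`, `lambda`, `proportion`; monomorphic SNPs carry `NA`
#'   results.
#' @export
snpScan <- function(yAdj, panel = NULL, A = NULL, eigenA = NULL,
                    rotation = NULL, perSnpLambda = TRUE,
                    lambdaGrid = exp(seq(log(1e-5), log(1e5), length.out = 61)),
                    exclude = NULL) {
  if (is.null(rotation)) {
    if (is.null(panel)) stop("supply 'panel' or 'rotation'")
    rotation <- prepareSnpScan(panel, A = A, eigenA = eigenA)
  }
  stopifnot(length(yAdj) == rotation$n)
  ty <- drop(crossprod(rotation$U, yAdj))
  lambdaFixed <- -1
  if (!perSnpLambda) {
    fit0 <- .nullLambda(ty, rotation$Ut1, rotation$d)
    lambdaFixed <- fit0
  }
  res <- snp_scan_cpp(rotation$UtW, rotation$Ut1, ty, rotation$d,
                      lambdaGrid, lambdaFixed, rotation$mono)
  vp <- var(yAdj)
  prop <- 2 * rotation$eaf * (1 - rotation$eaf) * res$beta^2 / vp
  capped <- !is.na(prop) & prop > 1
  if (any(capped)) {
    warning(sum(capped), " SNP(s) with variance proportion > 1; capped at 1")
    prop[capped] <- 1
  }
  out <- data.frame(
    snp_id = rotation$map$snp_id, chrom = rotation$map$chrom,
    pos = rotation$map$pos, effect_allele = rotation$map$alt,
    eaf = rotation$eaf, beta = res$beta, se = res$se, p = res$p,
    lambda = res$lambda, proportion = prop, row.names = NULL)
  if (!is.null(exclude)) {
    drop_ <- if (is.character(exclude)) out$snp_id %in% exclude
             else seq_len(nrow(out)) %in% exclude
    out <- out[!drop_, , drop = FALSE]
  }
  out
}

# Null-model (intercept-only) variance ratio on rotated data.
.nullLambda <- function(ty, t1, d) {
  obj <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    a <- sum(w * t1^2); b <- sum(w * t1 * ty)
    rss <- sum(w * ty^2) - b^2 / a
    0.5 * (sum(log(lam * d + 1)) + (length(ty) - 1) * log(rss) + log(a))
  }
  exp(optimize(obj, interval = log(c(1e-6, 1e4)))$minimum)
}

#' Proportion of phenotypic variance explained by a SNP
#'
#' \eqn{2 p (1 - p) \beta^2 / V_P}, reported capped at 1 with a warning if
#' the formula exceeds 1.
#'
#' @param p Allele frequency in (0, 1).
#' @param beta Allele substitution effect.
#' @param VP Phenotypic variance (> 0).
#' @return Numeric fraction in `[0, 1]`.
#' @examples
#' proportionVariance(0.5, 1, 2)  # 0.25
#' @export
proportionVariance <- function(p, beta, VP) {
  if (any(VP <= 0)) stop("'VP' must be > 0")
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  out <- 2 * p * (1 - p) * beta^2 / VP
  if (any(out > 1)) {
    warning("variance proportion exceeds 1; capped")
    out <- pmin(out, 1)
  }
  out
}
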