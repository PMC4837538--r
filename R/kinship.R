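# Pedigree inbreeding (Meuwissen-Luo) and the numerator relationship matrix.

# Internal: integer parent indices (0 = unknown) in pedigree order.
.parentIdx <- function(pedigree) {
  pos <- setNames(seq_along(pedigree@id), pedigree@id)
  s <- ifelse(is.na(pedigree@sire), 0L, pos[pedigree@sire])
  d <- ifelse(is.na(pedigree@dam), 0L, pos[pedigree@dam])
  cbind(sire = as.integer(s), dam = as.integer(d))
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the pedigree inbreeding coefficient of every animal without
#' storing the full relationship matrix, by building, per animal, the row of
#' the Cholesky factor L over its ancestors together with the
#' within-family (Mendelian sampling) variances D:
#' \eqn{F_i + 1 = \sum_j L_{ij}^2 D_j}.
#'
#' @param pedigree A [Pedigree-class] (topologically ordered by validity).
#' @return Named numeric vector of inbreeding coefficients (0 for founders).
#' @export
pedigreeInbreeding <- function(pedigree) {
  p <- .parentIdx(pedigree)
  n <- length(pedigree)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- p[i, 1]; d <- p[i, 2]
    Fs <- if (s > 0L) F[s] else -1
    Fd <- if (d > 0L) F[d] else -1
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s == 0L && d == 0L) { F[i] <- 0; next }
    # accumulate L-row of animal i over its ancestors
    L <- numeric(i)
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      sj <- p[j, 1]; dj <- p[j, 2]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * lj
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * lj
      acc <- acc + lj * lj * D[j]
    }
    F[i] <- acc - 1
  }
  setNames(F, pedigree@id)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the full additive relationship matrix A by the tabular recursion:
#' \eqn{a_{ij} = (a_{j,s_i} + a_{j,d_i})/2} for j < i and
#' \eqn{a_{ii} = 1 + a_{s_i d_i}/2}. The diagonal equals 1 + F.
#'
#' @param pedigree A [Pedigree-class].
#' @return Symmetric numeric matrix with animal-id dimnames and attribute
#'   `"F"` (the inbreeding vector, diagonal minus 1).
#' @export
relationshipMatrix <- function(pedigree) {
  p <- .parentIdx(pedigree)
  n <- length(pedigree)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p[i, 1]; d <- p[i, 2]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(pedigree@id, pedigree@id)
  attr(A, "F") <- diag(A) - 1
  A
}
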