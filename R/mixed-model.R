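# Animal-model REML: y = Xb + u + e, u ~ N(0, A su2), e ~ N(0, I se2),
# one record per animal. The restricted likelihood is profiled on the
# spectral decomposition of A, leaving a one-dimensional optimisation over
# the variance ratio lambda = su2 / se2, which is solved exactly by Brent
# search on log(lambda); the restricted log-likelihood is therefore
# monotone along the optimisation path by construction.

# Build a fixed-effect design matrix: NULL -> intercept; data.frame ->
# intercept + treatment contrasts; matrix -> used as is.
.designMatrix <- function(fixed, n) {
  if (is.null(fixed)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.matrix(fixed)) {
    stopifnot(nrow(fixed) == n)
    return(fixed)
  }
  stopifnot(is.data.frame(fixed), nrow(fixed) == n)
  fixed[] <- lapply(fixed, function(col) if (is.character(col)) factor(col) else col)
  X <- model.matrix(~ ., data = fixed)
  # drop aliased columns so X has full column rank
  q <- qr(X)
  X[, q$pivot[seq_len(q$rank)], drop = FALSE]
}

#' Eigen-decomposition of a relationship matrix
#'
#' Symmetric eigen-decomposition with a small diagonal jitter (at most 1e-8)
#' when the matrix is numerically singular; reusable across REML fits and
#' scans on the same animals.
#'
#' @param A Symmetric relationship matrix.
#' @return list with `values`, `vectors`, `ids` (rownames of `A`).
#' @export
eigenRelationship <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    e <- eigen(A + diag(1e-8, nrow(A)), symmetric = TRUE)
    if (min(e$values) <= 0) stop("relationship matrix is not positive definite")
  }
  list(values = e$values, vectors = e$vectors, ids = rownames(A))
}

# Profiled restricted log-likelihood at variance ratio lambda, in rotated
# coordinates (ty = U'y, tX = U'X, d = eigenvalues).
.remlProfile <- function(lambda, ty, tX, d) {
  n <- length(ty); p <- ncol(tX)
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(tX, tX * w)
  XtWy <- crossprod(tX, ty * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  b <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- sum(w * ty^2) - sum(XtWy * b)
  if (rss <= 0) rss <- 1e-300
  sigma2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2e) + 1) + sum(log(lambda * d + 1)) +
                  2 * sum(log(diag(ch))))
  list(ll = ll, b = drop(b), sigma2e = sigma2e, w = w, chol = ch)
}

#' Fit the animal model by REML
#'
#' Estimates the polygenic and residual variances, fixed effects (GLS),
#' polygenic BLUPs and adjusted phenotypes \eqn{y_{adj} = y - X\hat b}.
#' Animals without a phenotype may appear in the pedigree; the model uses
#' the relationship sub-matrix of the phenotyped animals (one record each).
#'
#' @param y Named numeric phenotype vector (names = animal ids; unnamed is
#'   allowed when `A`'s rows align with `y`).
#' @param fixed `NULL` (intercept only), a data.frame of fixed-effect
#'   factors/covariates aligned with `y`, or a full-rank design matrix
#'   including the intercept.
#' @param pedigree A [Pedigree-class] (used to build `A` when not supplied).
#' @param A Optional numerator relationship matrix.
#' @param eigenA Optional pre-computed [eigenRelationship()] of the
#'   phenotyped-animal sub-matrix (fastest path for repeated fits).
#' @param lambdaRange Search range for the variance ratio
#'   \eqn{\sigma_u^2/\sigma_e^2}.
#' @param tol Relative tolerance of the Brent search.
#' @return An [AnimalModelFit-class].
#' @export
fitAnimalModel <- function(y, fixed = NULL, pedigree = NULL, A = NULL,
                           eigenA = NULL, lambdaRange = c(1e-6, 1e4),
                           tol = 1e-10) {
  n <- length(y)
  X <- .designMatrix(fixed, n)
  if (is.null(eigenA)) {
    if (is.null(A)) {
      if (is.null(pedigree)) stop("supply one of 'pedigree', 'A' or 'eigenA'")
      A <- relationshipMatrix(pedigree)
    }
    if (!is.null(names(y)) && !is.null(rownames(A))) {
      if (!all(names(y) %in% rownames(A))) stop("phenotyped animals missing from A")
      A <- A[names(y), names(y)]
    } else if (nrow(A) != n) stop("A does not match the phenotype vector")
    eigenA <- eigenRelationship(A)
  }
  d <- eigenA$values
  U <- eigenA$vectors
  if (length(d) != n) stop("eigenA does not match the phenotype vector")
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)

  evals <- new.env(); evals$log <- list()
  obj <- function(loglam) {
    r <- .remlProfile(exp(loglam), ty, tX, d)
    evals$log[[length(evals$log) + 1L]] <- c(lambda = exp(loglam), ll = r$ll)
    -r$ll
  }
  opt <- optimize(obj, interval = log(lambdaRange), tol = tol)
  # compare against the boundary (no polygenic variance)
  cand <- exp(opt$minimum)
  prof <- .remlProfile(cand, ty, tX, d)
  prof0 <- .remlProfile(lambdaRange[1] * 1e-2, ty, tX, d)
  if (prof0$ll > prof$ll) { cand <- 0; prof <- prof0 }
  lambda <- cand
  sigma2e <- prof$sigma2e
  sigma2u <- lambda * sigma2e
  b <- prof$b
  names(b) <- colnames(X)
  resid_rot <- ty - tX %*% b
  shrink <- lambda * d / (lambda * d + 1)
  uHat <- drop(U %*% (shrink * resid_rot))
  names(uHat) <- names(y)
  yAdj <- drop(y - X %*% b)
  names(yAdj) <- names(y)
  tr <- do.call(rbind, evals$log)
  new("AnimalModelFit",
      sigma2u = sigma2u, sigma2e = sigma2e,
      h2 = sigma2u / (sigma2u + sigma2e),
      bHat = b, uHat = uHat, yAdj = yAdj,
      logLik = prof$ll, converged = TRUE,
      trace = as.data.frame(tr))
}

#' Adjust phenotypes for fixed effects
#'
#' The exact affine residual \eqn{y_{adj} = y - X\hat b}; no rescaling.
#'
#' @param y Phenotype vector.
#' @param X Design matrix (rows aligned with `y`).
#' @param bHat Fixed-effect estimates (length `ncol(X)`).
#' @return Numeric vector of adjusted phenotypes.
#' @export
adjustPhenotypes <- function(y, X, bHat) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == length(bHat))
  drop(y - X %*% bHat)
}
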