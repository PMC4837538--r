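test_that("K = 1 collapses to a single ancestral state with dosage 2", {
  pop <- smallPop()
  sub <- pop$panel[1:50, ]
  hmm <- fitHaplotypeHMM(sub, K = 1, nEmIter = 3, seed = 1)
  H <- hmm$dosages@H
  expect_equal(dim(H), c(nAnimals(sub), 1L, 50L))
  expect_true(all(abs(H - 2) < 1e-12))
})

test_that("EM log-likelihood is non-decreasing and K bounds are enforced", {
  pop <- smallPop()
  sub <- pop$panel[1:120, ]
  hmm <- fitHaplotypeHMM(sub, K = 6, nEmIter = 12, seed = 2)
  ll <- hmm$model@logLik
  expect_equal(length(ll), 13L)  # 12 iterations + final pass
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
  expect_error(fitHaplotypeHMM(sub, K = 2 * nAnimals(sub) + 1), "twice")
  # zero-iteration call returns the initialisation likelihood only
  hmm0 <- fitHaplotypeHMM(sub, K = 6, nEmIter = 0, seed = 2)
  expect_equal(length(hmm0$model@logLik), 1L)
})

test_that("every H_i row sums to 2 (conservation of gametes)", {
  pop <- smallPop()
  sub <- pop$panel[1:80, ]
  masked <- maskMissing(sub, 0.05, seed = 3)
  hmm <- fitHaplotypeHMM(masked, K = 5, nEmIter = 8, seed = 4)
  H <- hmm$dosages@H
  rs <- apply(H, c(1, 3), sum)
  expect_lt(max(abs(rs - 2)), 1e-9)
  expect_true(all(H >= -1e-12 & H <= 2 + 1e-12))
})

test_that("hard-assignment dosages are integer copy counts summing to 2", {
  pop <- smallPop()
  sub <- pop$panel[1:60, ]
  hmm <- fitHaplotypeHMM(sub, K = 4, nEmIter = 5, seed = 31, hardAssign = TRUE)
  H <- hmm$dosages@H
  expect_true(all(H %in% c(0, 1, 2)))
  expect_true(all(apply(H, c(1, 3), sum) == 2))
})

test_that("two divergent ancestral pools are recovered by K = 2", {
  set.seed(5)
  m <- 200; nPer <- 30
  thA <- rbinom(m, 1, 0.5) * 0.9 + 0.05
  thB <- (1 - (thA > 0.5)) * 0.9 + 0.05
  gen <- function(th, n) {
    vapply(seq_len(n), function(i)
      as.integer(rbinom(m, 1, th) + rbinom(m, 1, th)), integer(m))
  }
  G <- cbind(gen(thA, nPer), gen(thB, nPer))
  panel <- toyPanel(G, pos = sort(sample.int(2e7, m)))
  hmm <- fitHaplotypeHMM(panel, K = 2, nEmIter = 30, seed = 6)
  H <- hmm$dosages@H
  dominant <- apply(apply(H, c(1, 2), mean), 1, which.max)
  origin <- rep(1:2, each = nPer)
  agreement <- max(mean(dominant == origin), mean(dominant == 3 - origin))
  expect_gt(agreement, 0.9)
})

test_that("HMM imputation beats the major-allele baseline", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  masked <- maskMissing(qc, 0.05, seed = 7)
  hmm <- fitHaplotypeHMM(masked, K = 10, nEmIter = 12, seed = 8)
  d0 <- dosages(qc); dm <- dosages(masked); di <- dosages(hmm$imputed)
  mi <- is.na(dm)
  acc <- mean(di[mi] == d0[mi])
  pj <- rowMeans(d0) / 2
  major <- ifelse(pj > 2 / 3, 2L, ifelse(pj < 1 / 3, 0L, 1L))
  base <- mean(matrix(major, nrow(d0), ncol(d0))[mi] == d0[mi])
  expect_gt(acc, base)
  expect_false(anyNA(di))
})

test_that("glascowResiduals match a direct mixed-model-equation solve", {
  ped <- generatePedigree(data.frame(male = c(2, 4), female = c(3, 6)), seed = 9)
  A <- relationshipMatrix(ped)
  y <- simulateBasePhenotype(ped, h2 = 0.5, seed = 10)
  r <- glascowResiduals(y, A = A)
  fit <- attr(r, "fit")
  # Henderson MME oracle at the fitted variance ratio
  n <- length(y)
  lam <- fit@sigma2u / fit@sigma2e
  X <- matrix(1, n, 1)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + solve(A) / lam))
  sol <- solve(lhs, c(sum(y), y))
  expect_equal(unname(fit@bHat[1]), unname(sol[1]), tolerance = 1e-6)
  expect_equal(unname(fit@uHat), unname(sol[-1]), tolerance = 1e-6)
  expect_equal(as.numeric(r), as.numeric(y) - unname(sol[1]) - unname(sol[-1]),
               tolerance = 1e-6)
  # constant phenotype -> zero residuals
  y0 <- setNames(rep(2.5, n), names(y))
  expect_lt(max(abs(glascowResiduals(y0, A = A))), 1e-8)
})

test_that("scoreStatistic equals hand matrix arithmetic", {
  expect_equal(scoreStatistic(c(0, 0, 0), matrix(1, 3, 2)), 0)
  expect_equal(scoreStatistic(c(1, -1), diag(2)), 1)
  expect_equal(scoreStatistic(c(2, 0), rbind(c(2, 0), c(0, 2))), 8)
  # invariance to permuting state labels (columns)
  set.seed(11)
  H <- matrix(runif(40, 0, 2), 10, 4)
  r <- rnorm(10)
  expect_equal(scoreStatistic(r, H), scoreStatistic(r, H[, c(3, 1, 4, 2)]))
})

test_that("gamma moment matching follows the stated identities", {
  # shape = m^2/v, scale = v/m: m = 2, v = 2 -> shape 2, scale 1
  out <- SnpHapPower:::.gammaTail(1.5, 2, 2)
  expect_equal(out$gamma_shape, 2)
  expect_equal(out$gamma_scale, 1)
  # shape 1, scale 1 is Exp(1): p = exp(-T)
  e1 <- SnpHapPower:::.gammaTail(0, 1, 1)
  expect_equal(e1$p, 1)
  e2 <- SnpHapPower:::.gammaTail(log(2), 1, 1)
  expect_equal(e2$p, 0.5)
  # degenerate null
  dg <- SnpHapPower:::.gammaTail(3, 2, 0)
  expect_equal(dg$p, 1)
})

test_that("analytic permutation moments equal exhaustive enumeration", {
  set.seed(12)
  for (rep_ in 1:3) {
    n <- 6; K <- 2 + rep_
    H <- matrix(runif(n * K, 0, 2), n, K)
    r <- rnorm(n)
    B <- tcrossprod(H)
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == n), ]
    Ts <- apply(perms, 1, function(p) 0.5 * drop(r[p] %*% B %*% r[p]))
    inv <- matrix(c(sum(diag(B)), sum(diag(B)^2), sum(B),
                    sum(diag(B) * rowSums(B)), sum(B^2), sum(rowSums(B)^2)),
                  1, 6, dimnames = list(NULL, c("D1", "D2", "SB", "C", "F2", "P2")))
    mv <- SnpHapPower:::.permGammaMoments(inv, r)
    expect_equal(unname(mv[1, "mean"]), mean(Ts), tolerance = 1e-10)
    expect_equal(unname(mv[1, "var"]),
                 mean((Ts - mean(Ts))^2), tolerance = 1e-8)
  }
})

test_that("analytic and sampled permutation moments agree on real dosages", {
  pop <- smallPop()
  hmm <- fitHaplotypeHMM(pop$panel[1:60, ], K = 4, nEmIter = 6, seed = 13)
  H <- ancestralDosages(hmm$dosages, 30)
  r <- withr::with_seed(14, rnorm(nrow(H)))
  a <- gammaNullPvalue(10, r, H, method = "analytic")
  p <- gammaNullPvalue(10, r, H, nPerm = 4000, seed = 15, method = "permutation")
  expect_equal(a$gamma_shape * a$gamma_scale, p$gamma_shape * p$gamma_scale,
               tolerance = 0.05)  # means agree within Monte-Carlo error
  expect_error(gammaNullPvalue(1, r, H, nPerm = 50), "nPerm")
})

test_that("null score-test p-values are uniform at a fixed position", {
  pop <- smallPop()
  hmm <- fitHaplotypeHMM(pop$panel[1:100, ], K = 6, nEmIter = 8, seed = 16)
  H <- ancestralDosages(hmm$dosages, 50)
  n <- nrow(H)
  ps <- vapply(1:500, function(i) {
    r <- withr::with_seed(2000 + i, rnorm(n))
    r <- r - mean(r)
    gammaNullPvalue(scoreStatistic(r, H), r, H, method = "analytic")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("null score-test statistics match the fitted gamma in the body", {
  pop <- smallPop()
  hmm <- fitHaplotypeHMM(pop$panel[1:100, ], K = 6, nEmIter = 8, seed = 17)
  H <- ancestralDosages(hmm$dosages, 80)
  r <- withr::with_seed(18, rnorm(nrow(H)))
  r <- r - mean(r)
  Tnull <- withr::with_seed(19, vapply(1:2000, function(i)
    scoreStatistic(sample(r), H), numeric(1)))
  g <- gammaNullPvalue(1, r, H, method = "analytic")
  ecdfT <- ecdf(Tnull)
  grid <- quantile(Tnull, seq(0.02, 0.98, by = 0.02))
  kol <- max(abs(ecdfT(grid) -
                   pgamma(grid, shape = g$gamma_shape, scale = g$gamma_scale)))
  expect_lt(kol, 0.05)
})

test_that("hapScan flags constant dosage panels and localises planted effects", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  hmm <- fitHaplotypeHMM(qc, K = 8, nEmIter = 10, seed = 20)
  # identical H across animals (K = 1 limit): T constant, p = 1 everywhere
  hmm1 <- fitHaplotypeHMM(qc[1:30, ], K = 1, nEmIter = 2, seed = 21)
  y <- simulateBasePhenotype(pop$ped, h2 = 0.3, seed = 22)
  sc1 <- hapScan(y, dosages = hmm1$dosages, eigenA = pop$eigenA)
  expect_true(all(sc1$p == 1))
  # strong planted haplotype effect: minimum p at or adjacent to the locus
  d <- dosages(qc)
  p <- rowMeans(d) / 2
  qi <- which(pmin(p, 1 - p) > 0.3)[25]
  beta <- sqrt(0.25 / (2 * p[qi] * (1 - p[qi])))
  y2 <- sqrt(0.75) * as.numeric(y) + beta * d[qi, ]
  names(y2) <- names(y)
  fit <- fitAnimalModel(y2, eigenA = pop$eigenA)
  sc2 <- hapScan(fit@yAdj, dosages = hmm$dosages, eigenA = pop$eigenA)
  top <- sc2$pos[which.min(sc2$p)]
  expect_lt(abs(top - markerMap(qc)$pos[qi]), 1.5e6)
  # T is invariant to state relabelling by construction (columns of H)
  Hq <- ancestralDosages(hmm$dosages, qi)
  rr <- glascowResiduals(fit@yAdj, eigenA = pop$eigenA)
  expect_equal(scoreStatistic(rr, Hq), scoreStatistic(rr, Hq[, sample(ncol(Hq))]))
})
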