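test_that("hweExactTest matches direct enumeration", {
  # independent oracle: enumerate all heterozygote counts given allele counts
  hweEnum <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
    if (nA == 0 || na == 0) return(1)
    hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
    pr <- vapply(hets, function(h) {
      choose(n, (nA - h) / 2) * choose(n - (nA - h) / 2, h) *
        choose(n - (nA - h) / 2 - h, (na - h) / 2) * 2^h
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[hets == nAa] * (1 + 1e-12)])
  }
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 5, 3), c(1, 10, 30),
                c(0, 2, 98), c(3, 0, 1))
  for (cs in cases)
    expect_equal(hweExactTest(cs[1], cs[2], cs[3]),
                 hweEnum(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  expect_equal(hweExactTest(0, 0, 50), 1)   # monomorphic
  expect_lt(hweExactTest(50, 0, 50), 1e-20) # total heterozygote deficit
  expect_error(hweExactTest(-1, 0, 3))
})

test_that("hweExactTest controls type-I error at alpha = 0.001 under HWE", {
  set.seed(31)
  nsim <- 10000; n <- 150
  rej <- 0
  for (i in seq_len(nsim)) {
    p <- runif(1, 0.05, 0.95)
    g <- rbinom(n, 2, p)
    if (hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.001)
      rej <- rej + 1
  }
  # exact test is conservative: super-uniform p-values
  expect_lte(rej / nsim, 0.0025)
})

test_that("qcFilter applies the exclusion rules and is idempotent", {
  set.seed(5)
  n <- 100
  good <- matrix(rbinom(30 * n, 2, 0.4), 30, n)
  mono <- matrix(0L, 1, n)                       # MAF 0
  rare <- matrix(0L, 1, n)                       # one carrier: MAF = 0.005
  rare[1, 1] <- 1L
  lowcall <- matrix(rbinom(n, 2, 0.4), 1, n)
  lowcall[1, 1:6] <- NA                          # 6% missing
  hweviol <- matrix(rep(c(0L, 2L), n / 2), 1, n) # no hets at p = 0.5
  d <- rbind(good, mono, rare, lowcall, hweviol)
  panel <- toyPanel(d)
  res <- qcFilter(panel)
  kept <- keptSnps(res$report)
  expect_setequal(kept, paste0("s", 1:30))
  expect_equal(nSnps(res$panel), 30L)
  st <- res$report@snpStats
  expect_false(st$kept[st$snp_id == "s31"])  # monomorphic
  expect_false(st$kept[st$snp_id == "s32"])  # MAF
  expect_false(st$kept[st$snp_id == "s33"])  # call rate
  expect_false(st$kept[st$snp_id == "s34"])  # HWE
  expect_lt(st$hwe_p[st$snp_id == "s34"], 0.001)
  # idempotence
  res2 <- qcFilter(res$panel)
  expect_identical(dosages(res2$panel), dosages(res$panel))
  # animal filter precedes SNP filter
  d2 <- d[1:30, ]
  d2[, 1] <- NA
  res3 <- qcFilter(toyPanel(d2))
  expect_equal(sum(res3$report@animalStats$kept), n - 1L)
  expect_equal(ncol(dosages(res3$panel)), n - 1L)
  expect_error(qcFilter(toyPanel(mono)), "every SNP")
})

test_that("Meuwissen-Luo inbreeding equals the tabular diagonal minus one", {
  expect_equal(unname(pedigreeInbreeding(fullSibPedigree())["x"]), 0.25)
  expect_equal(unname(pedigreeInbreeding(halfSibPedigree())["x"]), 0.125)
  ped <- fullSibPedigree()
  A <- relationshipMatrix(ped)
  expect_true(isSymmetric(A))
  expect_equal(unname(diag(A)[1:4]), rep(1, 4))  # founders
  expect_true(all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0))
  for (sd in 1:50) {
    rp <- randomPedigree(nGen = sample(2:5, 1), seed = sd)
    expect_equal(pedigreeInbreeding(rp),
                 setNames(diag(relationshipMatrix(rp)) - 1, animalIds(rp)),
                 tolerance = 1e-12)
  }
})

test_that("ldR2 matches hand arithmetic and its invariances", {
  g1 <- c(0, 0, 1, 1, 2, 2); g2 <- c(0, 1, 0, 1, 2, 2)
  expect_equal(ldR2(g1, g2), cor(g1, g2)^2)
  expect_equal(ldR2(g1, g1), 1)
  expect_equal(ldR2(g1, 2 - g1), 1)          # perfect negative correlation
  expect_equal(ldR2(g1, 2 - g2), ldR2(g1, g2))  # allele relabelling
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(ldR2(g1[perm], g2[perm]), ldR2(g1, g2))  # animal permutation
  expect_true(is.na(ldR2(c(1, 1, 1), c(0, 1, 2))))      # monomorphic
  expect_true(is.na(ldR2(c(0, NA, NA), c(0, 1, 2))))    # < 2 complete pairs
  expect_equal(ldR2(c(0, 0, 1, 2, NA), c(0, 1, NA, 2, 2)),
               cor(c(0, 0, 2), c(0, 1, 2))^2)            # pairwise exclusion
})

test_that("ldDecayCurve bins pairs and averages across chromosomes", {
  # two perfectly correlated SNPs 500 bp apart -> one occupied bin, mean 1
  d <- matrix(rep(c(0L, 1L, 2L), each = 2), 2, 30)[, sample(30)]
  d <- rbind(d[1, ], d[1, ])
  panel <- toyPanel(d, pos = c(1000L, 1500L))
  cur <- ldDecayCurve(panel, maxDist = 1e4, binBp = 1000)
  expect_equal(sum(cur$n_pairs), 1)
  expect_equal(cur$mean_r2[cur$n_pairs > 0], 1)
  expect_true(all(is.na(cur$mean_r2[cur$n_pairs == 0])))
  # independent SNPs: curve flat near E[r2] ~ 1/n
  set.seed(21)
  n <- 836; m <- 120
  ind <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), m, n)
  cur2 <- ldDecayCurve(toyPanel(ind, pos = sort(sample.int(5e6, m))),
                       maxDist = 5e6, binBp = 5e5)
  mean_r2 <- sum(cur2$mean_r2 * cur2$n_pairs, na.rm = TRUE) / sum(cur2$n_pairs)
  expect_lt(abs(mean_r2 - 1 / n), 3 / n)
  # unweighted cross-chromosome averaging
  pc <- attr(cur2, "per_chrom")
  expect_equal(ncol(pc), 1L)
  expect_error(ldDecayCurve(toyPanel(ind[1, , drop = FALSE])), "two SNPs")
})

test_that("calibrated panels show monotone LD decay with distance", {
  pop <- smallPop()
  cur <- ldDecayCurve(pop$panel, maxDist = 8e6, binBp = 1e6)
  r2 <- cur$mean_r2[cur$n_pairs > 50]
  expect_true(all(diff(r2) < 0.015))  # non-increasing up to binning noise
  expect_gt(r2[1], tail(r2, 1))
})
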