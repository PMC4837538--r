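test_that("bonferroniThreshold reproduces the genome-wide thresholds", {
  expect_equal(signif(bonferroniThreshold(38128), 3), 1.31e-6)
  expect_equal(bonferroniThreshold(1), 0.05)
  expect_equal(bonferroniThreshold(1000, 0.01), 1e-5)
  expect_error(bonferroniThreshold(0), ">= 1")
})

test_that("simulationConfig carries the study defaults and rejects typos", {
  cfg <- simulationConfig()
  expect_equal(cfg$h2_base, 0.30)
  expect_equal(cfg$VP_base, 1)
  expect_equal(cfg$qtl_h2_grid, c(0.01, 0.03, 0.05, 0.07, 0.10, 0.15))
  expect_equal(cfg$n_replicates, 100L)
  expect_equal(signif(cfg$genomewide_p, 3), 1.31e-6)
  expect_equal(cfg$suggestive_p, 5e-5)
  expect_equal(names(cfg$maf_classes), c("low", "high"))
  expect_error(simulationConfig(replicates = 5), "unknown")
})

test_that("base phenotype follows the inbreeding-adjusted Mendelian sampling", {
  # non-inbred full-sib family: Var(u_off - midparent) = 0.5 su2
  ped <- Pedigree(id = c("s", "d", paste0("k", 1:10000)),
                  sire = c(NA, NA, rep("s", 10000)),
                  dam = c(NA, NA, rep("d", 10000)),
                  sex = c("male", "female", rep("female", 10000)),
                  generation = c(1L, 1L, rep(2L, 10000)))
  y <- simulateBasePhenotype(ped, h2 = 0.3, seed = 1)
  u <- attr(y, "u")
  ms <- u[-(1:2)] - 0.5 * (u["s"] + u["d"])
  expect_equal(var(ms), 0.5 * 0.3, tolerance = 0.05)
  expect_equal(mean(ms), 0, tolerance = 0.02)
  # fully inbred parents: Mendelian sampling variance collapses to zero
  Ffake <- c(s = 1, d = 1, setNames(rep(0, 10000), paste0("k", 1:10000)))
  y2 <- simulateBasePhenotype(ped, F = Ffake, h2 = 0.3, seed = 2)
  u2 <- attr(y2, "u")
  expect_lt(var(u2[-(1:2)] - 0.5 * (u2["s"] + u2["d"])), 1e-20)
  # h2 = 0: y is pure noise with variance ~ VP
  y0 <- simulateBasePhenotype(ped, h2 = 0, seed = 3)
  expect_true(all(attr(y0, "u") == 0))
  expect_equal(var(as.numeric(y0)), 1, tolerance = 0.05)
})

test_that("qtlEffect has the stated magnitude and random sign", {
  expect_equal(abs(qtlEffect(0.5, 0.125, seed = 1)), 0.5)
  expect_equal(abs(qtlEffect(0.1, 0.05, seed = 2)), sqrt(0.05 / 0.18),
               tolerance = 1e-12)
  for (cs in list(c(0.2, 0.01), c(0.45, 0.15), c(0.03, 0.07))) {
    b <- qtlEffect(cs[1], cs[2], seed = 3)
    expect_equal(2 * cs[1] * (1 - cs[1]) * b^2, cs[2], tolerance = 1e-12)
  }
  signs <- vapply(1:200, function(s) sign(qtlEffect(0.5, 0.1, seed = s)),
                  numeric(1))
  expect_gt(mean(signs == 1), 0.35)
  expect_lt(mean(signs == 1), 0.65)
  expect_error(qtlEffect(0, 0.05), "p")
  expect_error(qtlEffect(0.5, 0), "qtlH2")
})

test_that("injectQtl masks the QTL, honours the MAF class and the variance", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  y <- simulateBasePhenotype(pop$ped, h2 = 0.3, seed = 4)
  ids <- animalIds(qc)
  qvars <- vapply(1:60, function(r) {
    inj <- injectQtl(y[ids], qc, c(0.10, 0.5), qtlH2 = 0.05, seed = 40 + r)
    expect_false(inj$qtl$snp_id %in% markerMap(inj$panel)$snp_id)
    expect_equal(nSnps(inj$panel), nSnps(qc) - 1L)
    expect_gt(inj$qtl$maf, 0.10)
    var(inj$qtl$beta * dosages(qc)[inj$qtl$snp_id, ])
  }, numeric(1))
  expect_equal(mean(qvars), 0.05, tolerance = 0.2)
  expect_error(injectQtl(y[ids], qc, c(0.49999, 0.5), 0.05, seed = 1), "MAF")
  # additive mode: difference is exactly beta * w
  inj <- injectQtl(y[ids], qc, c(0.10, 0.5), 0.05, mode = "additive", seed = 5)
  w <- dosages(qc)[inj$qtl$snp_id, ]
  expect_equal(unname(inj$y - y[ids]), unname(inj$qtl$beta * w))
})

test_that("degenerate thresholds give power one and zero", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  cfg <- simulationConfig(n_replicates = 2L, qtl_h2_grid = 0.10,
                          maf_classes = list(high = c(0.10, 0.5)),
                          methods = "snp", seed = 5)
  cfg$genomewide_p <- 1
  g1 <- runPowerGrid(cfg, qc, pop$ped, eigenA = pop$eigenA)
  expect_true(all(powerTable(g1)$power[powerTable(g1)$window == "inner"] == 1))
  cfg$genomewide_p <- 0
  g0 <- runPowerGrid(cfg, qc, pop$ped, eigenA = pop$eigenA)
  expect_true(all(powerTable(g0)$power == 0))
})

test_that("identical seeds reproduce the power grid bit for bit", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  cfg <- simulationConfig(n_replicates = 3L, qtl_h2_grid = c(0.05, 0.15),
                          maf_classes = list(high = c(0.10, 0.5)),
                          methods = "snp", seed = 17)
  g1 <- runPowerGrid(cfg, qc, pop$ped, eigenA = pop$eigenA)
  g2 <- runPowerGrid(cfg, qc, pop$ped, eigenA = pop$eigenA)
  expect_identical(powerTable(g1), powerTable(g2))
  expect_identical(g1@replicates, g2@replicates)
})

test_that("window accounting: union of the three windows equals +/-2 Mb", {
  pop <- smallPop()
  qc <- qcFilter(pop$panel)$panel
  cfg <- simulationConfig(n_replicates = 6L, qtl_h2_grid = 0.15,
                          maf_classes = list(high = c(0.10, 0.5)),
                          methods = "snp", seed = 23)
  g <- runPowerGrid(cfg, qc, pop$ped, eigenA = pop$eigenA)
  reps <- g@replicates
  minAll <- pmin(reps$snp_minp_inner, reps$snp_minp_mid, reps$snp_minp_outer,
                 na.rm = TRUE)
  thr <- cfg$genomewide_p
  detUnion <- (reps$snp_minp_inner < thr) | (reps$snp_minp_mid < thr) |
    (reps$snp_minp_outer < thr)
  detUnion[is.na(detUnion)] <- FALSE
  expect_equal(detUnion, !is.na(minAll) & minAll < thr)
  # windows are disjoint annuli around the QTL
  expect_true(all(is.na(reps$snp_minp_inner) | reps$snp_minp_inner > 0))
})

test_that("callRegions merges by distance and labels by the top SNP", {
  scan0 <- data.frame(snp_id = "a", chrom = 1L, pos = 1e6, p = 0.5)
  expect_equal(nrow(callRegions(scan0)), 0L)
  # 0.8 Mb apart -> one region; 1.2 Mb apart -> two
  sc <- data.frame(snp_id = c("a", "b"), chrom = 1L, pos = c(1e6, 1.8e6),
                   p = c(1e-7, 1e-8))
  expect_equal(nrow(callRegions(sc)), 1L)
  sc2 <- sc; sc2$pos[2] <- 2.2e6
  expect_equal(nrow(callRegions(sc2)), 2L)
  # 10-SNP toy scan against a brute-force single-linkage oracle
  set.seed(6)
  toy <- data.frame(snp_id = letters[1:10], chrom = rep(c(1L, 2L), each = 5),
                    pos = c(sort(sample.int(1e7, 5)), sort(sample.int(1e7, 5))),
                    p = 10^-runif(10, 3, 9))
  got <- callRegions(toy, genomewide_p = 1.31e-6, suggestive_p = 5e-5)
  sig <- toy[toy$p < 5e-5, ]
  oracle <- do.call(rbind, lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$pos), ]
    grp <- 1
    g <- c(1)
    if (nrow(s) > 1)
      for (i in 2:nrow(s)) {
        if (s$pos[i] - s$pos[i - 1] > 1e6) grp <- grp + 1
        g <- c(g, grp)
      }
    do.call(rbind, lapply(split(s, g), function(x)
      data.frame(chrom = x$chrom[1], start = min(x$pos), end = max(x$pos),
                 top_p = min(x$p))))
  }))
  oracle <- oracle[order(oracle$chrom, oracle$start), ]
  expect_equal(got$start, oracle$start)
  expect_equal(got$end, oracle$end)
  expect_equal(got$top_p, oracle$top_p)
  expect_true(all(got$level[got$top_p < 1.31e-6] == "significant"))
  expect_true(all(got$level[got$top_p >= 1.31e-6] == "suggestive"))
  # tie on p resolved towards the smaller position
  tie <- data.frame(snp_id = c("x", "y"), chrom = 1L, pos = c(2e6, 1e6),
                    p = c(1e-8, 1e-8))
  expect_equal(callRegions(tie)$top_snp, "y")
})
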