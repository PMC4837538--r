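test_that("generatePedigree reproduces the study generation sizes", {
  ped <- generatePedigree(seed = 1)
  expect_equal(length(ped), 836L)
  gs <- defaultGenerationSizes()
  tab <- table(generations(ped))
  expect_equal(as.integer(tab), gs$male + gs$female)
  df <- as.data.frame(ped)
  expect_equal(sum(df$sex != "female"), sum(gs$male))
  expect_equal(sum(df$sex == "castrate"), sum(gs$castrate))
  expect_true(validObject(ped))
})

test_that("single-generation pedigrees are all founders", {
  ped <- generatePedigree(data.frame(male = 3, female = 4), seed = 2)
  expect_true(all(isFounder(ped)))
  expect_equal(length(ped), 7L)
})

test_that("with one sire every offspring descends from it", {
  ped <- generatePedigree(data.frame(male = c(1, 5), female = c(2, 5)), seed = 3)
  df <- as.data.frame(ped)
  sire <- df$id[df$sex == "male" & df$generation == 1]
  kids <- df[df$generation == 2, ]
  expect_true(all(kids$sire == sire))
  expect_true(all(kids$dam %in% df$id[df$sex == "female" & df$generation == 1]))
})

test_that("impossible mating constraints fail loudly", {
  expect_error(generatePedigree(data.frame(male = c(0, 3), female = c(2, 3)),
                                seed = 1), "male")
  expect_error(generatePedigree(data.frame(male = c(2, 3), female = c(0, 3)),
                                seed = 1), "female")
})

test_that("matings avoid full-sib pairs when alternatives exist", {
  for (sd in 1:5) {
    ped <- generatePedigree(data.frame(male = c(4, 10, 10),
                                       female = c(6, 10, 10)), seed = sd)
    df <- as.data.frame(ped)
    par <- df[match(df$sire, df$id), c("sire", "dam")]
    parD <- df[match(df$dam, df$id), c("sire", "dam")]
    mated_fs <- !is.na(par$sire) & !is.na(parD$sire) &
      par$sire == parD$sire & par$dam == parD$dam
    expect_false(any(mated_fs, na.rm = TRUE))
  }
})

test_that("founder haplotype edge cases behave as specified", {
  map <- makeMarkerMap(1, 1e6, 50, seed = 1)
  # single ancestral haplotype: all founders identical, panel monomorphic
  pool1 <- makeHaplotypePool(1, map, seed = 2)
  fh <- generateFounderHaplotypes(pool1, 5, seed = 3)
  expect_true(all(fh$h1 == pool1@alleles[1, ]))
  expect_true(all(fh$h2 == pool1@alleles[1, ]))
  # zero switch rate: each haplotype equals one pool haplotype end-to-end
  pool0 <- makeHaplotypePool(6, map, switchRate = 0, seed = 4)
  fh0 <- generateFounderHaplotypes(pool0, 20, seed = 5)
  pools <- t(pool0@alleles)
  for (i in 1:20) {
    expect_true(any(colSums(fh0$h1[, i] != pools) == 0))
    expect_true(any(colSums(fh0$h2[, i] != pools) == 0))
  }
  expect_error(generateFounderHaplotypes(
    new("HaplotypePool", alleles = matrix(integer(), 0, 0), switchRate = 1,
        persistCM = 1, freq = numeric(), map = map), 3), "pool")
})

test_that("gene drop is Mendelian-consistent and respects homozygous parents", {
  pop <- smallPop()
  d <- dosages(pop$panel)
  df <- as.data.frame(pop$ped)
  kids <- which(!is.na(df$sire))
  for (a in sample(kids, 30)) {
    gs <- d[, df$sire[a]]; gd <- d[, df$dam[a]]; go <- d[, df$id[a]]
    # offspring allele from each parent bounded by parental dosage
    lo <- (gs == 2) + (gd == 2)
    hi <- 2 - ((gs == 0) + (gd == 0))
    expect_true(all(go >= lo & go <= hi))
  }
  # direct cross 2/2 x 0/0 -> all offspring dosage 1
  m <- 20
  map <- data.frame(snp_id = paste0("s", 1:m), chrom = 1, pos = 1:m * 1e5)
  ped <- Pedigree(id = c("p1", "p2", "k1", "k2"), sire = c(NA, NA, "p1", "p1"),
                  dam = c(NA, NA, "p2", "p2"),
                  sex = c("male", "female", "male", "female"),
                  generation = c(1L, 1L, 2L, 2L))
  fh <- list(h1 = cbind(rep(1L, m), rep(0L, m)), h2 = cbind(rep(1L, m), rep(0L, m)))
  panel <- geneDrop(ped, fh, map, seed = 1)
  expect_true(all(dosages(panel)[, c("k1", "k2")] == 1L))
})

test_that("recombination fraction matches the Haldane closed form", {
  # two loci 1 cM apart: c = 0.5 (1 - exp(-0.02)) ~ 0.00990
  map <- data.frame(snp_id = c("l", "r"), chrom = 1L, pos = c(1e6, 2e6))
  nk <- 4000L
  ped <- Pedigree(id = c("p1", "p2", paste0("k", 1:nk)),
                  sire = c(NA, NA, rep("p1", nk)), dam = c(NA, NA, rep("p2", nk)),
                  sex = c("male", "female", rep("female", nk)),
                  generation = c(1L, 1L, rep(2L, nk)))
  # sire heterozygous in coupling (1-1 / 0-0); dam 0/0 everywhere
  fh <- list(h1 = cbind(c(1L, 1L), c(0L, 0L)), h2 = cbind(c(0L, 0L), c(0L, 0L)))
  panel <- geneDrop(ped, fh, map, seed = 42)
  h <- dosages(panel)[, -(1:2)]
  recomb <- mean(h[1, ] != h[2, ])  # paternal gamete recombinant
  cHaldane <- 0.5 * (1 - exp(-0.02))
  # 99% binomial band around the closed-form value
  band <- 3 * sqrt(cHaldane * (1 - cHaldane) / nk)
  expect_lt(abs(recomb - cHaldane), band + 1e-12)
})

test_that("generation-1 allele frequencies equal founder haplotype frequencies", {
  pop <- smallPop()
  df <- as.data.frame(pop$ped)
  fndr <- df$id[is.na(df$sire)]
  h1 <- SummarizedExperiment::assay(pop$panel, "hap1")[, fndr]
  h2 <- SummarizedExperiment::assay(pop$panel, "hap2")[, fndr]
  freqHap <- rowMeans(cbind(h1, h2))
  freqDos <- rowMeans(dosages(pop$panel)[, fndr]) / 2
  expect_equal(freqDos, freqHap, tolerance = 1e-12)
})

test_that("mean inbreeding starts at zero and increases down a closed line", {
  Fs <- lapply(1:4, function(sd) {
    ped <- generatePedigree(data.frame(male = c(5, 8, 8, 8, 8),
                                       female = c(8, 10, 10, 10, 10)), seed = sd)
    tapply(pedigreeInbreeding(ped), generations(ped), mean)
  })
  Fbar <- Reduce(`+`, Fs) / length(Fs)
  expect_equal(as.numeric(Fbar[1:2]), c(0, 0))
  expect_true(all(diff(Fbar[-1]) > 0))
})

test_that("maskMissing hits the requested rate and leaves the input intact", {
  set.seed(10)
  d <- matrix(rbinom(100 * 100, 2, 0.4), 100, 100)
  panel <- toyPanel(d)
  expect_identical(dosages(maskMissing(panel, 0, seed = 1)), dosages(panel))
  masked <- maskMissing(panel, 0.5, seed = 2)
  frac <- mean(is.na(dosages(masked)))
  # 99% binomial interval around 0.5 with n = 10,000 entries
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / 1e4))
  expect_false(anyNA(dosages(panel)))
  expect_error(maskMissing(panel, 1), "rate")
  expect_error(maskMissing(panel, -0.1), "rate")
})
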