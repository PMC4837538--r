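# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# seven-animal pedigree: two full sibs mated -> inbred offspring (F = 0.25)
fullSibPedigree <- function() {
  Pedigree(id = c("a", "b", "c", "d", "s1", "s2", "x"),
           sire = c(NA, NA, NA, NA, "a", "a", "s1"),
           dam = c(NA, NA, NA, NA, "b", "b", "s2"),
           sex = c("male", "female", "male", "female", "male", "female", "male"),
           generation = c(1L, 1L, 1L, 1L, 2L, 2L, 3L))
}

# half sibs (shared sire, unrelated dams) mated -> F = 0.125
halfSibPedigree <- function() {
  Pedigree(id = c("a", "b", "c", "h1", "h2", "x"),
           sire = c(NA, NA, NA, "a", "a", "h1"),
           dam = c(NA, NA, NA, "b", "c", "h2"),
           sex = c("male", "female", "female", "male", "female", "female"),
           generation = c(1L, 1L, 1L, 2L, 2L, 3L))
}

# random valid pedigree for property tests
randomPedigree <- function(nGen = 4, seed = 1) {
  withr::with_seed(seed, {
    gs <- data.frame(male = sample(2:6, nGen, TRUE),
                     female = sample(3:8, nGen, TRUE))
    generatePedigree(gs, seed = seed + 1L)
  })
}

# small three-generation population with genotypes (memoised; used by
# several module tests)
smallPop <- function() {
  fixture("smallPop", function() {
    ped <- generatePedigree(data.frame(male = c(15, 20, 25),
                                       female = c(20, 30, 40)), seed = 7)
    map <- makeMarkerMap(nChrom = 1L, chromLengthBp = 3e7,
                         nSnpsPerChrom = 400L, seed = 8)
    panel <- simulateGenotypePanel(ped, map, seed = 9)
    A <- relationshipMatrix(ped)
    list(ped = ped, map = map, panel = panel, A = A,
         eigenA = eigenRelationship(A))
  })
}

# tiny unstructured panel from explicit dosages
toyPanel <- function(dosage, pos = NULL, chrom = 1L) {
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom, pos = pos)
  GenotypePanel(dosage, map, paste0("A", seq_len(ncol(dosage))))
}
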