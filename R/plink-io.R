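# PLINK 1.9 PED/MAP and BED/BIM/FAM readers and writers, plus pedigree CSV.
#
# Conventions: BIM columns chrom, id, cM, bp, A1, A2; dosages count the A1
# allele (the panel's alt allele); BED is SNP-major with magic bytes
# 0x6c 0x1b 0x01 and two-bit genotypes 00 = A1/A1, 10 = het, 11 = A2/A2,
# 01 = missing, packed little-endian (first sample in the lowest bits).
# Only pig autosome codes 1-18 are accepted.

.checkChrom <- function(chrom, file) {
  bad <- !(chrom %in% 1:18)
  if (any(bad))
    stop("unsupported chromosome code(s) in ", file, ": ",
         paste(unique(chrom[bad]), collapse = ", "), " (autosomes 1-18 only)")
}

#' Write a genotype panel in PLINK format
#'
#' @param panel A [GenotypePanel-class].
#' @param prefix Output path prefix.
#' @param format `"bed"` (BED/BIM/FAM) or `"ped"` (PED/MAP).
#' @return Invisibly, the paths written.
#' @export
writePlink <- function(panel, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  map <- markerMap(panel)
  .checkChrom(map$chrom, "panel")
  d <- dosages(panel)
  n <- ncol(d); m <- nrow(d)
  ids <- colnames(d)
  if (format == "ped") {
    mapPath <- paste0(prefix, ".map")
    pedPath <- paste0(prefix, ".ped")
    write.table(data.frame(map$chrom, map$snp_id, map$pos / 1e6, map$pos),
                mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    a1 <- map$alt; a2 <- map$ref
    lines <- vapply(seq_len(n), function(i) {
      g <- d[, i]
      al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
      al2 <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
      paste(c("FAM1", ids[i], "0", "0", "0", "-9", rbind(al1, al2)),
            collapse = " ")
    }, character(1))
    writeLines(lines, pedPath)
    return(invisible(c(pedPath, mapPath)))
  }
  bimPath <- paste0(prefix, ".bim")
  famPath <- paste0(prefix, ".fam")
  bedPath <- paste0(prefix, ".bed")
  write.table(data.frame(map$chrom, map$snp_id, map$pos / 1e6, map$pos,
                         map$alt, map$ref),
              bimPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame("FAM1", ids, 0L, 0L, 0L, -9L),
              famPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # two-bit codes per dosage of A1: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, m, n)
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[is.na(d)] <- 1L
  bps <- ceiling(n / 4)
  con <- file(bedPath, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bps - n
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cj <- c(code[j, ], rep(1L, pad))  # pad with missing
    bytes <- colSums(matrix(cj * mult, 4L, bps))
    writeBin(as.raw(bytes), con)
  }
  invisible(c(bedPath, bimPath, famPath))
}

#' Read a genotype panel from PLINK files
#'
#' Accepts a BED/BIM/FAM triple or a PED/MAP pair; the dosage counts the A1
#' (BIM column 5) allele. Missing codes (`0` alleles in PED, `01` in BED)
#' become `NA`.
#'
#' @param prefix Path prefix; `<prefix>.bed` is used if present, else
#'   `<prefix>.ped`.
#' @return A [GenotypePanel-class].
#' @export
readPlink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) return(.readBed(prefix))
  if (file.exists(paste0(prefix, ".ped"))) return(.readPed(prefix))
  stop("no ", prefix, ".bed or ", prefix, ".ped found")
}

.readBed <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer", "character", "character"))
  .checkChrom(bim$chrom, paste0(prefix, ".bim"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file: ", prefix, ".bed (bad magic bytes)")
  if (raw[3] != as.raw(0x01)) stop(prefix, ".bed is not SNP-major")
  bps <- ceiling(n / 4)
  if (length(raw) - 3L != bps * m)
    stop("BED payload size does not match ", prefix, ".bim/.fam dimensions")
  body <- as.integer(raw[-(1:3)])
  codes <- vapply(c(1L, 4L, 16L, 64L), function(m) (body %/% m) %% 4L,
                  integer(length(body)))
  codes <- matrix(t(codes), nrow = 4L * bps)[seq_len(n), , drop = FALSE]
  # codes: n x m; 0 -> 2 copies of A1, 2 -> 1, 3 -> 0, 1 -> NA
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  dosage <- matrix(lut[codes + 1L], nrow = n)
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                    ref = bim$a2, alt = bim$a1)
  GenotypePanel(dosage = t(dosage), map = map, animalIds = fam$V2)
}

.readPed <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"),
                    colClasses = c("integer", "character", "numeric", "integer"))
  .checkChrom(map$chrom, paste0(prefix, ".map"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop(prefix, ".ped has ", ncol(ped), " columns; expected ", 6L + 2L * m,
         " for ", m, " SNPs in ", prefix, ".map")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  # infer ref/alt per SNP: alt = the allele counted by dosage; prefer the
  # lexicographically larger label for determinism when both appear
  dosage <- matrix(NA_integer_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    lv <- sort(unique(obs[obs != "0"]))
    if (length(lv) == 0L) lv <- c("A", "B")
    if (length(lv) == 1L) lv <- c(lv, if (lv == "B") "A" else "B")
    ref[j] <- lv[1]; alt[j] <- lv[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dosage[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    dosage[miss, j] <- NA_integer_
  }
  mp <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                   ref = ref, alt = alt)
  GenotypePanel(dosage = t(dosage), map = mp, animalIds = ids)
}

#' Write / read a pedigree as headered CSV
#'
#' Columns `id`, `sire`, `dam`, `sex`, `generation`; empty fields denote
#' unknown parents.
#'
#' @param pedigree A [Pedigree-class].
#' @param path CSV path.
#' @return `writePedigreeCsv` invisibly returns `path`; `readPedigreeCsv`
#'   returns a [Pedigree-class].
#' @export
writePedigreeCsv <- function(pedigree, path) {
  df <- as.data.frame(pedigree)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
readPedigreeCsv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, colClasses = "character",
                   na.strings = c("", "NA"))
  Pedigree(id = df$id, sire = df$sire, dam = df$dam, sex = df$sex,
           generation = as.integer(df$generation))
}
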