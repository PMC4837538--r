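# Constructors, accessors and show methods.

#' Construct a Pedigree
#'
#' @param id,sire,dam Character vectors; `NA` marks an unknown parent.
#' @param sex Character vector (`"male"`, `"female"`, `"castrate"`).
#' @param generation Integer vector of 1-based generation numbers.
#' @return A [Pedigree-class] object.
#' @examples
#' Pedigree(id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
#'          sex = c("male", "female", "female"), generation = c(1L, 1L, 2L))
#' @export
Pedigree <- function(id, sire, dam, sex, generation) {
  new("Pedigree", id = as.character(id), sire = as.character(sire),
      dam = as.character(dam), sex = as.character(sex),
      generation = as.integer(generation))
}

#' Coerce a Pedigree to a data.frame
#'
#' @param x A [Pedigree-class].
#' @param ... Ignored.
#' @return data.frame with columns `id`, `sire`, `dam`, `sex`, `generation`.
#' @export
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             generation = x@generation, stringsAsFactors = FALSE)
}

#' @describeIn Pedigree Number of animals.
#' @param x A Pedigree.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' @rdname SnpHapPower-generics
#' @export
setMethod("animalIds", "Pedigree", function(x, ...) x@id)

#' @rdname SnpHapPower-generics
#' @export
setMethod("isFounder", "Pedigree", function(x, ...) is.na(x@sire) & is.na(x@dam))

#' @rdname SnpHapPower-generics
#' @export
setMethod("generations", "Pedigree", function(x, ...) x@generation)

setMethod("show", "Pedigree", function(object) {
  tab <- table(object@generation)
  cat(sprintf("Pedigree: %d animals, %d generations (%d founders)\n",
              length(object@id), length(tab), sum(isFounder(object))))
  cat("  per generation:", paste(sprintf("G%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Construct a GenotypePanel
#'
#' @param dosage Integer/numeric matrix, SNPs x animals, values 0/1/2/`NA`.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` and optionally
#'   `ref`, `alt`; one row per row of `dosage`.
#' @param animalIds Character vector of animal ids (defaults to
#'   `colnames(dosage)`).
#' @param hap1,hap2 Optional 0/1 matrices of the two gametes (phased panel).
#' @return A [GenotypePanel-class].
#' @export
GenotypePanel <- function(dosage, map, animalIds = colnames(dosage),
                          hap1 = NULL, hap2 = NULL) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(map))
  if (is.null(animalIds)) animalIds <- paste0("A", seq_len(ncol(dosage)))
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "B"
  mode(dosage) <- "integer"
  dimnames(dosage) <- list(map$snp_id, animalIds)
  al <- list(dosage = dosage)
  if (!is.null(hap1)) {
    stopifnot(!is.null(hap2), all(dim(hap1) == dim(dosage)), all(dim(hap2) == dim(dosage)))
    mode(hap1) <- "integer"; mode(hap2) <- "integer"
    dimnames(hap1) <- dimnames(dosage); dimnames(hap2) <- dimnames(dosage)
    al$hap1 <- hap1; al$hap2 <- hap2
  }
  se <- SummarizedExperiment(
    assays = al,
    rowData = DataFrame(chrom = as.integer(map$chrom), pos = as.integer(map$pos),
                        ref = map$ref, alt = map$alt, row.names = map$snp_id),
    colData = DataFrame(row.names = animalIds))
  new("GenotypePanel", se)
}

#' @rdname SnpHapPower-generics
#' @param transpose For `dosages`, return animals x SNPs instead of the native
#'   SNPs x animals orientation.
#' @export
setMethod("dosages", "GenotypePanel", function(x, transpose = FALSE, ...) {
  d <- assay(x, "dosage")
  if (transpose) t(d) else d
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("markerMap", "GenotypePanel", function(x, ...) {
  rd <- rowData(x)
  data.frame(snp_id = rownames(x), chrom = rd$chrom, pos = rd$pos,
             ref = rd$ref, alt = rd$alt, stringsAsFactors = FALSE)
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("animalIds", "GenotypePanel", function(x, ...) colnames(x))

#' @rdname SnpHapPower-generics
#' @export
setMethod("nAnimals", "GenotypePanel", function(x, ...) ncol(x))

#' @rdname SnpHapPower-generics
#' @export
setMethod("nSnps", "GenotypePanel", function(x, ...) nrow(x))

#' Is the panel phased?
#'
#' @param x A [GenotypePanel-class].
#' @return `TRUE` if gamete assays (`hap1`, `hap2`) are present.
#' @export
isPhased <- function(x) all(c("hap1", "hap2") %in% names(assays(x)))

setMethod("show", "GenotypePanel", function(object) {
  rd <- rowData(object)
  miss <- mean(is.na(assay(object, "dosage")))
  cat(sprintf("GenotypePanel: %d SNPs x %d animals on %d chromosome(s)%s\n",
              nrow(object), ncol(object), length(unique(rd$chrom)),
              if (isPhased(object)) " [phased]" else ""))
  cat(sprintf("  missing rate %.3f%%\n", 100 * miss))
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("keptSnps", "QCReport", function(x, ...) x@snpStats$snp_id[x@snpStats$kept])

#' @rdname SnpHapPower-generics
#' @export
setMethod("keptAnimals", "QCReport", function(x, ...) x@animalStats$animal_id[x@animalStats$kept])

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d/%d SNPs kept, %d/%d animals kept\n",
              sum(object@snpStats$kept), nrow(object@snpStats),
              sum(object@animalStats$kept), nrow(object@animalStats)))
  th <- object@thresholds
  cat(sprintf("  thresholds: MAF >= %g, SNP call rate >= %g, HWE p >= %g, animal call rate >= %g\n",
              th$maf_min, th$call_rate_min, th$hwe_p_min, th$animal_call_rate_min))
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("heritability", "AnimalModelFit", function(x, ...) x@h2)

#' @rdname SnpHapPower-generics
#' @export
setMethod("varianceComponents", "AnimalModelFit", function(x, ...)
  c(sigma2u = x@sigma2u, sigma2e = x@sigma2e))

#' @rdname SnpHapPower-generics
#' @export
setMethod("adjustedPhenotypes", "AnimalModelFit", function(x, ...) x@yAdj)

setMethod("show", "AnimalModelFit", function(object) {
  cat(sprintf("AnimalModelFit: sigma2_u = %.4f, sigma2_e = %.4f, h2 = %.3f (%s)\n",
              object@sigma2u, object@sigma2e, object@h2,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "HaplotypeModel", function(object) {
  cat(sprintf("HaplotypeModel: K = %d ancestral states, %d loci, rho = %.1f switches/Morgan\n",
              object@K, nrow(object@theta), object@rho))
  ll <- object@logLik
  if (length(ll)) cat(sprintf("  EM: %d iterations, logLik %.2f -> %.2f\n",
                              length(ll), ll[1], ll[length(ll)]))
})

#' @rdname SnpHapPower-generics
#' @param position Integer index or SNP id of the tested position.
#' @export
setMethod("ancestralDosages", "DosagePanel", function(x, position, ...) {
  if (is.character(position)) position <- match(position, x@map$snp_id)
  H <- x@H[, , position, drop = TRUE]
  dimnames(H) <- list(x@animalIds, paste0("anc", seq_len(x@K)))
  H
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("nAnimals", "DosagePanel", function(x, ...) dim(x@H)[1])

#' @rdname SnpHapPower-generics
#' @export
setMethod("markerMap", "DosagePanel", function(x, ...) x@map)

setMethod("show", "DosagePanel", function(object) {
  cat(sprintf("DosagePanel: %d animals x %d states at %d positions\n",
              dim(object@H)[1], object@K, dim(object@H)[3]))
})

#' @rdname SnpHapPower-generics
#' @export
setMethod("powerTable", "PowerGrid", function(x, ...) x@grid)

setMethod("show", "PowerGrid", function(object) {
  cat(sprintf("PowerGrid: %d cells, %d replicate records\n",
              nrow(object@grid), nrow(object@replicates)))
  print(head(object@grid, 12))
})
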