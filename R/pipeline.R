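# Config-driven pipeline tying the stages together: simulate -> qc -> hmm ->
# reml -> scans -> power -> regions, with a manifest for exact re-runs.

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(generation_sizes = NULL,  # NULL -> defaultGenerationSizes()
                    n_chrom = 2L, chrom_length_bp = 1e8, n_snps_per_chrom = 1667L,
                    n_anc = 14L, switch_rate = 5, persist_cm = 6, phase_align_prob = 0.7,
                    missing_rate = 0.01, missing_high_rate = 0.08,
                    missing_high_frac = 0.03),
    qc = list(maf_min = 0.01, call_rate_min = 0.95, hwe_p_min = 0.001,
              animal_call_rate_min = 0.95),
    hmm = list(K = 20L, n_em_iter = 25L, rho = 20),
    reml = list(h2 = 0.30, VP = 1),
    power = list(enabled = FALSE, n_replicates = 5L,
                 qtl_h2_grid = c(0.05, 0.15), maf_classes = NULL,
                 methods = c("snp", "hap")),
    regions = list(genomewide_p = 1.31e-6, suggestive_p = 5.0e-5,
                   merge_dist = 1e6))
}

.mergeConfig <- function(base, user, path = "") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]], paste0(path, nm, "$"))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), validates it against the
#' known keys (unknown keys are rejected) and fills defaults.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .mergeConfig(.defaultRunConfig(), config)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on a fresh synthetic population and writes
#' TSV outputs plus a `manifest.json` (seed, package version, config, file
#' checksums) that makes the run exactly reproducible: running the same
#' configuration twice produces identical artifacts.
#'
#' @param config See [readRunConfig()].
#' @param outDir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param verbose Print stage progress.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outDir = NULL, verbose = FALSE) {
  cfg <- readRunConfig(config)
  outDir <- outDir %||% cfg$out_dir
  if (is.null(outDir)) stop("an output directory is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  seed <- cfg$seed
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  say("stage: simulate")
  sc <- cfg$simulate
  gs <- sc$generation_sizes %||% defaultGenerationSizes()
  if (!is.data.frame(gs)) gs <- as.data.frame(gs)
  ped <- generatePedigree(gs, seed = childSeed(seed, 11L))
  map <- makeMarkerMap(sc$n_chrom, sc$chrom_length_bp, sc$n_snps_per_chrom,
                       seed = childSeed(seed, 12L))
  panel <- simulateGenotypePanel(ped, map, nAnc = sc$n_anc,
                                 switchRate = sc$switch_rate,
                                 persistCM = sc$persist_cm,
                                 phaseAlignProb = sc$phase_align_prob,
                                 seed = childSeed(seed, 13L))
  rates <- withSeed(childSeed(seed, 14L), {
    r <- rep(sc$missing_rate, nSnps(panel))
    hi <- runif(nSnps(panel)) < sc$missing_high_frac
    r[hi] <- sc$missing_high_rate
    r
  })
  masked <- maskMissing(panel, rates, seed = childSeed(seed, 15L))
  writePedigreeCsv(ped, file.path(outDir, "pedigree.csv"))
  files <- c(files, file.path(outDir, "pedigree.csv"))

  say("stage: qc")
  qc <- do.call(qcFilter, c(list(masked), cfg$qc))
  emit(qc$report@snpStats, "qc_snps.tsv")
  emit(qc$report@animalStats, "qc_animals.tsv")

  say("stage: hmm")
  hc <- cfg$hmm
  hmm <- fitHaplotypeHMM(qc$panel, K = hc$K, nEmIter = hc$n_em_iter,
                         rho = hc$rho, seed = childSeed(seed, 16L))
  imputed <- hmm$imputed

  say("stage: reml")
  A <- relationshipMatrix(ped)
  ids <- animalIds(imputed)
  eigenA <- eigenRelationship(A[ids, ids])
  y <- simulateBasePhenotype(ped, h2 = cfg$reml$h2, VP = cfg$reml$VP,
                             seed = childSeed(seed, 17L))[ids]
  pedDf <- as.data.frame(ped)
  rownames(pedDf) <- pedDf$id
  fixedDf <- data.frame(sex = factor(pedDf[ids, "sex"]),
                        generation = factor(pedDf[ids, "generation"]))
  fit <- fitAnimalModel(y, fixed = fixedDf, eigenA = eigenA)
  emit(data.frame(animal_id = ids, y = as.numeric(y), y_adj = fit@yAdj,
                  u_hat = fit@uHat), "reml_yadj.tsv")
  emit(data.frame(parameter = c("sigma2_u", "sigma2_e", "h2"),
                  value = c(fit@sigma2u, fit@sigma2e, fit@h2)),
       "reml_components.tsv")

  say("stage: scans")
  snp <- snpScan(fit@yAdj, panel = imputed, eigenA = eigenA)
  emit(snp, "scan_snp.tsv")
  hap <- hapScan(fit@yAdj, dosages = hmm$dosages, eigenA = eigenA)
  emit(hap, "scan_hap.tsv")
  rg <- cfg$regions
  emit(callRegions(snp, rg$genomewide_p, rg$suggestive_p, rg$merge_dist),
       "regions_snp.tsv")

  if (isTRUE(cfg$power$enabled)) {
    say("stage: power")
    pw <- cfg$power
    pcfg <- simulationConfig(
      n_replicates = pw$n_replicates, qtl_h2_grid = pw$qtl_h2_grid,
      methods = pw$methods, seed = childSeed(seed, 18L))
    if (!is.null(pw$maf_classes)) pcfg$maf_classes <- pw$maf_classes
    grid <- runPowerGrid(pcfg, imputed, ped, dosages = hmm$dosages,
                         eigenA = eigenA)
    emit(powerTable(grid), "power_grid.tsv")
  }

  manifest <- list(
    package = "SnpHapPower",
    version = as.character(packageVersion("SnpHapPower")),
    seed = seed,
    config = cfg,
    files = lapply(setNames(basename(files), basename(files)),
                   function(f) unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
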