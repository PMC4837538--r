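# Replicated QTL-detection power study: polygenic gene-drop phenotypes,
# QTL injection, both scans, distance-window power, thresholds and regions.

#' Bonferroni genome-wide threshold
#'
#' @param nTests Number of tests (>= 1).
#' @param alpha Family-wise significance level.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(38128)  # 1.31e-06 to 3 significant figures
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (any(nTests < 1)) stop("'nTests' must be >= 1")
  alpha / nTests
}

#' Power-study configuration
#'
#' Default study conditions: base heritability 0.30 with phenotypic
#' variance 1; QTL heritabilities {0.01, 0.03, 0.05, 0.07, 0.10, 0.15};
#' low (0.01, 0.10] and high (0.10, 0.5] MAF classes; 100 replicates;
#' genome-wide threshold 1.31e-6 (Bonferroni 5% for 38,128 tests) and
#' suggestive threshold 5.0e-5; distance windows +/-0.5, +/-0.5-1.0 and
#' +/-1.0-2.0 Mb around the masked QTL.
#'
#' @param ... Overrides of the default fields (unknown names are rejected).
#' @return Named list of class `simulationConfig`.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    h2_base = 0.30,
    VP_base = 1,
    qtl_h2_grid = c(0.01, 0.03, 0.05, 0.07, 0.10, 0.15),
    maf_classes = list(low = c(0.01, 0.10), high = c(0.10, 0.5)),
    n_replicates = 100L,
    genomewide_p = 1.31e-6,
    suggestive_p = 5.0e-5,
    windows_mb = list(inner = c(0, 0.5), mid = c(0.5, 1.0), outer = c(1.0, 2.0)),
    methods = c("snp", "hap"),
    qtl_error_mode = "rescale",
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(length(cfg$qtl_h2_grid) > 0, length(cfg$maf_classes) > 0)
  class(cfg) <- c("simulationConfig", "list")
  cfg
}

#' Simulate a base phenotype by polygenic gene dropping
#'
#' Null-model phenotype on a pedigree: founders receive
#' \eqn{u_j \sim N(0, \sigma_u^2)}; non-founders
#' \eqn{u_j \sim N(0.5(u_{Sj} + u_{Dj}),\; 0.5(1 - 0.5(F_{Sj}+F_{Dj}))\sigma_u^2)}
#' with parental inbreeding coefficients F; residuals
#' \eqn{e_j \sim N(0, \sigma_e^2)}. With the defaults
#' \eqn{\sigma_u^2 = h^2 V_P = 0.30} and \eqn{\sigma_e^2 = 0.70}.
#'
#' @param pedigree A [Pedigree-class].
#' @param F Named inbreeding vector (computed by [pedigreeInbreeding()] when
#'   `NULL`); required for all parents.
#' @param h2 Base heritability.
#' @param VP Phenotypic variance.
#' @param seed Integer seed.
#' @return Named phenotype vector with attributes `"u"` and `"e"`.
#' @export
simulateBasePhenotype <- function(pedigree, F = NULL, h2 = 0.30, VP = 1,
                                  seed = NULL) {
  if (is.null(F)) F <- pedigreeInbreeding(pedigree)
  ids <- animalIds(pedigree)
  par <- .parentIdx(pedigree)
  if (!all(ids %in% names(F))) stop("inbreeding coefficients missing for some animals")
  F <- F[ids]
  s2u <- h2 * VP
  s2e <- (1 - h2) * VP
  withSeed(seed, {
    n <- length(ids)
    u <- numeric(n)
    for (j in seq_len(n)) {
      s <- par[j, 1]; d <- par[j, 2]
      if (s == 0L && d == 0L) {
        u[j] <- rnorm(1, 0, sqrt(s2u))
      } else {
        mv <- 0.5 * (1 - 0.5 * (F[s] + F[d])) * s2u
        u[j] <- rnorm(1, 0.5 * (u[s] + u[d]), sqrt(mv))
      }
    }
    e <- rnorm(n, 0, sqrt(s2e))
    y <- u + e
    names(y) <- ids
    attr(y, "u") <- setNames(u, ids)
    attr(y, "e") <- setNames(e, ids)
    y
  })
}

#' QTL allele-substitution effect for a target QTL heritability
#'
#' \eqn{|\beta| = \sqrt{\sigma^2_{QTL} / (2p(1-p))}} with a random sign, so
#' that \eqn{2p(1-p)\beta^2 = \sigma^2_{QTL}} (the QTL variance equals the
#' QTL heritability when the phenotypic variance is 1).
#'
#' @param p QTL allele frequency, strictly in (0, 1).
#' @param qtlH2 QTL variance (= heritability at \eqn{V_P = 1}); > 0.
#' @param seed Integer seed for the sign.
#' @return Signed effect size.
#' @examples
#' abs(qtlEffect(0.5, 0.125, seed = 1))  # 0.5
#' @export
qtlEffect <- function(p, qtlH2, seed = NULL) {
  if (p <= 0 || p >= 1) stop("'p' must lie strictly in (0, 1)")
  if (qtlH2 <= 0) stop("'qtlH2' must be > 0")
  mag <- sqrt(qtlH2 / (2 * p * (1 - p)))
  withSeed(seed, mag * sample(c(-1, 1), 1L))
}

#' Inject a masked QTL into a base phenotype
#'
#' Selects one SNP uniformly at random among those whose MAF (on the
#' imputed, missing-free genotypes) falls in `mafClass`, adds
#' \eqn{\beta w_{QTL}} to the phenotype, and removes the QTL SNP from the
#' analysis panel. With `mode = "rescale"` (default) the base phenotype is
#' scaled by \eqn{\sqrt{1 - h^2_{QTL}}} before the effect is added, so the
#' total phenotypic variance stays at 1 and the realised QTL heritability
#' equals `qtlH2`; `mode = "additive"` adds the effect without rescaling.
#'
#' @param yBase Base phenotype (see [simulateBasePhenotype()]), aligned with
#'   the panel animals.
#' @param panel Imputed (missing-free) [GenotypePanel-class].
#' @param mafClass Numeric `c(lo, hi)`: the MAF interval `(lo, hi]`.
#' @param qtlH2 QTL heritability (variance at \eqn{V_P = 1}).
#' @param mode `"rescale"` or `"additive"`.
#' @param seed Integer seed (QTL choice and effect sign).
#' @return list with `y` (new phenotype), `panel` (QTL removed), `qtl`
#'   (one-row data.frame: `snp_id`, `chrom`, `pos`, `maf`, `beta`,
#'   `qtl_h2`).
#' @export
injectQtl <- function(yBase, panel, mafClass, qtlH2, mode = c("rescale", "additive"),
                      seed = NULL) {
  mode <- match.arg(mode)
  d <- dosages(panel)
  if (anyNA(d)) stop("'panel' must be imputed (no missing genotypes)")
  stopifnot(length(yBase) == ncol(d))
  p <- rowMeans(d) / 2
  maf <- pmin(p, 1 - p)
  cand <- which(maf > mafClass[1] & maf <= mafClass[2])
  if (!length(cand)) stop("no SNP with MAF in (", mafClass[1], ", ", mafClass[2], "]")
  withSeed(seed, {
    qi <- cand[sample.int(length(cand), 1L)]
    w <- d[qi, ]
    pq <- p[qi]
    beta <- sqrt(qtlH2 / (2 * pq * (1 - pq))) * sample(c(-1, 1), 1L)
    yNew <- if (mode == "rescale") sqrt(1 - qtlH2) * as.numeric(yBase) + beta * w
            else as.numeric(yBase) + beta * w
    names(yNew) <- names(yBase)
    map <- markerMap(panel)
    qtl <- data.frame(snp_id = map$snp_id[qi], chrom = map$chrom[qi],
                      pos = map$pos[qi], maf = maf[qi], beta = beta,
                      qtl_h2 = qtlH2)
    list(y = yNew, panel = panel[-qi, ], qtl = qtl)
  })
}

# Minimum p within each distance window (annuli in Mb) around the QTL.
.windowMinP <- function(scan, qtl, windows_mb) {
  same <- scan$chrom == qtl$chrom
  distMb <- abs(scan$pos - qtl$pos) / 1e6
  vapply(windows_mb, function(wd) {
    sel <- same & distMb > wd[1] & distMb <= wd[2] & !is.na(scan$p)
    if (!any(sel)) NA_real_ else min(scan$p[sel])
  }, numeric(1))
}

#' Run the QTL-detection power grid
#'
#' For every (MAF class, QTL heritability) cell, runs `n_replicates`
#' seeded replicates: simulate the base phenotype, inject and mask a QTL,
#' adjust phenotypes with the sex + generation animal model, run the
#' SNP-based mixed-model scan and/or the haplotype score-test scan, and
#' record the minimum p-value in each distance window around the QTL.
#' Power is the fraction of replicates whose window minimum falls below the
#' genome-wide threshold; the outer windows are annuli excluding the inner
#' ones. A cell is flagged when more than 5% of its replicates failed.
#'
#' @param config A [simulationConfig()].
#' @param panel Imputed [GenotypePanel-class] (analysis panel).
#' @param pedigree The [Pedigree-class] of the panel animals.
#' @param dosages A [DosagePanel-class] (required when `"hap"` is among the
#'   configured methods).
#' @param A,eigenA Relationship matrix or its eigen-decomposition.
#' @param verbose Print per-cell progress.
#' @return A [PowerGrid-class].
#' @export
runPowerGrid <- function(config, panel, pedigree, dosages = NULL, A = NULL,
                         eigenA = NULL, verbose = FALSE) {
  methods <- config$methods
  if ("hap" %in% methods && is.null(dosages))
    stop("'dosages' is required for the haplotype scan")
  ids <- animalIds(panel)
  if (is.null(eigenA)) {
    if (is.null(A)) A <- relationshipMatrix(pedigree)
    eigenA <- eigenRelationship(A[ids, ids])
  }
  Fcoef <- pedigreeInbreeding(pedigree)
  pedDf <- as.data.frame(pedigree)
  fixedDf <- data.frame(sex = factor(pedDf$sex),
                        generation = factor(pedDf$generation))
  rownames(fixedDf) <- pedDf$id
  fixedDf <- fixedDf[ids, , drop = FALSE]
  rotation <- if ("snp" %in% methods) prepareSnpScan(panel, eigenA = eigenA) else NULL
  snpIdx <- setNames(seq_len(nSnps(panel)), markerMap(panel)$snp_id)
  wnames <- names(config$windows_mb)

  cells <- expand.grid(maf_class = names(config$maf_classes),
                       qtl_h2 = config$qtl_h2_grid,
                       stringsAsFactors = FALSE)
  repRecords <- list()
  for (ci in seq_len(nrow(cells))) {
    mc <- cells$maf_class[ci]
    qh <- cells$qtl_h2[ci]
    if (verbose) message(sprintf("cell %d/%d: MAF %s, qtl_h2 %.2f",
                                 ci, nrow(cells), mc, qh))
    for (rep_ in seq_len(config$n_replicates)) {
      sd <- childSeed(config$seed, 10000L * ci + rep_)
      rec <- tryCatch({
        yB <- simulateBasePhenotype(pedigree, F = Fcoef, h2 = config$h2_base,
                                    VP = config$VP_base, seed = sd)[ids]
        inj <- injectQtl(yB, panel, config$maf_classes[[mc]], qh,
                         mode = config$qtl_error_mode, seed = childSeed(sd, 1L))
        fit <- fitAnimalModel(inj$y, fixed = fixedDf, eigenA = eigenA)
        yAdj <- fit@yAdj
        qidx <- snpIdx[[inj$qtl$snp_id]]
        out <- data.frame(maf_class = mc, qtl_h2 = qh, replicate = rep_,
                          qtl_snp = inj$qtl$snp_id, qtl_pos = inj$qtl$pos,
                          qtl_chrom = inj$qtl$chrom, qtl_maf = inj$qtl$maf,
                          qtl_beta = inj$qtl$beta, failed = FALSE)
        if ("snp" %in% methods) {
          scan <- snpScan(yAdj, rotation = rotation, exclude = qidx)
          mp <- .windowMinP(scan, inj$qtl, config$windows_mb)
          for (wi in seq_along(wnames))
            out[[paste0("snp_minp_", wnames[wi])]] <- mp[wi]
        }
        if ("hap" %in% methods) {
          r <- glascowResiduals(yAdj, eigenA = eigenA)
          scan <- hapScan(r = r, dosages = dosages, exclude = qidx)
          mp <- .windowMinP(scan, inj$qtl, config$windows_mb)
          for (wi in seq_along(wnames))
            out[[paste0("hap_minp_", wnames[wi])]] <- mp[wi]
        }
        out
      }, error = function(e) {
        data.frame(maf_class = mc, qtl_h2 = qh, replicate = rep_,
                   qtl_snp = NA, qtl_pos = NA, qtl_chrom = NA, qtl_maf = NA,
                   qtl_beta = NA, failed = TRUE)
      })
      repRecords[[length(repRecords) + 1L]] <- rec
    }
  }
  reps <- do.call(rbind, lapply(repRecords, function(x) {
    # align columns across success/failure rows
    allc <- unique(unlist(lapply(repRecords, names)))
    for (nm in setdiff(allc, names(x))) x[[nm]] <- NA
    x[allc]
  }))
  grid <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    mc <- cells$maf_class[ci]; qh <- cells$qtl_h2[ci]
    sel <- reps$maf_class == mc & reps$qtl_h2 == qh
    ok <- sel & !reps$failed
    do.call(rbind, lapply(methods, function(meth) {
      do.call(rbind, lapply(wnames, function(wn) {
        col <- paste0(meth, "_minp_", wn)
        mp <- reps[[col]][ok]
        det <- sum(!is.na(mp) & mp < config$genomewide_p)
        data.frame(method = meth, maf_class = mc, qtl_h2 = qh, window = wn,
                   n_rep = sum(ok), n_detected = det,
                   power = det / max(sum(ok), 1L),
                   flagged = sum(sel & reps$failed) > 0.05 * sum(sel))
      }))
    }))
  }))
  rownames(grid) <- NULL
  new("PowerGrid", grid = grid, replicates = reps, config = unclass(config))
}

#' Merge significant SNPs into regions
#'
#' SNPs below the suggestive threshold are grouped per chromosome by
#' single-linkage within `mergeDist`; each region is labelled by its most
#' significant SNP (ties broken towards the smaller position) and called
#' `"significant"` when the top p-value passes the genome-wide threshold,
#' `"suggestive"` otherwise.
#'
#' @param scan Scan results sorted by position (columns `snp_id`, `chrom`,
#'   `pos`, `p`).
#' @param genomewide_p,suggestive_p Thresholds.
#' @param mergeDist Merge distance (bp), default 1 Mb.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `top_snp`,
#'   `top_p`, `level` (zero rows when nothing passes).
#' @export
callRegions <- function(scan, genomewide_p = 1.31e-6, suggestive_p = 5.0e-5,
                        mergeDist = 1e6) {
  sig <- scan[!is.na(scan$p) & scan$p < suggestive_p, , drop = FALSE]
  empty <- data.frame(chrom = integer(), start = integer(), end = integer(),
                      n_snps = integer(), top_snp = character(),
                      top_p = numeric(), level = character())
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > mergeDist))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      top <- sg[order(sg$p, sg$pos), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sg$pos), end = max(sg$pos), n_snps = nrow(sg),
        top_snp = top$snp_id, top_p = top$p,
        level = if (top$p < genomewide_p) "significant" else "suggestive")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
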