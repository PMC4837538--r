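# Pairwise linkage disequilibrium and distance-binned decay curves.

#' Pairwise LD as squared dosage correlation
#'
#' r-squared between two SNPs as the squared Pearson correlation of their
#' 0/1/2 dosages (the PLINK `--r2` convention). Observations with either
#' value missing are excluded pairwise; the value is `NA` (undefined) when
#' fewer than two complete pairs remain or either SNP is monomorphic among
#' them.
#'
#' @param g1,g2 Equal-length dosage vectors (0/1/2/`NA`).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @examples
#' ldR2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 2, 2))
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Chromosome-averaged LD-decay curve
#'
#' Computes r-squared for all intra-chromosome SNP pairs up to `maxDist`,
#' bins pairs by distance (bin `b` covers `((b-1) binBp, b binBp]`), takes
#' the per-chromosome mean within each bin and then the unweighted average
#' across chromosomes. Bins with no pairs are `NA`, not zero.
#'
#' @param panel A [GenotypePanel-class] with at least two SNPs on some
#'   chromosome.
#' @param maxDist Maximum pair distance (bp); default 10 Mb.
#' @param binBp Bin width (bp); default 1 kb.
#' @return data.frame with `bin_start`, `bin_end`, `dist_mid` (bp),
#'   `n_pairs` (total across chromosomes), `mean_r2` (cross-chromosome
#'   unweighted average). The per-chromosome bin means and counts are
#'   attached as attributes `"per_chrom"` and `"counts"`.
#' @export
ldDecayCurve <- function(panel, maxDist = 10e6, binBp = 1000) {
  map <- markerMap(panel)
  d <- dosages(panel)
  chroms <- unique(map$chrom)
  nb <- as.integer(ceiling(maxDist / binBp))
  perChrom <- matrix(NA_real_, nb, length(chroms),
                     dimnames = list(NULL, paste0("chr", chroms)))
  counts <- matrix(0L, nb, length(chroms), dimnames = dimnames(perChrom))
  any_pairs <- FALSE
  for (ci in seq_along(chroms)) {
    sel <- which(map$chrom == chroms[ci])
    if (length(sel) < 2L) next
    any_pairs <- TRUE
    res <- ld_bins_cpp(d[sel, , drop = FALSE], as.numeric(map$pos[sel]),
                       as.numeric(maxDist), as.numeric(binBp))
    cnt <- res$count
    perChrom[cnt > 0L, ci] <- res$sum[cnt > 0L] / cnt[cnt > 0L]
    counts[, ci] <- cnt
  }
  if (!any_pairs) stop("need at least two SNPs on some chromosome")
  out <- data.frame(
    bin_start = (seq_len(nb) - 1) * binBp,
    bin_end = seq_len(nb) * binBp,
    dist_mid = (seq_len(nb) - 0.5) * binBp,
    n_pairs = rowSums(counts),
    mean_r2 = rowMeans(perChrom, na.rm = TRUE))
  out$mean_r2[out$n_pairs == 0L] <- NA_real_
  attr(out, "per_chrom") <- perChrom
  attr(out, "counts") <- counts
  out
}

#' Average r-squared of a decay curve near a target distance
#'
#' Pair-count-weighted mean of the binned r-squared over bins whose midpoint
#' lies within `halfWindow` of `dist`; used e.g. to read the curve at the
#' 1.0 Mb useful-LD distance.
#'
#' @param curve Output of [ldDecayCurve()].
#' @param dist Target distance (bp).
#' @param halfWindow Half-width (bp) of the neighbourhood; default 50 kb.
#' @return Numeric scalar (possibly `NA` if no occupied bins).
#' @export
ldAt <- function(curve, dist, halfWindow = 5e4) {
  sel <- abs(curve$dist_mid - dist) <= halfWindow & curve$n_pairs > 0
  if (!any(sel)) return(NA_real_)
  sum(curve$mean_r2[sel] * curve$n_pairs[sel]) / sum(curve$n_pairs[sel])
}
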