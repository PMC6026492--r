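# Pairwise genotype-correlation LD (plink-style r^2), decay curves in
# 10 kb bins, index-anchored LD-block extension, PCA stratification and
# VanRaden kinship.

#' Pairwise r^2 between markers
#'
#' The classical squared Pearson correlation between genotype dosage
#' vectors, computed within an optional sample subset.  Markers that are
#' monomorphic in the subset are excluded.  In distance-limited mode only
#' same-chromosome pairs within `max_dist` bp are returned.
#'
#' @param panel a complete [genotype_panel()].
#' @param subset optional sample index (logical or integer); default all.
#' @param max_dist maximum pair distance in bp, or `Inf` for all
#'   same-chromosome pairs.
#' @return data.frame with `chrom`, `i`, `j` (marker column indices),
#'   `pos_i`, `pos_j`, `dist`, `r2`.
#' @export
pairwise_r2 <- function(panel, subset = NULL, max_dist = Inf) {
  d <- panel$dosage
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 samples for r^2")
  poly <- apply(d, 2L, function(x) stats::var(x) > 0)
  out <- lapply(unique(panel$markers$chrom), function(ch) {
    j <- which(panel$markers$chrom == ch & poly)
    if (length(j) < 2L) return(NULL)
    pos <- panel$markers$pos[j]
    cc <- suppressWarnings(stats::cor(d[, j, drop = FALSE]))^2
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- pos[pr[, 2L]] - pos[pr[, 1L]]
    keep <- dist <= max_dist
    data.frame(chrom = ch,
               i = j[pr[keep, 1L]], j = j[pr[keep, 2L]],
               pos_i = pos[pr[keep, 1L]], pos_j = pos[pr[keep, 2L]],
               dist = dist[keep], r2 = cc[pr[keep, , drop = FALSE]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LD decay curve and decay distance
#'
#' Bins marker pairs by physical distance (default 10 kb bins from 0) and
#' reports the median r^2 per bin.  The decay distance is the left edge of
#' the first bin whose median falls below the threshold; `Inf` when no bin
#' does.
#'
#' @param pairs output of [pairwise_r2()].
#' @param bin bin width in bp (default 10 kb).
#' @param threshold r^2 level defining decay (default 0.2).
#' @return list with `curve` (data.frame `bin_left`, `median_r2`,
#'   `n_pairs`) and `decay_distance` (bp, possibly `Inf`).
#' @export
ld_decay <- function(pairs, bin = 10000, threshold = 0.2) {
  edges <- seq(0, max(pairs$dist) + bin, by = bin)
  b <- findInterval(pairs$dist, edges, left.open = TRUE,
                    rightmost.closed = TRUE)
  b[pairs$dist == 0] <- 1L
  curve <- data.frame(bin_left = edges[seq_len(length(edges) - 1L)])
  med <- tapply(pairs$r2, factor(b, levels = seq_len(nrow(curve))),
                stats::median)
  cnt <- tapply(pairs$r2, factor(b, levels = seq_len(nrow(curve))),
                length)
  curve$median_r2 <- as.numeric(med)
  curve$n_pairs <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  below <- which(!is.na(curve$median_r2) & curve$median_r2 < threshold)
  list(curve = curve,
       decay_distance = if (length(below)) curve$bin_left[min(below)]
                        else Inf)
}

#' Extend an index SNP to its LD block
#'
#' The genomic interval from the leftmost to the rightmost marker within
#' `max_span` bp of the index SNP whose r^2 with it is at least `r2_min`
#' (inclusive boundary).  With no linked neighbour the interval degenerates
#' to the index position.
#'
#' @param panel a complete [genotype_panel()].
#' @param index_snp marker column index.
#' @param r2_min r^2 threshold (default 0.8).
#' @param max_span maximum distance searched either side (default 500 kb).
#' @param subset optional sample subset for the correlations.
#' @return list with `chrom`, `start`, `end`, `n_linked`.
#' @export
ld_block_extend <- function(panel, index_snp, r2_min = 0.8,
                            max_span = 500000, subset = NULL) {
  mk <- panel$markers
  ch <- mk$chrom[index_snp]
  p0 <- mk$pos[index_snp]
  cand <- which(mk$chrom == ch & abs(mk$pos - p0) <= max_span)
  d <- panel$dosage
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  r2 <- suppressWarnings(
    stats::cor(d[, cand, drop = FALSE], d[, index_snp])[, 1L]
  )^2
  linked <- cand[!is.na(r2) & r2 >= r2_min]
  linked <- union(linked, index_snp)
  list(chrom = ch, start = min(mk$pos[linked]), end = max(mk$pos[linked]),
       n_linked = length(linked) - 1L)
}

#' PCA of the dosage matrix
#'
#' Principal components of the column-centered (optionally unit-variance
#' scaled) dosage matrix.  The sign of each component is fixed so its
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param panel a complete [genotype_panel()].
#' @param n_components number of components to return.
#' @param scale. scale columns to unit variance (default `FALSE`).
#' @return list of class `structure_result`: `scores` (samples x
#'   components), `var_prop` (proportion of total variance per component).
#' @export
panel_pca <- function(panel, n_components = 3L, scale. = FALSE) {
  if (n_components > n_samples(panel)) {
    stop("more components than samples")
  }
  d <- panel$dosage
  keep <- apply(d, 2L, function(x) stats::var(x) > 0)
  pc <- stats::prcomp(d[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(i) {
    v <- rot[, i]
    sign(v[which.max(abs(v))])
  }, 1)
  scores <- sweep(pc$x[, k, drop = FALSE], 2L, flip, "*")
  rownames(scores) <- panel$samples$sample_id
  structure(list(scores = scores,
                 var_prop = (pc$sdev^2 / sum(pc$sdev^2))[k]),
            class = "structure_result")
}

#' VanRaden genomic kinship matrix
#'
#' `K = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the dosage matrix centered
#' at twice the allele frequency — the familial-relatedness term of the
#' mixed association model.
#'
#' @param panel a complete [genotype_panel()] with polymorphic markers.
#' @return symmetric samples x samples matrix.
#' @export
kinship_vanraden <- function(panel) {
  d <- panel$dosage
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic")
  Z <- sweep(d[, keep, drop = FALSE], 2L, 2 * p[keep], "-")
  K <- tcrossprod(Z) / (2 * sum(p[keep] * (1 - p[keep])))
  dimnames(K) <- list(panel$samples$sample_id, panel$samples$sample_id)
  K
}
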