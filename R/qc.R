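# Panel construction: platform merge (array wins at shared markers),
# missing-rate filtering, LD-kNN imputation, MAF filtering, with a
# per-stage accounting report.

#' Merge array and RAD-seq panels into one
#'
#' Markers shared between the two platforms (matched on chrom, pos) keep
#' the array genotypes.  If ref/alt are exchanged between the platforms
#' the RAD-seq record is recoded (dosage -> 2 - dosage) before comparison;
#' markers whose alleles cannot be reconciled are dropped and logged.  The
#' sample sets are intersected with a warning when they differ.
#'
#' @param panel_array,panel_radseq two [genotype_panel()]s.
#' @return A merged `genotype_panel` (union of markers, platform tags
#'   preserved) with attribute `"merge_log"` listing dropped markers.
#' @export
merge_platforms <- function(panel_array, panel_radseq) {
  common <- intersect(panel_array$samples$sample_id,
                      panel_radseq$samples$sample_id)
  if (length(common) < n_samples(panel_array) ||
      length(common) < n_samples(panel_radseq)) {
    warning("sample sets differ between platforms; using the ",
            length(common), "-sample intersection")
  }
  if (!length(common)) stop("no shared samples between platforms")
  pa <- subset_panel(panel_array,
                     match(common, panel_array$samples$sample_id))
  pr <- subset_panel(panel_radseq,
                     match(common, panel_radseq$samples$sample_id))
  pa$markers$platform <- "array"
  pr$markers$platform <- "radseq"

  key_a <- paste(pa$markers$chrom, pa$markers$pos)
  key_r <- paste(pr$markers$chrom, pr$markers$pos)
  shared <- intersect(key_a, key_r)
  drop_log <- character()
  if (length(shared)) {
    ia <- match(shared, key_a)
    ir <- match(shared, key_r)
    same <- pa$markers$ref[ia] == pr$markers$ref[ir] &
      pa$markers$alt[ia] == pr$markers$alt[ir]
    swapped <- pa$markers$ref[ia] == pr$markers$alt[ir] &
      pa$markers$alt[ia] == pr$markers$ref[ir]
    bad <- !(same | swapped)
    if (any(bad)) {
      drop_log <- paste0(shared[bad], ": allele mismatch, dropped")
      keep_a <- setdiff(seq_len(n_markers(pa)), ia[bad])
      pa <- subset_panel(pa, markers = keep_a)
      key_a <- key_a[keep_a]
      shared <- shared[!bad]
    }
    # array wins at every reconcilable shared marker: drop them from radseq
    pr <- subset_panel(pr, markers = which(!(key_r %in% c(shared,
                                                          sub(":.*", "", drop_log)))))
  }
  markers <- rbind(pa$markers, pr$markers)
  dosage <- cbind(pa$dosage, pr$dosage)
  ord <- order(markers$chrom, markers$pos)
  out <- genotype_panel(dosage[, ord, drop = FALSE],
                        markers[ord, , drop = FALSE], pa$samples)
  attr(out, "merge_log") <- drop_log
  out
}

#' Filter markers and samples by missing rate
#'
#' Two-pass call-rate filter: markers with a missing rate above the
#' threshold are removed first, then samples with a missing rate above the
#' threshold computed on the surviving markers (a call rate below
#' `1 - max_missing_rate`).
#'
#' @param panel a [genotype_panel()].
#' @param max_missing_rate maximum tolerated missing rate, in (0, 1).
#' @return list with `panel` (filtered) and `report` (a `filter_report`:
#'   per-platform marker counts removed, samples removed).
#' @export
filter_missingness <- function(panel, max_missing_rate = 0.2) {
  stopifnot(max_missing_rate > 0, max_missing_rate < 1)
  d <- panel$dosage
  marker_rate <- colMeans(is.na(d))
  drop_m <- marker_rate > max_missing_rate
  kept <- subset_panel(panel, markers = which(!drop_m))
  sample_rate <- rowMeans(is.na(kept$dosage))
  drop_s <- sample_rate > max_missing_rate
  if (all(drop_s)) stop("all samples exceed the missing-rate threshold")
  out <- subset_panel(kept, samples = which(!drop_s))
  report <- filter_report(
    stage = "missingness",
    initial = platform_counts(panel),
    removed = platform_counts(panel, drop_m),
    final = platform_counts(out),
    samples_initial = n_samples(panel),
    samples_removed = sum(drop_s)
  )
  list(panel = out, report = report)
}

#' Filter markers by minor allele frequency
#'
#' MAF is `min(p, 1 - p)` with p the mean dosage over 2; markers with MAF
#' strictly below the threshold are removed (MAF exactly at the threshold
#' is retained).  Intended to run after imputation, on a complete matrix,
#' but missing entries are tolerated (frequency over observed genotypes).
#'
#' @param panel a [genotype_panel()].
#' @param min_maf MAF threshold (default 0.05).
#' @return list with `panel` and `report` as in [filter_missingness()].
#' @export
filter_maf <- function(panel, min_maf = 0.05) {
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_m <- maf < min_maf
  out <- subset_panel(panel, markers = which(!drop_m))
  if (n_markers(out) == 0L) warning("no markers survive the MAF filter")
  report <- filter_report(
    stage = "maf",
    initial = platform_counts(panel),
    removed = platform_counts(panel, drop_m),
    final = platform_counts(out),
    samples_initial = n_samples(panel),
    samples_removed = 0L
  )
  list(panel = out, report = report)
}

#' Per-marker minor allele frequencies
#' @param panel a [genotype_panel()].
#' @return numeric vector of MAF values.
#' @export
panel_maf <- function(panel) {
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

filter_report <- function(stage, initial, removed, final,
                          samples_initial, samples_removed) {
  platforms <- union(names(initial), names(final))
  tab <- data.frame(
    platform = platforms,
    initial = as.integer(initial[platforms]),
    removed = as.integer(removed[platforms]),
    final = as.integer(final[platforms]),
    stringsAsFactors = FALSE
  )
  tab[is.na(tab)] <- 0L
  stopifnot(all(tab$initial - tab$removed == tab$final))
  structure(list(stage = stage, markers = tab,
                 samples_initial = samples_initial,
                 samples_removed = samples_removed,
                 samples_final = samples_initial - samples_removed),
            class = "filter_report")
}

platform_counts <- function(panel, which_markers = NULL) {
  pf <- panel$markers$platform
  if (!is.null(which_markers)) pf <- pf[which_markers]
  tab <- table(factor(pf, levels = unique(panel$markers$platform)))
  stats::setNames(as.integer(tab), names(tab))
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("filter stage:", x$stage, "\n")
  print(x$markers, row.names = FALSE)
  cat("samples:", x$samples_initial, "->", x$samples_final,
      sprintf("(%d removed)\n", x$samples_removed))
  invisible(x)
}

#' Combine per-stage filter reports into a Table-1-style accounting
#'
#' @param reports list of `filter_report` objects in pipeline order.
#' @return data.frame with one row per platform plus a total row:
#'   initial count, removals per stage, final count.
#' @export
filter_accounting <- function(reports) {
  platforms <- unique(unlist(lapply(reports,
                                    function(r) r$markers$platform)))
  out <- data.frame(platform = c(platforms, "total"),
                    stringsAsFactors = FALSE)
  first <- reports[[1L]]$markers
  init <- stats::setNames(first$initial, first$platform)[platforms]
  init[is.na(init)] <- 0L
  out$initial <- c(init, sum(init))
  for (r in reports) {
    rem <- stats::setNames(r$markers$removed, r$markers$platform)[platforms]
    rem[is.na(rem)] <- 0L
    out[[paste0("removed_", r$stage)]] <- c(rem, sum(rem))
  }
  last <- reports[[length(reports)]]$markers
  fin <- stats::setNames(last$final, last$platform)[platforms]
  fin[is.na(fin)] <- 0L
  out$final <- c(fin, sum(fin))
  out
}

#' LD-kNN genotype imputation
#'
#' Fills every missing genotype by a k-nearest-neighbour vote computed in
#' LD space (LD-kNNi).  For a missing entry (sample s, marker m): the `l`
#' markers in highest r^2 with m (r^2 over pairwise-complete samples) define
#' the distance `d(s, t) = (1/l) * sum |g_s - g_t| + eps`, summing only
#' markers observed in both samples; the `k` nearest samples with an
#' observed genotype at m vote with weight `1/d^2`; the imputed genotype is
#' the weighted-majority class, ties broken toward the smaller dosage.
#' Deterministic: no randomness is involved.
#'
#' @param panel a [genotype_panel()] with missing entries.
#' @param k number of voting neighbours (default 5).
#' @param l number of high-LD markers used for the distance (default 20).
#' @param eps additive distance constant guarding against zero distances.
#' @return A complete `genotype_panel`; markers observed in fewer than two
#'   samples are filled with their major genotype and listed in the
#'   `"imputation_flags"` attribute.
#' @export
impute_knn <- function(panel, k = 5L, l = 20L, eps = 0.01) {
  d <- panel$dosage
  n <- nrow(d)
  if (n < k + 1L) stop("need at least k + 1 samples")
  miss_cols <- which(colSums(is.na(d)) > 0L)
  flagged <- character()
  storage.mode(d) <- "double"
  out <- d
  for (m in miss_cols) {
    obs_m <- !is.na(d[, m])
    miss_s <- which(!obs_m)
    if (sum(obs_m) < 2L) {
      g <- d[obs_m, m]
      major <- if (length(g)) as.integer(names(sort(table(g),
                                                    decreasing = TRUE))[1L])
               else 0L
      out[miss_s, m] <- major
      flagged <- c(flagged, panel$markers$id[m])
      next
    }
    r <- suppressWarnings(stats::cor(d, d[, m],
                                     use = "pairwise.complete.obs"))
    r2 <- r[, 1L]^2
    r2[m] <- NA_real_
    r2[is.na(r2)] <- -1
    top <- order(r2, decreasing = TRUE)[seq_len(min(l, length(r2) - 1L))]
    sub <- d[, top, drop = FALSE]
    for (s in miss_s) {
      diff <- abs(sweep(sub, 2L, sub[s, ], "-"))
      dist <- rowSums(diff, na.rm = TRUE) / l + eps
      cand <- which(obs_m)
      cand <- cand[cand != s]
      nb <- cand[order(dist[cand])][seq_len(min(k, length(cand)))]
      w <- tapply(1 / dist[nb]^2, factor(d[nb, m], levels = 0:2), sum,
                  default = 0)
      out[s, m] <- as.integer(names(w)[which.max(w)])  # which.max: first
    }
  }
  storage.mode(out) <- "integer"
  panel$dosage <- out
  attr(panel, "imputation_flags") <- flagged
  panel
}

#' Run the full panel-construction chain
#'
#' Missing-rate filter, LD-kNN imputation, then MAF filter — the order the
#' statistics downstream assume (Tajima's constants need a complete matrix
#' of fixed sample size).
#'
#' @param panel a merged [genotype_panel()].
#' @param max_missing_rate,min_maf,k,l,eps stage parameters, see
#'   [filter_missingness()], [impute_knn()], [filter_maf()].
#' @return list with `panel` (complete, filtered), `reports` (per-stage
#'   `filter_report`s) and `accounting` (combined table).
#' @export
qc_pipeline <- function(panel, max_missing_rate = 0.2, min_maf = 0.05,
                        k = 5L, l = 20L, eps = 0.01) {
  s1 <- filter_missingness(panel, max_missing_rate)
  imputed <- impute_knn(s1$panel, k = k, l = l, eps = eps)
  s2 <- filter_maf(imputed, min_maf)
  reports <- list(s1$report, s2$report)
  list(panel = s2$panel, reports = reports,
       accounting = filter_accounting(reports))
}
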