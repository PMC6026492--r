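# The core computation: per-site Weir-Cockerham (1984) variance
# components between sativa and sylvestris, 100 kb / 10 kb sliding-window
# F_ST, per-group nucleotide diversity and Tajima's D, empirical and
# label-permutation outlier thresholds.

#' Window specification for the sliding-window scan
#' @param size window size in bp (default 100 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(size = 100000L, step = 10000L) {
  stopifnot(size > 0, step > 0, step <= size)
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "window_spec")
}

#' Per-site Weir-Cockerham variance components
#'
#' For every marker, the two-population Weir & Cockerham (1984) components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals), computed from per-group sample sizes, allele
#' frequencies and observed heterozygosities:
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{s^2}{2} - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{s^2}{2} - \frac{2\bar n - 1}{4\bar n}\bar h\right], \quad
#'   c = \bar h / 2}
#' with \eqn{\theta = a/(a+b+c)} the per-site estimate.  Sites genotyped in
#' fewer than two diploids in either group have undefined components
#' (`NA`); sites where \eqn{a+b+c \le 0} keep their components (they still
#' enter window sums) but have undefined \eqn{\theta}.
#'
#' @param panel a [genotype_panel()].
#' @param groups factor with exactly two levels over samples; defaults to
#'   the panel's sativa/sylvestris labels.
#' @return data.frame with one row per marker: `n1`, `n2` (diploids
#'   genotyped), `p1`, `p2`, `h1`, `h2`, `a`, `b`, `c`, `theta`.
#' @export
site_fst <- function(panel, groups = panel_groups(panel)) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) {
    stop("exactly two groups required (two-population estimator)")
  }
  d <- panel$dosage
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  comp <- wc_components(d[g1, , drop = FALSE], d[g2, , drop = FALSE])
  cbind(data.frame(chrom = panel$markers$chrom, pos = panel$markers$pos),
        comp)
}

# vectorised W&C components from the two group dosage sub-matrices
wc_components <- function(d1, d2) {
  stats_g <- function(dg) {
    n <- colSums(!is.na(dg))
    p <- colMeans(dg, na.rm = TRUE) / 2
    h <- colMeans(dg == 1L, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_g(d1)
  s2 <- stats_g(d2)
  n1 <- s1$n; n2 <- s2$n
  ok <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * s1$p + n2 * s2$p) / (2 * nbar)
  ssq <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / nbar
  hbar <- (n1 * s1$h + n2 * s2$h) / (2 * nbar)
  a <- (nbar / nc) *
    (ssq - (pbar * (1 - pbar) - ssq / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ssq / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  tot <- a + b + cc
  theta <- ifelse(!is.na(tot) & tot > 0, a / tot, NA_real_)
  data.frame(n1 = n1, n2 = n2, p1 = s1$p, p2 = s2$p,
             h1 = s1$h, h2 = s2$h, a = a, b = b, c = cc, theta = theta)
}

# Tajima (1989) normalising constants for n sequences
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window F_ST, nucleotide diversity and Tajima's D
#'
#' Windows are anchored at position 1 on each chromosome and advance by
#' `spec$step`; a marker at position x belongs to window
#' `[w, w + size - 1]` iff `w <= x <= w + size - 1` (1-based inclusive).
#' Windows with no markers are omitted.  Per window:
#' `fst_weighted = sum(a) / sum(a + b + c)` over the window's markers
#' (negative per-site components retained, not truncated), `fst_mean` the
#' mean of defined per-site theta.  Per group, pi is the sum of per-site
#' heterozygosity `2 c0 c1 / (n (n - 1))` over the window divided by the
#' window size in bp (n = 2 x diploids, c0/c1 allele counts), and Tajima's
#' D compares the mean pairwise difference `khat = sum(c0 c1) / C(n, 2)`
#' with the scaled segregating-site count (D is `NA` when S = 0).
#'
#' @param panel a complete (imputed) [genotype_panel()]; missing genotypes
#'   are an error — run [impute_knn()] first.
#' @param groups two-level factor over samples (default panel labels).
#' @param spec a [window_spec()].
#' @return data.frame with one row per non-empty window: `chrom`, `start`,
#'   `end`, `n_snps`, `fst_weighted`, `fst_mean`, `pi_sativa`,
#'   `pi_sylvestris`, `tajd_sativa`, `tajd_sylvestris`, `pi_ratio`
#'   (`pi_sylvestris / pi_sativa`).  The group columns follow the factor's
#'   two levels in order, named by level.
#' @export
window_scan <- function(panel, groups = panel_groups(panel),
                        spec = window_spec()) {
  if (anyNA(panel$dosage)) {
    stop("panel has missing genotypes; impute first (impute_knn)")
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  lv <- levels(groups)
  d <- panel$dosage
  comp <- wc_components(d[groups == lv[1L], , drop = FALSE],
                        d[groups == lv[2L], , drop = FALSE])

  # per-site, per-group ingredients for pi and Tajima's D
  site_group <- function(dg) {
    nhap <- 2L * nrow(dg)
    c1 <- colSums(dg)
    c0 <- nhap - c1
    list(nhap = nhap,
         pi_site = 2 * c0 * c1 / (nhap * (nhap - 1)),
         khat_site = c0 * c1 / choose(nhap, 2),
         seg = c1 > 0L & c1 < nhap)
  }
  sg1 <- site_group(d[groups == lv[1L], , drop = FALSE])
  sg2 <- site_group(d[groups == lv[2L], , drop = FALSE])
  k1 <- tajima_constants(sg1$nhap)
  k2 <- tajima_constants(sg2$nhap)

  abc <- comp$a + comp$b + comp$c
  res <- lapply(split(seq_len(n_markers(panel)), panel$markers$chrom),
                function(j) {
    pos <- panel$markers$pos[j]
    starts <- seq.int(1L, max(pos), by = spec$step)
    lo <- findInterval(starts - 1L, pos) + 1L
    hi <- findInterval(starts + spec$size - 1L, pos)
    keep <- hi >= lo
    starts <- starts[keep]; lo <- lo[keep]; hi <- hi[keep]
    wsum <- function(x) {
      cs <- cumsum(ifelse(is.na(x), 0, x))
      cs[hi] - c(0, cs)[lo]
    }
    wn <- function(x) {  # count of non-NA
      cs <- cumsum(!is.na(x))
      cs[hi] - c(0, cs)[lo]
    }
    a_w <- wsum(comp$a[j]); abc_w <- wsum(abc[j])
    th_sum <- wsum(comp$theta[j]); th_n <- wn(comp$theta[j])
    pi1 <- wsum(sg1$pi_site[j]) / spec$size
    pi2 <- wsum(sg2$pi_site[j]) / spec$size
    tajd <- function(sg, k) {
      S <- wsum(as.numeric(sg$seg[j]))
      khat <- wsum(sg$khat_site[j])
      v <- k$e1 * S + k$e2 * S * (S - 1)
      ifelse(S > 0 & v > 0, (khat - S / k$a1) / sqrt(v), NA_real_)
    }
    data.frame(
      chrom = panel$markers$chrom[j][1L],
      start = starts, end = starts + spec$size - 1L,
      n_snps = hi - lo + 1L,
      fst_weighted = ifelse(abc_w != 0, a_w / abc_w, NA_real_),
      fst_mean = ifelse(th_n > 0, th_sum / th_n, NA_real_),
      pi_g1 = pi1, pi_g2 = pi2,
      tajd_g1 = tajd(sg1, k1), tajd_g2 = tajd(sg2, k2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  names(out)[names(out) == "pi_g1"] <- paste0("pi_", lv[1L])
  names(out)[names(out) == "pi_g2"] <- paste0("pi_", lv[2L])
  names(out)[names(out) == "tajd_g1"] <- paste0("tajd_", lv[1L])
  names(out)[names(out) == "tajd_g2"] <- paste0("tajd_", lv[2L])
  if (all(c("pi_sativa", "pi_sylvestris") %in% names(out))) {
    out$pi_ratio <- ifelse(out$pi_sativa > 0,
                           out$pi_sylvestris / out$pi_sativa,
                           ifelse(out$pi_sylvestris == 0, NA_real_, Inf))
  }
  out
}

#' Genome-wide weighted F_ST
#'
#' The ratio of summed Weir-Cockerham numerator components to summed total
#' components over all markers — the single number summarising overall
#' differentiation between the two subpopulations.
#'
#' @inheritParams site_fst
#' @return a single numeric value.
#' @export
global_fst <- function(panel, groups = panel_groups(panel)) {
  comp <- site_fst(panel, groups)
  sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

#' Empirical percentile thresholds of the window F_ST distribution
#'
#' Percentiles of `fst_weighted` across all emitted windows, by linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param stats_df output of [window_scan()].
#' @param percentiles percent levels (default 95 and 99).
#' @return named numeric vector of thresholds (`"p95"`, `"p99"`, ...).
#' @export
empirical_thresholds <- function(stats_df, percentiles = c(95, 99)) {
  x <- stats_df$fst_weighted
  x <- x[!is.na(x)]
  if (!length(x)) stop("no windows with defined F_ST")
  stats::setNames(
    stats::quantile(x, percentiles / 100, type = 7, names = FALSE),
    paste0("p", percentiles)
  )
}

#' Label-permutation null distribution of window F_ST
#'
#' Each replicate shuffles the group labels over samples genome-wide
#' (group sizes preserved) and recomputes the full sliding-window
#' `fst_weighted` scan; the pooled window values across replicates form
#' the null distribution from which percentile thresholds are derived.
#' The per-replicate maxima are also kept for FWER-style thresholds.
#'
#' @inheritParams window_scan
#' @param n_reps number of label permutations (default 1000).
#' @param seed RNG seed; fixed seed gives an identical null.
#' @param percentiles percent levels for the pooled thresholds.
#' @return list of class `permutation_null`: `values` (windows x reps
#'   matrix of null `fst_weighted`), `max_per_rep`, `thresholds` (pooled
#'   percentiles), `thresholds_max` (same percentiles of the per-replicate
#'   maxima), `n_reps`, `seed`.
#' @export
permutation_null <- function(panel, groups = panel_groups(panel),
                             spec = window_spec(), n_reps = 1000L,
                             seed = 1L, percentiles = c(95, 99)) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  groups <- droplevels(as.factor(groups))
  idx <- window_index(panel, spec)
  n_win <- sum(vapply(idx, function(w) length(w$lo), 1L))
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      g <- sample(groups)
      window_fst_only(panel, g, idx)
    }, numeric(n_win))
  })
  vals <- matrix(vals, ncol = n_reps)
  pooled <- as.numeric(vals)
  pooled <- pooled[!is.na(pooled)]
  maxima <- apply(vals, 2L, max, na.rm = TRUE)
  structure(list(
    values = vals,
    max_per_rep = maxima,
    thresholds = stats::setNames(
      stats::quantile(pooled, percentiles / 100, type = 7, names = FALSE),
      paste0("p", percentiles)),
    thresholds_max = stats::setNames(
      stats::quantile(maxima, percentiles / 100, type = 7, names = FALSE),
      paste0("p", percentiles)),
    n_reps = n_reps, seed = seed
  ), class = "permutation_null")
}

# window membership per chromosome: marker indices j and, per window,
# the [lo, hi] range into j (windows with zero markers already dropped)
window_index <- function(panel, spec) {
  lapply(split(seq_len(n_markers(panel)), panel$markers$chrom),
         function(j) {
    pos <- panel$markers$pos[j]
    starts <- seq.int(1L, max(pos), by = spec$step)
    lo <- findInterval(starts - 1L, pos) + 1L
    hi <- findInterval(starts + spec$size - 1L, pos)
    keep <- hi >= lo
    list(j = j, starts = starts[keep], lo = lo[keep], hi = hi[keep])
  })
}

# weighted window F_ST only — the permutation inner loop
window_fst_only <- function(panel, groups, idx) {
  d <- panel$dosage
  lv <- levels(groups)
  comp <- wc_components(d[groups == lv[1L], , drop = FALSE],
                        d[groups == lv[2L], , drop = FALSE])
  abc <- comp$a + comp$b + comp$c
  unlist(lapply(idx, function(w) {
    wsum <- function(x) {
      cs <- cumsum(ifelse(is.na(x), 0, x))
      cs[w$hi] - c(0, cs)[w$lo]
    }
    a_w <- wsum(comp$a[w$j])
    abc_w <- wsum(abc[w$j])
    ifelse(abc_w != 0, a_w / abc_w, NA_real_)
  }), use.names = FALSE)
}

#' Flag outlier windows against empirical and permutation thresholds
#'
#' Adds flag columns at the 95th/99th empirical percentile levels and, when
#' a [permutation_null()] is supplied, each window's null exceedance
#' probability (fraction of pooled null values at least as large).
#'
#' @param stats_df output of [window_scan()].
#' @param thresholds output of [empirical_thresholds()].
#' @param null optional `permutation_null`.
#' @return `stats_df` with logical columns `flag_95`, `flag_99` and, with a
#'   null, numeric `null_exceedance`.
#' @export
call_outliers <- function(stats_df, thresholds, null = NULL) {
  stats_df$flag_95 <- !is.na(stats_df$fst_weighted) &
    stats_df$fst_weighted >= thresholds[["p95"]]
  stats_df$flag_99 <- !is.na(stats_df$fst_weighted) &
    stats_df$fst_weighted >= thresholds[["p99"]]
  if (!is.null(null)) {
    pooled <- as.numeric(null$values)
    pooled <- pooled[!is.na(pooled)]
    npool <- length(pooled)
    srt <- sort(pooled)
    # exceedance = fraction of null >= observed, via binary search
    idx <- findInterval(stats_df$fst_weighted, srt, left.open = TRUE)
    stats_df$null_exceedance <- (npool - idx) / npool
    stats_df$null_exceedance[is.na(stats_df$fst_weighted)] <- NA_real_
  }
  stats_df
}
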