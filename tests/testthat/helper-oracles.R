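# Independent brute-force oracles, transcribed directly from the
# published definitions and kept structurally distinct from the package's
# vectorised implementations.

# Weir & Cockerham (1984) two-population variance components for one
# marker, scalar arithmetic with the population count r kept explicit.
oracle_wc_site <- function(g1, g2) {
  r <- 2
  per_pop <- function(g) {
    g <- g[!is.na(g)]
    list(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
  }
  s <- list(per_pop(g1), per_pop(g2))
  n <- sapply(s, `[[`, "n")
  p <- sapply(s, `[[`, "p")
  h <- sapply(s, `[[`, "h")
  if (any(n < 2)) return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                              theta = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (tot > 0) a / tot else NA_real_)
}

# nucleotide diversity of a window by literal all-pairs allele
# enumeration: expand every site into its 2N-allele vector, count
# differences over every haplotype pair, average, divide by window bp
oracle_pi_window <- function(dosages, window_bp) {
  dosages <- unname(as.matrix(dosages))
  n_hap <- 2L * nrow(dosages)
  total <- 0
  for (j in seq_len(ncol(dosages))) {
    alleles <- unlist(lapply(dosages[, j], function(g) {
      c(rep(1L, g), rep(0L, 2L - g))
    }))
    for (i1 in 1:(n_hap - 1L)) {
      for (i2 in (i1 + 1L):n_hap) {
        total <- total + (alleles[i1] != alleles[i2])
      }
    }
  }
  total / choose(n_hap, 2) / window_bp
}

# Tajima (1989) D from a genotype window, textbook transcription
oracle_tajima_d <- function(dosages) {
  n <- 2L * nrow(dosages)
  ac <- colSums(dosages)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  khat <- sum(ac * (n - ac)) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# squared Pearson correlation from first principles
oracle_r2 <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  (cxy / sqrt(var(x) * var(y)))^2
}

# imputation accuracy of the per-marker major-genotype baseline
baseline_major_accuracy <- function(masked_panel, mask) {
  major <- apply(masked_panel$dosage, 2, function(x) {
    tb <- table(x)
    as.integer(names(tb)[which.max(tb)])
  })
  mean(major[mask$marker] == mask$truth)
}
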