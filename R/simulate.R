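# Two-subpopulation simulator: Balding-Nichols divergence with an
# exponential haplotype-copying process for LD, planted sweep windows and
# QTLs, platform-differential missingness, two-year phenotypes.

#' Simulation configuration
#'
#' Defaults emulate the wild-vs-cultivated grapevine panel the pipeline is
#' designed for: 48 sativa + 44 sylvestris diploids, 19 chromosomes, one
#' SNP per ~18 kb, background divergence F = 0.12 under the
#' Balding-Nichols model, LD decaying on a ~10 kb scale, heavier
#' missingness and a low-MAF excess on one platform, and 2-year
#' quantitative phenotypes with subpopulation mean shifts.
#'
#' @param n_sativa,n_sylvestris diploid sample sizes per subpopulation.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (recycled across chromosomes).
#' @param marker_spacing mean inter-marker distance in bp (exponential gaps).
#' @param f_background Balding-Nichols divergence parameter F for
#'   non-sweep markers; the expected genome-wide Weir-Cockerham F_ST.
#' @param sweeps data.frame of planted sweep windows with columns `chrom`
#'   (integer index), `start`, `end`, `f_sweep`, `mode` (one of
#'   `"divergent"`, `"mono_sylvestris"`, `"mono_sativa"`); `NULL` for none.
#' @param rho LD copying length scale in bp: a haplotype copies its allele
#'   from the previous marker with probability `exp(-d / rho)` (`d` the bp
#'   gap), else draws fresh from the subpopulation frequency, so r^2 decays
#'   with distance at scale `rho`.  A named vector
#'   `c(sativa = ..., sylvestris = ...)` gives group-specific scales.
#' @param maf_range ancestral allele frequencies are drawn uniformly on
#'   this interval.
#' @param missing_array,missing_radseq per-platform missing-genotype rates.
#' @param prop_array proportion of markers tagged as array-derived.
#' @param array_low_maf_frac fraction of array markers whose ancestral
#'   frequency is forced near 0/1, emulating a low-MAF excess from
#'   genotype-calling artefacts on that platform.
#' @param qtls data.frame of planted QTLs with columns `marker` (global
#'   marker index), `trait`, `beta` (effect per alt allele); `NULL` for none.
#' @param traits data.frame of quantitative trait definitions with columns
#'   `trait`, `mu`, `shift_sativa` (added to sativa means), `sd_resid`;
#'   defaults cover SBCW, SBW, yield, NBCs, Brix and pH with sativa-larger
#'   bunch/berry/sugar values and sylvestris-lower pH.
#' @param year_effects additive fixed effects for the two harvest years.
#' @param seed RNG seed; the same config yields byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sativa = 48L, n_sylvestris = 44L,
                       n_chromosomes = 19L, chrom_length = 25e6,
                       marker_spacing = 18000,
                       f_background = 0.12,
                       sweeps = NULL,
                       rho = 10000,
                       maf_range = c(0.05, 0.95),
                       missing_array = 0.02, missing_radseq = 0.15,
                       prop_array = 0.4,
                       array_low_maf_frac = 0.05,
                       qtls = NULL,
                       traits = default_traits(),
                       year_effects = c(`2016` = 0, `2017` = 0.3),
                       seed = 1L) {
  stopifnot(f_background > 0, f_background < 1,
            n_sativa >= 2, n_sylvestris >= 2, marker_spacing > 0)
  if (!is.null(sweeps)) {
    stopifnot(all(c("chrom", "start", "end", "f_sweep", "mode") %in%
                    names(sweeps)))
    if (!all(sweeps$mode %in% c("divergent", "mono_sylvestris",
                                "mono_sativa"))) {
      stop("unknown sweep mode")
    }
    len <- rep_len(chrom_length, n_chromosomes)
    if (any(sweeps$start < 1 | sweeps$end > len[sweeps$chrom])) {
      stop("sweep window outside chromosome bounds")
    }
    div <- sweeps$mode == "divergent"
    if (any(sweeps$f_sweep[div] <= f_background)) {
      stop("divergent sweep f_sweep must exceed f_background")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

default_traits <- function() {
  data.frame(
    trait = c("SBCW", "SBW", "yield", "NBCs", "Brix", "pH"),
    mu = c(60, 1.0, 0.8, 10, 16, 3.1),
    shift_sativa = c(90, 0.6, 1.2, 5, 4, 0.3),
    sd_resid = c(30, 0.3, 0.5, 3, 1.5, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-subpopulation genotype/phenotype dataset
#'
#' Marker positions are laid down with exponential gaps; each marker's
#' ancestral frequency p is drawn from the configured spectrum and the two
#' subpopulation frequencies from the Balding-Nichols beta
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with F the background divergence, or the
#' sweep-specific F inside divergent windows.  `mono_*` windows fix the
#' named subpopulation at 0/1 (monomorphic).  Haplotypes are built by the
#' exponential copying process (see [sim_config()]); genotypes are sums of
#' two haplotypes.  Phenotypes follow
#' `y = mu + group shift + year effect + sum(beta_q g_q) + N(0, sd^2)`
#' over two years, plus the binary `Species` trait (1 = sativa).  Toy gene
#' models are tiled every ~20 kb; genes inside sweep windows carry an
#' enriched GO term (`GO:0099999`).
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` ([genotype_panel()], with missingness
#'   applied), `phenotypes` (`phenotype_table`), `annotation`
#'   (`gene_annotation`) and `truth` (planted sweep windows with marker
#'   counts, per-marker subpopulation frequencies, QTL effects, per-trait
#'   group means).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  len <- rep_len(cfg$chrom_length, cfg$n_chromosomes)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  rho <- cfg$rho
  if (is.null(names(rho))) rho <- c(sativa = rho[[1L]], sylvestris = rho[[1L]])

  # marker map: exponential gaps at the target density
  map <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ci) {
    pos <- cumsum(1 + stats::rexp(ceiling(2 * len[ci] / cfg$marker_spacing),
                                  rate = 1 / cfg$marker_spacing))
    pos <- as.integer(round(pos[pos <= len[ci]]))
    pos <- unique(pos)
    data.frame(chrom = chroms[ci], chrom_idx = ci, pos = pos,
               stringsAsFactors = FALSE)
  }))
  m <- nrow(map)

  # ancestral frequencies, with a low-MAF excess planted on the array
  platform <- ifelse(stats::runif(m) < cfg$prop_array, "array", "radseq")
  p_anc <- stats::runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
  low <- platform == "array" & stats::runif(m) < cfg$array_low_maf_frac
  p_anc[low] <- stats::runif(sum(low), 0.005, 0.04)

  # per-marker divergence parameter and sweep membership
  f_mark <- rep(cfg$f_background, m)
  mono_syl <- rep(FALSE, m)
  mono_sat <- rep(FALSE, m)
  truth_sweeps <- NULL
  if (!is.null(cfg$sweeps)) {
    sw <- cfg$sweeps
    sw$n_markers <- 0L
    for (i in seq_len(nrow(sw))) {
      inwin <- map$chrom_idx == sw$chrom[i] &
        map$pos >= sw$start[i] & map$pos <= sw$end[i]
      sw$n_markers[i] <- sum(inwin)
      if (!any(inwin)) {
        warning("sweep window ", i, " contains no markers")
        next
      }
      if (sw$mode[i] == "divergent") f_mark[inwin] <- sw$f_sweep[i]
      if (sw$mode[i] == "mono_sylvestris") mono_syl[inwin] <- TRUE
      if (sw$mode[i] == "mono_sativa") mono_sat[inwin] <- TRUE
    }
    truth_sweeps <- sw
  }

  # Balding-Nichols subpopulation frequencies
  bn_draw <- function(p, f) {
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p_sat <- bn_draw(p_anc, f_mark)
  p_syl <- bn_draw(p_anc, f_mark)
  fix_at <- as.numeric(p_anc >= 0.5)
  p_syl[mono_syl] <- fix_at[mono_syl]
  p_sat[mono_sat] <- fix_at[mono_sat]

  # Haplotype copying process per subpopulation per chromosome.  The
  # latent uniform quantile (not the allele itself) is copied from the
  # previous marker with probability exp(-d / rho): this preserves each
  # marker's subpopulation frequency exactly (so the Balding-Nichols
  # F_ST target survives) while alleles at nearby markers stay highly
  # correlated, giving r^2 decay at scale rho.
  hap_group <- function(n_dip, freq, scale) {
    nh <- 2L * n_dip
    H <- matrix(0L, nrow = nh, ncol = m)
    for (ci in unique(map$chrom_idx)) {
      j <- which(map$chrom_idx == ci)
      gaps <- c(Inf, diff(map$pos[j]))
      pcopy <- exp(-gaps / scale)
      fresh <- matrix(stats::runif(length(j) * nh), nrow = nh)
      keep <- matrix(stats::runif(length(j) * nh) < rep(pcopy, each = nh),
                     nrow = nh)
      u <- fresh[, 1L]
      H[, j[1L]] <- as.integer(u < freq[j[1L]])
      for (k in seq_along(j)[-1L]) {
        u <- ifelse(keep[, k], u, fresh[, k])
        H[, j[k]] <- as.integer(u < freq[j[k]])
      }
    }
    H
  }
  H_sat <- hap_group(cfg$n_sativa, p_sat, rho[["sativa"]])
  H_syl <- hap_group(cfg$n_sylvestris, p_syl, rho[["sylvestris"]])
  # monomorphic windows are forced after copying so no allele leaks in
  # from flanking markers
  if (any(mono_sat)) H_sat[, mono_sat] <- rep(as.integer(fix_at[mono_sat]),
                                              each = nrow(H_sat))
  if (any(mono_syl)) H_syl[, mono_syl] <- rep(as.integer(fix_at[mono_syl]),
                                              each = nrow(H_syl))
  dose <- function(H) H[seq(1, nrow(H), 2), , drop = FALSE] +
    H[seq(2, nrow(H), 2), , drop = FALSE]
  d <- rbind(dose(H_sat), dose(H_syl))

  samples <- data.frame(
    sample_id = c(sprintf("sat%02d", seq_len(cfg$n_sativa)),
                  sprintf("syl%02d", seq_len(cfg$n_sylvestris))),
    group = rep(c("sativa", "sylvestris"),
                c(cfg$n_sativa, cfg$n_sylvestris)),
    stringsAsFactors = FALSE
  )
  markers <- data.frame(chrom = map$chrom, pos = map$pos,
                        ref = "A", alt = "G", platform = platform,
                        stringsAsFactors = FALSE)

  # phenotypes: two years, group shifts, planted QTLs, residual noise
  n <- nrow(samples)
  sat <- samples$group == "sativa"
  years <- names(cfg$year_effects)
  ph <- list()
  truth_means <- list()
  for (i in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[i, ]
    gval <- rep(0, n)
    if (!is.null(cfg$qtls)) {
      qt <- cfg$qtls[cfg$qtls$trait == tr$trait, , drop = FALSE]
      for (q in seq_len(nrow(qt))) {
        gval <- gval + qt$beta[q] * d[, qt$marker[q]]
      }
    }
    base <- tr$mu + ifelse(sat, tr$shift_sativa, 0) + gval
    for (y in years) {
      ph[[length(ph) + 1L]] <- data.frame(
        sample_id = samples$sample_id, trait = tr$trait, year = y,
        value = base + cfg$year_effects[[y]] +
          stats::rnorm(n, 0, tr$sd_resid),
        stringsAsFactors = FALSE
      )
    }
    truth_means[[tr$trait]] <- c(
      sativa = tr$mu + tr$shift_sativa + mean(gval[sat]),
      sylvestris = tr$mu + mean(gval[!sat])
    )
  }
  ph[[length(ph) + 1L]] <- data.frame(
    sample_id = samples$sample_id, trait = "Species", year = years[1L],
    value = as.numeric(sat), stringsAsFactors = FALSE
  )
  phenotypes <- as_phenotype_table(do.call(rbind, ph))

  # toy gene models every ~20 kb; the enriched GO term marks sweep genes
  # (plus a thin background scatter so the term exists genome-wide)
  go_pool <- sprintf("GO:%07d", 1:20)
  ann <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ci) {
    starts <- seq(5001, len[ci] - 10000, by = 20000)
    data.frame(chrom = chroms[ci], chrom_idx = ci, start = as.integer(starts),
               end = as.integer(starts + 9999L), stringsAsFactors = FALSE)
  }))
  ann$gene_id <- sprintf("VIT_%05d", seq_len(nrow(ann)))
  ann$strand <- rep_len(c("+", "-"), nrow(ann))
  base_go <- lapply(seq_len(nrow(ann)), function(i) {
    sample(go_pool, 1L + stats::rbinom(1L, 2L, 0.5))
  })
  enriched <- stats::runif(nrow(ann)) < 0.02
  if (!is.null(truth_sweeps)) {
    for (i in seq_len(nrow(truth_sweeps))) {
      enriched <- enriched |
        (ann$chrom_idx == truth_sweeps$chrom[i] &
           ann$end >= truth_sweeps$start[i] &
           ann$start <= truth_sweeps$end[i])
    }
  }
  ann$go <- lapply(seq_len(nrow(ann)), function(i) {
    if (enriched[i]) c(base_go[[i]], "GO:0099999") else base_go[[i]]
  })
  ann$chrom_idx <- NULL
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand", "go")]
  class(ann) <- c("gene_annotation", "data.frame")

  # platform-differential missingness
  miss_rate <- ifelse(platform == "array", cfg$missing_array,
                      cfg$missing_radseq)
  mask <- matrix(stats::runif(n * m) < rep(miss_rate, each = n), nrow = n)
  d[mask] <- NA_integer_

  panel <- genotype_panel(d, markers, samples)
  truth <- list(sweeps = truth_sweeps,
                freq = data.frame(chrom = map$chrom, pos = map$pos,
                                  p_sativa = p_sat, p_sylvestris = p_syl,
                                  f = f_mark, stringsAsFactors = FALSE),
                qtls = cfg$qtls,
                trait_means = truth_means,
                enriched_term = "GO:0099999")
  list(panel = panel, phenotypes = phenotypes, annotation = ann,
       truth = truth)
}

#' Mask observed genotypes for imputation cross-validation
#'
#' Sets exactly `floor(fraction * n_observed)` observed entries to missing,
#' never leaving a marker with fewer than two observed genotypes, and
#' returns the mask so accuracy can be scored against the held-out truth.
#'
#' @param panel a [genotype_panel()].
#' @param fraction fraction of currently observed entries to mask, in (0, 1);
#'   0 returns the panel unchanged with an empty mask.
#' @param seed RNG seed (same seed, same mask).
#' @return list with `panel` (masked) and `mask` (data.frame `sample`,
#'   `marker` indices and the held-out `truth` dosage).
#' @export
mask_genotypes <- function(panel, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  obs <- which(!is.na(panel$dosage))
  n_mask <- floor(fraction * length(obs))
  if (n_mask == 0L) {
    return(list(panel = panel,
                mask = data.frame(sample = integer(), marker = integer(),
                                  truth = integer())))
  }
  d <- panel$dosage
  sel <- withr::with_seed(seed, {
    sel <- sample(obs, n_mask)
    # keep >= 2 observed genotypes per marker: resample clashes
    for (iter in 1:20) {
      tmp <- d
      tmp[sel] <- NA_integer_
      short <- which(colSums(!is.na(tmp)) < 2L)
      if (!length(short)) break
      bad_cols <- (sel - 1L) %/% nrow(d) + 1L
      drop <- sel[bad_cols %in% short]
      keep <- setdiff(sel, drop)
      pool <- setdiff(obs, keep)
      pool <- pool[!(((pool - 1L) %/% nrow(d) + 1L) %in% short)]
      if (length(pool) < length(drop)) {
        stop("cannot mask ", n_mask, " entries without emptying a marker")
      }
      sel <- c(keep, sample(pool, length(drop)))
    }
    sel
  })
  truth <- d[sel]
  d[sel] <- NA_integer_
  out <- panel
  out$dosage <- d
  list(panel = out,
       mask = data.frame(sample = (sel - 1L) %% nrow(d) + 1L,
                         marker = (sel - 1L) %/% nrow(d) + 1L,
                         truth = truth))
}
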