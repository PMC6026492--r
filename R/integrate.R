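# Combining the scan with the GWAS: the intersection filter, candidate
# gene windows (+/-10 kb or the LD block), hypergeometric GO
# over-representation and the final pipeline report.

#' Keep associations that fall inside flagged selection windows
#'
#' The cross-evidence rule: a marker-trait association is reported only
#' when its marker lies inside at least one outlier window of the F_ST
#' scan (1-based inclusive containment).  Every containing window is
#' listed with its F_ST and flag tier.
#'
#' @param assoc an `assoc_result` (or any data.frame with `chrom`, `pos`,
#'   `id`, `p`, plus adjusted columns).
#' @param flagged output of [call_outliers()], restricted by the caller to
#'   the rows considered outliers (e.g. `flag_95`).
#' @return data.frame: the surviving association rows with `window_start`,
#'   `window_end`, `window_fst` and `window_tier` columns (one row per
#'   association x containing window).
#' @export
intersect_gwas_sweeps <- function(assoc, flagged) {
  if (!nrow(flagged)) return(assoc[0, , drop = FALSE])
  if (!any(assoc$chrom %in% flagged$chrom)) {
    stop("association and window chromosome namespaces are disjoint")
  }
  out <- lapply(seq_len(nrow(flagged)), function(i) {
    w <- flagged[i, ]
    hit <- assoc$chrom == w$chrom & assoc$pos >= w$start &
      assoc$pos <= w$end
    if (!any(hit)) return(NULL)
    cbind(assoc[hit, , drop = FALSE],
          window_start = w$start, window_end = w$end,
          window_fst = w$fst_weighted,
          window_tier = if (isTRUE(w$flag_99)) "99th" else "95th")
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(cbind(assoc[0, , drop = FALSE],
                                 window_start = integer(),
                                 window_end = integer(),
                                 window_fst = numeric(),
                                 window_tier = character()))
  rownames(res) <- NULL
  res
}

#' Candidate genes around a marker
#'
#' Searches `marker position +/- flank` (default 10 kb each side, the
#' 20 kb total window) for overlapping gene models; when an LD block
#' anchored at the marker extends beyond the flanks, the whole block
#' interval is searched instead.  Overlap is any-overlap, 1-based
#' inclusive.
#'
#' @param panel a complete [genotype_panel()] (used for the LD block).
#' @param marker marker column index in the panel.
#' @param annotation a `gene_annotation` (see [read_gff()]).
#' @param flank bp searched either side of the marker (default 10 kb).
#' @param use_ld_block extend the interval by [ld_block_extend()] when the
#'   block is wider than the flanks (default `TRUE`).
#' @param r2_min LD-block threshold passed through.
#' @return data.frame of overlapping genes with `distance`: signed bp from
#'   the marker to the nearest gene edge, 0 when the gene contains the
#'   marker (negative = gene upstream of the marker).
#' @export
candidate_genes <- function(panel, marker, annotation, flank = 10000,
                            use_ld_block = TRUE, r2_min = 0.8) {
  ch <- panel$markers$chrom[marker]
  pos <- panel$markers$pos[marker]
  lo <- pos - flank
  hi <- pos + flank
  if (use_ld_block) {
    blk <- ld_block_extend(panel, marker, r2_min = r2_min)
    if (blk$start < lo || blk$end > hi) {
      lo <- min(lo, blk$start)
      hi <- max(hi, blk$end)
    }
  }
  if (!any(annotation$chrom == ch)) {
    warning("chromosome ", ch, " absent from annotation")
    return(annotation[0, , drop = FALSE])
  }
  hit <- annotation$chrom == ch & annotation$end >= lo &
    annotation$start <= hi
  genes <- annotation[hit, , drop = FALSE]
  genes$distance <- ifelse(
    genes$start <= pos & genes$end >= pos, 0L,
    ifelse(genes$start > pos, genes$start - pos, genes$end - pos)
  )
  rownames(genes) <- NULL
  genes
}

#' Hypergeometric GO over-representation
#'
#' One-sided upper-tail hypergeometric test per GO term: k of the n
#' candidate genes carry the term against K of the N universe genes, with
#' Benjamini-Hochberg adjustment across terms.  Terms absent from the
#' universe are skipped.
#'
#' @param candidates character vector of candidate gene ids (must all be
#'   in the universe).
#' @param annotation the `gene_annotation` defining the universe and the
#'   gene-to-GO mapping.
#' @return data.frame per term: `term`, `k`, `K`, `n`, `N`, `p`, `q_bh`,
#'   sorted by p.
#' @export
enrichment_hypergeom <- function(candidates, annotation) {
  if (!all(candidates %in% annotation$gene_id)) {
    stop("candidate gene(s) not in the annotation universe")
  }
  N <- nrow(annotation)
  n <- length(unique(candidates))
  gene_terms <- annotation$go
  names(gene_terms) <- annotation$gene_id
  term_genes <- split(
    rep(annotation$gene_id, vapply(gene_terms, length, 1L)),
    unlist(gene_terms)
  )
  res <- do.call(rbind, lapply(names(term_genes), function(tm) {
    Kg <- unique(term_genes[[tm]])
    k <- sum(candidates %in% Kg)
    data.frame(term = tm, k = k, K = length(Kg), n = n, N = N,
               p = stats::phyper(k - 1L, length(Kg), N - length(Kg), n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q_bh <- adjust_pvalues(res$p, "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full scan-plus-GWAS pipeline and build the report
#'
#' Convenience driver: QC chain, PCA, kinship, window scan with empirical
#' and permutation thresholds, LD decay per group, GWAS (all three models)
#' on each trait's across-year BLUPs and on the binary Species trait,
#' intersection with flagged windows, candidate genes and GO enrichment.
#' All randomness flows from `seed`, so the report is reproducible
#' byte-for-byte.
#'
#' @param panel a raw [genotype_panel()] (missingness allowed).
#' @param phenotypes a `phenotype_table`.
#' @param annotation a `gene_annotation`.
#' @param spec a [window_spec()].
#' @param n_perm label permutations for the null (default 1000).
#' @param n_pcs covariate components for GLM-Q / MLM-QK (default 3).
#' @param seed RNG seed for the permutation null.
#' @param alpha Bonferroni significance level for reported hits.
#' @return list of class `pipeline_report`; see [report_json()].
#' @export
run_pipeline <- function(panel, phenotypes, annotation,
                         spec = window_spec(), n_perm = 1000L,
                         n_pcs = 3L, seed = 1L, alpha = 0.05) {
  qc <- qc_pipeline(panel)
  pan <- qc$panel
  groups <- panel_groups(pan)
  scan <- window_scan(pan, groups, spec)
  thr <- empirical_thresholds(scan)
  null <- permutation_null(pan, groups, spec, n_reps = n_perm, seed = seed)
  scan <- call_outliers(scan, thr, null)

  pca <- panel_pca(pan, n_pcs)
  K <- kinship_vanraden(pan)
  decay <- lapply(c(all = NA, sativa = "sativa", sylvestris = "sylvestris"),
                  function(g) {
    sub <- if (is.na(g)) NULL else which(pan$samples$group == g)
    ld_decay(pairwise_r2(pan, subset = sub, max_dist = 200000))
  })

  traits <- setdiff(unique(phenotypes$trait), "Species")
  gwas <- list()
  for (tr in traits) {
    y <- compute_blups(phenotypes, tr)$blup
    gwas[[tr]] <- list(
      `naive-GLM` = glm_assoc(pan, y),
      `GLM-Q` = glm_assoc(pan, y, Q = pca$scores),
      `MLM-QK` = mlm_assoc(pan, y, Q = pca$scores, K = K)
    )
  }
  sp <- phenotypes[phenotypes$trait == "Species", ]
  ysp <- stats::setNames(sp$value, sp$sample_id)
  gwas[["Species"]] <- list(
    `naive-GLM` = glm_assoc(pan, ysp),
    `GLM-Q` = glm_assoc(pan, ysp, Q = pca$scores),
    `MLM-QK` = mlm_assoc(pan, ysp, Q = pca$scores, K = K)
  )

  flagged <- scan[scan$flag_95, , drop = FALSE]
  hits <- list()
  for (tr in names(gwas)) {
    a <- gwas[[tr]][["MLM-QK"]]
    sig <- a[!is.na(a$p_bonferroni) & a$p_bonferroni <= alpha, ,
             drop = FALSE]
    if (nrow(sig)) {
      hits[[tr]] <- intersect_gwas_sweeps(sig, flagged)
    }
  }
  cand <- unique(unlist(lapply(names(hits), function(tr) {
    h <- hits[[tr]]
    unlist(lapply(match(h$id, pan$markers$id), function(mi) {
      candidate_genes(pan, mi, annotation)$gene_id
    }))
  })))
  enr <- if (length(cand)) enrichment_hypergeom(cand, annotation) else NULL

  structure(list(
    accounting = qc$accounting,
    n_samples = n_samples(pan), n_markers = n_markers(pan),
    global_fst = global_fst(pan, groups),
    thresholds = thr, null_thresholds = null$thresholds,
    scan = scan,
    mean_pi_ratio = mean(scan$pi_ratio[is.finite(scan$pi_ratio)],
                         na.rm = TRUE),
    mean_tajd = c(
      sativa = mean(scan$tajd_sativa, na.rm = TRUE),
      sylvestris = mean(scan$tajd_sylvestris, na.rm = TRUE)),
    decay_distance = vapply(decay, function(x) x$decay_distance, 1),
    pca_var_prop = pca$var_prop,
    gwas = gwas, hits = hits,
    candidate_genes = cand, enrichment = enr,
    seed = seed
  ), class = "pipeline_report")
}

#' Serialise a pipeline report
#'
#' Machine-readable JSON (deterministic: no timestamps, fixed ordering)
#' plus a short human-readable summary.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param path optional file to write the JSON to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  flat <- list(
    n_samples = report$n_samples,
    n_markers = report$n_markers,
    accounting = report$accounting,
    global_fst = report$global_fst,
    empirical_thresholds = as.list(report$thresholds),
    permutation_thresholds = as.list(report$null_thresholds),
    n_windows = nrow(report$scan),
    n_flagged_95 = sum(report$scan$flag_95),
    n_flagged_99 = sum(report$scan$flag_99),
    mean_pi_ratio = report$mean_pi_ratio,
    mean_tajd = as.list(report$mean_tajd),
    decay_distance_bp = as.list(report$decay_distance),
    pca_var_prop = report$pca_var_prop,
    hits = lapply(report$hits, function(h)
      h[, c("chrom", "pos", "id", "p", "p_bonferroni", "window_fst",
            "window_tier")]),
    candidate_genes = report$candidate_genes,
    enrichment_top = if (!is.null(report$enrichment))
      utils::head(report$enrichment, 10) else NULL,
    seed = report$seed
  )
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @method print pipeline_report
#' @export
print.pipeline_report <- function(x, ...) {
  cat("vitiscan pipeline report\n")
  cat(sprintf("  panel: %d samples x %d markers\n", x$n_samples,
              x$n_markers))
  cat(sprintf("  genome-wide weighted F_ST: %.4f\n", x$global_fst))
  cat(sprintf("  window F_ST 95th / 99th percentile: %.3f / %.3f\n",
              x$thresholds[["p95"]], x$thresholds[["p99"]]))
  cat(sprintf("  permutation-null 95th percentile: %.3f\n",
              x$null_thresholds[["p95"]]))
  cat(sprintf("  windows: %d (%d flagged at 95th, %d at 99th)\n",
              nrow(x$scan), sum(x$scan$flag_95), sum(x$scan$flag_99)))
  cat(sprintf("  mean pi_sylvestris/pi_sativa: %.3f\n", x$mean_pi_ratio))
  cat(sprintf("  mean Tajima's D: sativa %.3f, sylvestris %.3f\n",
              x$mean_tajd[["sativa"]], x$mean_tajd[["sylvestris"]]))
  cat(sprintf("  LD decay below r2=0.2 (all samples): %s bp\n",
              format(x$decay_distance[["all"]])))
  nh <- sum(vapply(x$hits, nrow, 1L))
  cat(sprintf("  GWAS hits inside flagged windows: %d\n", nh))
  invisible(x)
}
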