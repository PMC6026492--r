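# intersection filter, candidate-gene windows, hypergeometric
# enrichment, report consistency

fake_assoc <- function(chrom, pos) {
  data.frame(chrom = chrom, pos = pos,
             id = paste0(chrom, "_", pos),
             beta = 0.1, se = 0.05, p = 1e-6,
             p_bonferroni = 1e-4, q_bh = 1e-5,
             model = "MLM-QK", stringsAsFactors = FALSE)
}

fake_windows <- function(chrom, start, end, fst = 0.4, f99 = TRUE) {
  data.frame(chrom = chrom, start = start, end = end,
             fst_weighted = fst, flag_95 = TRUE, flag_99 = f99,
             stringsAsFactors = FALSE)
}

test_that("intersection containment is 1-based inclusive at both edges", {
  win <- fake_windows("chr1", 1001L, 2000L)
  hits <- intersect_gwas_sweeps(
    fake_assoc("chr1", c(1000L, 1001L, 1500L, 2000L, 2001L)), win)
  expect_equal(hits$pos, c(1001L, 1500L, 2000L))
  expect_equal(unique(hits$window_tier), "99th")
  expect_equal(unique(hits$window_fst), 0.4)
})

test_that("the intersection filter never adds hits and honours edge cases", {
  a <- fake_assoc("chr1", c(500L, 1500L, 2500L))
  win_all <- fake_windows("chr1", 1L, 10000L)
  expect_equal(intersect_gwas_sweeps(a, win_all)$pos, a$pos)  # identity
  expect_equal(nrow(intersect_gwas_sweeps(a, win_all[0, ])), 0L)
  expect_error(intersect_gwas_sweeps(a, fake_windows("chrX", 1L, 1e6L)),
               "disjoint")
  # overlapping windows each produce a row for a contained marker
  win2 <- rbind(fake_windows("chr1", 1L, 2000L),
                fake_windows("chr1", 1000L, 3000L))
  h2 <- intersect_gwas_sweeps(fake_assoc("chr1", 1500L), win2)
  expect_equal(nrow(h2), 2L)
})

test_that("candidate genes come from the flank window with inclusive boundaries", {
  pan <- random_panel(n = 10, m = 30, seed = 81)  # positions 1..30 kb
  ann <- toy_annotation()
  # marker 20 sits at 20000: genes overlapping [10000, 30000]
  g <- candidate_genes(pan, 20L, ann, flank = 10000, use_ld_block = FALSE)
  expect_setequal(g$gene_id, "g3")
  expect_equal(g$distance[g$gene_id == "g3"], 0L)  # contains the marker
  # flank = 0 returns only containing genes
  g0 <- candidate_genes(pan, 20L, ann, flank = 0, use_ld_block = FALSE)
  expect_equal(g0$gene_id, "g3")
  g5 <- candidate_genes(pan, 3L, ann, flank = 0, use_ld_block = FALSE)
  expect_equal(nrow(g5), 0L)  # marker at 3000 lies between genes
  # a gene starting exactly flank bp away is included
  g2 <- candidate_genes(pan, 30L, ann, flank = 10000,
                        use_ld_block = FALSE)
  expect_true("g4" %in% g2$gene_id)  # g4 starts at 40000 = pos + flank
  expect_equal(g2$distance[g2$gene_id == "g4"], 10000L)
  # absent chromosome: warning and empty result
  pan2 <- random_panel(n = 10, m = 3, seed = 82)
  pan2$markers$chrom <- "chr9"
  expect_warning(gg <- candidate_genes(pan2, 1L, ann, use_ld_block = FALSE),
                 "absent")
  expect_equal(nrow(gg), 0L)
})

test_that("an LD block wider than the flanks widens the search interval", {
  x <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 1L)
  set.seed(83)
  d <- cbind(x, sample(x), x)
  pan <- make_panel(d, pos = c(1000L, 20000L, 39000L))
  ann <- toy_annotation()
  # index marker 1 is in perfect LD with the marker at 39 kb: the block
  # [1000, 39000] catches g3 even though the 10 kb flank would not
  g <- candidate_genes(pan, 1L, ann, flank = 10000, use_ld_block = TRUE)
  expect_true("g3" %in% g$gene_id)
  g_noblock <- candidate_genes(pan, 1L, ann, flank = 10000,
                               use_ld_block = FALSE)
  expect_false("g3" %in% g_noblock$gene_id)
})

test_that("hypergeometric enrichment matches hand combinatorics and Monte Carlo", {
  ann <- toy_annotation()
  # candidates = universe: every term has p = 1
  enr_all <- enrichment_hypergeom(ann$gene_id, ann)
  expect_true(all(enr_all$p == 1))
  expect_error(enrichment_hypergeom("nope", ann), "universe")

  # K = 5 of N = 100 genes carry the term; n = 10 candidates, k = 5
  big <- data.frame(gene_id = paste0("G", 1:100), chrom = "chr1",
                    start = 1:100 * 1000L, end = 1:100 * 1000L + 500L,
                    strand = "+", stringsAsFactors = FALSE)
  big$go <- c(rep(list("GO:X"), 5), rep(list("GO:Y"), 95))
  class(big) <- c("gene_annotation", "data.frame")
  enr <- enrichment_hypergeom(paste0("G", 1:10), big)
  hand <- choose(5, 5) * choose(95, 5) / choose(100, 10)
  expect_equal(enr$p[enr$term == "GO:X"], hand, tolerance = 1e-12)

  # Monte-Carlo cross-check within 3 simulation SDs on a moderate tail:
  # 2 of the 10 candidates carry the 5-gene term
  enr2 <- enrichment_hypergeom(paste0("G", c(4, 5, 11:18)), big)
  p2 <- enr2$p[enr2$term == "GO:X"]
  set.seed(84)
  n_mc <- 40000
  k_mc <- replicate(n_mc, sum(sample(100, 10) <= 5))
  p_mc <- mean(k_mc >= 2)
  se_mc <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p2 - p_mc), 3 * se_mc)
})

test_that("the planted enriched term ranks first on sweep-window candidates", {
  sw <- data.frame(chrom = 1L, start = 2e5, end = 4e5, f_sweep = 0.5,
                   mode = "divergent")
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 1e6,
                    marker_spacing = 10000, sweeps = sw,
                    missing_array = 0, missing_radseq = 0, seed = 85L)
  sim <- simulate_panel(cfg)
  ann <- sim$annotation
  cand <- ann$gene_id[ann$chrom == "chr1" & ann$end >= 2e5 &
                        ann$start <= 4e5]
  enr <- enrichment_hypergeom(cand, ann)
  expect_equal(enr$term[1], sim$truth$enriched_term)
  expect_lt(enr$q_bh[1], 0.05)
})

test_that("the end-to-end report is internally consistent and deterministic", {
  qt <- data.frame(marker = 30L, trait = "SBW", beta = 0.6)
  sw <- data.frame(chrom = 1L, start = 2e5, end = 35e4, f_sweep = 0.5,
                   mode = "divergent")
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 8e5,
                    marker_spacing = 8000, sweeps = sw, qtls = qt,
                    seed = 86L)
  sim <- simulate_panel(cfg)
  rep1 <- run_pipeline(sim$panel, sim$phenotypes, sim$annotation,
                       spec = window_spec(100000, 50000), n_perm = 20L,
                       seed = 99L)
  expect_equal(rep1$mean_pi_ratio,
               mean(rep1$scan$pi_ratio[is.finite(rep1$scan$pi_ratio)],
                    na.rm = TRUE))
  expect_equal(sum(rep1$scan$flag_95), sum(
    rep1$scan$fst_weighted >= rep1$thresholds[["p95"]], na.rm = TRUE))
  js1 <- report_json(rep1)
  rep2 <- run_pipeline(sim$panel, sim$phenotypes, sim$annotation,
                       spec = window_spec(100000, 50000), n_perm = 20L,
                       seed = 99L)
  expect_identical(as.character(js1), as.character(report_json(rep2)))
})
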