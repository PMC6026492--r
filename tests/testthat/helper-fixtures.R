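# programmatic fixtures shared across test files

# quick panel from a dosage matrix; positions default to 1 kb spacing on
# one chromosome, half sativa / half sylvestris
make_panel <- function(dosage, chrom = NULL, pos = NULL, group = NULL,
                       platform = "array", ref = "A", alt = "G") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  n <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(group)) {
    group <- rep(c("sativa", "sylvestris"), c(ceiling(n / 2), floor(n / 2)))
  }
  genotype_panel(
    dosage,
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               platform = platform, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%02d", seq_len(n)), group = group,
               stringsAsFactors = FALSE)
  )
}

# random complete biallelic panel
random_panel <- function(n = 20, m = 30, seed = 1, maf = c(0.1, 0.9)) {
  withr::with_seed(seed, {
    p <- runif(m, maf[1], maf[2])
    d <- sapply(p, function(pp) rbinom(n, 2, pp))
    make_panel(d)
  })
}

# tiny gene annotation at known coordinates
toy_annotation <- function() {
  ann <- data.frame(
    gene_id = paste0("g", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 5000L, 19000L, 40000L, 100L, 900L),
    end = c(900L, 9000L, 21000L, 45000L, 800L, 900L),
    strand = "+",
    stringsAsFactors = FALSE
  )
  ann$go <- list(c("GO:1"), c("GO:1", "GO:2"), c("GO:2"), c("GO:3"),
                 c("GO:2"), c("GO:3"))
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
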