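# Format plumbing: VCF 4.2 (GT only), GFF3 gene models, delimited
# phenotype/metadata tables.  Coordinates are 1-based inclusive throughout.

#' Read a VCF into a genotype panel
#'
#' Parses a diploid, GT-carrying VCF (via \pkg{vcfR}) and joins it with a
#' sample-metadata table mapping every VCF sample to a subpopulation group.
#' Per-marker platform tags are taken from a sidecar marker list
#' (`marker_platform_path`, TSV with columns `chrom`, `pos`, `platform`)
#' or, alternatively, from an INFO `SRC=` tag; unlisted markers default to
#' `"array"`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_metadata_path CSV/TSV with columns `sample_id`, `group`.
#'   Every VCF sample must appear; an unmapped sample is a hard error.
#' @param marker_platform_path optional sidecar marker list (see above).
#' @param drop_nonbiallelic if `TRUE` (default) multi-allelic records are
#'   dropped with a message; if `FALSE` they are an error.
#' @return A [genotype_panel()].  Dosage is the alternate-allele count;
#'   `./.` and half-calls become `NA`.  Markers are sorted by (chrom, pos).
#' @export
read_vcf <- function(path, sample_metadata_path,
                     marker_platform_path = NULL,
                     drop_nonbiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    if (!drop_nonbiallelic) stop(sum(multi), " multi-allelic record(s)")
    message("dropping ", sum(multi), " multi-allelic record(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  pos <- as.integer(fix$POS)
  key <- paste(fix$CHROM, pos)
  if (anyDuplicated(key)) {
    stop("duplicate marker position: ", key[duplicated(key)][1L])
  }
  # GT strings -> alt-allele dosage; half-calls (e.g. "./1") -> NA
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L

  meta <- read_table_auto(sample_metadata_path)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("sample metadata needs columns sample_id, group")
  }
  vcf_samples <- colnames(gt)
  unmapped <- setdiff(vcf_samples, meta$sample_id)
  if (length(unmapped)) {
    stop("VCF sample(s) missing from metadata: ",
         paste(unmapped, collapse = ", "))
  }
  group <- meta$group[match(vcf_samples, meta$sample_id)]

  platform <- rep("array", nrow(fix))
  info <- fix$INFO
  if (!is.null(info)) {
    src <- sub(".*SRC=([^;]+).*", "\\1", info)
    has <- grepl("SRC=", info)
    platform[has] <- src[has]
  }
  if (!is.null(marker_platform_path)) {
    ml <- read_table_auto(marker_platform_path)
    idx <- match(paste(fix$CHROM, pos), paste(ml$chrom, ml$pos))
    platform[!is.na(idx)] <- ml$platform[idx[!is.na(idx)]]
  }

  markers <- data.frame(chrom = fix$CHROM, pos = pos,
                        ref = fix$REF, alt = fix$ALT,
                        platform = platform, stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  genotype_panel(t(dos)[, ord, drop = FALSE],
                 markers[ord, , drop = FALSE],
                 data.frame(sample_id = vcf_samples, group = group,
                            stringsAsFactors = FALSE))
}

#' Write a genotype panel to VCF 4.2
#'
#' GT-only records, missing genotypes as `./.`, platform tag carried in the
#' INFO field as `SRC=`.  The writer is deterministic: identical panels give
#' byte-identical files.
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  mk <- panel$markers
  d <- panel$dosage
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Genotyping platform\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (ncol(d)) {
    gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
    for (g in 0:2) gt[t(d) == g] <- gt_code[g + 1L]
    body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS",
                  paste0("SRC=", mk$platform), "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expects columns `sample_id`, `trait`, `year`, `value`.  Quantitative
#' traits must be numeric; the binary trait `Species` may only take values
#' 0 (sylvestris) and 1 (sativa).
#'
#' @param path CSV or TSV file.
#' @return data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  ph <- read_table_auto(path)
  need <- c("sample_id", "trait", "year", "value")
  if (!all(need %in% names(ph))) {
    stop("phenotype table needs columns ", paste(need, collapse = ", "))
  }
  suppressWarnings(v <- as.numeric(ph$value))
  if (anyNA(v) & !anyNA(ph$value)) {
    stop("non-numeric phenotype value at row ", which(is.na(v))[1L])
  }
  ph$value <- v
  as_phenotype_table(ph)
}

#' @rdname read_phenotypes
#' @param df a data.frame with the phenotype columns, already in memory.
#' @export
as_phenotype_table <- function(df) {
  key <- paste(df$sample_id, df$trait, df$year)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, trait, year) record: ",
         key[duplicated(key)][1L])
  }
  sp <- df$value[df$trait == "Species"]
  if (length(sp) && !all(sp %in% c(0, 1))) {
    stop("Species trait must be 0 (sylvestris) or 1 (sativa)")
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features (1-based inclusive coordinates) and extracts the
#' `ID` and any `Ontology_term` GO annotations from the attribute column.
#' Strand is recorded but ignored by all downstream computations.
#'
#' @param path GFF3 file.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `go` (list column).
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (any(g$end < g$start)) {
    stop("GFF gene with end < start at row ", which(g$end < g$start)[1L])
  }
  att <- as.character(g$attributes)
  ids <- ifelse(grepl("ID=", att), sub(".*ID=([^;]+).*", "\\1", att),
                paste0("gene", seq_len(nrow(g))))
  go <- lapply(att, function(a) {
    if (grepl("Ontology_term=", a)) {
      strsplit(sub(".*Ontology_term=([^;]+).*", "\\1", a), ",")[[1L]]
    } else character()
  })
  ann <- data.frame(gene_id = ids, chrom = as.character(g$seqid),
                    start = as.integer(g$start), end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  ann$go <- go
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation to GFF3
#' @param annotation a `gene_annotation` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  att <- paste0("ID=", annotation$gene_id)
  has_go <- vapply(annotation$go, length, 1L) > 0L
  att[has_go] <- paste0(att[has_go], ";Ontology_term=",
                        vapply(annotation$go[has_go], paste, "",
                               collapse = ","))
  lines <- paste(annotation$chrom, "vitiscan", "gene", annotation$start,
                 annotation$end, ".", annotation$strand, ".", att,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Gene length under the 1-based inclusive convention
#' @param annotation a `gene_annotation` data.frame.
#' @return integer vector, `end - start + 1`.
#' @export
gene_lengths <- function(annotation) {
  annotation$end - annotation$start + 1L
}

# sniff the delimiter (comma vs tab) and read with headers
read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
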