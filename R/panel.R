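#' Construct a genotype panel
#'
#' The container every stage of the pipeline consumes: a samples x markers
#' dosage matrix (counts of the alternate allele, 0/1/2, `NA` for missing)
#' together with the marker map, per-sample subpopulation labels and
#' per-marker genotyping-platform tags.
#'
#' @param dosage integer matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`.  Row names are sample ids, column names marker ids.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` and optionally `platform` (`"array"` or `"radseq"`),
#'   one row per dosage column, ordered by (chrom, pos).
#' @param samples data.frame with columns `sample_id` and `group`
#'   (`"sativa"` or `"sylvestris"`), one row per dosage row.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, markers, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(markers$platform)) markers$platform <- "array"
  if (is.null(markers$id)) {
    markers$id <- if (nrow(markers)) paste0(markers$chrom, "_", markers$pos)
                  else character()
  }
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- markers$id
  obj <- structure(
    list(dosage = dosage, markers = markers, samples = samples),
    class = "genotype_panel"
  )
  validate_panel(obj)
  obj
}

#' Validate the invariants of a genotype panel
#'
#' Checks biallelic markers, dosage values in `{0,1,2,NA}`, strictly
#' increasing positions within each chromosome, consistent dimensions and
#' no duplicated (chrom, pos) pairs.
#'
#' @param panel a `genotype_panel`.
#' @return The panel, invisibly; stops with an informative error otherwise.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  mk <- panel$markers
  sm <- panel$samples
  if (nrow(d) != nrow(sm)) stop("sample table and dosage rows disagree")
  if (ncol(d) != nrow(mk)) stop("marker table and dosage columns disagree")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosage values outside {0,1,2,NA}")
  }
  if (!all(sm$group %in% c("sativa", "sylvestris"))) {
    stop("sample group labels must be 'sativa' or 'sylvestris'")
  }
  key <- paste(mk$chrom, mk$pos)
  if (anyDuplicated(key)) {
    stop("duplicate marker position: ", key[duplicated(key)][1L])
  }
  for (ch in unique(mk$chrom)) {
    p <- mk$pos[mk$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on ", ch)
    }
  }
  invisible(panel)
}

#' @method print genotype_panel
#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "markers\n")
  cat("  groups:   ", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                    table(x$samples$group)), collapse = ", "),
      "\n")
  cat("  platforms:", paste(sprintf("%s=%d", names(table(x$markers$platform)),
                                    table(x$markers$platform)), collapse = ", "),
      "\n")
  cat("  chromosomes:", length(unique(x$markers$chrom)), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing:  %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / markers in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$dosage)

#' @rdname n_samples
#' @export
n_markers <- function(panel) ncol(panel$dosage)

#' Subset a panel by samples and/or markers
#'
#' @param panel a `genotype_panel`.
#' @param samples logical/integer index into sample rows (default all).
#' @param markers logical/integer index into marker columns (default all).
#' @return A `genotype_panel` restricted to the selection; marker order is
#'   preserved, so (chrom, pos) ordering remains valid.
#' @export
subset_panel <- function(panel, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(panel))
  if (is.null(markers)) markers <- seq_len(n_markers(panel))
  genotype_panel(panel$dosage[samples, markers, drop = FALSE],
                 panel$markers[markers, , drop = FALSE],
                 panel$samples[samples, , drop = FALSE])
}

#' Per-sample group labels as a factor
#' @param panel a `genotype_panel`.
#' @return factor with levels `sativa`, `sylvestris`.
#' @export
panel_groups <- function(panel) {
  factor(panel$samples$group, levels = c("sativa", "sylvestris"))
}
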