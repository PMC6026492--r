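# Trait preparation (across-year BLUPs, trait correlations) and GWAS
# under three confounding models: naive GLM, GLM-Q (PCA covariates) and
# MLM-QK (PCA covariates + kinship random effect, P3D-style).

#' Across-year genotypic BLUPs for a trait
#'
#' Fits `value = mu + year (fixed) + genotype (random) + error` by REML
#' (via \pkg{lme4}) and returns the shrunken genotype effects.  With a
#' single year the model degenerates to a shrunken per-sample mean and a
#' warning is issued.
#'
#' @param phenotypes a `phenotype_table` (see [read_phenotypes()]).
#' @param trait trait name to extract.
#' @return list of class `trait_blups`: `blup` (named vector, one value
#'   per sample, centered on the fitted mean), `varcomp` (genotypic and
#'   residual variance, year fixed effects), `fit` (the lmer object).
#' @export
compute_blups <- function(phenotypes, trait) {
  ph <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                   drop = FALSE]
  if (nrow(ph) < 2L) stop("trait '", trait, "' has fewer than 2 records")
  ph$year <- factor(ph$year)
  single_year <- nlevels(ph$year) < 2L
  replicated <- any(duplicated(ph$sample_id))
  if (single_year && !replicated) {
    # one record per sample: the genotype/residual split is not
    # identifiable, so the "BLUP" is the centered raw value
    warning("single year for trait '", trait,
            "': returning centered per-sample values (no shrinkage)")
    blup <- stats::setNames(ph$value - mean(ph$value), ph$sample_id)
    return(structure(list(
      blup = blup,
      varcomp = list(genotypic = stats::var(ph$value), residual = NA_real_,
                     year = NULL),
      fit = NULL
    ), class = "trait_blups"))
  }
  if (single_year) {
    warning("single year for trait '", trait,
            "': BLUPs are shrunken per-sample means")
    fit <- lme4::lmer(value ~ (1 | sample_id), data = ph,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  } else {
    fit <- lme4::lmer(value ~ year + (1 | sample_id), data = ph,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  }
  re <- lme4::ranef(fit)$sample_id
  blup <- stats::setNames(re[, 1L], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- list(
    genotypic = vc$vcov[vc$grp == "sample_id"],
    residual = vc$vcov[vc$grp == "Residual"],
    year = if (single_year) NULL else lme4::fixef(fit)
  )
  structure(list(blup = blup, varcomp = varcomp, fit = fit),
            class = "trait_blups")
}

#' Pairwise Pearson correlations between traits
#'
#' Builds a sample x trait matrix (values averaged over years) for an
#' optional group subset and returns the pairwise-complete Pearson
#' correlation matrix; cells with a constant trait or fewer than 3
#' complete pairs are `NA`.
#'
#' @param phenotypes a `phenotype_table`.
#' @param samples optional character vector of sample ids to keep.
#' @param traits optional trait names (default: all quantitative traits
#'   present).
#' @return correlation matrix (traits x traits).
#' @export
trait_correlations <- function(phenotypes, samples = NULL, traits = NULL) {
  ph <- phenotypes
  if (!is.null(samples)) ph <- ph[ph$sample_id %in% samples, , drop = FALSE]
  if (is.null(traits)) traits <- setdiff(unique(ph$trait), "Species")
  wide <- sapply(traits, function(tr) {
    sub <- ph[ph$trait == tr, , drop = FALSE]
    m <- tapply(sub$value, sub$sample_id, mean, na.rm = TRUE)
    ids <- sort(unique(ph$sample_id))
    as.numeric(m[ids])
  })
  R <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(wide))
  R[n_pairs < 3L] <- NA_real_
  R
}

#' Single-marker GWAS by ordinary least squares
#'
#' Per marker, fits `y = mu + Q gamma + g beta + e` and tests `beta = 0`
#' with a two-sided t-test.  With `Q = NULL` this is the naive GLM; with
#' PCA scores as `Q` it is the GLM-Q model.  Markers collinear with the
#' covariates (including monomorphic ones) get `NA` results and are
#' flagged.  The binary Species trait is handled by the same linear model.
#'
#' @param panel a complete [genotype_panel()].
#' @param y named numeric vector of trait values (BLUPs or single-year
#'   means); names must match panel sample ids, missing samples dropped.
#' @param Q optional covariate matrix (samples x q), e.g.
#'   `panel_pca(panel, 3)$scores`.
#' @param model_tag label stored in the result (defaults to `"naive-GLM"`
#'   or `"GLM-Q"` depending on `Q`).
#' @return data.frame of class `assoc_result`: per marker `beta`, `se`,
#'   `p`, `p_bonferroni`, `q_bh`, `model`.
#' @export
glm_assoc <- function(panel, y, Q = NULL,
                      model_tag = if (is.null(Q)) "naive-GLM" else "GLM-Q") {
  keep <- panel$samples$sample_id %in% names(y)[!is.na(y)]
  pan <- if (all(keep)) panel else subset_panel(panel, which(keep))
  yv <- as.numeric(y[pan$samples$sample_id])
  X0 <- matrix(1, length(yv), 1L,
               dimnames = list(NULL, "(Intercept)"))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)
    if (!is.null(rownames(Qm))) Qm <- Qm[pan$samples$sample_id, ,
                                         drop = FALSE]
    X0 <- cbind(X0, Qm)
  }
  res <- ols_scan(yv, X0, pan$dosage)
  res$model <- model_tag
  finish_assoc(res, pan)
}

# Frisch-Waugh residualised per-marker OLS over a (possibly weighted /
# rotated) design; X0 must have full column rank
ols_scan <- function(y, X0, G) {
  # rank detection on unit-norm columns (the projection is invariant to
  # column scaling, the QR tolerance is not)
  cs <- sqrt(colSums(X0^2))
  cs[cs == 0] <- 1
  qr0 <- qr(sweep(X0, 2L, cs, "/"))
  if (qr0$rank < ncol(X0)) {
    keep <- sort(qr0$pivot[seq_len(qr0$rank)])
    warning("dropping ", ncol(X0) - qr0$rank, " collinear covariate(s)")
    qr0 <- qr(sweep(X0[, keep, drop = FALSE], 2L, cs[keep], "/"))
  }
  yt <- qr.resid(qr0, y)
  Gt <- qr.resid(qr0, G)
  gg <- colSums(Gt^2)
  gy <- as.numeric(crossprod(Gt, yt))
  df <- length(y) - qr0$rank - 1L
  beta <- ifelse(gg > 1e-10, gy / gg, NA_real_)
  rss <- sum(yt^2) - beta^2 * gg
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(beta = beta, se = ifelse(is.na(beta), NA_real_, se), p = p)
}

#' Single-marker GWAS under the mixed model (MLM-QK)
#'
#' `y = mu + Q gamma + g beta + u + e` with `u ~ N(0, sigma_g^2 K)`.  The
#' variance ratio `delta = sigma_e^2 / sigma_g^2` is estimated once under
#' the null model by REML on the spectral decomposition of K (P3D), then
#' every marker is tested by generalized least squares in the rotated
#' space.
#'
#' @inheritParams glm_assoc
#' @param K kinship matrix (see [kinship_vanraden()]); must be symmetric
#'   positive semi-definite.
#' @return data.frame of class `assoc_result` as in [glm_assoc()], plus
#'   attribute `"delta"` (the REML variance ratio).
#' @export
mlm_assoc <- function(panel, y, Q = NULL, K, model_tag = "MLM-QK") {
  keep <- panel$samples$sample_id %in% names(y)[!is.na(y)]
  pan <- if (all(keep)) panel else subset_panel(panel, which(keep))
  ids <- pan$samples$sample_id
  yv <- as.numeric(y[ids])
  if (!is.null(dimnames(K))) {
    K <- K[ids, ids]
  } else if (nrow(K) != length(ids)) {
    stop("K has no dimnames and does not match the retained samples")
  }
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("K is not positive semi-definite; smallest eigenvalue ",
         format(min(eg$values)))
  }
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  X0 <- matrix(1, n_samples(pan), 1L,
               dimnames = list(NULL, "(Intercept)"))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)
    if (!is.null(rownames(Qm))) Qm <- Qm[ids, , drop = FALSE]
    X0 <- cbind(X0, Qm)
  }
  ys <- crossprod(U, yv)
  X0s <- crossprod(U, X0)
  n <- length(yv)
  p0 <- ncol(X0)
  # REML profile over log(delta): V propto diag(lam + delta)
  reml_nll <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (lam + delta)
    sw <- sqrt(w)
    Xw <- X0s * sw
    yw <- ys * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    0.5 * ((n - p0) * log(rss) - sum(log(w)) +
             determinant(crossprod(Xw), logarithm = TRUE)$modulus[1L])
  }
  opt <- stats::optimize(reml_nll, interval = c(-12, 12))
  delta <- exp(opt$minimum)
  sw <- sqrt(1 / (lam + delta))
  Gs <- crossprod(U, pan$dosage) * sw
  res <- ols_scan(ys * sw, X0s * sw, Gs)
  res$model <- model_tag
  out <- finish_assoc(res, pan)
  attr(out, "delta") <- delta
  out
}

finish_assoc <- function(res, pan) {
  res$p_bonferroni <- adjust_pvalues(res$p, "bonferroni")
  res$q_bh <- adjust_pvalues(res$p, "BH")
  out <- cbind(pan$markers[, c("chrom", "pos", "id")], res)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR, with `NA`
#' p-values excluded from the effective test count.
#'
#' @param p numeric vector of raw p-values.
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted vector, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

#' Genomic inflation factor lambda
#'
#' The median 1-df chi-square statistic implied by the p-values divided by
#' its null expectation (0.4549...) — the numeric summary of the Q-Q plot
#' used to choose between association models.
#'
#' @param p vector of raw p-values (`NA` dropped).
#' @return lambda (1 under a well-calibrated null).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
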