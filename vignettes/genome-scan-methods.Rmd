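---
title: "Methods: scanning wild and cultivated grapevine for signatures of selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning wild and cultivated grapevine for signatures of selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitiscan)
```

## The problem

Cultivated grapevine (*Vitis vinifera* subsp. *sativa*) and its wild
progenitor (subsp. *sylvestris*) are still inter-fertile and only
moderately diverged, so domestication left localized rather than
genome-wide footprints: windows of elevated allele-frequency
differentiation, depressed diversity in one subspecies, and marker-trait
associations for berry, bunch and must traits.  `vitiscan` implements
the full desk-side analysis for a diploid biallelic SNP panel genotyped
on a mixed array/RAD-seq design: panel construction, a windowed
differentiation scan with permutation-calibrated thresholds, diversity
and LD profiling, mixed-model association mapping, and the intersection
of the two lines of evidence.

All coordinates in the package are 1-based and inclusive, the native
convention of VCF and GFF3; a gene with `start == end` has length 1, and
a window `[w, w + size - 1]` contains a marker at position `x` iff
`w <= x <= w + size - 1`.  Strand is ignored everywhere: after counting
alternate alleles a dosage is strand-free.  Missing genotypes are `NA`
in an integer matrix, never a numeric sentinel.

## Panel construction

The QC chain mirrors how mixed-platform grape panels are built, in this
order:

1. **Platform merge** (`merge_platforms`).  Markers shared between the
   array and RAD-seq panels (matched on chromosome and position) keep
   the array genotypes, which are the more reliable calls.  If the two
   platforms report the same site with ref/alt exchanged, the records
   reconcile (complement recoding makes the dosages comparable) and the
   marker is retained; alleles that cannot be reconciled drop the marker
   with a log entry.  Sample sets are intersected with a warning.
2. **Call-rate filter** (`filter_missingness`, threshold 0.2).  Markers
   with missing rate above the threshold go first; samples are then
   filtered on the surviving markers.  Marker-before-sample ordering is
   a design choice (the accounting table reports marker removals per
   platform before sample removals); the opposite order is a one-line
   change but is not exposed because the defaults reproduce the standard
   workflow.
3. **LD-kNN imputation** (`impute_knn`, k = 5, l = 20, eps = 0.01).  For
   a missing genotype at marker *m* in sample *s*: the *l* markers in
   highest r² with *m* define a distance
   `d(s,t) = (1/l) * sum |g_s - g_t| + eps` over markers observed in
   both samples; the *k* nearest samples with an observed genotype at
   *m* vote with weight 1/d²; the imputed value is the weighted-majority
   dosage, ties broken toward the smaller dosage.  The defaults are the
   published defaults of the LD-kNNi method; the procedure is fully
   deterministic.  A marker observed in fewer than two samples falls
   back to its major genotype and is flagged.
4. **MAF filter** (`filter_maf`, threshold 0.05, strict `<`).  Run after
   imputation, on complete frequencies; a marker at exactly MAF 0.05 is
   retained.

Each stage emits a `filter_report`; `filter_accounting` combines them
into a per-platform table whose rows always satisfy
`initial - removed = final`.

## The differentiation scan

Per-site differentiation uses the Weir–Cockerham (1984) two-population
variance components.  With per-group diploid counts `n1, n2`, alternate
allele frequencies `p1, p2` and observed heterozygote proportions
`h1, h2`:

```
nbar = (n1 + n2)/2
nc   = 2 nbar - (n1^2 + n2^2)/(2 nbar)
pbar = (n1 p1 + n2 p2)/(2 nbar)
s2   = (n1 (p1 - pbar)^2 + n2 (p2 - pbar)^2)/nbar
hbar = (n1 h1 + n2 h2)/(2 nbar)
a = (nbar/nc) [ s2 - (pbar(1-pbar) - s2/2 - hbar/4)/(nbar - 1) ]
b = (nbar/(nbar-1)) [ pbar(1-pbar) - s2/2 - (2 nbar - 1)/(4 nbar) hbar ]
c = hbar/2
```

θ per site is `a/(a+b+c)`, undefined when the denominator is not
positive (near-monomorphic sites); undefined sites are excluded from
per-site output but their components still enter window sums.  Negative
components are retained, not truncated — the standard convention that
keeps the weighted ratio unbiased.  The implementation is vectorised;
the test suite checks it against a scalar transcription of the original
definitions on hundreds of random fixtures at 1e-10.

`window_scan` anchors windows at position 1 on each chromosome
(default 100 kb size, 10 kb step, matching the windowed-VCF-statistics
convention), omits windows with no markers, and reports both the
weighted estimate `sum(a)/sum(a+b+c)` (the primary statistic) and the
mean of defined per-site θ.  Per group it adds:

- **π** — `sum_sites 2 c0 c1 / (n (n-1))` over the window divided by the
  window size in bp (`n` = haplotypes, `c0/c1` allele counts).  Windows
  truncated by a chromosome end are still divided by the nominal size.
- **Tajima's D** — `D = (khat - S/a1) / sqrt(e1 S + e2 S (S-1))` with
  `khat = sum c0 c1 / C(n,2)`, `S` the segregating-site count and the
  usual constants from `n`; `NA` when `S = 0`.  A complete (imputed)
  matrix is required — this keeps `n` fixed so the constants are exact,
  and matches the position of imputation in the QC chain.  A
  missing-tolerant mode is deliberately out of scope.
- **π ratio** — `pi_sylvestris / pi_sativa`; exactly 0 for windows
  monomorphic in the wild pool, `Inf` when only the cultivated pool is
  monomorphic, `NA` when both are.

Outlier calling is empirical: the 95th and 99th percentiles of the
window `fst_weighted` distribution, computed by linear interpolation
between order statistics (`quantile` type 7; fixed and documented for
reproducibility).  `permutation_null` validates the cutoff: each
replicate shuffles the group labels over samples genome-wide (group
sizes preserved — one permutation per replicate, all windows
recomputed), and the pooled null window values give percentile
thresholds; per-replicate maxima are also stored for an FWER-style
alternative.  Pooling is the default: it estimates the per-window null
quantile, which is what an empirical per-window cutoff should be
checked against.  `call_outliers` attaches flags and each window's null
exceedance probability.

## LD, structure and kinship

r² is the squared Pearson correlation of dosage vectors — the
"genotype r²" of standard GWAS toolchains, not a haplotype/EM D'
estimate — computed within any sample subset, excluding markers
monomorphic in the subset.  Decay curves take the median r² in 10 kb
distance bins; the decay distance is the left edge of the first bin
whose median falls below 0.2 (`Inf` when none does).  LD blocks are
index-anchored: the interval from the leftmost to the rightmost marker
within 500 kb whose r² with the index SNP is at least 0.8 (inclusive),
degenerating to the index position when nothing is linked.  Anchored
spans implement the "region between the extreme linked SNPs" usage
directly; confidence-interval block definitions are visualization
conventions and out of scope.

PCA runs on the column-centered (optionally unit-scaled; default
unscaled, which keeps the usual MAF weighting) dosage matrix, with each
component's sign fixed so its largest-magnitude loading is positive.
Kinship is VanRaden's `K = ZZ'/(2 sum p_j (1 - p_j))` with
`Z = dosage - 2 p_j`.

## Association mapping

Phenotypes are long-format (sample, trait, year, value) over two years.
`compute_blups` fits `value = mu + year (fixed) + genotype (random) +
error` by REML (via `lme4`) and returns shrunken genotype effects; with
a single year and one record per sample the genotype/residual split is
not identifiable, so the function returns centered raw values with a
warning rather than pretending to shrink.

GWAS offers the standard confounding ladder:

- **naive GLM** — per marker OLS `y = mu + g b + e`, two-sided t-test.
- **GLM-Q** — adds q PCA score columns (default q = 3) as fixed
  covariates.  PCA components stand in for model-based ancestry
  coefficients; for two subpopulations the leading components carry the
  same stratification signal.
- **MLM-QK** — `y = X beta + u + e`, `u ~ N(0, sigma_g^2 K)`.  The
  variance ratio is estimated once under the null by REML on the
  spectral decomposition of K (the P3D shortcut), then every marker is
  tested by GLS in the rotated, whitened space.  With `K = I` the model
  collapses to GLM-Q exactly, a property the tests assert.

Implementation note: all three models reduce to one residualised
per-marker OLS core (Frisch–Waugh), with covariate rank checked on
unit-norm columns so the collinearity guard is scale-free.  Markers
collinear with the covariates (including markers duplicated as
covariates) return `NA` and a warning.  The binary Species trait
(1 = sativa, 0 = sylvestris) runs through the same linear model, the
behaviour of the standard GWAS toolchain for binary traits; a logistic
mode was considered and rejected to keep effect sizes comparable across
traits.  Bonferroni and BH-FDR adjustments wrap `p.adjust`;
`genomic_lambda` summarises the Q-Q plot as the median implied 1-df
chi-square over its null expectation.

## Integration

`intersect_gwas_sweeps` keeps associations whose marker falls inside at
least one flagged window (inclusive containment; every containing
window is listed).  `candidate_genes` searches marker ± 10 kb — the
20 kb total window — or the LD block when it extends beyond the flanks;
gene overlap is any-overlap, since no overlap fraction is standard for
"gene in LD with a SNP".  GO over-representation is a one-sided
hypergeometric upper tail per term against the full annotated-gene
universe, BH-adjusted; graph-aware decorrelation algorithms (weight01
and relatives) are out of scope by design — the plain hypergeometric is
transparent and testable against Monte-Carlo resampling.
`run_pipeline`/`report_json` chain everything into a deterministic
report (no timestamps; identical seed, identical bytes).

## The synthetic-data generator

No germplasm genotypes of this design are publicly deposited, so the
generator is a first-class module rather than a test fixture.  Its
defaults are the study conditions: 48 *sativa* + 44 *sylvestris*
diploids, 19 chromosomes, one SNP per ~18 kb, background divergence
F = 0.12, LD scale ρ = 10 kb, heavier missingness on the RAD-seq
platform (0.15 vs 0.02) and a low-MAF excess planted on the array
platform.

**Divergence** follows the Balding–Nichols model: each marker draws an
ancestral frequency `p` uniformly on (0.05, 0.95), then subpopulation
frequencies `p1, p2 ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, with F the
background value or the sweep-specific value inside planted divergent
windows; `mono_*` windows fix one subpopulation at 0/1.  The model's
closed-form E[F_ST] = F is what the recovery tests exploit.  An
explicit coalescent would add realism (shared genealogies, site
frequency spectra) the downstream statistics do not need at desk scale,
and the real demography is unknown anyway.

**LD** comes from a copying process along each haplotype: marker `j`
copies from marker `j-1` with probability `exp(-d/rho)` (`d` the bp
gap), else draws fresh.  The package copies the *latent uniform
quantile*, not the allele: the allele at marker `j` is
`1(u_j < p_subpop,j)` where `u_j` is either inherited or fresh.
Copying the allele itself would mix Balding–Nichols draws across
neighbouring markers, attenuating the realized between-population
divergence well below F (we measured ~0.03 instead of 0.12 at 4 kb
spacing) and washing out planted low-MAF markers; quantile copying
preserves every marker's subpopulation frequency exactly while r²
still decays exponentially at scale ρ.  Monomorphic windows are forced
after the copying pass so no flanking allele leaks in.  One consequence
worth knowing: because neighbouring markers draw independent
frequencies, the short-range median r² is lower than in real panels
(where adjacent markers share genealogies); the decay *shape* and
ordering in ρ are faithful, the absolute level is conservative.

**Phenotypes** are `y = mu + group shift + year effect +
sum(beta_q g_q) + N(0, sd^2)` over two years, with default group shifts
in the directions seen in domesticated grape (larger bunch/berry/sugar
values in *sativa*, lower pH in *sylvestris*) and magnitudes chosen so
planted QTLs of moderate effect are detectable at n = 92; per-trait
variances are configuration, not claims about real grapes.  The binary
Species trait (1 = sativa) is emitted alongside.  Toy gene models tile
every 20 kb; genes inside sweep windows (plus a thin 2% background
scatter) carry an enriched GO term for recovery tests of the
over-representation machinery.

What passing tests on this generator do show: the estimators recover
known divergence, calibrated thresholds, planted sweeps, QTLs and
enrichment under the stated statistical model.  What they cannot show:
robustness to realistic site-frequency spectra, mutation/recombination
heterogeneity, clonal relatedness within the cultivated pool, or
genotyping error beyond random missingness.  In particular the uniform
ancestral-frequency spectrum produces strongly positive Tajima's D in
both subpopulations (intermediate-frequency excess by construction), so
D's absolute level in simulations is not comparable to real panels —
only its sign behaviour and its oracle arithmetic are tested.

## Numerical conventions and degenerate inputs

- Percentiles: linear interpolation between order statistics
  (`quantile` type 7), everywhere.
- Imputation votes: ties toward the smaller dosage; distances carry an
  additive `eps = 0.01` so exact duplicates cannot divide by zero.
- Windows with zero markers are omitted, never emitted as zeros.
- θ sites with non-positive denominators: excluded from `fst_mean`,
  included in `fst_weighted` sums.
- `pi_ratio`: 0 / positive = 0; positive / 0 = `Inf`; 0 / 0 = `NA`.
  Genome summaries average finite values only.
- PCA sign: largest-magnitude loading positive.
- The permutation null, the simulator and the masking helper take
  explicit seeds and restore the RNG state afterwards
  (`withr::with_seed`), so library calls never perturb a session's RNG.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run the statistics at reduced
but honest sizes chosen to keep a full run in tens of seconds: ~5,000
markers for divergence recovery and GWAS calibration, 19 × 2 Mb
chromosomes (~3,800 windows) for threshold calibration with 200 label
permutations, 20 replicates for sweep recovery and 20–50 for GWAS
power.  These sizes are the package's own reproducibility choices; all
of them are plain arguments, and nothing in the implementation depends
on them.

## Known limitations

- Two populations only (the estimator is the r = 2 case); multi-group
  F_ST is out of scope.
- No haplotype-based sweep statistics (iHS, XP-EHH) and no phasing.
- The scan requires a complete matrix; missing-tolerant windowed
  statistics are deliberately not offered.
- The Species GWAS under structure correction is close to
  self-conditioning (the covariates encode the phenotype); the naive
  model is the informative one for that trait, and the report labels
  significance tiers explicitly rather than electing a headline.
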