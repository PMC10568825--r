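---
title: "Methods: multi-population GWAS meta-analysis and QTL calling"
author: "bovmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-population GWAS meta-analysis and QTL calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovmeta)
```

## The problem

Sequence-level GWAS in cattle test tens of millions of imputed variants
per population, but within-breed linkage disequilibrium (LD) extends
over long distances, so a significant region rarely pins down a causal
variant. Combining summary statistics from several breeds in a
meta-analysis (MA) raises power (more animals) and sharpens mapping
(LD patterns differ between breeds, so only signals tied closely to the
causal site reinforce each other). `bovmeta` implements that workflow
end to end for beef production traits: per-study quality control and
harmonization, two combination methods, QTL calling with a
peak-relative confidence interval, and the usual post-GWAS summaries.
Because individual-level cattle data are rarely shareable, the package
also ships a multi-population simulator with known ground truth; every
statistical claim below is checked against it in the test suite.

## Quality control and harmonization

Per-study records carry `(chrom, pos, ref, alt)`, the effect allele,
`beta`, `se`, two-sided `p`, MAF, imputation R² and `n`. The QC chain
is:

1. **Standardization.** `beta` and `se` are divided by the study's
   trait genetic standard deviation, so effects are in genetic-SD units
   and comparable across populations and trait scales. P-values are
   untouched (the Wald statistic is scale-free).
2. **Marginal filters.** Keep a variant iff MAF ≥ the per-study
   threshold (0.005 by default; 0.02 is the conventional choice for
   cohorts of ~1000, where 0.005 would mean ~10 minor-allele copies)
   and imputation R² ≥ 0.20. Both comparisons are inclusive.
3. **Outlier removal.** After the marginal filters, drop markers with
   |standardized beta| > 5. The field convention speaks of "five
   standard deviations of the trait distribution"; since effects here
   are already on the genetic-SD scale we apply the rule there and
   expose `k` as a parameter — on either scale it removes only the
   pathological tail of very rare, poorly imputed variants.
4. **Two-partner rule.** A site is retained iff carried by at least two
   studies and all carriers agree on the unordered {REF, ALT} pair.
   The canonical orientation is that of the first study (input order)
   carrying the site — any fixed convention works; first-seen is
   deterministic and order-stable. Swapped labels are rewritten;
   genuinely discordant allele pairs (and sites duplicated within one
   study) are dropped. Strand-ambiguity resolution (A/T, C/G flips) is
   deliberately *not* attempted: dropping is conservative and such
   sites cannot be disambiguated from summary data alone.
5. **Effect-allele alignment.** Effects whose dose allele is the
   canonical REF are negated and re-labelled to the canonical ALT.

Re-encoding any study (swapping its REF/ALT labels and negating its
betas) leaves every downstream significance value unchanged; when the
re-encoded study is not the orientation donor the whole panel is
bit-identical. The suite checks both forms of this invariance.

## Meta-analysis

Two per-variant combinations over the k ≥ 2 carrying studies:

* **Fixed effects (inverse variance).** With weights
  $w_i = 1/se_i^2$: $\hat\beta = \sum w_i \beta_i / \sum w_i$,
  $se = 1/\sqrt{\sum w_i}$, $Z = \hat\beta / se$. Assumes one true
  allele effect across studies.
* **Sample-size-weighted z-score.** With $w_i = \sqrt{n_i}$ and
  $z_i = \Phi^{-1}(1 - p_i/2)\,d_i$ ($d_i$ the effect direction):
  $Z = \sum_i z_i w_i \big/ \sqrt{\textstyle\sum_i w_i^2}$.
  Some descriptions of this estimator typeset the denominator without
  the radical; only the square-root form gives Z unit variance under
  the null, which is the property the method needs and the one our
  null-calibration experiment verifies empirically (the suite requires
  the empirical SD of null Z to fall in [0.97, 1.03] over ~50,000
  variants and the type-I error at α = 0.05 to match within ±0.01).

All significance arithmetic runs on the −log10 p scale
(`mlogp_from_z()` uses `pnorm(..., log.p = TRUE)`), so peaks with
−log10 p in the hundreds — routine for major cattle QTL — never
underflow; result files store p as a scientific-notation string
rendered from −log10 p. The direction string records one of `+`/`-`/`?`
per panel study in panel order, `?` marking absence. A variant must be
carried by at least two studies to be combined (mirroring the
two-partner retention rule); the minimum is configurable.

No heterogeneity statistics (Cochran's Q, I²) are computed: the
workflow treats between-study disagreement as signal attenuation, not
as a quantity to model, and a random-effects combination is a
non-goal.

## QTL definition

Association profiles are scanned per chromosome with
`detect_qtl(results, threshold_mlogp = 8.7, window_bp = 2e6,
peak_fraction = 1/3)`:

1. the unmasked variant with the largest −log10 p at or above the
   threshold becomes the lead (ties: smallest position, then
   lexicographic REF/ALT — fully deterministic);
2. members are the unmasked variants within ±2 Mb of the lead whose
   −log10 p reaches the upper third of the peak, i.e.
   ≥ (2/3) · lead −log10 p;
3. the confidence interval (CI) spans the most distant members;
4. *all* variants within ±2 Mb of the lead are masked (not only the
   members), so a peak's shoulder can never be re-called as a second
   QTL and leads of distinct QTL on one chromosome are > 2 Mb apart;
5. repeat until nothing unmasked exceeds the threshold.

The default threshold 8.7 is the 5% genome-wide Bonferroni level for
~25 million sequence variants (−log10(0.05/25·10⁶) = 8.69897). Three
interpretation choices were genuinely open and are fixed as follows:
the "upper third of the peak" is taken on the −log10 p scale (the
scale on which peaks are drawn and compared; `peak_fraction` is a
parameter); the ±2 Mb window stays centered on the lead rather than
re-centering as members accrue (re-centering would make the CI depend
on accrual order); and CI membership requires only the peak-relative
cutoff, not genome-wide significance, because the rule is purely
relative. A single isolated significant variant yields a degenerate CI
of size 0 — a real outcome, not an error. QTL from different analyses
are matched by same-chromosome inclusive CI overlap, greedily in
decreasing lead significance; the identity criterion across analyses
is not standardized anywhere, and interval overlap is the least
committal choice.

`detect_qtl` is verified against a brute-force oracle (literal
re-scan after every masking step) on hundreds of random profiles, and
raising the threshold can only reduce the number of calls.

## Post-GWAS summaries

* **Consequence distribution**: percentages of CI variants per
  functional-consequence category, in a fixed vocabulary order;
  variants missing from the table count as `other` with a warning.
* **Interval-database enrichment**: for each trait-type category of an
  interval database, the upper-tail hypergeometric probability of the
  observed number of category records overlapping any CI, given the
  database totals (overlap = any base-pair intersection, both sides
  1-based inclusive). The database record is the sampling unit — the
  natural exchangeable unit when comparing against a QTL catalogue.
  P-values are BH-adjusted across categories; a category is retained
  as enriched iff FDR is *strictly* below 0.05.
* **Colocalization**: a variant colocalizes iff its MA p-value is
  below 2 × 10⁻⁹ (Bonferroni-adjusted 0.05 for ~25 M tests) and it has
  an e/sQTL record with adjusted p < 0.05. The adjusted p is taken as
  given from the input table (it comes from the expression atlas's own
  permutation scheme; re-adjusting it here would be wrong). In
  pan-tissue mode the lowest-nominal-p record per variant is retained;
  multi-tissue mode first restricts to a tissue subset. Tissue aliases
  (e.g. gathering the `Muscle_*` labels into one `Muscle` group) are
  applied at read time. Over-representation of regulatory variants
  among MA-significant variants is tested with a two-sided Fisher
  exact test on the 2×2 table over all MA-analyzed variants, and the
  Pearson correlation of −log10 p between the two analyses is
  reported over jointly tested variants (undefined below two).

## The synthetic-data generator

`sim_config()` describes a multi-population study set; the generator
is first-class, tested code, not a fixture.

* **Allele frequencies.** Ancestral ALT frequencies uniform on
  [0.05, 0.5]; per-population frequencies from the Balding–Nichols
  beta distribution with divergence parameter Fst = 0.1 — a typical
  between-breed value for cattle.
* **LD.** Haplotypes are built blockwise by Gaussian thresholding: a
  latent AR(1) chain with correlation ρ between adjacent variants
  within a block (default ρ = 0.9, blocks of 100 variants),
  independence across blocks. Per-population ρ and block-boundary
  offsets may differ, emulating between-breed LD divergence. This is a
  stand-in with config-exposed parameters, not a calibrated model of
  cattle LD (no coalescent realism, no long-range LD, one chromosome).
* **Imputation noise.** Per variant and population a target R² is
  drawn from [0.15, 1] and the true dosage is degraded in the
  BLUP-dosage form $x_{obs} = m + R^2 (x - m) + e$ with
  $Var(e) = R^2(1-R^2)Var(x)$, so that $cor(x_{obs}, x)^2 = R^2$
  and — crucially — regression of the phenotype on the observed dosage
  stays unbiased. The same R² is reported in the INFO_R2 column, so
  the R² ≥ 0.20 filter acts on exactly the quantity that was injected.
* **Phenotypes.** $y = \sum x b + g^* + e$ on a scale where the total
  genetic SD is exactly 1 (so planted betas are true values in
  genetic-SD units), then multiplied by the population's `genetic_sd`.
  The polygenic term of the single-variant mixed model is replaced by
  an independent Gaussian surrogate $g^*$ with variance `h2_poly`
  (default 0.3) of the phenotypic variance: simulated individuals are
  unrelated, so a relationship-matrix term would be statistically
  indistinguishable from it. Residuals have variance
  $\sigma_e^2 / w_r$ with per-record weights $w_r = 1$ for
  yield-deviation (YD) phenotypes and gamma-dispersed around 1 (CV
  0.3) for daughter-yield-deviation/de-regressed-proof (DYD/DRP)
  phenotypes. When `h2_poly = 0` the residual variance is set equal to
  the unit genetic variance.
* **Association scan.** Per-variant weighted least squares of y on
  dosage with intercept, using the true record weights; two-sided p
  from the t distribution with n − 2 df. Monomorphic variants are
  excluded and counted.
* **Defaults as study conditions.** Three populations of 3000/2000/
  1200 animals (heterogeneous, like real multi-partner consortia scaled
  to desk size), 5000 variants at 3 kb spacing on one chromosome, six
  planted causal variants — four shared at 0.45 genetic SD, two
  population-specific at 0.6, the magnitude of major beef
  growth/muscularity loci.
* **Reproducibility.** All randomness derives from the master seed
  through one seeded stream per (population, block), plus reserved
  per-population streams for frequencies/accuracies, phenotype noise
  and weights. This lets large panels be regenerated block by block
  (the scan never materializes a full dosage matrix), and adding a
  population never perturbs the data of existing ones. Identical
  configurations produce byte-identical files.

What the simulator does **not** emulate: realistic cattle LD and MAF
spectra, relatedness/pedigree structure (hence no GRM in the scan),
admixed or F2 designs, multiple chromosomes, sex chromosomes, and
imputation-software-specific R² biases. Passing tests therefore
demonstrate the correctness and calibration of the statistical
machinery under a controlled generative model — not performance claims
about real cattle data.

## Replicated experiments and problem sizes

Three experiments bundle the package's statistical guarantees; the
acceptance script and the test suite run them at these sizes, chosen
to give tight Monte-Carlo error at desk scale:

* `null_calibration_experiment()`: 50,000 variants, 3 populations of
  2000, no causal variants; checks unit-variance null Z (both methods)
  and the 5% type-I rate.
* `power_ci_experiment()`: 15 replicate study sets of the divergent-LD
  design (6000 variants at 2 kb, ρ = 0.99/0.97/0.94 per population,
  shifted block boundaries, four shared 0.45-SD causal variants 3 Mb
  apart, imputation R² ∈ [0.9, 1]); a causal variant counts as
  detected iff an analysis calls a QTL whose lead is within ±2 Mb of
  it. Checks that the MA detection rate is at least the best
  single-study rate minus two MC standard errors, and that MA
  confidence intervals are no wider (median kb) and hold no more
  candidate variants (mean count) than single-study ones. The high-R²,
  strong-LD regime is what makes CI widths non-degenerate: with weak
  LD or noisy dosages nearly every CI collapses to a single variant
  and the comparison would be vacuous.
* `coverage_experiment()`: 500 replicates of a minimal three-population
  set with one shared 0.45-SD causal variant; checks that the nominal
  95% fixed-effects CI covers the truth at 95% ± 3%.

## Numerical and degenerate-input choices

* P-values are validated into (0, 1]; zero is rejected at parse time
  (a true p of zero is an encoding error, not a measurement).
* `z_from_p` and `mlogp_from_z` work on the log scale and are exact
  for p down to 10⁻³⁰⁰ and |z| of any size; the round trip is tested
  to 10⁻⁹ relative error for |z| ≤ 37.
* Threshold comparisons: QC filters are inclusive (≥); significance
  cutoffs (genome-wide, colocalization, FDR) are strict (<, or > on
  the −log10 scale), following how each rule is conventionally stated.
* Empty inputs: header-only files parse to empty tables; an empty QTL
  table summarizes to count 0 with flagged-undefined means; an empty
  e/sQTL table yields zero colocalization counts and an undefined
  correlation; enrichment with no overlap returns p = 1 everywhere.
* BED export converts the internal 1-based inclusive coordinates to
  0-based half-open only at that boundary.

## Limitations

The two-partner concordance rule keys sites by (chromosome, position),
so two different bi-allelic variants at one position are treated as
discordant rather than coexisting — conservative, and consistent with
how multi-allelic sites are usually excluded upstream. Fixed-effects
results assume a shared true effect; population-specific QTL are
attenuated by design (the simulator plants such variants precisely to
exercise this). The enrichment null treats database records as
exchangeable and ignores interval lengths. The matching of QTL across
analyses by CI overlap is permissive for very wide CIs. None of the
components model trans-e/sQTL, conditional signals, or fine-mapping
posteriors.
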