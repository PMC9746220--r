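---
title: "Methods: multi-tissue proteome-by-phenome Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue proteome-by-phenome Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(proteomr)
```

# The problem

Protein abundances are heritable, and a genetic variant that changes a
protein's level (a pQTL) can serve as an instrumental variable for that
protein in two-sample Mendelian randomization (MR): if carriers of the
allele have both more protein and more disease, and the variant affects the
disease only through the protein, the protein is causally implicated and is
a candidate drug target. `proteomr` implements that inference chain for
multi-tissue proteomics (e.g. CSF, plasma, brain), from raw aptamer plates
to drug-direction calls, with a synthetic-data generator that provides
ground truth for every stage.

# Models and procedures

## Proteomic quality control

Raw abundances arrive as relative fluorescence units (RFU) on plates that
carry, besides study samples, calibrator wells (a common reference sample)
and buffer wells (no biological material). Four analyte-level filters run in
a fixed order, and an analyte must pass all four:

1. **Detection limit.** LOD = mean(buffer) + 2·sd(buffer), per analyte,
   pooled over plates. A study sample below the LOD is an outlier; the
   analyte fails when outliers exceed 15% of samples (strict inequality —
   the rule reads "greater than 15%").
2. **Scale-factor difference.** Per analyte and plate the calibration scale
   factor is median(reference)/median(plate calibrators), where the
   reference is the cross-plate median of the plate calibrator medians.
   The analyte fails when the largest absolute deviation from the median
   scale factor exceeds 0.5. The source text uses the factor without
   defining its computation; the median-ratio form above is this package's
   choice and is configurable territory for a fork — it is deliberately a
   ratio so that a plate measuring uniformly 3× high yields a factor of
   1/3 and a deviation of ~0.67.
3. **Calibrator CV.** sd/mean over pooled calibrator wells, with the
   sample (n−1) standard deviation because calibrator counts are small
   (8 per plate here). Fails above 0.15.
4. **IQR outliers.** On log10 values, a sample outside
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR] (type-7 quartiles, the interpolation
   default recorded in the report) is an outlier; fails above 15%. A zero
   IQR collapses the fence to the median, so any deviating value is an
   outlier — the continuous limit of the rule.

A second, orthogonal pass flags **sample outliers**: a sample that is an
IQR outlier in more than 15% of the passing analytes. Analytes outlying in
at least 80% of those samples are removed, outliers are re-called once, and
the final outlier samples are dropped. Two numerical choices matter here:

* The shared-analyte removal requires **at least two** sample outliers.
  With exactly one, every analyte the sample deviates in is trivially
  "shared by 100%", and the blame belongs to the sample. The threshold is
  exposed as `min_outliers`.
* The 15%-of-analytes rule is scale-dependent: with very few analytes
  (say 5) a single deviating analyte exceeds 15% and clean samples get
  flagged at the binomial background rate. The procedure is intended for
  panels of hundreds of analytes; the package applies the rule literally,
  and the test fixtures use ≥ 20 analytes, where the background rate is
  negligible.

`run_qc()` returns the cleaned matrix on the log10 scale with calibrator
and buffer wells retained, which is what makes the pipeline idempotent:
re-running QC on its own output computes the same verdicts (a scale flag
on the object records whether values are raw or log10).

## pQTL mapping and the study-wide threshold

Association is ordinary least squares of protein level on dosage (additive
model) with covariates, computed by residualizing both sides on the
covariates (Frisch–Waugh), so the per-pair slope and SE equal the full
multiple regression at a fraction of the cost; p-values use the t reference
with n − k − 2 degrees of freedom, where k counts **all** covariates (the
source is ambiguous between adjusting for two stratification PCs or the
full covariate set; the package adjusts for what it is given). Variants
with minor allele frequency below 2% are excluded, mirroring genotype QC.

Because aptamer panels measure hundreds of correlated proteins, the
multiple-testing burden is estimated by PCA: nPC is the smallest number of
principal components of the column-standardized protein matrix explaining
95% of total variance, and the study-wide threshold is
α = 5×10⁻⁸ / nPC. Standardization is used (rather than raw log abundances)
because aptamers span very different dynamic ranges; the choice is recorded
in the `threshold_spec`. The unrounded α drives filtering — rounding to one
significant figure, as reports print it, would change inclusion near the
boundary; `study_wide_alpha()` returns both.

## Meta-analysis

Two classic schemes, applied per variant after aligning every study's
alleles to the first study with the same harmonization rules as MR:

* **STDERR**: weights 1/SE², pooled β and SE = (Σw)^(−1/2), Cochran's
  Q = Σwᵢ(βᵢ − β̂)² with k − 1 df.
* **SAMPLESIZE**: weights √nᵢ, ẑ = Σ√nᵢ zᵢ / √Σnᵢ. The source names this
  scheme's heterogeneity flag but not its formula. This package uses the
  exact chi-square projection consistent with the estimator: under a
  homogeneous standardized effect, E(zᵢ) = ẑ·√(nᵢ/Σn), and
  Q = Σ(zᵢ − ẑ·√(nᵢ/Σn))² is χ²(k−1) because each zᵢ has unit variance.
  The suite verifies the implied uniformity of the heterogeneity p-value
  under homogeneity.

Records present in a single study pass through unflagged with
`n_studies = 1`. Flags: `flag_heterogeneity` (STDERR het p < 0.05),
`flag_heterogeneity2` (SAMPLESIZE), `flag_hetero.all` (both).

## Instrument selection

Two workflows mirror the two significance regimes: **workflow-a** keeps cis
variants at the study-wide α (closed comparison, p ≤ α); **workflow-b**
keeps cis and trans variants at genome-wide 5×10⁻⁸. Then, in order:

1. **Pleiotropy filter.** A variant associated (at genome-wide
   significance, within the tissue by default) with ≥ 5 proteins is a
   pleiotropic sentinel and is removed together with its LD block —
   implemented as variants with r² ≥ 0.1 within ±1 Mb of the sentinel.
   The source gives no numbers for the block definition; 0.1/±1 Mb are
   conservative defaults, configurable and logged in provenance.
2. **LD clumping.** Greedy by ascending p (ties broken by variant id):
   accept a variant iff r² < 0.001 with every accepted variant. LD is the
   squared Pearson correlation of dosages in the provided panel — no
   external reference panel dependency.
3. **Instrument strength.** F = (β/SE)² ≥ 10.

The stated order is canonical; the package does not assume the final set is
invariant to reordering the filters, and records counts after each step.

## Two-sample MR

Harmonization resolves, in order: swapped effect/other alleles (sign-flip
the outcome β, reflect its EAF), strand flips (A↔T/C↔G complements),
palindromic A/T and C/G variants (oriented by allele frequency when both
EAFs fall outside [0.42, 0.58], otherwise dropped — the band is
conventional, the source names the step but not a threshold), and
incompatible alleles (dropped). Estimation uses the Wald ratio
β_out/β_exp with the first-order delta SE (SE_out/|β_exp|; exposure
uncertainty ignored, matching the standard tooling default) for one
instrument, and fixed-effect IVW of the per-variant ratios — algebraically
the zero-intercept weighted regression — for several. MR-Egger and
MR-PRESSO are deliberately absent: in this setting most proteins carry a
single valid instrument after clumping, and those estimators need many.

FDR control is Benjamini–Hochberg within tissue × workflow (one FDR per
analysis table; whether the source pooled tissues is ambiguous, and the
scope is an argument). Steiger filtering converts instrument t-statistics
to variance explained, r² = t²/(t² + n − 2) summed over instruments per
trait, requires r²_exposure > r²_outcome strictly, and reports the Fisher-z
comparison p-value. For binary outcomes the same t-based formula on the
logistic z is an approximation, noted as such.

A record is **significant** iff FDR q < 0.05 AND averaged PP.H4 > 0.80 AND
the Steiger direction is correct. When both workflows run, pairs shared
with workflow-a are labelled `cis-only` and pairs unique to workflow-b
`trans-additional`.

## Colocalization

For each instrument, a ±500 kb window around it is intersected between the
exposure and outcome summary statistics, and the five single-causal-variant
hypotheses are scored from Wakefield log approximate Bayes factors,
log ABF = ½log(1−r) + r·z²/2 with r = W/(V+W), V = SE², W = prior variance.
Priors are p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵ per variant; the prior effect SD
defaults to 0.15 for quantitative traits (0.2 is conventional for log-odds
traits and is an argument) — the source invokes the reference defaults
without printing them. All hypothesis masses are accumulated in log space;
the H3 mass uses log-difference (S1·S2 − S12), which degrades gracefully to
zero for single-variant regions. With several instruments the arithmetic
mean PP.H4 across instrument-centred windows is reported, and
colocalization means PP.H4 > 0.80 strictly — a mean of (0.9, 0.7) fails.
Multi-causal-variant (credible-set) colocalization is out of scope.

## Cross-tissue comparison and annotation

Concordance: among significant, colocalized records, a (protein, phenotype)
pair carried by ≥ 2 tissues is concordant when all tissue estimates share a
sign. Category proportions between tissues are compared by a chi-square
homogeneity test with categories of expected count < 1 pooled into
"other" (the source names the test family, not the variant); for 2×2
tables the Yates continuity correction applies. The chi-square p agrees
with an exact Fisher computation only asymptotically — deviations up to
~0.26 exist for totals ≤ 30 — so exactness claims at small counts are not
made; the suite checks 0.02-level agreement at totals ~1000 per group.
Replication between tissues uses Storey's π₁ = 1 − π₀, with π₀ from the
λ-grid (0.05…0.95) smoothed by a natural cubic spline (df = 3) and
evaluated at the largest λ, clipped to [0, 1]; a fixed-λ (0.5) estimator is
exposed for small m where the smoother is unstable.

Replication against a prior study's MR table: replicated means prior
p < 0.05 with the same sign; the rate is replicated/(replicated + not
replicated); pairs absent from the prior table are novel. Druggable-genome
annotation assigns each significant protein's gene to tier 1 (targets of
approved/clinical compounds), tier 2 (drug-like binding partners), tier 3
(secreted/extracellular and family-adjacent), or unclassified "tier 4",
after deduplicating by gene; the headline percent is the tier 1–3 share.
Drug repurposing keeps phase-4, no-warning drugs and reads the direction
off the MR sign: a risk-increasing protein calls for an inhibitor, a
protective one for an activator.

One rounding convention applies to all printed percentages: half-up
(`percent_round()`), because half-to-even rounding turns 69/80 = 86.25%
into 86.2 whereas reports print 86.3.

# The synthetic world

The generator emulates the statistical structure the analysis assumes, with
defaults chosen once:

* **Genotypes.** A Gaussian copula: per haplotype, latent AR(1) normals
  thresholded at the allele-frequency quantile; dosage = sum of two
  haplotypes, giving Hardy–Weinberg genotypes. Thresholding attenuates
  latent correlation, so the per-step latent coefficient is calibrated (by
  inverting the bivariate-normal quadrant probability) to make the
  realized adjacent dosage correlation equal the requested ρ — adjacent
  r² is ρ² by design, up to sampling noise and the Fréchet bound of the
  MAF pair (e.g. r = 0.9 is unattainable between MAF 0.3 and 0.5
  indicators; the generator then delivers the maximum). Blocks sit on
  separate chromosomes, variants 5 kb apart, MAFs uniform in a range
  bounded below by the 2% QC floor. No real haplotype structure,
  imputation uncertainty, or recombination maps are emulated: a green LD
  test establishes that clumping and block removal behave as specified,
  not that the generator reproduces human LD.
* **Proteins.** protein = Σb·dosage + Γ·covariates + N(0, noise²) on the
  log scale; one strong cis variant per protein (default b = 0.5, the
  effect size used throughout the recovery criteria), optional trans
  effects and pleiotropic hubs with ≥ 5 targets. Gene TSSs are placed
  1 kb from the cis variant, inside any reasonable cis window.
* **Outcomes.** y = Σθ·protein + direct variant effects + noise, with
  marginal per-variant summary statistics emitted for every panel variant.
  Quantitative outcomes only: the formulas under test are identical for
  binary traits up to the logistic z approximation, so quantitative
  outcomes exercise every code path.
* **Raw plates.** 8 calibrator and 4 buffer wells per plate, three plates
  by default — the minimum metadata that exercises all four filters.
  Calibrators are drawn with an exact 5% CV (defects inject 30%), buffers
  sit two orders of magnitude below the sample range. Injected defects are
  ledgered so QC recovery is testable exactly.

Recovery criteria run at n = 2000, b_cis = 0.5, θ = 0.3 (estimator bias
and coverage), 500 protein–phenotype pairs under a global null (FDR
calibration, p-uniformity), 100 regions per colocalization scenario, and
200 reverse-causal runs for Steiger. These sizes keep the suite inside a
few seconds per block while leaving Monte-Carlo margins of several standard
errors on each asserted bound.

# Known limitations

* LD is block-diagonal AR(1); no inter-block LD, no MAF-LD coupling.
* Colocalization assumes a single causal variant per window.
* The Steiger r² formula is exact for quantitative traits only.
* The scale-factor definition is a reconstruction (the source uses the
  quantity without defining it); the 0.5 rule removes the analyte here,
  with flag-only behaviour achievable by consuming the report instead.
* Cross-assay protein bridging is reduced to an id intersection.
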