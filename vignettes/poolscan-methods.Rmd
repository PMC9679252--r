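---
title: "Divergence scans for Pool-Seq data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence scans for Pool-Seq data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem

Pooled whole-genome sequencing (Pool-Seq) genotypes a population as a single
library built from equimolar DNA of tens of individuals. What comes out is
not genotypes but population allele frequencies, and when allele frequencies
are called at a fixed pool ploidy `C` (20 here, i.e. the caller assigns
exactly 20 allele copies per pool per locus) they are quantized to a grid of
`1/C = 0.05`. poolscan screens such data for *genomic islands of
differentiation*: localized runs of windows in which relative divergence
(F\_ST) between two groups of pools is elevated against the genome-wide
background, the signature expected under migration–selection balance, where
gene flow homogenizes most of the genome and selection maintains divergence
at a few loci.

## Statistics

**Superpools.** Pools are grouped into superpools (populations); a
superpool's frequency is the unweighted arithmetic mean of member pool
frequencies, and its effective ploidy is `C` times the member count (e.g.
120 for six pools at ploidy 20).

**Relative divergence.** Per SNP, Nei's
\(F_{ST} = (\hat H_T - \hat H_S)/\hat H_T\) with
\(\hat H_T = 2\bar p(1-\bar p)\) over the unweighted group mean and
\(\hat H_S\) the mean within-group expected heterozygosity. For two groups
this is algebraically \((p_1-p_2)^2 / (4\bar p \bar q)\), which shows it is
nonnegative under equal weighting and undefined at sites monomorphic within
the pair (such sites are excluded from all F\_ST averages). This plain
estimator is upwardly biased at finite pool ploidy — the bias is visible in
real replicate pools, which show nonzero F\_ST from sampling alone — but the
bias is shared across comparisons made at similar depth and pool size, so
relative statements remain meaningful. A bias-corrected estimator is out of
scope.

**Absolute divergence.** \(d_{XY} = p_X q_Y + q_X p_Y\) for unphased pooled
frequencies; its expectation does not depend on within-group diversity, so
elevated \(d_{XY}\) inside an F\_ST island argues against the island being a
pure diversity artefact.

**Within-group diversity.** Per window and superpool, nucleotide diversity
\(\pi = \sum_{sites} 2j(C-j)/(C(C-1)) / n\) with `j` the allele count on the
superpool ploidy grid and `n` the window length in bp, and Tajima's
\(D = (\pi - \theta_W)/\sqrt{\widehat{var}}\) with the 1989 variance
constants at sample size `C`.

**Concordance.** Lin's \(\rho_c\) measures agreement of two pools'
frequency vectors with the identity line, using population-moment
(n-denominator) variances so \(\rho_c = 1\) exactly iff the vectors are
identical. Replicate pools should show high \(\rho_c\) and low pairwise
global F\_ST; both orderings are exercised in the tests.

## The kernel scan

Windows are centred every `step = 20` kb; each SNP contributes to a window
with Gaussian weight \(\exp(-(p-c)^2/2\sigma^2)\), \(\sigma = 30\) kb,
truncated at \(3\sigma\). The full window therefore spans
\(6\sigma = 180\) kb, and windows are only placed where they fit entirely
inside a linkage group. Weighted window F\_ST is the kernel-weighted mean
over SNPs with defined F\_ST. Window \(d_{XY}\) divides the kernel-weighted
SNP sum by the kernel mass over *every* bp of the span
(`kernel_bp_mass()`), because monomorphic sites contribute zero nucleotide
difference: this makes window \(d_{XY}\) a per-bp quantity of order
\(10^{-4}\)–\(10^{-3}\) at realistic SNP densities.

Two conventions deserve a note:

* \(\pi\) is reported per bp (divided by `n`), but Tajima's D is computed
  from the per-window \(\pi\) total so that \(\pi\) and \(\theta_W\) are on
  the same scale; mixing scales would let \(\theta_W\) dominate D.
* The standard Watterson normalizer \(\sum_{i=1}^{C-1} 1/i\) is the
  default; `theta_sum_upper = "C"` switches to an upper limit of `C` for
  compatibility with pipelines that use that convention.

Windows carry two SNP counts: `n_snps` (all SNPs in the span; used for
\(\theta_W\) and D, so both superpools see the same count) and `n_fst`
(SNPs with defined pairwise F\_ST; the number of values actually averaged,
used to index the bootstrap null).

## Significance and island calling

The null reference resamples, for each window SNP count `n`, `B` sets of
`n` per-SNP F\_ST values with replacement from the genome-wide pool, and
weights each set at `n` positions drawn uniformly over the window span —
the least-informative way to attach kernel weights to randomly ordered
draws. The default `B` is \(10^4\) in tests (the p-value resolution floor
is `1/B`; production runs can raise it to \(10^6\)). A window's p-value is
the proportion of replicates at or above its observed weighted F\_ST, using
the distribution matching its exact `n_fst` (capped at `n_max`);
Benjamini–Hochberg converts p-values to q-values, and windows with
`q < 0.05` are F\_ST outlier windows.

Islands are maximal runs of at least `min_run = 4` consecutive windows
(centre spacing exactly `step`; a gap, e.g. a linkage-group end, breaks the
run) with weighted F\_ST above a fixed threshold of 0.03. The threshold can
alternatively be taken as the upper 10% quantile of all window values
(`fst_threshold_from_quantile()`). The island interval is
`[first_centre − step/2, last_centre + step/2]`, i.e. `n_windows × step`
long — islands can be smaller than one full window span. Summaries count
member windows whose \(d_{XY}\) exceeds the genome-wide mean and upper 5%
quantile, and whose \(\pi\) or D falls below the genome-wide lower 5%
quantile, the combinations used to separate candidate local adaptation from
background selection.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the scan assumes: an 11-pool
design in three superpools (6 EBS-like, 3 AI-like, 2 WA-like replicates) at
ploidy 20 with mean depths 60–98; Poisson SNP counts at density
\(10^{-3}\)/bp on 5 (configurable) linkage groups of 2 Mb; ancestral
frequencies from Beta(0.5, 0.5) truncated to [0.05, 0.95] (a conventional
U-shaped spectrum; the truncation keeps ploidy-20 quantization from fixing
sites too often — real site-frequency spectra are not calibrated here);
population frequencies from the Balding–Nichols model; binomial pool counts;
Poisson depths; and a 1% rate of single-pool missing calls to exercise the
completeness filter. Pools of the same population share its frequency
exactly (replicate grade); a per-pool `perturb_fst` adds a small extra
jitter for temporal-replicate realism. Every run returns a ground-truth
record (ancestral and population frequencies, island membership) for
recovery tests.

**Calibration.** The config's `background_fst` is a target for the
*measured* superpool Nei F\_ST, which includes binomial pool-sampling
variance \(\approx p(1-p)/(Ck)\) per `k`-pool superpool on top of the
population-process divergence. `bn_param_for_target()` inverts the
first-order expectation
\(E[F_{ST}] \approx u/(2-u)\), \(u = F' + (a+b)(1-F')/2\) with
\(a = 1/(Ck_X)\), \(b = 1/(Ck_Y)\), to find the per-population
Balding–Nichols parameter \(F'\). At the default design this lands within
about 5% of the nominal background (0.019 measured for 0.02 nominal). The
same mapping is applied to island-level divergence, where it is knowingly
conservative (a nominal 0.15 yields roughly 0.12 measured — far above the
0.03 island threshold, so recovery is unaffected); the first-order
approximation degrades as \(F\) grows. A target at or below what sampling
noise alone produces is rejected as unattainable; `background_fst = 0`
is special-cased to "no population divergence at all".

**What the generator does not emulate:** linkage disequilibrium and
haplotype structure (impossible to validate from pooled data anyway),
sequencing error, reference bias, site-level depth heterogeneity beyond
Poisson, and within-superpool substructure (real pools from distinct
spawning sites show small nonzero pairwise F\_ST even within a region).
Passing recovery tests therefore demonstrates correctness of the scan
machinery under the stated model, not robustness to these real-data
features.

## Filtering

The two-step filter mirrors standard Pool-Seq practice: first remove SNPs
with any pool below 20× depth or above 2% of that pool's total reads
(totals computed over the matrix being filtered — the cap adapts to each
pool's coverage); then remove SNPs missing in any pool and SNPs invariant
across all pools. Filters are idempotent in practice; note the depth cap is
defined relative to the supplied matrix, so re-filtering an already
filtered matrix recomputes slightly smaller caps.

Reading PoPoolation2 sync files involves one approximation: sync stores raw
read counts, so pool frequencies are taken as depth ratios of the two
retained alleles and rounded to the nearest `1/C`. A maximum-likelihood
frequency call (as some upstream callers perform) is not reproducible from
sync input; the rounding stand-in is flagged here deliberately.

## Problem sizes and numerical choices

Tests and the acceptance script run the full pipeline at 5–6 linkage groups
of 2 Mb, SNP density \(10^{-3}\) (10–12k SNPs), `B = 10^4` bootstrap
replicates, and 10 seeds per property — sizes chosen so the whole validation
suite completes in minutes while keeping Monte-Carlo error well inside the
asserted tolerances. Degenerate inputs are handled by sentinel `NA`s:
per-SNP F\_ST at monomorphic pairs, windows with no SNPs (excluded from
FDR), Tajima's D at `S_n = 0`, and the outlier CV when no window is
significant. Quantiles use the linear-interpolation definition
(`stats::quantile` type 7). Ties in the bootstrap p-value count as "at or
above" the observation, so p-values are conservative at the resolution
floor.

## Known limitations

* The F\_ST estimator is the plain expected-heterozygosity form; absolute
  F\_ST levels inherit its ploidy bias and should be read comparatively.
* Island boundaries are blurred by the kernel: called intervals extend
  roughly \(\pm 1.4\sigma\) beyond a strong truth region's edges before
  window means drop below threshold, so very small islands (≲ 100 kb) may
  fail reciprocal-overlap matching even when detected.
* The bootstrap null resamples per-SNP F\_ST independently, ignoring local
  autocorrelation; with strongly clustered selection targets the null is
  anti-conservative in principle, which is why island calling additionally
  requires a fixed effect-size threshold and a minimum run length.
* Superpool comparisons weight groups equally regardless of pool count; a
  ploidy-weighted variant would change \(\bar p\) at unbalanced designs.
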