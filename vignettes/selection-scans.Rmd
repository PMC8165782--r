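---
title: "Scanning the avian Z chromosome for selection signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning the avian Z chromosome for selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zsweep)
```

## The problem

Two broiler chicken lines divergently selected for abdominal fat content for
many generations accumulate allele-frequency and haplotype differences at the
loci that selection acted on. `zsweep` scans biallelic SNP-chip genotypes of
two such populations for these selection signatures, with the chicken Z
chromosome as its reference design: males are ZZ, so an all-male cohort is
diploid for Z and ordinary diploid statistics apply (one reason the package
does not model ZW females, hemizygosity or dosage compensation).

Three complementary statistics are computed, each sensitive to a different
footprint of selection:

* **Windowed F~ST~** — classical allele-frequency differentiation, strongest
  for older, near-complete sweeps;
* **XPEHH** — cross-population extended haplotype homozygosity, strongest
  for recent or ongoing sweeps whose long haplotypes have not yet been broken
  up by recombination;
* **EigenGWAS** — per-SNP regression of a genotype-derived eigenvector,
  which flags the SNPs that drive the population-structure axis separating
  the lines.

Significant SNPs and windows are merged within and then across methods into
*candidate regions*, annotated against gene/QTL interval tracks, and the
genes falling in candidate regions can be screened with a two-group
microarray differential-expression stage (5 fat-line vs 5 lean-line arrays in
the reference design).

## The statistics

### Weir–Cockerham F~ST~

For two populations with $n_A, n_B$ called gametes (two per diploid sample)
the per-SNP estimator is the gamete-level one-way ANOVA

$$F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG},$$

where $MSP$ is the mean square among populations, $MSG$ the mean square among
gametes within populations and $n_c = n - (n_A^2+n_B^2)/n$ the corrected
average gamete count for $r = 2$ groups. Negative estimates are a known
property of the estimator and are retained unclamped so that window means
stay unbiased. A SNP monomorphic across both populations carries no
information and is scored 0 with a `monomorphic` flag. Window means use
100 kb windows stepped every 10 kb, tiled from coordinate 0 with half-open
bounds `[start, end)` — anchoring at 0 makes the tiling deterministic and
independent of where the SNPs happen to sit. Empty windows are omitted, and
the outlier threshold is the Tukey fence $Q_3 + 1.5\,(Q_3 - Q_1)$ over the
non-empty window means (quartiles by linear interpolation, the common
default; the strict `>` comparison means a flat distribution yields no
outliers). The fence is recomputed from every dataset — thresholds published
for specific datasets (e.g. a 0.51 fence for a real chip dataset) are
properties of those data, not constants of the method.

### EHH, iHH and XPEHH

EHH at distance $d$ from a core SNP is the probability that two haplotypes
drawn at random from the population are identical at every SNP from the core
out to $d$: partitioning the haplotypes by their extended haplotype,
$EHH = \sum_h \binom{n_h}{2} / \binom{n}{2}$. The package uses the
population-level convention (all haplotypes, no split by core allele), the
form that cross-population comparison needs — one score per SNP per
population pair. iHH integrates the left and right EHH curves over physical
distance by the trapezoid rule, truncated at the first point where EHH falls
below 0.05 (the usual cutoff in the XPEHH literature; included as the last
integrated point) and capping any single inter-SNP gap's contribution at
200 kb to guard sparse regions. Physical distance stands in for genetic
distance because no Z-chromosome genetic map is assumed; both the cutoff and
the gap cap are exposed as arguments. The cross-population score is
$\ln(iHH_A/iHH_B)$, standardised chromosome-wide to mean 0 and sd 1, and a
SNP is significant when $|XPEHH| > 2$ — a two-sided 0.05 rule that is only
meaningful on the standardised, approximately normal score, which is why
standardisation precedes thresholding. Positive scores mean longer
homozygosity in population A.

### EigenGWAS

The genomic relationship matrix standardises each SNP's dosages by
$2p$ and $\sqrt{2p(1-p)}$ (missing set to 0 after centring) and averages
over SNPs. Its leading eigenvectors are the population-structure axes; with
two diverged lines, PC1 separates them, which is why PC1 is the default
tested component (an argument, not a constant). Each SNP is then fit by
ordinary least squares in $y = \mu + b\,x + e$ with $y$ the eigenvector and
$x$ the dosage (complete-case per SNP), giving $\chi^2 = (b/se)^2$.

Because $y$ is computed from the same genotypes, the null median of these
statistics is not 1: it equals the leading GRM eigenvalue, which for pure
noise sits at the Marchenko–Pastur bulk edge $(1+\sqrt{n/M})^2$ — about 2.2
at 475 samples by 2,000 SNPs. Genomic control divides all statistics by
$\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549$, exactly removing this
drift/sampling inflation, and p-values come from the 1-df chi-square upper
tail with Bonferroni significance at $0.05/M$. The correction can be
disabled (`gc = FALSE`) for the raw scan. A mixed-model (EMMAX-style) fit is
deliberately not reproduced: the scanned model is the plain single-marker
regression printed above.

### Regions

Each method's significant output becomes intervals: outlier windows pass
through as-is, significant SNPs expand by ±200 kb (matching the 0.40 Mb
minimum width of published per-method intervals), and same-method intervals
within 1 Mb are unioned. Across methods, single-linkage merging joins
intervals whose gap is strictly below 1.0 Mb + 0.1 Mb: the 0.1 Mb tolerance
absorbs endpoint rounding at 0.01 Mb precision, where a truly sub-1 Mb gap
can print as 1.04–1.06 Mb. Without the tolerance the published worked
example would split two of its regions; with a strict < 1.1 Mb rule it
reproduces all 17. Region lengths are reported as `end − start` in Mb at two
decimals, the convention of the published tables. Annotation attaches a
track label on any ≥1 bp inclusive overlap; on disk, BED is 0-based
half-open and converted at the boundary (tested both ways).

The package ships the published per-method intervals
(`chicken_z_intervals()`) as a worked example. One printed F~ST~ interval
had its end (47.58) before its start (47.72); it is corrected to
47.72–48.58, consistent with its candidate region, and the correction is
recorded in the fixture's `note` column rather than applied silently. The
published per-method *region* counts (1 XPEHH, 11 F~ST~, 12 EigenGWAS)
emerge from this fixture as the number of candidate regions each method
supports; the intra-method rule behind the published counts was not stated,
so the shipped intervals, not any re-derived count, are treated as ground
truth.

### Differential expression

Per gene, a one-way ANOVA across the two lines on log2 values — with two
groups this is the classical equal-variance F-test, $F = t^2$. Fold change
is $2^{|\bar y_A - \bar y_B|}$ from the log2 line means (the alternative
convention, means of linear-scale values, is a documented switch away via
the log2 columns the result carries); a gene is differentially expressed iff
$p < 0.05$ *and* fold change strictly exceeds 2 — a fold change of exactly
2.0 never passes. No multiple-testing correction is applied, matching the
conventional microarray screen this stage mirrors. "Expressed in a line"
means a strict majority of that line's samples carry a detection flag;
detection flags are taken as supplied (or simulated) because the array
detection p-values they derive from need the raw probe data, which is out of
scope.

## What the simulator emulates — and what it does not

`simulate_divergent_pops()` draws, per SNP, an ancestral frequency uniform
in (0.05, 0.5) and per-population frequencies from the Balding–Nichols Beta
distribution with differentiation parameter `fst_target`; haplotypes are
sampled independently per site, genotypes are haplotype sums, and
missingness is applied to dosages only. Defaults are the reference study's
design: 203 + 272 all-male samples, 2,000 SNPs on an 83 Mb chromosome, 2%
missingness. The differentiation default of 0.2 is a realistic magnitude for
lines divergently selected over many generations (no published value exists
for this quantity); it was chosen once and not tuned. Positions are uniform then sorted,
with duplicate collisions resolved by +1 bp shifts.

The baseline is deliberately LD-free: background linkage disequilibrium,
recombination maps and coalescent ancestry are not modelled.
Haplotype-based behaviour is exercised through `inject_sweep()`, which
overwrites a chosen fraction of the target population's haplotypes with one
core haplotype across a span — the long shared haplotypes and frequency
shift a recent sweep leaves. Passing tests therefore demonstrate that the
statistics respond correctly to the *modelled* signal; they do not
demonstrate robustness to background LD, ascertainment bias of chip SNPs,
genotyping error structure, or array-normalisation artefacts in the
expression stage, all of which real data carry.

Two calibration facts from pilot simulation (50 and 20 replicates
respectively, run before the corresponding tests were frozen) are worth
knowing. First, the *mean per-SNP* Weir–Cockerham estimate at
`fst_target = 0.2`, 200 + 200 samples and 2,000 SNPs is ≈ 0.147 (range
0.141–0.163): averaging per-SNP ratio estimators and scoring boundary-fixed
SNPs as 0 both bias the average below the nominal parameter. The tests
assert the calibrated band, not 0.2. Second, the null
$\lambda_{GC} \approx (1+\sqrt{n/M})^2$ relationship above was verified
across matrix shapes; the unit tests assert $\lambda_{GC}$ within 15% of
the top eigenvalue rather than near 1.

`simulate_expression()` defaults to 5 + 5 arrays, 200 genes, 8% truly
differential at a true log2 fold change of 2 with noise sd 0.25 on the log2
scale and a 10% per-cell detection failure rate — levels at which the
published thresholds give essentially complete recall, so the DE tests
measure the thresholds' behaviour, not a power cliff.

## Numerical and design choices

* Missing dosage is `NA`; every arithmetic step masks it explicitly
  (call-rate and MAF computations, per-SNP complete-case regression,
  GRM centring-then-zeroing).
* QC order is fixed: SNP call rate, then sample call rate, then MAF
  recomputed on surviving samples; all thresholds keep-if-≥, so applying QC
  twice is a no-op.
* Eigenvector signs are fixed by forcing the first nonzero loading
  positive, making eigendecompositions reproducible across runs.
* Quartiles use linear interpolation (type 7), flagged here because other
  quantile dialects shift Tukey fences slightly.
* Degenerate cases: a core SNP whose population homozygosity is already
  below the EHH cutoff is unscored rather than integrated; zero-variance
  genes with equal means get $p = 1$; merging an empty interval set returns
  an empty region table.
* Every scan result echoes its parameters (`params`, `glance()`), and
  `run_pipeline()` writes them into `summary.json`, so no default is
  silent.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data and
the shipped interval fixture. Stochastic checks use the study-scale design
(475 samples × 2,000 SNPs) where the claim is about that design — 20
replicate end-to-end pipelines for sweep recovery, 3 replicates for
parameter recovery — and desk-scale fixtures (tens of samples, a few hundred
SNPs) for oracle-equivalence and property checks, which are
scale-independent.

## Known limitations

* Two populations only (no $r > 2$ F~ST~), one chromosome at a time.
* No phasing: phased haplotypes must be supplied (or simulated); XPEHH is
  skipped when only unphased genotypes are given.
* Physical-distance iHH; no genetic-map interpolation, no iHS.
* Quantities published for the real chip dataset this design mirrors —
  its post-QC SNP/sample counts, its 0.51 window fence, its PCA variance
  fractions, per-method significant-SNP counts and expression counts —
  depend on those arrays and annotation versions and are not reproduced
  here; the worked example reproduces the published *region table* from the
  published per-method intervals, which is the part that is a function of
  the method rather than of raw data access.
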