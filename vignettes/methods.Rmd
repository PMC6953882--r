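---
title: "Mapping trans-regulators of TE CHH methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-regulators of TE CHH methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chhscan)
```

# The problem

In plants, CHH-context cytosine methylation (mCHH; H = A, T or C) is
asymmetric and must be re-established every cell generation by one of two
de novo pathways: RNA-directed DNA methylation (RdDM, Pol V/NRPE1- and
DRM2-dependent) and the CHROMOMETHYLASE 2 (CMT2) pathway acting on deep
heterochromatin.  In a panel of inbred lines with population bisulfite
data, natural alleles of the genes in these pathways act as
*trans*-regulators: a single segregating polymorphism shifts mCHH levels at
hundreds of transposable elements (TEs) genome-wide.  `chhscan` implements
the full inference chain for detecting and characterizing such regulators:

1. **Methylome summaries** -- weighted methylation levels per TE, a
   common-TE filter, family averages, rank transforms, pathway-target
   classification against knockout methylomes, positional metaplots and
   complete-linkage family clustering.
2. **Association** -- an EMMAX-style linear mixed model per phenotype with
   identity-by-state (IBS) kinship, plus an uncorrected linear model for
   contrast, MAF > 5% filtering, Box-Cox preparation of expression
   phenotypes, and single-SNP variance explained.
3. **Meta-analysis** -- Fisher's method across the per-family scans, a
   candidate-gene enrichment FDR to calibrate the genome-wide threshold,
   and greedy LD pruning of peaks.
4. **Allelic effects** -- per-TE differential methylation (DML) by allele,
   Spearman correlation against a knockout-panel DML matrix with a
   1,500-SNP permutation null, joint two-locus metaplots, and Welch tests
   for expression differences.
5. **LD and geography** -- standardized linkage disequilibrium D' between
   unlinked loci against a matched-MAF empirical null with one-sided exact
   tests, genotype-combination frequencies against random mating, and
   longitudinal clines with allele regression-out or BLUP structure
   correction.
6. **A synthetic-data module** that generates panels with all of the
   statistical structure the analysis assumes, so that every stage is
   testable at desk scale.

# Statistical models

## Weighted methylation and phenotypes

The methylation level of a region is the ratio of summed methylated-read
counts to summed covered-read counts, never the mean of per-site ratios
(which would overweight shallow positions).  Only TEs covered in every
line ("common" TEs) become phenotypes; family phenotypes are unweighted
means over member TEs (the data carry no obvious weighting scheme, and an
unweighted mean keeps family values on the same scale as TE values).
Before scanning, each phenotype is converted to ranks across lines
(average ranks on ties), which makes the scans invariant to monotone
changes of the methylation scale and robust to its bounded, skewed
distribution.

## The mixed-model scan

For a phenotype $y$ and SNP genotype $x$ (haploid 0/1; the panel is
inbred, so no heterozygotes exist) the model is

$$y = \mu + x\beta + u + \varepsilon,\qquad
  u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I),$$

with $K$ the IBS kinship (pairwise fraction of shared alleles, missing
genotypes excluded pairwise).  The variance components are estimated once
on the null model ($\beta = 0$) by REML through the eigendecomposition of
$K$, profiling the ratio $\delta = \sigma_e^2/\sigma_g^2$ on a log grid
with an optimizer; each SNP is then tested by generalized least squares in
the rotated space with the components held fixed (the P3D/EMMAX
approximation), using a two-sided Wald $t$ on $n - 2$ degrees of freedom.
This makes a scan $O(nm)$ after one eigendecomposition.  Numerical
choices: eigenvalues of $K$ are floored at $10^{-8}$; when the REML
profile is flat or maximized at the boundary $\sigma_g^2 = 0$ (always the
case for $K = I$), the scan collapses exactly to ordinary least squares.
Missing genotypes are mean-imputed per SNP; the panels this mirrors are
essentially complete, so imputation is a formality.

**Known limitation.**  P3D holds the variance ratio fixed from the null
model.  At desk-scale sample sizes (tens of lines) a SNP that partially
tags the population structure can shift the per-SNP REML optimum of
$\delta$ toward the $\sigma_g^2 = 0$ boundary, and its P3D p-value then
deviates from the exact per-SNP fit.  In our experiments at $n = 60$ with
structured kinship, 80--95% of SNPs agree with a per-SNP
restricted-likelihood grid oracle within 0.05 in $-\log_{10} p$; the
remainder deviate by up to ~0.6.  The discrepancy shrinks with $n$ and
does not affect the rank of strong peaks, but exact per-SNP fits are the
reference when they matter.

## Fisher's method and the enrichment FDR

Per SNP, the $k$ per-family scan p-values are combined as
$X^2 = -2\sum_i \ln p_i$, referred to a $\chi^2_{2k}$ upper tail.
Component p-values of exactly zero are clamped to $10^{-300}$.  The
family scans are correlated phenotypes of one panel, so the $\chi^2$ null
is anti-conservative to an unknown degree; we do not attempt an
analytical correction.  Instead -- as in the study design this follows --
the genome-wide threshold is calibrated empirically: each gene receives
the best combined p-value among MAF > 5% SNPs within 15 kb of its span
(closed interval), and for a descending grid of observed scores $t$ the
FDR is estimated as

$$\widehat{\mathrm{FDR}}(t) =
  \frac{(\#\{\text{background genes} \ge t\} + 1)/(N_{bg} + 1)}
       {(\#\{\text{a priori genes} \ge t\} - 1)/N_{ap}},$$

capped at 1, with the threshold the smallest $t$ at which
$\widehat{\mathrm{FDR}}(t) \le 0.2$ supported by at least 3 a priori
genes.  The three guards -- add-one smoothing of the background tail, a
leave-one-out a priori count (candidate thresholds are observed scores,
so the a priori gene sitting at a threshold always counts itself as
enriched there), and the minimum count -- matter because the estimator is
a ratio of tail counts: without them the one or two best-scoring a priori
genes claim a spurious "threshold" in roughly one exchangeable-null panel
in five, with them the rate is about 1%.  At a genuinely enriched
threshold the guards move the estimate by a few percent at most.  SNPs above
the threshold are pruned greedily: sort by $X^2$ descending (ties broken
by genomic order), keep a SNP iff $r^2 \le 0.2$ with every kept SNP, and
record which peak absorbed each pruned SNP.

## Allelic effects and the permutation null

The DML profile of an allele is, per TE, the mean level in
alternative-allele lines minus the mean in reference lines (negative =
the alternative allele lowers methylation).  Knockout panels use the same
convention (mutant minus wild-type), so a loss-of-function allele and its
matched knockout correlate positively.  Causality is probed by Spearman
correlation of the allele's profile with each mutant's profile, referred
to an empirical null built from 1,500 SNPs drawn uniformly from the
MAF-filtered genome; the two-sided empirical p is
$(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm} + 1)$, never exactly zero.
Permutation SNPs are not frequency-matched (frequency-matched nulls
belong to the LD module, where the hypothesis concerns a specific pair).

## D', matched-MAF null, and geography

For haploid lines haplotypes are observed directly:
$D = p_{AB} - p_A p_B$, $D' = D/D_{max}$ with the usual signed
normalization.  To ask whether two specific unlinked loci are in unusual
LD, the observed $D'$ is compared with $D'$ between the target SNP and
every SNP matching the partner's MAF within ±0.5 percentage points on
chromosomes other than either focal SNP's.  The one-sided direction is
fixed a priori to repulsion (depletion of the double-carrier class, the
signature of selection against the combination); fixing the direction is
what makes the empirical p uniform under independence, whereas choosing
the direction from the observed sign would bound it near 0.5.  A
one-sided Fisher exact test on the 2x2 haplotype table accompanies each
pair.

Longitudinal clines are ordinary least squares of a per-line value on
longitude within a configurable window (default [-25, 100]).  With a
covariate allele the value is first regressed on the genotype and the
residuals are regressed on longitude, so a fully allele-mediated cline
loses significance.  `blup_correct()` removes kinship-structured signal:
REML fit of value = mean + u + e with cov(u) proportional to K, then
subtraction of the BLUP of u from the centered values; if the REML
estimate of the genetic variance is 0 (including the unidentifiable
$K = I$ case, where the profile is exactly flat) the centered values are
returned unchanged, which also makes the correction idempotent.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions of every acceptance check.  It emulates:

* **Population structure.** Haploid 0/1 genotypes for 500 inbred lines at
  5,000 background SNPs under a Balding-Nichols model (3 subpopulations,
  divergence 0.1; ancestral frequencies uniform on [0.05, 0.5]).
* **Geography.** Longitude from a Europe-heavy mixture: 80% of lines
  uniform on [-20, 45], 20% uniform on [55, 100].  A uniform longitude
  cannot give a 9%-frequency allele more than $r^2 \approx 0.25$ with
  longitude; the clumped mixture reproduces the strong eastern-allele
  cline ($r^2 \approx 0.33$) that the geographic analyses need.
  Longitude is independent of subpopulation by default, so geography and
  structure are confounded only through planted clines.
* **Planted trans-QTLs** (`default_causal_spec()`): an eastern allele
  (MAF 9%, logistic cline slope 6 on scaled longitude) with effect -0.05
  on RdDM-class TEs and a -0.04 cross-class effect on CMT2-class TEs; and
  two mutually exclusive alleles of one locus affecting only CMT2-class
  TEs, -0.05 (MAF 23.7%, western, slope -1.9191) and +0.04 (MAF 20%,
  geographically flat).  The western slope was solved (once, numerically)
  so that the expected longitudinal gradient of CMT2-class methylation --
  including the eastern allele's cross-class contribution -- is zero:
  compensating geography.  Logistic intercepts are solved per panel so
  realized MAFs land within ±20% relative of their targets (resampled up
  to 50 times, then an error naming the locus).
* **Methylomes.** Latent level = class baseline (0.15 RdDM / 0.25 CMT2 /
  0.12 untargeted) + per-TE offset (sd 0.02) + allelic effects +
  polygenic line effect (sd $0.055\sqrt{0.3}$, covariance proportional to
  the IBS kinship, so the mixed model has something to correct; centered
  across lines, since a panel-wide shift is invisible to every analysis
  and would only drive clipping) + iid
  line-by-class noise (sd $0.055\sqrt{0.7}$) + iid cell noise (sd 0.04),
  clipped to [0, 1] (a warning reports clipping above 5% of cells; under
  the defaults ~1% of cells clip).  Observed counts are beta-binomial
  (overdispersion 0.1) at Poisson depth 40.  With these values the
  eastern allele explains ~6% of the variance of the RdDM-class average
  at $n = 500$.
* **Positional structure.** Optionally each TE gets 60 bins (20 upstream,
  20 body, 20 downstream): flanks taper the baseline, CMT2-pathway
  effects act on bodies only, RdDM-like and cross-class effects act over
  the whole element including edges; scalar counts are the body-bin sums,
  so both paths share one latent body level.
* **Knockout panel.** Two class-pure classifier knockouts (loss 0.2 on
  their class), one matched mutant per causal allele with profile 4x the
  planted allelic profile (knockouts are stronger than natural alleles
  but hit the same targets) plus noise (sd 0.02), and 12 decoys with
  random sparse profiles.
* **Expression.** Log-normal baseline with an additive cis shift (in
  baseline-SD units) for carriers of a designated allele, floored at the
  smallest positive double so values stay positive.

What the generator does **not** emulate: per-cytosine resolution and
sequence context, TE insertion polymorphism, LD between background SNPs
beyond shared population structure, depth heterogeneity between lines,
and batch or tissue effects.  Passing tests therefore demonstrate that
the inference machinery is correct under its stated assumptions -- not
that those assumptions hold in any particular real panel.

# Design choices on open points

* **Tie handling in ranks**: average ranks (preserves rank sums).
* **TEs exceeding the 0.1 DML threshold in both classifier knockouts**
  get a `both` label; class-specific analyses exclude them by default.
* **Clustering**: Euclidean distance on per-line ranks, complete linkage,
  cut at $k = 4$ by default; all config-exposed.
* **Family averages** are unweighted (no length or coverage weighting).
* **Gene windows**: span ±15 kb, closed; genes without an in-window SNP
  are excluded from the FDR input rather than scored 0.
* **Targeted-TE sets** use per-TE mixed-model association with the focal
  SNP at $-\log_{10} p \ge 6$ on large panels; the desk-scale default in
  the pipeline is 1.5, calibrated to the per-TE power available at
  $n = 500$, depth 40 (at those sizes a true target's median score is
  ~1.4--2).
* **Permutation SNPs** are uniform over the MAF-filtered genome, not
  frequency- or chromosome-matched.
* **Seeds.** Every generator is a pure function of (config, seed); the
  pipeline derives per-stage sub-seeds by XOR of the master seed with the
  stage index, so stages re-run in isolation reproduce byte-identical
  outputs (stages exchange data only through files).

## Calibration-test design note

With exactly two subpopulations a panel has a single genetic structure
axis, and the projection of one polygenic draw onto it is a single
chi-square(1) variate: the inflation of the naive (uncorrected) scan on
one null phenotype is therefore a lottery, ranging from ~1 to >10 across
draws, while the mixed model stays calibrated throughout.  The shipped
calibration check consequently scans five independent null phenotype
draws of one structured panel and judges inflation on the median.

# Problem sizes

The shipped tests and the acceptance script run, per check: Fisher
uniformity at 10,000 SNPs x 20 scans; oracle comparisons at 60 lines x
~200 SNPs; calibration at 500 lines x 5,000 SNPs; parameter recovery over
20 seeds of the 500-line default panel; permutation-null calibration over
200 runs at 199 permutations; matched-MAF calibration over 60 panels; and
three full end-to-end runs of the default configuration.  These sizes
were chosen so the full suite completes on a single CPU in minutes while
keeping every stochastic bound comfortably powered.

# Known limitations

* The P3D approximation error at small $n$ (quantified above).
* Fisher's combination treats the family scans as independent; they are
  not, and the combined p-values are anti-conservative.  The enrichment
  FDR, not the $\chi^2$ scale, carries the inferential weight, and extra
  non-causal peaks above threshold are expected on synthetic panels.
* The enrichment-FDR estimator is a tail-count ratio: noisy at extreme
  thresholds (hence the minimum a priori count guard) and biased upward
  when many a priori genes carry true signal.
* The empirical matched-MAF p has resolution $1/(n_{matched}+1)$ and is
  mildly conservative under heavy ties of the discrete D' distribution.
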