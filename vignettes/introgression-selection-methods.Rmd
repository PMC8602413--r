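---
title: "Methods: introgression scans, selection signatures and the ILS null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression scans, selection signatures and the ILS null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Wild and domestic sheep (*Ovis*) exchange genes across species
boundaries, and some of that introgressed variation overlaps regions
later shaped by domestication. Detecting these events from
multi-population SNP cohorts needs three ingredients: statistics that
discriminate gene flow from shared ancestral variation, a selection scan
that flags diversity loss plus differentiation in the domestic cohort,
and a null model for how long a shared haplotype tract can remain intact
without gene flow. `introscan` implements that toolkit on diploid
genotype tables, plus a seeded simulator that plants known introgression
tracts and sweeps so every stage can be validated against ground truth.

# Statistics

## Site filtering and polarization

Sites enter the analyses after cohort-level filters: missing-genotype
fraction at most 0.1, pooled minor-allele frequency at least 0.05, and a
one-sided exact test for heterozygote *excess* at p < 0.001. Two
deliberate choices here:

* The heterozygote test is one-sided and uses the mid-p correction of
  the conditional (Levene) exact distribution. Common GWAS tooling
  defaults to a two-sided test; only an excess of heterozygotes
  indicates the paralog-collapse artefacts this filter targets, so a
  deficit (which real population structure produces constantly via the
  Wahlund effect) never removes a site.
* MAF is computed on all samples pooled, after removing missing calls.

Derived-allele frequencies are polarized against an outgroup column: the
ancestral allele is the allele fixed among the outgroup's called
genotypes, and sites with a polymorphic or fully missing outgroup are
excluded from the four-taxon statistics. Missing genotypes are never
imputed; every frequency uses observed calls only.

## Windowed diversity

All windowed statistics run on a sliding grid (100-kb windows, 20-kb
steps by default) in 0-based half-open coordinates. Per window:

* Nucleotide diversity
  $\pi = \sum_s \frac{n}{n-1} 2\hat p(1-\hat p) / L$ — the per-site term
  equals the mean pairwise Hamming distance over haplotype pairs.
* $d_{xy} = \sum_s [\hat p_A(1-\hat p_B) + \hat p_B(1-\hat p_A)] / L$.
* Hudson's $F_{ST}$ as a ratio of averages of per-site components, the
  estimator recommended for unequal, small sample sizes (cohorts here
  range from 3 to 18 diploids). Negative window values are preserved so
  genome-wide means stay unbiased.

The denominator $L$ is the window length in bp, which treats absent
sites as invariant — correct after joint genotyping, an overestimate of
accessible sequence otherwise; a callable-sites correction can be
applied by adjusting window lengths upstream. Windows without usable
sites report `NA`, never 0, and partial terminal windows are flagged and
excluded from quantile computations.

LD decay uses the squared Pearson correlation of unphased genotype codes
(Rogers–Huff style); phase is not required anywhere in the package.

## D, f3 and the fd scan

For a quartet (P1, P2, P3, outgroup) with polarized frequencies,
per-site $ABBA = (1-\hat p_1)\hat p_2\hat p_3$ and
$BABA = \hat p_1(1-\hat p_2)\hat p_3$ (the outgroup is ancestral, so its
derived frequency is 0). Genome-wide
$D = (\sum ABBA - \sum BABA)/(\sum ABBA + \sum BABA)$ with a
delete-one weighted block jackknife (1-Mb blocks, per-block usable-site
counts as weights) providing the standard error; |Z| > 3 is the
significance rule. f3 uses the bias-corrected Patterson form with the
same jackknife.

The window scan uses Martin et al.'s $f_d$: the D numerator divided by
the same quantity with the per-site donor-maximized frequency
$\hat p_D = \max(\hat p_2, \hat p_3)$ substituted for both P2 and P3.
Pattern sums run over all usable sites of a window; the count of
*informative* sites (ABBA + BABA > 0) only gates low-information
windows (default minimum 10). $f_d$ is undefined for windows with
non-positive window D or denominator.

Defined $f_d$ values are standardized genome-wide, mapped through the
one-sided upper normal tail and BH-adjusted. Three standardization
modes:

* `mean_sd` (operation default): mean and SD of all defined windows —
  the plainest reading of a "Z-transformed fd";
* `two_pass` (pipeline default): re-estimates the null moments after
  removing the first pass's discoveries. When a few percent of windows
  carry real signal, those windows inflate the naive SD and mask
  moderate signal; on a pure null the first pass discovers almost
  nothing and the two modes coincide, so calibration is unchanged;
* `robust`: median/MAD. Noticeably anti-conservative here, because the
  conditional (D > 0) null of $f_d$ is right-skewed and the MAD
  understates its upper tail; provided for comparison.

## Tract calling

Windows with positive D and q < 0.05 merge when overlapping or
book-ended. Two refinements, both off at the operation level and on in
the pipeline wrapper:

* `edge_trim`: a significant window only localizes signal to somewhere
  inside it, so the union of overlapping significant windows overhangs
  the true signal edge by up to a window length. Trimming
  $(\text{window} - \text{step})/2 = 40$ kb from each end (never below
  one window of remaining length) removes the expected overhang when
  windows covering at least half their span with signal trigger.
* `min_windows = 2`: discards singleton significant windows. BH keeps
  the *window-level* FDR at 5%, but each false window costs a full
  100 kb of called sequence while true windows share their span with
  overlapping neighbours, so singletons dominate the base-pair-level
  error; real tracts longer than a step recruit several windows.

## Selection scan

Per window: cohort-pooled $\pi$ for the wild and domestic cohorts, their
ratio $\pi_w/\pi_d$, and pooled-cohort Hudson $F_{ST}$. Selection =
joint membership in the top decile of both statistics, computed
empirically over defined, non-partial windows with ties included (≥).
The thresholds are data-dependent by construction — a published cutoff
like a realized ratio threshold is that dataset's 90th percentile, not a
constant — and the rank basis makes the selected set invariant under
monotone rescaling of either statistic. Windows where either statistic
is undefined are excluded from both threshold estimation and selection.

## ILS tract-length null

A haplotype tract inherited from the common ancestor of two species that
split $t$ generations ago has expected length $L = 1/(rt)$ bp; the
probability that such a tract is at least $m$ bp is the Erlang-2
survival $e^{-m/L}(1 + m/L)$, i.e. 1 − GammaCDF(m; shape 2, rate 1/L).
The default arithmetic uses the per-branch time $t = \text{years}/g$,
reproducing the published sheep computations exactly
(L = 115.94 bp for the 2.3-My snow sheep comparison, 155.04 bp for the
1.72-My argali comparison at r = 1.5e-8, g = 4); a `two_branches` flag
doubles $t$ for the total-branch-length convention used elsewhere in the
literature. Observed tracts hundreds of times longer than $L$ push the
survival below the double-precision minimum; these are reported as
exactly 0 rather than as a subnormal artefact. Dating converts
generations to years by plain multiplication with the generation time.

## qPCR copy-number calls

$\Delta\Delta C_T$ compares segment-vs-reference threshold cycles
between a target and a two-copy control sample; relative copy number is
$2 \times 2^{-\Delta\Delta C_T}$, calling deletion below 1.5,
duplication above 3 and normal inside the closed interval [1.5, 3]
(boundary values are normal; a small relative epsilon guards the
boundaries against floating-point noise). The replicate SD propagates as
$s = \sqrt{s_1^2 + s_2^2}$ with $s_1, s_2$ the sample SDs (n−1) of the
per-replicate $\Delta C_T$ in each sample — the formula only makes
dimensional sense if the two terms are SDs being squared, so they are
treated as SDs even though source descriptions of this propagation
sometimes label them variances. Replicates pair positionally when
segment and reference have equal counts, else each segment replicate is
taken against the reference mean.

# The simulator

Population frequencies follow the Balding–Nichols model: ancestral
frequency $p \sim \text{Beta}(0.8, 0.8)$ per site (U-shaped, standing
variation), each population at
$\text{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with its own drift coefficient
$F$, genotypes binomial. Under this model the expected Hudson $F_{ST}$
between two populations is $(F_1 + F_2)/2$, which the test suite checks
by numerical integration. The outgroup is a fixed pseudo-population
carrying the alternate allele at 25% of sites so polarization is
exercised. Ancestral frequencies are clamped to [1e-4, 1 − 1e-4] so no
site is degenerate by construction.

Introgression events draw non-overlapping tracts (exponential lengths,
rejection-sampled starts, truncated at contig ends); inside a tract each
recipient haplotype is replaced by a donor draw with probability
$\alpha$, with the replaced-haplotype count drawn once per sample per
tract so ancestry is contiguous along the tract. Sweeps push the pooled
cohort frequency toward the nearest fixation boundary until expected
heterozygosity drops by the configured factor, set all cohort
populations to that common swept frequency (sweeps homogenize), and
redraw the cohort's genotypes in the window. All draws flow from one
seeded generator stream, base cohort first, so populations untouched by
an event are bit-identical to a run without it.

## Demonstration conditions

The default demonstration cohort fixes the study-scale conditions:

* eight populations at cohort sizes typical of an *Ovis* resequencing
  panel (18, 16, 3, 7, 8, 8, 6, 6 diploids) on one 270-Mb contig;
* SNP density 2.5 per kb, the density of a quality-filtered
  whole-genome SNP set for such a panel (~6.6M SNPs over a ~2.6-Gb
  genome);
* drift coefficients at species scale: F = 0.6 for the three
  Pachyceriform-like species (the donor lineage split ~2.3 Mya from the
  recipient, so between-species differentiation, not conspecific
  population structure, is the realistic regime; pairwise Hudson FST to
  the Moufloniform-like populations comes out near 0.35–0.45), 0.3 for
  the argali-like species, 0.25 for the island-bottlenecked European
  mouflon analogue, 0.2 for the bottlenecked domestic cohort (reduced
  diversity relative to its wild progenitor at F = 0.08), 0.15 urial;
* one donor event: 20 tracts, exponential mean 500 kb (~3.7% of the
  genome in expectation), per-haplotype replacement probability 0.5;
* ten 100-kb sweep windows in the domestic cohort at a 10-fold
  diversity reduction.

The null-calibration configuration is four populations of 10 diploids
at F = 0.1 with 50,000 SNPs on a 50-Mb contig and no events.

## What the simulator does not emulate

Sites are independent given the population frequencies: there is no
within-population linkage beyond what drift induces, no recombination
map, no mutation-rate variation, and the species tree is a star (every
population drifts independently from one ancestor) rather than the true
nested phylogeny. There is no missingness, no genotyping error and no
reference bias. Passing the planted-signal tests therefore demonstrates
that the statistics and their calibration behave correctly on data
satisfying their own assumptions — it does not demonstrate robustness
to LD-induced pseudo-replication between nearby windows on real data
(the block jackknife addresses this for genome-wide D, the window-level
FDR does not), nor to sister-population shared drift, which in real
quartets absorbs part of the ABBA/BABA symmetry.

# Numerical choices and problem sizes

Window sums use cumulative-sum lookups per contig, so the sliding scan
is linear in sites plus windows. The jackknife follows the weighted
delete-one formulation with block size 1 Mb; blocks are genomic, so
unequal usable-site counts are expected and handled by the weights. The
suite's end-to-end checks run the demonstration cohort (675,000 sites,
74 samples, 13,496 windows) and twenty null cohorts, sizes chosen to
keep the full validation deterministic and desk-scale while leaving
every window with a realistic (~250 pre-filter) site count. Seeds fix
every random draw; identical configuration and seed reproduce output
files byte for byte.

# Known limitations

* $f_d$ can in principle exceed 1 in windows where P1's derived
  frequency exceeds the donor pair's (the per-site difference between
  numerator and denominator is $(p_2-p_3)(p_1-p_2)$); such windows are
  reported as computed rather than clamped, and did not arise in the
  validation cohorts.
* The fd scan's per-window p-values inherit the normality of the
  standardized fd distribution; heavy-tailed nulls (e.g. from strong
  LD) would need the robust or two-pass modes plus block-aware
  resampling, which the package does not implement at window scale.
* Cohort-pooled $\pi$ treats the cohort as one population; deep
  substructure inside a cohort inflates it (Wahlund), which is the
  intended reading of a multi-breed "domestic" cohort but should be
  kept in mind for other groupings.
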