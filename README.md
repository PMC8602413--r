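# introscan

Population-genomic scans for interspecific introgression and
domestication selection in multi-population biallelic-SNP cohorts, built
for the *Ovis* (sheep) setting: several wild species, a bottlenecked
domestic cohort, and a diverged outgroup (goat) for allele polarization.
Everything runs on plain diploid genotype tables (VCF in, TSV/BED out)
and is validated end to end against a seeded simulator that plants known
introgression tracts and selective sweeps.

## What it computes

* **Site filtering & polarization** — missingness ≤ 0.1, pooled MAF ≥
  0.05, one-sided exact heterozygote-excess test (mid-p) at 0.001;
  derived-allele frequencies polarized against the allele fixed in the
  outgroup.
* **Windowed diversity** — nucleotide diversity
  π = Σ [n/(n−1)]·2p̂(1−p̂)/L, absolute divergence
  d<sub>xy</sub> = Σ [p̂<sub>A</sub>(1−p̂<sub>B</sub>) + p̂<sub>B</sub>(1−p̂<sub>A</sub>)]/L,
  Hudson F<sub>ST</sub> as a ratio of averages, and a genotype-r²
  LD-decay curve, on a 100-kb/20-kb sliding grid.
* **Gene flow** — Patterson's D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA) with
  weighted 1-Mb block jackknife (|Z| > 3 rule), the f3 three-population
  test, and Martin et al.'s windowed f<sub>d</sub> admixture-fraction
  scan with Benjamini–Hochberg FDR control; significant windows merge
  into introgressed tracts.
* **Selection** — overlap of the top-decile π<sub>wild</sub>/π<sub>dom</sub>
  ratio and top-decile F<sub>ST</sub> windows, merged into candidate
  regions and intersected with gene annotations (Fisher-exact overlap
  enrichment).
* **ILS null** — expected shared ancestral tract length L = 1/(r·t) and
  the Erlang-2 survival e^(−m/L)(1 + m/L) for an observed tract of
  length m, plus generation↔year dating arithmetic.
* **qPCR CNV calls** — ΔΔC<sub>T</sub> relative copy number
  2×2^(−ΔΔC<sub>T</sub>) with replicate-SD propagation
  s = √(s₁² + s₂²) and the 1.5/3 deletion/duplication thresholds.
* **Simulator** — Balding–Nichols drifted populations, planted
  donor→recipient tracts, planted sweeps, truth BEDs, bit-reproducible
  under a single seed.

See `vignettes/introgression-selection-methods.Rmd` for the models,
parameter defaults and their rationale.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
simulated demonstration cohort (eight populations, 270 Mb, 675,000
SNPs, 20 planted tracts at per-haplotype replacement probability 0.5,
ten planted sweeps). For example:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/03_gene_flow.R
Rscript analysis/04_introgression_scan.R
```

`03_gene_flow.R` prints the donor screen — only the quartet containing
the true donor is significant:

```
P1   P2    P3    O     D        se        Z     significant
DOM  AMUF  SNWS  goat  0.00980  0.002854  3.43  TRUE
DOM  AMUF  THNH  goat  0.00125  0.001225  1.02  FALSE
DOM  AMUF  BIGH  goat  0.00106  0.001212  0.88  FALSE
DOM  AMUF  ARG   goat  0.00153  0.001071  1.43  FALSE
DOM  AMUF  URI   goat  0.00145  0.001090  1.33  FALSE
```

and `04_introgression_scan.R` reports the fd tract calls against the
planted truth:

```
n_tracts  called_mb  truth_mb  genome_fraction  bp_recall  bp_precision  genomewide_D  D_Z
17        8.38       8.009     0.03104          0.981      0.937         0.0098        3.43
```

i.e. 17 called tracts covering 8.38 Mb recover 98.1% of the planted
introgressed sequence at 93.7% base-pair precision, and the genome-wide
D test on the admixed quartet is significant (Z = 3.43) even though
only ~3% of the genome is introgressed. `06_ils_dating.R` evaluates the
ILS null at the published parameters (L = 115.94 bp and 155.04 bp for
the 2.3-My and 1.72-My comparisons; survival probability 0 and ~1.5e-272
at the observed 96,410-bp and 98,037-bp tracts — such tracts cannot be
retained ancestral variation) and the dating conversion (2493
generations × 4 y = 9,972 years BP; 3481 × 4 = 13,924 years BP).
`07_qpcr_cnv.R` calls the bundled synthetic qPCR table:

```
assay_id    ddct    s      copy_number  call
cnv_del_b   2.000   0.016  0.500        deletion
cnv_dup_a   -1.977  0.082  7.872        duplication
cnv_norm_c  0.007   0.063  1.991        normal
```

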