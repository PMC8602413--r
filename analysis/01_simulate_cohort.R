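#!/usr/bin/env Rscript
# Build the demonstration cohort: eight drift-differentiated Ovis-like
# populations plus a fixed outgroup on a 270-Mb contig, with 20 planted
# snow-sheep-like introgression tracts into the Asiatic-mouflon-like
# recipient (per-haplotype replacement probability 0.5) and ten 100-kb
# selective sweeps in the domestic cohort. Truth files and the population
# map are written under results/sim/; the (large) cohort VCF goes to
# scratch/.

library(introscan)

seed <- 42
cfg <- demo_config(seed)
cohort <- simulate_cohort(cfg)
print(cohort)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
write_bed(cohort$truth$tracts, "results/sim/truth_tracts.bed",
          score = "realized_alpha")
write_bed(cohort$truth$sweeps, "results/sim/truth_sweeps.bed",
          score = "factor")
writeLines(c("sample\tpopulation",
             paste(names(cohort$popmap$assignments),
                   cohort$popmap$assignments, sep = "\t")),
           "results/sim/popmap.tsv")

dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
write_vcf(cohort$gt, "scratch/sim/cohort.vcf.gz")

tr <- cohort$truth$tracts
cat(sprintf("planted %d tracts totalling %.2f Mb (%.2f%% of the genome)\n",
            nrow(tr), sum(tr$end - tr$start) / 1e6,
            100 * sum(tr$end - tr$start) / sum(cfg$contigs)))
cat(sprintf("mean realized donor-haplotype fraction inside tracts: %.3f\n",
            mean(tr$realized_alpha)))
cat("wrote results/sim/{truth_tracts.bed,truth_sweeps.bed,popmap.tsv}",
    "and scratch/sim/cohort.vcf.gz\n")
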