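# Small in-code fixtures shared across the suite.

# genotype table from a sites x samples matrix of 0/1/2/NA codes
toy_gt <- function(geno, chrom = NULL, pos = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(geno)))
  genotype_table(chrom, pos, rep("A", ns), rep("G", ns), geno, samples)
}

# population map assigning consecutive sample blocks to labelled pops
toy_pm <- function(samples, sizes, labels, outgroup = NULL) {
  population_map(stats::setNames(rep(labels, sizes), samples), outgroup)
}

# random genotype table: n_pop populations of n_dip diploids, plus a fixed
# outgroup sample; frequencies drifted independently per population
random_cohort <- function(n_sites = 200, n_pops = 3, n_dip = 5, seed = 1,
                          og_alt_frac = 0.3) {
  set.seed(seed)
  p_anc <- stats::rbeta(n_sites, 1, 1)
  labels <- paste0("pop", seq_len(n_pops))
  geno <- NULL
  for (k in seq_len(n_pops)) {
    pk <- stats::rbeta(n_sites, p_anc * 9, (1 - p_anc) * 9)
    geno <- cbind(geno, matrix(stats::rbinom(n_sites * n_dip, 2, pk),
                               nrow = n_sites))
  }
  og <- 2L * stats::rbinom(n_sites, 1, og_alt_frac)
  geno <- cbind(geno, og)
  samples <- c(paste0("s", seq_len(n_pops * n_dip)), "og1")
  gt <- toy_gt(geno, pos = sort(sample.int(1000000L, n_sites)),
               samples = samples)
  pm <- toy_pm(samples, c(rep(n_dip, n_pops), 1), c(labels, "OG"),
               outgroup = "OG")
  list(gt = gt, pm = pm, labels = labels)
}

# write a small VCF text file and return its path
write_toy_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("toy", fileext = ".vcf")
  writeLines(lines, path)
  path
}
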