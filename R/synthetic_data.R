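#' Simulation configuration
#'
#' Describes a seeded multi-population diploid genotype cohort with known
#' drift structure, optional donor-to-recipient introgression tracts and
#' planted selective sweeps. Population allele frequencies follow the
#' Balding-Nichols model: an ancestral frequency p is drawn per site from
#' a symmetric Beta, and each population's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with its own drift coefficient F (F = 0
#' means no drift: the population sits at the ancestral frequency).
#' Diploid genotypes are then binomial draws. The outgroup is emitted as a
#' pseudo-population fixed at every site, carrying the alternate allele at
#' a fraction `d_out` of sites (so polarization is non-trivial).
#'
#' @param seed integer seed; it fully determines the cohort.
#' @param contigs named numeric vector of contig lengths (bp).
#' @param site_density expected SNPs per bp.
#' @param populations data.frame with columns `label`, `n` (diploids) and
#'   `F` (drift coefficient in \[0, 1)).
#' @param outgroup list with `label`, `n` (diploids) and `d_out` (fraction
#'   of sites where the outgroup carries the alternate allele).
#' @param beta_shape shape of the symmetric Beta for ancestral
#'   frequencies (values below 1 give the U-shaped spectrum typical of
#'   drifted standing variation).
#' @param introgression list of events, each a list with `donor`,
#'   `recipient`, `alpha` (per-haplotype replacement probability),
#'   `n_tracts` and `mean_length` (bp, exponential).
#' @param sweeps list of events, each a list with `populations` (cohort
#'   swept), `windows` (data.frame `chrom`, `start`, `end`) and `factor`
#'   (> 1, diversity reduction).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, contigs, site_density = 2.5e-3,
                       populations, outgroup = list(label = "goat", n = 2,
                                                    d_out = 0.25),
                       beta_shape = 0.8, introgression = list(),
                       sweeps = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            !is.null(names(contigs)), all(contigs > 0),
            site_density > 0, site_density <= 0.1,
            all(c("label", "n", "F") %in% names(populations)),
            all(populations$F >= 0), all(populations$F < 1),
            all(populations$n >= 1),
            outgroup$d_out >= 0, outgroup$d_out <= 1)
  for (ev in introgression) {
    stopifnot(all(c(ev$donor, ev$recipient) %in% populations$label),
              ev$alpha >= 0, ev$alpha <= 1,
              ev$n_tracts >= 1, ev$mean_length > 0)
    if (ev$n_tracts * ev$mean_length > 0.5 * sum(contigs)) {
      stop("requested tract mass exceeds half the genome; reduce n_tracts or mean_length")
    }
  }
  for (ev in sweeps) {
    stopifnot(all(ev$populations %in% populations$label), ev$factor > 1,
              all(ev$windows$chrom %in% names(contigs)),
              all(ev$windows$end <= contigs[ev$windows$chrom]))
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 site_density = site_density, populations = populations,
                 outgroup = outgroup, beta_shape = beta_shape,
                 introgression = introgression, sweeps = sweeps),
            class = "sim_config")
}

#' Simulate a genotype cohort with planted ground truth
#'
#' Draws the base cohort under the Balding-Nichols model, then applies
#' the configured introgression events ([plant_introgression()]) and
#' sweeps ([plant_sweep()]), in that order, from a single seeded RNG
#' stream. Because planting consumes RNG draws only after the base cohort
#' is complete, populations untouched by an event are bit-identical to a
#' run of the same seed without it.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: list with `gt` (a
#'   [genotype_table()] including the outgroup samples), `popmap` (a
#'   [population_map()] with the outgroup set), `freqs` (true
#'   per-population allele-frequency matrix, sites x populations),
#'   `truth` (list `tracts`, `sweeps`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cohort <- simulate_base_cohort(config)
  for (ev in config$introgression) cohort <- plant_introgression(cohort, ev)
  for (ev in config$sweeps) cohort <- plant_sweep(cohort, ev)
  cohort
}

simulate_base_cohort <- function(config) {
  pops <- config$populations
  chroms <- character(0); pos <- integer(0)
  for (ch in names(config$contigs)) {
    len <- config$contigs[[ch]]
    ns <- round(len * config$site_density)
    p_ch <- sort(sample.int(len, ns))
    chroms <- c(chroms, rep(ch, ns)); pos <- c(pos, p_ch)
  }
  ns <- length(pos)
  a <- config$beta_shape
  p_anc <- stats::rbeta(ns, a, a)
  # clamp away from exact fixation so every population can segregate
  p_anc <- pmin(pmax(p_anc, 1e-4), 1 - 1e-4)
  labels <- pops$label
  freqs <- matrix(NA_real_, ns, length(labels),
                  dimnames = list(NULL, labels))
  geno <- NULL
  samples <- character(0)
  popmap_vec <- character(0)
  for (i in seq_len(nrow(pops))) {
    F <- pops$F[i]
    pk <- if (F == 0) p_anc else {
      stats::rbeta(ns, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
    freqs[, labels[i]] <- pk
    g <- matrix(stats::rbinom(ns * pops$n[i], 2, pk), nrow = ns)
    ids <- sprintf("%s_%02d", labels[i], seq_len(pops$n[i]))
    geno <- cbind(geno, g)
    samples <- c(samples, ids)
    popmap_vec <- c(popmap_vec, rep(labels[i], pops$n[i]))
  }
  og <- config$outgroup
  og_state <- stats::rbinom(ns, 1, og$d_out)   # 1: outgroup fixed for alt
  g_og <- matrix(rep(2L * og_state, og$n), nrow = ns)
  ids_og <- sprintf("%s_%02d", og$label, seq_len(og$n))
  geno <- cbind(geno, g_og)
  samples <- c(samples, ids_og)
  popmap_vec <- c(popmap_vec, rep(og$label, og$n))
  gt <- genotype_table(chroms, pos, ref = rep("A", ns), alt = rep("G", ns),
                       geno = geno, samples = samples)
  pm <- population_map(stats::setNames(popmap_vec, samples),
                       outgroup = og$label)
  structure(list(gt = gt, popmap = pm, freqs = freqs,
                 truth = list(tracts = empty_tracts(),
                              sweeps = empty_sweeps()),
                 config = config),
            class = "sim_cohort")
}

empty_tracts <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             donor = character(), recipient = character(),
             realized_alpha = numeric())
}
empty_sweeps <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             factor = numeric())
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$gt$pos), "sites,",
      length(x$gt$samples), "samples,",
      nrow(x$truth$tracts), "planted tract(s),",
      nrow(x$truth$sweeps), "planted sweep window(s)\n")
  invisible(x)
}

#' Plant donor-to-recipient introgression tracts
#'
#' Draws `n_tracts` non-overlapping tracts (exponential lengths with mean
#' `mean_length`, truncated at contig ends; starts uniform, overlaps
#' rejected) and, inside each tract, independently replaces each
#' recipient haplotype by a draw from the donor population's drifted
#' allele frequency with probability `alpha`. The number of replaced
#' haplotypes per sample is drawn once per tract, so ancestry is
#' contiguous along a planted tract as it would be for a real
#' introgressed haplotype. Genotypes outside tracts are untouched.
#'
#' @param cohort a `sim_cohort`.
#' @param event list with `donor`, `recipient`, `alpha`, `n_tracts`,
#'   `mean_length`.
#' @return the modified cohort; planted tracts (with realized
#'   per-tract donor-haplotype fraction) appended to `truth$tracts`.
#' @export
plant_introgression <- function(cohort, event) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  tracts <- draw_tracts(cfg$contigs, event$n_tracts, event$mean_length)
  rec_samples <- which(cohort$gt$samples %in%
                         pop_samples(cohort$popmap, event$recipient))
  p_don_all <- cohort$freqs[, event$donor]
  p_rec_all <- cohort$freqs[, event$recipient]
  tracts$donor <- event$donor
  tracts$recipient <- event$recipient
  tracts$realized_alpha <- NA_real_
  for (k in seq_len(nrow(tracts))) {
    sel <- which(cohort$gt$chrom == tracts$chrom[k] &
                   cohort$gt$pos - 1L >= tracts$start[k] &
                   cohort$gt$pos - 1L < tracts$end[k])
    z <- stats::rbinom(length(rec_samples), 2, event$alpha)
    tracts$realized_alpha[k] <- mean(z) / 2
    if (length(sel) == 0) next
    for (j in seq_along(rec_samples)) {
      zj <- z[j]
      g <- stats::rbinom(length(sel), zj, p_don_all[sel]) +
        stats::rbinom(length(sel), 2L - zj, p_rec_all[sel])
      cohort$gt$geno[sel, rec_samples[j]] <- as.integer(g)
    }
  }
  cohort$truth$tracts <- rbind(cohort$truth$tracts, tracts)
  cohort
}

# non-overlapping exponential-length tracts by rejection sampling
draw_tracts <- function(contigs, n_tracts, mean_length, max_try = 10000) {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  tries <- 0
  while (nrow(out) < n_tracts) {
    tries <- tries + 1
    if (tries > max_try) stop("could not place non-overlapping tracts")
    ch <- sample(names(contigs), 1, prob = contigs / sum(contigs))
    len <- max(1, round(stats::rexp(1, 1 / mean_length)))
    start <- floor(stats::runif(1, 0, contigs[[ch]]))
    end <- min(start + len, contigs[[ch]])
    clash <- out$chrom == ch & out$start < end & out$end > start
    if (any(clash)) next
    out <- rbind(out, data.frame(chrom = ch, start = start, end = end))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plant selective sweeps
#'
#' Within each sweep window, the pooled allele frequency of the swept
#' cohort is pushed toward the nearest fixation boundary so that the
#' expected heterozygosity 2p(1-p) drops by `factor`, the cohort's
#' populations are set to that common swept frequency (a sweep also
#' homogenizes the cohort), and the cohort's genotypes in the window are
#' redrawn. Other populations and all sites outside the windows are
#' untouched.
#'
#' @param cohort a `sim_cohort`.
#' @param event list with `populations`, `windows` (data.frame `chrom`,
#'   `start`, `end`, 0-based half-open) and `factor` (> 1).
#' @return the modified cohort; windows appended to `truth$sweeps`.
#' @export
plant_sweep <- function(cohort, event) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(event$factor) || event$factor <= 1) {
    stop("sweep diversity-reduction factor must exceed 1")
  }
  pops <- event$populations
  samp_idx <- which(cohort$gt$samples %in%
                      pop_samples(cohort$popmap, pops))
  n_dip <- vapply(pops, function(p)
    length(pop_samples(cohort$popmap, p)), 1L)
  for (k in seq_len(nrow(event$windows))) {
    w <- event$windows[k, ]
    sel <- which(cohort$gt$chrom == w$chrom &
                   cohort$gt$pos - 1L >= w$start &
                   cohort$gt$pos - 1L < w$end)
    if (length(sel) == 0) next
    pmat <- cohort$freqs[sel, pops, drop = FALSE]
    p_pool <- as.vector(pmat %*% (2 * n_dip)) / sum(2 * n_dip)
    h <- 2 * p_pool * (1 - p_pool)
    h_new <- h / event$factor
    lo <- (1 - sqrt(pmax(0, 1 - 2 * h_new))) / 2
    p_new <- ifelse(p_pool <= 0.5, lo, 1 - lo)
    cohort$freqs[sel, pops] <- p_new
    g <- matrix(stats::rbinom(length(sel) * length(samp_idx), 2, p_new),
                nrow = length(sel))
    cohort$gt$geno[sel, samp_idx] <- as.integer(g)
  }
  sw <- event$windows[, c("chrom", "start", "end")]
  sw$factor <- event$factor
  cohort$truth$sweeps <- rbind(cohort$truth$sweeps, sw)
  cohort
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort VCF, the population map TSV and the planted-truth BED
#' files (`truth_tracts.bed`, `truth_sweeps.bed`).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @param gzip write the VCF gzip-compressed?
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, if (gzip) "cohort.vcf.gz" else "cohort.vcf")
  write_vcf(cohort$gt, vcf)
  pop <- file.path(dir, "popmap.tsv")
  writeLines(c("sample\tpopulation",
               paste(names(cohort$popmap$assignments),
                     cohort$popmap$assignments, sep = "\t")), pop)
  tb <- file.path(dir, "truth_tracts.bed")
  write_bed(cohort$truth$tracts, tb, score = "realized_alpha")
  sb <- file.path(dir, "truth_sweeps.bed")
  write_bed(cohort$truth$sweeps, sb, score = "factor")
  invisible(c(vcf = vcf, popmap = pop, tracts = tb, sweeps = sb))
}

#' Study-scale demonstration configuration
#'
#' The default end-to-end demonstration cohort: eight populations at
#' cohort sizes typical of an *Ovis* resequencing panel (3-18 diploids
#' per species) on one 270-Mb contig at 2.5 SNPs/kb, a
#' snow-sheep-like donor event into the Asiatic-mouflon-like recipient
#' (20 non-overlapping tracts of mean 500 kb at per-haplotype replacement
#' probability 0.5, about 3.7% of the genome), and ten 100-kb sweep
#' windows in the domestic cohort at a 10-fold diversity reduction.
#' Drift coefficients give the domestic cohort reduced diversity relative
#' to the wild recipient and strong divergence of the snow-sheep-like
#' lineage.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed) {
  contigs <- c(chr1 = 270e6)
  populations <- data.frame(
    label = c("DOM", "AMUF", "EMUF", "URI", "ARG", "SNWS", "THNH", "BIGH"),
    n = c(18L, 16L, 3L, 7L, 8L, 8L, 6L, 6L),
    F = c(0.20, 0.08, 0.25, 0.15, 0.30, 0.60, 0.60, 0.60))
  sweep_windows <- data.frame(chrom = "chr1",
                              start = seq(10e6, by = 27e6, length.out = 10),
                              end = seq(10e6, by = 27e6, length.out = 10) + 1e5)
  sim_config(
    seed = seed, contigs = contigs, site_density = 2.5e-3,
    populations = populations,
    introgression = list(list(donor = "SNWS", recipient = "AMUF",
                              alpha = 0.5, n_tracts = 20L,
                              mean_length = 5e5)),
    sweeps = list(list(populations = "DOM", windows = sweep_windows,
                       factor = 10)))
}

#' No-gene-flow null configuration
#'
#' Four populations of 10 diploids, 50,000 SNPs on a 50-Mb contig, no
#' introgression and no sweeps: the null cohort used to calibrate the
#' false-positive behaviour of the D statistic and the fd scan.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
null_config <- function(seed) {
  contigs <- c(chr1 = 50e6)
  populations <- data.frame(label = c("P1", "P2", "P3", "P4"),
                            n = rep(10L, 4), F = rep(0.1, 4))
  sim_config(seed = seed, contigs = contigs, site_density = 1e-3,
             populations = populations)
}
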