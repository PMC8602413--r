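#' Windowed nucleotide diversity
#'
#' Per-window nucleotide diversity for one population:
#' \deqn{\pi = \sum_{sites} \frac{n}{n-1} \, 2\hat p (1-\hat p) \; / \; L}
#' where \eqn{\hat p} is the allele frequency among the \eqn{n} called
#' haploid alleles at the site and \eqn{L} the accessible window length in
#' bp (the window length by default, assuming sites absent from the table
#' are invariant). The \eqn{n/(n-1)} factor makes the per-site term equal
#' the mean pairwise difference over all haplotype pairs. A window with no
#' site carrying at least 2 called alleles reports `pi = NA` (undefined),
#' never 0.
#'
#' @param freqs a [pop_freqs()] table (polarization irrelevant: the
#'   statistic is symmetric in the allele labels).
#' @param grid a [make_windows()] grid.
#' @param population population label.
#' @return data.frame: `chrom`, `start`, `end`, `partial`, `pi`,
#'   `n_sites`, `n_accessible_bp`.
#' @export
window_pi <- function(freqs, grid, population) {
  stopifnot(population %in% freqs$populations)
  p <- freqs$p[, population]
  n <- freqs$n[, population]
  ok <- !is.na(p) & n >= 2
  v <- ifelse(ok, n / (n - 1) * 2 * p * (1 - p), NA_real_)
  ws <- window_sums(freqs$chrom, freqs$pos, grid,
                    cbind(pi_sum = ifelse(ok, v, 0), used = as.numeric(ok)))
  used <- ws$sums[, "used"]
  len <- grid$end - grid$start
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             partial = grid$partial,
             pi = ifelse(used > 0, ws$sums[, "pi_sum"] / len, NA_real_),
             n_sites = used, n_accessible_bp = len)
}

#' Windowed absolute divergence dxy
#'
#' Mean per-bp pairwise difference between haplotypes drawn from two
#' populations:
#' \deqn{d_{xy} = \sum_{sites} [\hat p_A (1-\hat p_B) + \hat p_B (1-\hat p_A)] / L.}
#' Unlike FST this is unaffected by within-population diversity, which is
#' what makes it useful for distinguishing introgression (reduced dxy to
#' the donor) from shared ancestral variation.
#'
#' @inheritParams window_pi
#' @param popA,popB population labels.
#' @return data.frame as [window_pi()] with column `dxy`.
#' @export
window_dxy <- function(freqs, grid, popA, popB) {
  stopifnot(popA %in% freqs$populations, popB %in% freqs$populations)
  pA <- freqs$p[, popA]; pB <- freqs$p[, popB]
  ok <- !is.na(pA) & !is.na(pB)
  v <- pA * (1 - pB) + pB * (1 - pA)
  ws <- window_sums(freqs$chrom, freqs$pos, grid,
                    cbind(d = ifelse(ok, v, 0), used = as.numeric(ok)))
  used <- ws$sums[, "used"]
  len <- grid$end - grid$start
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             partial = grid$partial,
             dxy = ifelse(used > 0, ws$sums[, "d"] / len, NA_real_),
             n_sites = used, n_accessible_bp = len)
}

#' Windowed Hudson FST
#'
#' Hudson's estimator computed as a ratio of averages over the sites of a
#' window (Bhatia et al.'s recommendation, robust to unequal and small
#' sample sizes):
#' \deqn{F_{ST} = \frac{\sum_s (\hat p_A-\hat p_B)^2 - \frac{\hat p_A(1-\hat p_A)}{n_A-1} - \frac{\hat p_B(1-\hat p_B)}{n_B-1}}{\sum_s \hat p_A(1-\hat p_B) + \hat p_B(1-\hat p_A)}.}
#' Sites require at least 2 called alleles in each population. Windows
#' whose denominator is zero (no between-population variation) report
#' `NA`. Small negative values are preserved, keeping genome-wide averages
#' unbiased.
#'
#' @inheritParams window_dxy
#' @return data.frame as [window_pi()] with column `fst`.
#' @export
window_fst <- function(freqs, grid, popA, popB) {
  stopifnot(popA %in% freqs$populations, popB %in% freqs$populations)
  comp <- fst_site_components(freqs$p[, popA], freqs$n[, popA],
                              freqs$p[, popB], freqs$n[, popB])
  ws <- window_sums(freqs$chrom, freqs$pos, grid,
                    cbind(num = comp$num, den = comp$den,
                          used = as.numeric(comp$ok)))
  den <- ws$sums[, "den"]
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             partial = grid$partial,
             fst = ifelse(den > 0, ws$sums[, "num"] / den, NA_real_),
             n_sites = ws$sums[, "used"],
             n_accessible_bp = grid$end - grid$start)
}

# Hudson per-site numerator/denominator; zeroed where unusable
fst_site_components <- function(pA, nA, pB, nB) {
  ok <- !is.na(pA) & !is.na(pB) & nA >= 2 & nB >= 2
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  num[!ok] <- 0; den[!ok] <- 0
  list(num = num, den = den, ok = ok)
}

#' Genome-wide Hudson FST
#'
#' Ratio-of-averages Hudson FST over all usable sites (no windowing).
#'
#' @inheritParams window_dxy
#' @return single numeric value (`NA` if no between-population variation).
#' @export
hudson_fst <- function(freqs, popA, popB) {
  comp <- fst_site_components(freqs$p[, popA], freqs$n[, popA],
                              freqs$p[, popB], freqs$n[, popB])
  den <- sum(comp$den)
  if (den <= 0) return(NA_real_)
  sum(comp$num) / den
}

#' LD decay curve from genotype correlations
#'
#' Squared Pearson correlation of diploid genotype codes (Rogers-Huff
#' style r^2, no phasing required) for all intra-contig site pairs within
#' `max_dist`, averaged in distance bins. Pairs with fewer than 3
#' complete observations or a monomorphic member are skipped.
#'
#' @param gt a [genotype_table()].
#' @param pm a [population_map()].
#' @param population population whose samples are used.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame: `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gt, pm, population, max_dist = 100000,
                     bin_width = 1000) {
  ss <- intersect(gt$samples, pop_samples(pm, population))
  if (length(ss) < 2) stop("need at least 2 samples for LD")
  nb <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(nb); n_pair <- integer(nb)
  for (ch in unique(gt$chrom)) {
    sel <- which(gt$chrom == ch)
    if (length(sel) < 2) next
    g <- gt$geno[sel, ss, drop = FALSE]
    pos <- gt$pos[sel]
    segregating <- apply(g, 1, function(x) {
      x <- x[!is.na(x)]; length(x) >= 3 && stats::var(x) > 0
    })
    for (i in seq_along(sel)) {
      if (!segregating[i]) next
      jmax <- findInterval(pos[i] + max_dist, pos)
      js <- seq_len(jmax)
      js <- js[js > i & segregating[js]]
      if (length(js) == 0) next
      for (j in js) {
        r <- suppressWarnings(stats::cor(g[i, ], g[j, ],
                                         use = "complete.obs"))
        if (is.na(r)) next
        b <- min(nb, floor((pos[j] - pos[i] - 1) / bin_width) + 1L)
        sum_r2[b] <- sum_r2[b] + r^2
        n_pair[b] <- n_pair[b] + 1L
      }
    }
  }
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             mean_r2 = ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_),
             n_pairs = n_pair)
}
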