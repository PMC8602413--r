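#' Per-site ABBA/BABA pattern components
#'
#' For a quartet (P1, P2, P3, O) of populations with derived-allele
#' frequencies \eqn{\hat p_1..\hat p_3} (the outgroup carries the
#' ancestral allele after polarization, so \eqn{\hat p_4 = 0}):
#' \deqn{ABBA = (1-\hat p_1)\,\hat p_2\,\hat p_3, \qquad
#'       BABA = \hat p_1\,(1-\hat p_2)\,\hat p_3.}
#' Also computes the donor-maximized components used by the fd
#' denominator, where both P2 and P3 are replaced at each site by
#' whichever of the two has the larger derived frequency
#' (\eqn{\hat p_D = \max(\hat p_2, \hat p_3)}). Sites unusable in any
#' taxon (unpolarizable outgroup or no called alleles) are dropped.
#'
#' @param freqs a polarized [pop_freqs()] table.
#' @param taxa character vector of 4 labels `(P1, P2, P3, outgroup)`; the
#'   outgroup label must be the one the table was polarized against (it is
#'   carried only for bookkeeping).
#' @return object of class `site_patterns`: data.frame with columns
#'   `chrom`, `pos`, `abba`, `baba`, `abba_d`, `baba_d`; `taxa` attached
#'   as an attribute.
#' @export
site_patterns <- function(freqs, taxa) {
  stopifnot(length(taxa) == 4)
  if (!freqs$polarized) stop("site_patterns requires polarized frequencies")
  ing <- taxa[1:3]
  stopifnot(all(ing %in% freqs$populations))
  p1 <- freqs$p[, ing[1]]; p2 <- freqs$p[, ing[2]]; p3 <- freqs$p[, ing[3]]
  ok <- freqs$usable & !is.na(p1) & !is.na(p2) & !is.na(p3)
  pd <- pmax(p2, p3)
  out <- data.frame(chrom = freqs$chrom[ok], pos = freqs$pos[ok],
                    abba = ((1 - p1) * p2 * p3)[ok],
                    baba = (p1 * (1 - p2) * p3)[ok],
                    abba_d = ((1 - p1) * pd * pd)[ok],
                    baba_d = (p1 * (1 - pd) * pd)[ok])
  structure(out, class = c("site_patterns", "data.frame"), taxa = taxa)
}

#' Genome-wide Patterson's D with weighted block jackknife
#'
#' \deqn{D = \frac{\sum ABBA - \sum BABA}{\sum ABBA + \sum BABA}}
#' over all usable sites. The standard error comes from a delete-one
#' weighted block jackknife over contiguous genomic blocks of `block_size`
#' bp, weighting each block by its usable-site count (blocks carry unequal
#' information); Z = D / SE. |Z| > 3 is the conventional significance rule
#' for an excess of one pattern, i.e. gene flow between P3 and P2 (D > 0)
#' or P1 (D < 0).
#'
#' @param sums a [site_patterns()] table.
#' @param block_size jackknife block length in bp.
#' @return list with `D`, `se`, `Z`, `n_blocks`, `n_sites`, `taxa`.
#'   With fewer than 2 non-empty blocks `se` and `Z` are `NA` and D is
#'   still returned.
#' @export
genome_wide_d <- function(sums, block_size = 1000000) {
  stopifnot(block_size > 0)
  num <- sums$abba - sums$baba
  den <- sums$abba + sums$baba
  block <- paste(sums$chrom, floor((sums$pos - 1) / block_size))
  jk <- block_jackknife_ratio(num, den, block)
  list(D = jk$est, se = jk$se, Z = jk$z, n_blocks = jk$n_blocks,
       n_sites = nrow(sums), taxa = attr(sums, "taxa"))
}

# Weighted delete-one block jackknife for a ratio statistic
# est = sum(num)/sum(den); block weights = per-block usable site counts
# (Busing et al. 1999 formulation, as used for genome-wide f-statistics).
block_jackknife_ratio <- function(num, den, block) {
  tnum <- tapply(num, block, sum)
  tden <- tapply(den, block, sum)
  cnt <- tapply(rep(1, length(block)), block, sum)
  keep <- cnt > 0
  tnum <- tnum[keep]; tden <- tden[keep]; cnt <- cnt[keep]
  g <- length(cnt)
  Tn <- sum(tnum); Td <- sum(tden)
  est <- if (Td > 0) Tn / Td else NA_real_
  if (g < 2 || is.na(est)) {
    return(list(est = est, se = NA_real_, z = NA_real_, n_blocks = g))
  }
  loo <- (Tn - tnum) / (Td - tden)
  loo[!is.finite(loo)] <- est
  n <- sum(cnt)
  h <- n / cnt
  theta_dot <- g * est - sum((1 - cnt / n) * loo)
  tau <- h * est - (h - 1) * loo
  var_jk <- mean((tau - theta_dot)^2 / (h - 1))
  se <- sqrt(var_jk)
  z <- if (se > 0) est / se else if (abs(est) < .Machine$double.eps) 0 else NA_real_
  list(est = est, se = se, z = z, n_blocks = g)
}

#' Three-population (f3) admixture test
#'
#' Patterson's f3 for a target C and two sources A, B with the
#' small-sample bias correction on the target:
#' \deqn{f_3 = \mathrm{mean}_s\left[(\hat p_C-\hat p_A)(\hat p_C-\hat p_B)
#'   - \frac{\hat p_C(1-\hat p_C)}{n_C-1}\right].}
#' A significantly negative value (block-jackknife Z < -3) indicates that
#' C is admixed between populations related to A and B. Sites need called
#' alleles in all three populations and nC >= 2.
#'
#' @param freqs a [pop_freqs()] table (polarization optional; f3 is
#'   invariant to allele labelling).
#' @param target,sourceA,sourceB population labels.
#' @param block_size jackknife block length in bp.
#' @return list with `f3`, `se`, `Z`, `n_blocks`, `n_sites`.
#' @export
f3_statistic <- function(freqs, target, sourceA, sourceB,
                         block_size = 1000000) {
  stopifnot(all(c(target, sourceA, sourceB) %in% freqs$populations))
  pC <- freqs$p[, target]; pA <- freqs$p[, sourceA]; pB <- freqs$p[, sourceB]
  nC <- freqs$n[, target]
  ok <- !is.na(pC) & !is.na(pA) & !is.na(pB) & nC >= 2
  if (!any(ok)) stop("no usable sites with >= 2 called target alleles")
  v <- ((pC - pA) * (pC - pB) - pC * (1 - pC) / (nC - 1))[ok]
  block <- paste(freqs$chrom[ok], floor((freqs$pos[ok] - 1) / block_size))
  jk <- block_jackknife_ratio(v, rep(1, length(v)), block)
  list(f3 = jk$est, se = jk$se, Z = jk$z, n_blocks = jk$n_blocks,
       n_sites = sum(ok))
}

#' Windowed fd introgression scan
#'
#' Martin et al.'s window-scale admixture-fraction statistic on the
#' sliding grid. Per window, with sums over its informative sites
#' (sites where ABBA + BABA > 0):
#' \deqn{D_w = \frac{\sum ABBA - \sum BABA}{\sum ABBA + \sum BABA}, \qquad
#'       f_d = \frac{\sum ABBA - \sum BABA}
#'                  {\sum ABBA_D - \sum BABA_D}}
#' where the denominator substitutes the per-site donor-maximized
#' frequency for both P2 and P3, bounding fd in \[0, 1\]. fd is undefined
#' (NA) when the window has fewer than `min_sites` informative sites, a
#' non-positive D, or a non-positive denominator. Defined fd values are
#' Z-transformed against their genome-wide location and scale, converted
#' to one-sided upper-tail normal p-values, and Benjamini-Hochberg
#' adjusted. `zmode = "mean_sd"` standardizes with the mean and standard
#' deviation of all defined windows; `zmode = "two_pass"` re-estimates
#' the null mean and sd after excluding the first pass's discoveries, so
#' that a non-negligible fraction of truly introgressed windows does not
#' inflate the null moments and mask moderate signal (on a pure null the
#' first pass discovers almost nothing and the two modes coincide);
#' `zmode = "robust"` uses the median and normal-consistent MAD.
#'
#' @param freqs a polarized [pop_freqs()] table.
#' @param grid a [make_windows()] grid.
#' @param taxa labels `(P1, P2, P3, outgroup)` as in [site_patterns()].
#' @param min_sites minimum informative sites for fd to be defined.
#' @param zmode standardization of fd: `"mean_sd"` or `"robust"`.
#' @return data.frame of class `fd_scan`: `chrom`, `start`, `end`,
#'   `partial`, `n_sites` (informative), `D`, `fd`, `Z`, `p`, `q`.
#' @export
window_fd_scan <- function(freqs, grid, taxa, min_sites = 10,
                           zmode = c("mean_sd", "two_pass", "robust")) {
  zmode <- match.arg(zmode)
  sp <- site_patterns(freqs, taxa)
  # pattern sums run over every usable site; the informative count
  # (sites contributing to ABBA or BABA) only gates low-information windows
  informative <- sp$abba + sp$baba > 0
  ws <- window_sums(sp$chrom, sp$pos, grid,
                    cbind(abba = sp$abba, baba = sp$baba,
                          abba_d = sp$abba_d, baba_d = sp$baba_d,
                          inf = as.numeric(informative)))
  ninf <- ws$sums[, "inf"]
  num <- ws$sums[, "abba"] - ws$sums[, "baba"]
  dden <- ws$sums[, "abba"] + ws$sums[, "baba"]
  fden <- ws$sums[, "abba_d"] - ws$sums[, "baba_d"]
  D <- ifelse(dden > 0, num / dden, NA_real_)
  fd <- ifelse(!is.na(D) & D > 0 & fden > 0 & ninf >= min_sites,
               num / fden, NA_real_)
  def <- !is.na(fd)
  Z <- rep(NA_real_, length(fd))
  p <- rep(NA_real_, length(fd))
  q <- rep(NA_real_, length(fd))
  standardize <- function(null_vals) {
    centre <- if (zmode == "robust") stats::median(null_vals) else mean(null_vals)
    scale <- if (zmode == "robust") stats::mad(null_vals) else stats::sd(null_vals)
    if (!isTRUE(scale > 0)) return(FALSE)
    Z[def] <<- (fd[def] - centre) / scale
    p[def] <<- stats::pnorm(Z[def], lower.tail = FALSE)
    q[def] <<- fdr_bh(p[def])$q
    TRUE
  }
  if (sum(def) >= 2) {
    ok <- standardize(fd[def])
    if (ok && zmode == "two_pass") {
      null_windows <- def & q >= 0.05
      if (sum(null_windows) >= 2) standardize(fd[null_windows])
    }
    if (!ok) warning("fd windows have zero spread; Z/p/q undefined")
  } else if (sum(def) > 0) {
    warning("too few defined fd windows to standardize")
  }
  out <- data.frame(chrom = grid$chrom, start = grid$start,
                    end = grid$end, partial = grid$partial,
                    n_sites = ninf, D = D, fd = fd, Z = Z, p = p, q = q)
  structure(out, class = c("fd_scan", "data.frame"), taxa = taxa)
}

#' Call introgressed tracts from an fd scan
#'
#' Selects windows with positive window D and BH-adjusted q below `alpha`
#' and merges overlapping or book-ended significant windows on a contig
#' into concatenated introgressed tracts (with a 100-kb/20-kb sliding
#' grid, consecutive significant windows physically overlap).
#'
#' A significant window localizes signal only to somewhere within its
#' span, so the raw union of overlapping significant windows
#' systematically overhangs the true signal edges by up to a window
#' length. `edge_trim` shaves that many bp off each end of every merged
#' tract (never below one window-step of remaining length); with a
#' sliding grid a natural choice is `(window_size - step) / 2`, the
#' expected one-sided overhang when windows overlapping the signal by at
#' least half trigger. The default (`0`) reports the plain union.
#'
#' @param records an [window_fd_scan()] result.
#' @param alpha FDR level.
#' @param edge_trim bp removed from each end of every merged tract.
#' @param min_windows minimum number of member windows for a merged run
#'   to be reported as a tract. The default (`1`) reports every run; `2`
#'   discards singleton significant windows, which on an overlapping
#'   sliding grid are predominantly false discoveries spent from the FDR
#'   budget, while true tracts recruit several overlapping windows.
#' @return data.frame of class `introgression_tracts`: `chrom`, `start`,
#'   `end`, `n_windows`, `mean_fd`, `max_fd`; attributes `total_bp` and,
#'   when the scan grid covered the genome, `genome_fraction`.
#' @export
call_introgressed_tracts <- function(records, alpha = 0.05,
                                     edge_trim = 0, min_windows = 1) {
  stopifnot(edge_trim >= 0, min_windows >= 1)
  sig <- !is.na(records$q) & records$q < alpha &
    !is.na(records$D) & records$D > 0
  recs <- records[sig, , drop = FALSE]
  if (nrow(recs) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_fd = numeric(), max_fd = numeric())
  } else {
    merged <- merge_intervals(recs[, c("chrom", "start", "end")])
    merged <- merged[merged$n_members >= min_windows, , drop = FALSE]
    if (edge_trim > 0) {
      wlen <- min(recs$end - recs$start)  # keep at least one window length
      for (i in seq_len(nrow(merged))) {
        len <- merged$end[i] - merged$start[i]
        tr <- min(edge_trim, max(0, (len - wlen) / 2))
        merged$start[i] <- merged$start[i] + tr
        merged$end[i] <- merged$end[i] - tr
      }
    }
    out <- merged
    names(out)[names(out) == "n_members"] <- "n_windows"
    out$mean_fd <- rep(NA_real_, nrow(out))
    out$max_fd <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      inside <- recs$chrom == out$chrom[i] &
        recs$start < out$end[i] & recs$end > out$start[i]
      out$mean_fd[i] <- mean(recs$fd[inside])
      out$max_fd[i] <- max(recs$fd[inside])
    }
  }
  genome_bp <- sum(tapply(records$end, records$chrom, max))
  structure(out, class = c("introgression_tracts", "data.frame"),
            total_bp = sum(out$end - out$start),
            genome_fraction = sum(out$end - out$start) / genome_bp)
}

#' Write tracts or regions as BED
#'
#' BED6 with the mean fd (or another score column) in column 5.
#'
#' @param tracts data.frame with `chrom`, `start`, `end` and optionally a
#'   score column.
#' @param path output path.
#' @param score name of the column written to the BED score field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tracts, path, score = NULL) {
  sc <- if (!is.null(score) && score %in% names(tracts)) {
    signif(tracts[[score]], 4)
  } else rep(".", nrow(tracts))
  lines <- paste(tracts$chrom, format(tracts$start, scientific = FALSE, trim = TRUE),
                 format(tracts$end, scientific = FALSE, trim = TRUE),
                 paste0("region_", seq_len(max(1, nrow(tracts)))[seq_len(nrow(tracts))]),
                 sc, "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
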