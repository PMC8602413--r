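#' Construct a genotype table
#'
#' The substrate of every statistic in the package: biallelic SNP sites by
#' samples, with diploid genotypes coded as the count of alternate alleles
#' (0, 1, 2) and `NA` for missing calls. Positions are stored 1-based as in
#' VCF; all window arithmetic converts to 0-based half-open internally.
#'
#' @param chrom character vector of contig names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each contig.
#' @param ref,alt single-nucleotide reference / alternate alleles.
#' @param geno integer matrix, sites x samples, values in 0:2 or `NA`.
#' @param samples character vector of unique sample identifiers (column
#'   names of `geno`).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(chrom, pos, ref, alt, geno, samples) {
  geno <- as.matrix(geno)
  stopifnot(length(chrom) == length(pos),
            length(ref) == length(pos),
            length(alt) == length(pos),
            nrow(geno) == length(pos),
            ncol(geno) == length(samples),
            !anyDuplicated(samples))
  ok <- is.na(geno) | (geno %in% 0:2)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within contig ", ch)
    }
  }
  storage.mode(geno) <- "integer"
  colnames(geno) <- samples
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, samples = as.character(samples)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$pos), "sites x", length(x$samples),
      "samples on", length(unique(x$chrom)), "contig(s)\n")
  invisible(x)
}

n_sites <- function(gt) length(gt$pos)

subset_sites <- function(gt, keep) {
  genotype_table(gt$chrom[keep], gt$pos[keep], gt$ref[keep], gt$alt[keep],
                 gt$geno[keep, , drop = FALSE], gt$samples)
}

#' Read a biallelic-SNP genotype table from VCF
#'
#' Parses a VCF (plain or gzipped) through \pkg{vcfR} and keeps only
#' biallelic SNP records; multiallelic and non-SNP records are dropped and
#' their count reported via a message. Only the GT field is used; any
#' ploidy separator (`/` or `|`) is accepted and half-missing calls are
#' treated as missing.
#'
#' @param path VCF file path.
#' @param samples optional character vector restricting (and ordering) the
#'   samples kept.
#' @return a [genotype_table()].
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  gt_raw <- gt_raw[is_snp, , drop = FALSE]
  all_samples <- colnames(gt_raw)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, all_samples)
    if (length(missing_s) > 0) {
      stop("requested sample(s) absent from VCF: ",
           paste(missing_s, collapse = ", "))
    }
    gt_raw <- gt_raw[, samples, drop = FALSE]
    all_samples <- samples
  }
  a1 <- substr(gt_raw, 1, 1)
  a2 <- substr(gt_raw, 3, 3)
  code <- function(a) ifelse(a %in% c("0", "1"), as.integer(a), NA_integer_)
  g <- matrix(code(a1) + code(a2), nrow = nrow(gt_raw),
              dimnames = dimnames(gt_raw))
  genotype_table(chrom = fix[is_snp, "CHROM"],
                 pos = as.integer(fix[is_snp, "POS"]),
                 ref = ref[is_snp], alt = alt[is_snp],
                 geno = g, samples = all_samples)
}

#' Write a genotype table as VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype columns through
#' \pkg{vcfR}. A `.gz` suffix produces a gzip-compressed file (the vcfR
#' writer always compresses; plain-text output is written directly).
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  n <- n_sites(gt)
  gchar <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], nrow = n)
  gchar[is.na(gt$geno)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gt$samples), collapse = "\t"))
  body <- paste(gt$chrom, gt$pos, ".", gt$ref, gt$alt, ".", "PASS", ".",
                "GT", apply(gchar, 1, paste, collapse = "\t"), sep = "\t")
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "w")
  } else {
    con <- file(path, "w")
  }
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated file with header `sample<TAB>population`. Every sample
#' must be assigned to exactly one population.
#'
#' @param path TSV file path.
#' @param outgroup optional population label to mark as the outgroup used
#'   for allele polarization.
#' @return object of class `population_map`: list with `assignments`
#'   (named character vector sample -> population) and `outgroup`.
#' @export
read_popmap <- function(path, outgroup = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(tab))) {
    stop("population map must have columns 'sample' and 'population'")
  }
  population_map(stats::setNames(tab$population, tab$sample), outgroup)
}

#' @rdname read_popmap
#' @param assignments named character vector, names are sample ids and
#'   values population labels.
#' @export
population_map <- function(assignments, outgroup = NULL) {
  if (anyDuplicated(names(assignments))) {
    stop("each sample may be assigned to exactly one population")
  }
  if (!is.null(outgroup) && !(outgroup %in% assignments)) {
    stop("outgroup label '", outgroup, "' not present among populations")
  }
  structure(list(assignments = assignments, outgroup = outgroup),
            class = "population_map")
}

pop_samples <- function(pm, populations) {
  names(pm$assignments)[pm$assignments %in% populations]
}

#' Site quality filters
#'
#' Removes sites failing any of the cohort-level SNP filters used ahead of
#' the diversity and introgression analyses: missing-genotype fraction
#' above `max_missing`, pooled minor-allele frequency below `min_maf`, or
#' one-sided exact-test evidence of heterozygote excess at
#' `p < het_excess_alpha` (mid-p conditional test; only an excess of
#' heterozygotes is penalized, a deficit never removes a site). MAF is
#' computed over all samples pooled after excluding missing calls.
#'
#' @param gt a [genotype_table()].
#' @param max_missing maximum tolerated fraction of missing genotypes.
#' @param min_maf minimum pooled minor-allele frequency.
#' @param het_excess_alpha significance level of the heterozygote-excess
#'   exact test.
#' @return filtered `genotype_table`; the number of sites removed by each
#'   criterion is attached as attribute `removed` (a named integer vector;
#'   a site failing several criteria is counted under each).
#' @export
filter_variants <- function(gt, max_missing = 0.1, min_maf = 0.05,
                            het_excess_alpha = 0.001) {
  stopifnot(n_sites(gt) > 0)
  g <- gt$geno
  n_ind <- ncol(g)
  n_miss <- rowSums(is.na(g))
  fail_miss <- n_miss / n_ind > max_missing

  n_called <- 2L * (n_ind - n_miss)
  alt_count <- rowSums(g, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_count / n_called, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  fail_maf <- is.na(maf) | maf < min_maf

  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  n_hom_ref <- (n_ind - n_miss) - n_het - n_hom_alt
  p_het <- hwe_het_excess_p(n_hom_ref, n_het, n_hom_alt)
  fail_hwe <- !is.na(p_het) & p_het < het_excess_alpha

  keep <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep)) warning("all sites removed by filters")
  out <- subset_sites(gt, keep)
  attr(out, "removed") <- c(missingness = sum(fail_miss),
                            maf = sum(fail_maf),
                            het_excess = sum(fail_hwe))
  out
}

#' Heterozygote-excess exact test
#'
#' Mid-p one-sided exact test for an excess of heterozygotes under
#' Hardy-Weinberg equilibrium, conditional on the observed allele counts
#' (Levene's distribution): p = P(het > observed) + P(het = observed)/2,
#' with the heterozygote count enumerated over its full conditional
#' support. Vectorized over sites.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts per site.
#' @return numeric vector of one-sided mid-p values (`NA` where no
#'   genotypes were called).
#' @export
hwe_het_excess_p <- function(n_hom_ref, n_het, n_hom_alt) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0L) return(NA_real_)
    nb <- ab + 2L * bb            # minor/alt allele count
    na_ <- 2L * n - nb
    rare <- min(na_, nb)
    if (rare == 0L) return(1)
    hets <- seq(rare %% 2L, rare, by = 2L)
    # log P(het = h | n, rare) up to a constant: Levene's conditional law
    lp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
      lgamma(n - (rare + hets) / 2 + 1) + hets * log(2)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    i <- match(ab, hets)
    sum(pr[hets > ab]) + pr[i] / 2
  }, n_hom_ref, n_het, n_hom_alt)
}

#' Per-population allele frequencies, optionally polarized by an outgroup
#'
#' Computes, for every site and population, the frequency of the chosen
#' allele among non-missing calls and the number of called haploid
#' alleles. Without an outgroup, frequencies count the VCF alternate
#' allele. With an outgroup, the ancestral allele is the allele fixed
#' among the outgroup's called genotypes and frequencies count the derived
#' allele; sites where the outgroup is polymorphic or entirely missing are
#' flagged unusable (they are excluded from D/fd, which require
#' polarization, but retain their raw frequencies).
#'
#' @param gt a [genotype_table()].
#' @param pm a [population_map()]; when polarizing, `pm$outgroup` names
#'   the outgroup population, which is excluded from the frequency
#'   columns.
#' @param polarize logical; polarize against `pm$outgroup`?
#' @return object of class `freq_table`: list with `chrom`, `pos`,
#'   `populations`, `p` (sites x populations frequency matrix), `n`
#'   (called haploid alleles), `usable` (logical), `ancestral`
#'   (`"ref"`/`"alt"`/`NA` per site) and `polarized`.
#' @export
pop_freqs <- function(gt, pm, polarize = FALSE) {
  pops <- setdiff(unique(pm$assignments), if (polarize) pm$outgroup)
  ns <- n_sites(gt)
  ancestral <- rep(NA_character_, ns)
  usable <- rep(TRUE, ns)
  if (polarize) {
    if (is.null(pm$outgroup)) stop("polarization requires an outgroup")
    og <- intersect(gt$samples, pop_samples(pm, pm$outgroup))
    if (length(og) == 0) stop("no outgroup samples present in genotype table")
    go <- gt$geno[, og, drop = FALSE]
    n_called <- rowSums(!is.na(go))
    alt_ct <- rowSums(go, na.rm = TRUE)
    fixed_ref <- n_called > 0 & alt_ct == 0L
    fixed_alt <- n_called > 0 & alt_ct == 2L * n_called
    ancestral[fixed_ref] <- "ref"
    ancestral[fixed_alt] <- "alt"
    usable <- fixed_ref | fixed_alt
  }
  p <- matrix(NA_real_, ns, length(pops), dimnames = list(NULL, pops))
  n <- matrix(0L, ns, length(pops), dimnames = list(NULL, pops))
  for (pop in pops) {
    ss <- intersect(gt$samples, pop_samples(pm, pop))
    if (length(ss) == 0) stop("population '", pop, "' has no samples")
    gp <- gt$geno[, ss, drop = FALSE]
    nc <- 2L * rowSums(!is.na(gp))
    ac <- rowSums(gp, na.rm = TRUE)
    pa <- ifelse(nc > 0, ac / nc, NA_real_)
    if (polarize) {
      pa <- ifelse(ancestral == "alt", 1 - pa, pa)
    }
    p[, pop] <- pa
    n[, pop] <- nc
  }
  structure(list(chrom = gt$chrom, pos = gt$pos, populations = pops,
                 p = p, n = n, usable = usable, ancestral = ancestral,
                 polarized = polarize),
            class = "freq_table")
}

#' @rdname pop_freqs
#' @details `polarize_by_outgroup(gt, pm)` is shorthand for
#'   `pop_freqs(gt, pm, polarize = TRUE)`.
#' @export
polarize_by_outgroup <- function(gt, pm) pop_freqs(gt, pm, polarize = TRUE)

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", length(x$pos), "sites x", length(x$populations),
      "populations;", if (x$polarized) "polarized" else "unpolarized",
      "\n")
  invisible(x)
}

# pooled frequency/count across a set of populations (weighted by calls)
pool_freqs <- function(freqs, populations) {
  stopifnot(all(populations %in% freqs$populations))
  pmat <- freqs$p[, populations, drop = FALSE]
  nmat <- freqs$n[, populations, drop = FALSE]
  cnt <- pmat * nmat
  cnt[nmat == 0L] <- 0
  n <- rowSums(nmat)
  p <- ifelse(n > 0, rowSums(cnt, na.rm = TRUE) / n, NA_real_)
  list(p = p, n = n)
}

#' Sliding window grid
#'
#' Builds the sliding-window grid used by every windowed statistic:
#' windows of `window_size` bp advanced by `step` bp, per contig, in
#' 0-based half-open coordinates. The final window on a contig may be
#' shorter than `window_size`; such windows are flagged `partial` and are
#' excluded from empirical-quantile computations downstream.
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param window_size window length in bp.
#' @param step offset between consecutive window starts in bp.
#' @return object of class `window_grid`: data.frame with columns
#'   `chrom`, `start`, `end`, `partial`; `window_size` and `step` attached
#'   as attributes.
#' @export
make_windows <- function(contig_lengths, window_size = 100000,
                         step = 20000) {
  if (window_size <= 0 || step <= 0) stop("window_size and step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  res <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    stopifnot(len > 0)
    # full windows: every start with start + window_size <= len
    starts <- seq(0, max(0, len - window_size), by = step)
    starts <- starts[starts + window_size <= len]
    if (length(starts) == 0) starts <- numeric(0)
    covered <- if (length(starts)) max(starts) + window_size else 0
    if (covered < len) {
      # one trailing partial window so the union covers [0, len)
      starts <- c(starts, if (length(starts)) max(starts) + step else 0)
    }
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = ends - starts < window_size)
  })
  grid <- do.call(rbind, res)
  rownames(grid) <- NULL
  structure(grid, class = c("window_grid", "data.frame"),
            window_size = window_size, step = step)
}

# Sums of per-site values over every window of a grid.
# chrom/pos: site coordinates (pos 1-based, sorted within contig);
# values: numeric matrix (sites x k) or vector. Returns list(sums = windows
# x k matrix, n = per-window site counts). Sites contribute to every
# window containing them (windows overlap when step < window_size).
window_sums <- function(chrom, pos, grid, values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  nw <- nrow(grid)
  sums <- matrix(0, nw, ncol(values), dimnames = list(NULL, colnames(values)))
  nsite <- integer(nw)
  for (ch in unique(grid$chrom)) {
    wsel <- which(grid$chrom == ch)
    ssel <- which(chrom == ch)
    if (length(ssel) == 0) next
    p0 <- pos[ssel] - 1L           # 0-based site coordinate
    v <- values[ssel, , drop = FALSE]
    v[is.na(v)] <- 0
    cs <- apply(v, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(values))
    lo <- findInterval(grid$start[wsel] - 1L, p0)   # sites with p0 < start
    hi <- findInterval(grid$end[wsel] - 1L, p0)     # sites with p0 < end
    take <- function(m, i) ifelse(i >= 1, m[pmax(i, 1)], 0)
    for (j in seq_len(ncol(values))) {
      sums[wsel, j] <- take(cs[, j], hi) - take(cs[, j], lo)
    }
    nsite[wsel] <- hi - lo
  }
  list(sums = sums, n = nsite)
}

# count non-NA sites per window for an indicator vector
window_counts <- function(chrom, pos, grid, indicator) {
  window_sums(chrom, pos, grid, as.numeric(indicator))$sums[, 1]
}
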