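#' Pi-ratio by FST selection scan
#'
#' Scans for candidate selection regions in a "domestic" cohort relative
#' to a "wild" cohort: per window, nucleotide diversity of each cohort
#' (samples pooled across the cohort's populations), the diversity ratio
#' pi_wild / pi_domestic, and Hudson FST between the pooled cohorts. A
#' window is selected when both its pi-ratio and its FST lie at or above
#' the empirical `quantile` (default top decile) of the defined,
#' non-partial windows — a rank-based double-outlier criterion, so any
#' monotone rescaling of either statistic leaves the selected set
#' unchanged. The realized thresholds are attached as attributes.
#'
#' @param freqs a [pop_freqs()] table containing every population of both
#'   cohorts.
#' @param grid a [make_windows()] grid.
#' @param wild,domestic character vectors of population labels pooled
#'   into each cohort.
#' @param quantile empirical quantile defining an outlier in each
#'   statistic.
#' @return data.frame of class `selection_scan`: window coordinates,
#'   `pi_wild`, `pi_domestic`, `pi_ratio`, `fst`, `ratio_outlier`,
#'   `fst_outlier`, `selected`; attributes `ratio_threshold`,
#'   `fst_threshold`.
#' @export
selection_scan <- function(freqs, grid, wild, domestic, quantile = 0.9) {
  stopifnot(length(wild) >= 1, length(domestic) >= 1,
            quantile >= 0, quantile <= 1)
  w <- pool_freqs(freqs, wild)
  d <- pool_freqs(freqs, domestic)
  pi_site <- function(p, n) {
    ok <- !is.na(p) & n >= 2
    ifelse(ok, n / (n - 1) * 2 * p * (1 - p), 0)
  }
  comp <- fst_site_components(w$p, w$n, d$p, d$n)
  ws <- window_sums(freqs$chrom, freqs$pos, grid,
                    cbind(pw = pi_site(w$p, w$n), pd = pi_site(d$p, d$n),
                          num = comp$num, den = comp$den,
                          used = as.numeric(comp$ok)))
  len <- grid$end - grid$start
  any_site <- ws$sums[, "used"] > 0
  pi_w <- ifelse(any_site, ws$sums[, "pw"] / len, NA_real_)
  pi_d <- ifelse(any_site, ws$sums[, "pd"] / len, NA_real_)
  ratio <- ifelse(!is.na(pi_w) & !is.na(pi_d) & pi_d > 0,
                  pi_w / pi_d, NA_real_)
  fst <- ifelse(ws$sums[, "den"] > 0,
                ws$sums[, "num"] / ws$sums[, "den"], NA_real_)
  defined <- !is.na(ratio) & !is.na(fst) & !grid$partial
  rt <- stats::quantile(ratio[defined], quantile, names = FALSE)
  ft <- stats::quantile(fst[defined], quantile, names = FALSE)
  ratio_out <- defined & ratio >= rt
  fst_out <- defined & fst >= ft
  out <- data.frame(chrom = grid$chrom, start = grid$start,
                    end = grid$end, partial = grid$partial,
                    pi_wild = pi_w, pi_domestic = pi_d, pi_ratio = ratio,
                    fst = fst, n_sites = ws$sums[, "used"],
                    ratio_outlier = ratio_out, fst_outlier = fst_out,
                    selected = ratio_out & fst_out)
  structure(out, class = c("selection_scan", "data.frame"),
            ratio_threshold = rt, fst_threshold = ft)
}

#' Merge selected windows into candidate selection regions
#'
#' Overlapping or book-ended selected windows are collapsed into disjoint
#' candidate regions; the member-window count is conserved (the region
#' counts sum to the number of selected windows).
#'
#' @param records a [selection_scan()] result.
#' @return data.frame of class `selection_regions`: `chrom`, `start`,
#'   `end`, `n_windows`.
#' @export
merge_selection_regions <- function(records) {
  sel <- records[records$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), n_windows = integer()),
                     class = c("selection_regions", "data.frame")))
  }
  m <- merge_intervals(sel[, c("chrom", "start", "end")])
  names(m)[names(m) == "n_members"] <- "n_windows"
  structure(m, class = c("selection_regions", "data.frame"))
}

#' Read a BED gene annotation
#'
#' BED4+ (0-based half-open; gene name in column 4), plain text,
#' optionally with `#`-prefixed header lines.
#'
#' @param path BED file path.
#' @return data.frame: `chrom`, `start`, `end`, `name`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 4) stop("gene BED needs at least 4 columns (name in col 4)")
  if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]])) {
    stop("malformed BED: columns 2-3 must be numeric")
  }
  stats::setNames(tab[, 1:4], c("chrom", "start", "end", "name"))
}

#' Attach overlapping genes to regions
#'
#' Intersects candidate regions with a gene annotation (both 0-based
#' half-open); a gene is attached when the intersection is non-empty. The
#' per-region gene lists are deduplicated.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes a [read_gene_bed()] annotation.
#' @return `regions` with an added `genes` column (comma-separated,
#'   `""` when none) and `n_genes`; the union of overlapped gene names is
#'   attached as attribute `gene_set`.
#' @export
annotate_regions <- function(regions, genes) {
  gl <- character(nrow(regions))
  ng <- integer(nrow(regions))
  all_genes <- character(0)
  for (i in seq_len(nrow(regions))) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    nm <- unique(genes$name[hit])
    gl[i] <- paste(nm, collapse = ",")
    ng[i] <- length(nm)
    all_genes <- c(all_genes, nm)
  }
  regions$genes <- gl
  regions$n_genes <- ng
  attr(regions, "gene_set") <- unique(all_genes)
  regions
}
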