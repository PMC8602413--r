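#' Merge possibly overlapping genomic intervals
#'
#' Collapses intervals that overlap or are book-ended (end of one equals
#' start of the next) into maximal disjoint runs, per contig. Coordinates
#' are 0-based half-open throughout the package.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_members`,
#'   sorted by contig then start; disjoint within each contig.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_members = integer()))
  }
  stopifnot(all(intervals$end >= intervals$start))
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  iv <- intervals[ord, , drop = FALSE]
  out <- vector("list", nrow(iv))
  k <- 0L
  cur <- NULL
  for (i in seq_len(nrow(iv))) {
    row <- iv[i, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end) {
      if (!is.null(cur)) { k <- k + 1L; out[[k]] <- cur }
      cur <- data.frame(chrom = row$chrom, start = row$start,
                        end = row$end, n_members = 1L)
    } else {
      cur$end <- max(cur$end, row$end)
      cur$n_members <- cur$n_members + 1L
    }
  }
  k <- k + 1L; out[[k]] <- cur
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

# total bp covered by the union of intervals (assumed pre-merged or not)
interval_union_bp <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

# bp of intersection between two interval sets
interval_intersect_bp <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  tot <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(ai))) {
      ov <- pmin(ai$end[i], bi$end) - pmax(ai$start[i], bi$start)
      tot <- tot + sum(ov[ov > 0])
    }
  }
  tot
}

#' Benjamini-Hochberg FDR adjustment with discovery flags
#'
#' Step-up false discovery rate control. Adjustment is delegated to
#' [stats::p.adjust()]; this wrapper validates inputs, preserves `NA`s and
#' attaches discovery flags at the chosen level.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed; ignored
#'   for the adjustment and returned as `NA`).
#' @param alpha discovery threshold applied to the adjusted values.
#' @return list with `q` (BH-adjusted p-values) and `discovery`
#'   (logical, `q < alpha`).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stopifnot(alpha > 0, alpha <= 1)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, discovery = !is.na(q) & q < alpha)
}

#' Two-list gene overlap enrichment
#'
#' Given the sizes of two gene lists drawn from a universe of `universe`
#' genes and their observed overlap, tests whether the overlap exceeds the
#' hypergeometric expectation (two-sided Fisher's exact test on the 2x2
#' membership table).
#'
#' @param overlap number of genes in both lists.
#' @param n1,n2 sizes of the two lists.
#' @param universe total number of genes eligible for either list.
#' @return list with `p_value`, `odds_ratio` and `expected` overlap.
#' @export
overlap_enrichment <- function(overlap, n1, n2, universe) {
  stopifnot(overlap >= 0, overlap <= min(n1, n2),
            n1 <= universe, n2 <= universe,
            n1 + n2 - overlap <= universe)
  tab <- matrix(c(overlap, n1 - overlap,
                  n2 - overlap, universe - n1 - n2 + overlap), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       expected = n1 * n2 / universe)
}
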