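#' End-to-end introgression scan
#'
#' Convenience wrapper chaining the pipeline on a genotype table: outgroup
#' polarization, the windowed fd scan, tract calling, and the genome-wide
#' D test on the same quartet. Its defaults are the analysis
#' configuration used throughout the package's own workflow: two-pass
#' empirical-null standardization, an edge trim of half the window/step
#' overhang, and a two-window minimum tract support (see
#' [window_fd_scan()] and [call_introgressed_tracts()] for the rationale;
#' the underlying operations default to the plain single-pass,
#' untrimmed behaviour).
#'
#' @param gt a filtered [genotype_table()].
#' @param pm a [population_map()] with the outgroup set.
#' @param taxa quartet `(P1, P2, P3, outgroup)`.
#' @param contig_lengths named vector of contig lengths in bp; defaults
#'   to the largest observed position per contig.
#' @param window_size,step sliding-window geometry in bp.
#' @param alpha FDR level for tract calling.
#' @param min_sites minimum informative sites per window.
#' @param zmode fd standardization mode.
#' @param edge_trim bp trimmed from each tract end; default
#'   `(window_size - step) / 2`.
#' @param min_windows minimum member windows per tract.
#' @param block_size jackknife block size for the D test.
#' @return list with `scan` (fd windows), `tracts`, `d` (genome-wide D)
#'   and `freqs` (the polarized frequency table, for reuse).
#' @export
introgression_scan <- function(gt, pm, taxa, contig_lengths = NULL,
                               window_size = 100000, step = 20000,
                               alpha = 0.05, min_sites = 10,
                               zmode = "two_pass", edge_trim = NULL,
                               min_windows = 2, block_size = 1000000) {
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(gt$pos, gt$chrom, max)
  }
  if (is.null(edge_trim)) edge_trim <- (window_size - step) / 2
  freqs <- polarize_by_outgroup(gt, pm)
  grid <- make_windows(contig_lengths, window_size, step)
  scan <- window_fd_scan(freqs, grid, taxa, min_sites = min_sites,
                         zmode = zmode)
  tracts <- call_introgressed_tracts(scan, alpha = alpha,
                                     edge_trim = edge_trim,
                                     min_windows = min_windows)
  d <- genome_wide_d(site_patterns(freqs, taxa), block_size = block_size)
  list(scan = scan, tracts = tracts, d = d, freqs = freqs)
}

#' Compare called tracts against a truth set
#'
#' Base-pair level recall and precision of called tracts against planted
#' truth intervals.
#'
#' @param called,truth data.frames with `chrom`, `start`, `end`.
#' @return list with `recall`, `precision`, `called_bp`, `truth_bp`,
#'   `overlap_bp`.
#' @export
tract_accuracy <- function(called, truth) {
  tp <- interval_intersect_bp(called, truth)
  called_bp <- interval_union_bp(called)
  truth_bp <- interval_union_bp(truth)
  list(recall = if (truth_bp > 0) tp / truth_bp else NA_real_,
       precision = if (called_bp > 0) tp / called_bp else NA_real_,
       called_bp = called_bp, truth_bp = truth_bp, overlap_bp = tp)
}
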