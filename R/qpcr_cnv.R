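#' Relative copy number by the delta-delta-CT method
#'
#' Relative quantification of a CNV segment against a single-copy
#' internal reference gene, comparing a target sample with a two-copy
#' control sample:
#' \deqn{\Delta\Delta C_T = (\bar C_{T,seg} - \bar C_{T,ref})_{target}
#'       - (\bar C_{T,seg} - \bar C_{T,ref})_{control},}
#' with the bars denoting replicate means. The relative diploid copy
#' number is \eqn{2 \times 2^{-\Delta\Delta C_T}}. The replicate standard
#' deviation propagates as \eqn{s = \sqrt{s_1^2 + s_2^2}} where s1 and s2
#' are the sample SDs (n-1 denominator) of the per-replicate delta-CT in
#' the target and control sample. Copy-number calls use the 1.5 / 3 rule:
#' values in the closed interval \[1.5, 3\] are called `normal` (two
#' copies), below 1.5 `deletion`, above 3 `duplication`.
#'
#' @param ct_segment_target,ct_reference_target numeric CT replicates for
#'   the CNV segment and the reference gene in the target sample.
#' @param ct_segment_control,ct_reference_control same for the two-copy
#'   control sample.
#' @return list with `ddct`, `s` (propagated SD; `NA` with single
#'   replicates), `copy_number` and `call`.
#' @export
delta_delta_ct <- function(ct_segment_target, ct_reference_target,
                           ct_segment_control, ct_reference_control) {
  wells <- list(ct_segment_target, ct_reference_target,
                ct_segment_control, ct_reference_control)
  if (any(vapply(wells, length, 1L) == 0)) {
    stop("every well needs at least one CT replicate")
  }
  if (!all(vapply(wells, function(x) all(is.finite(x)), TRUE))) {
    stop("CT values must be finite")
  }
  # delta-CT replicates: paired segment - reference differences when the
  # replicate counts match (the usual 3x3 plate layout), otherwise each
  # segment replicate against the reference mean
  dct <- function(seg, ref) {
    if (length(seg) == length(ref)) seg - ref else seg - mean(ref)
  }
  dct_target <- dct(ct_segment_target, ct_reference_target)
  dct_control <- dct(ct_segment_control, ct_reference_control)
  ddct <- mean(dct_target) - mean(dct_control)
  s1 <- stats::sd(dct_target)
  s2 <- stats::sd(dct_control)
  s <- sqrt(s1^2 + s2^2)
  cn <- 2 * 2^(-ddct)
  # closed interval [1.5, 3] is "normal"; small relative tolerance so
  # boundary values are not mis-called through floating-point noise
  eps <- 1e-9
  call <- if (cn < 1.5 * (1 - eps)) "deletion" else {
    if (cn > 3 * (1 + eps)) "duplication" else "normal"
  }
  list(ddct = ddct, s = s, copy_number = cn, call = call)
}

#' Batch qPCR copy-number calling from a replicate table
#'
#' Reads a TSV of CT replicates with columns `assay_id`, `well_role` (one
#' of `segment_target`, `reference_target`, `segment_control`,
#' `reference_control`) and `ct`, one row per replicate, and calls
#' [delta_delta_ct()] per assay.
#'
#' @param path TSV file path.
#' @return data.frame: `assay_id`, `ddct`, `s`, `copy_number`, `call`.
#' @export
qpcr_cnv_calls <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("assay_id", "well_role", "ct")
  if (!all(need %in% names(tab))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  roles <- c("segment_target", "reference_target",
             "segment_control", "reference_control")
  res <- lapply(split(tab, tab$assay_id), function(a) {
    ws <- lapply(roles, function(r) a$ct[a$well_role == r])
    if (any(vapply(ws, length, 1L) == 0)) {
      stop("assay ", a$assay_id[1], " is missing a well role")
    }
    dd <- delta_delta_ct(ws[[1]], ws[[2]], ws[[3]], ws[[4]])
    data.frame(assay_id = a$assay_id[1], ddct = dd$ddct, s = dd$s,
               copy_number = dd$copy_number, call = dd$call)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
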