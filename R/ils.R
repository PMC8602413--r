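#' Expected length of a shared ancestral tract
#'
#' Under neutral recombination, a haplotype tract inherited intact from
#' the common ancestor of two species that diverged t generations ago has
#' expected length
#' \deqn{L = \frac{1}{r\,t}, \qquad t = \frac{\text{divergence years}}{g},}
#' with r the recombination rate per bp per generation and g the
#' generation time in years. Long shared tracts are therefore diagnostic
#' of gene flow rather than incomplete lineage sorting. By default t is
#' the per-branch time in generations, matching the arithmetic used for
#' the published sheep comparisons; `two_branches = TRUE` doubles t to
#' count both descending branches (the usual convention elsewhere in the
#' literature), which halves L.
#'
#' @param r recombination rate per bp per generation.
#' @param divergence_years years since the species split.
#' @param g generation time in years.
#' @param two_branches double the branch length to count both lineages?
#' @return expected tract length L in bp.
#' @export
expected_tract_length <- function(r, divergence_years, g,
                                  two_branches = FALSE) {
  stopifnot(r > 0, divergence_years > 0, g > 0)
  t <- divergence_years / g
  if (two_branches) t <- 2 * t
  1 / (r * t)
}

#' Probability that a tract of length m arose by incomplete lineage sorting
#'
#' Survival function of the tract-length null: the probability that a
#' shared ancestral tract is at least m bp long is
#' \deqn{1 - \mathrm{GammaCDF}(m;\ \mathrm{shape}=2,\ \mathrm{rate}=1/L)
#'       = e^{-m/L}\,(1 + m/L),}
#' an Erlang-2 survival with mean tract scale L from
#' [expected_tract_length()]. Observed tracts hundreds of times longer
#' than L give probabilities below the double-precision minimum; these are
#' reported as exactly 0.
#'
#' @param m observed tract length in bp (vectorized).
#' @param L expected tract length in bp.
#' @return probability in \[0, 1\].
#' @export
ils_survival_probability <- function(m, L) {
  stopifnot(all(m >= 0), L > 0)
  stats::pgamma(m, shape = 2, rate = 1 / L, lower.tail = FALSE)
}

#' Convert generations to years before present
#'
#' @param generations number of generations (vectorized).
#' @param g generation time in years.
#' @return years before present.
#' @export
generations_to_years <- function(generations, g) {
  stopifnot(all(generations >= 0), g > 0)
  generations * g
}

#' Batch ILS query table
#'
#' Evaluates the tract-length null for a table of queries, one row per
#' (recombination rate, divergence time, generation time, observed tract
#' length).
#'
#' @param queries data.frame with columns `r`, `divergence_years`, `g`,
#'   `m`.
#' @param two_branches passed to [expected_tract_length()].
#' @return `queries` with added columns `t_generations`, `L_bp` and
#'   `p_ils`.
#' @export
ils_query <- function(queries, two_branches = FALSE) {
  stopifnot(all(c("r", "divergence_years", "g", "m") %in% names(queries)))
  queries$t_generations <- queries$divergence_years / queries$g *
    (if (two_branches) 2 else 1)
  queries$L_bp <- mapply(expected_tract_length, queries$r,
                         queries$divergence_years, queries$g,
                         MoreArgs = list(two_branches = two_branches))
  queries$p_ils <- mapply(ils_survival_probability, queries$m, queries$L_bp)
  queries
}
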