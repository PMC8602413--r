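# Brute-force oracles: statistics recomputed from explicit haplotype
# pairs, independent of the frequency-based estimators under test.

# mean pairwise Hamming distance per bp over all haplotype pairs within a
# population; haplotypes materialized as allele bags per site
oracle_pi <- function(p, n, len) {
  per_site <- vapply(seq_along(p), function(i) {
    if (is.na(p[i]) || n[i] < 2) return(0)
    d <- round(p[i] * n[i])          # derived allele count
    d * (n[i] - d) / choose(n[i], 2)
  }, 1)
  sum(per_site) / len
}

oracle_dxy <- function(pA, nA, pB, nB, len) {
  per_site <- vapply(seq_along(pA), function(i) {
    if (is.na(pA[i]) || is.na(pB[i])) return(0)
    dA <- round(pA[i] * nA[i]); dB <- round(pB[i] * nB[i])
    (dA * (nB[i] - dB) + dB * (nA[i] - dA)) / (nA[i] * nB[i])
  }, 1)
  sum(per_site) / len
}

# independently coded per-site Hudson components
oracle_fst <- function(pA, nA, pB, nB) {
  num <- 0; den <- 0
  for (i in seq_along(pA)) {
    if (is.na(pA[i]) || is.na(pB[i]) || nA[i] < 2 || nB[i] < 2) next
    hA <- pA[i] * (1 - pA[i]) * nA[i] / (nA[i] - 1)
    hB <- pB[i] * (1 - pB[i]) * nB[i] / (nB[i] - 1)
    num <- num + (pA[i] - pB[i])^2 - hA / nA[i] - hB / nB[i]
    den <- den + pA[i] * (1 - pB[i]) + pB[i] * (1 - pA[i])
  }
  num / den
}

one_window <- function(len) make_windows(c(chr1 = len), len, len)

test_that("window pi matches closed forms and the haplotype-pair oracle", {
  # 2 diploids, one site at p = 0.5 in a 1-kb window: pi = (4/3 * 0.5)/1000
  g <- matrix(c(1L, 1L), 1, 2)
  gt <- toy_gt(g, pos = 500L)
  pm <- toy_pm(gt$samples, 2, "A")
  fr <- pop_freqs(gt, pm)
  res <- window_pi(fr, one_window(1000), "A")
  expect_equal(res$pi, (4 / 3 * 0.5) / 1000, tolerance = 1e-12)

  # monomorphic window: pi = 0
  gt0 <- toy_gt(matrix(2L, 3, 4))
  fr0 <- pop_freqs(gt0, toy_pm(gt0$samples, 4, "A"))
  expect_equal(window_pi(fr0, one_window(1000), "A")$pi, 0)

  # random window vs brute-force pairwise oracle
  co <- random_cohort(n_sites = 120, seed = 11)
  fr <- pop_freqs(co$gt, co$pm)
  len <- max(co$gt$pos) + 10
  res <- window_pi(fr, one_window(len), "pop1")
  expect_equal(res$pi,
               oracle_pi(fr$p[, "pop1"], fr$n[, "pop1"], len),
               tolerance = 1e-12)

  # window with no called sites: pi undefined, not zero
  gna <- toy_gt(matrix(NA_integer_, 2, 3))
  frna <- pop_freqs(gna, toy_pm(gna$samples, 3, "A"))
  expect_true(is.na(window_pi(frna, one_window(1000), "A")$pi))
})

test_that("window dxy matches closed forms and the between-pair oracle", {
  # one fixed difference in 1 kb: dxy = 0.001
  g <- cbind(matrix(0L, 1, 3), matrix(2L, 1, 3))
  gt <- toy_gt(g, pos = 100L)
  pm <- toy_pm(gt$samples, c(3, 3), c("A", "B"))
  fr <- pop_freqs(gt, pm)
  expect_equal(window_dxy(fr, one_window(1000), "A", "B")$dxy, 0.001)
  # identical fixed populations: dxy = 0
  g2 <- matrix(2L, 2, 6)
  fr2 <- pop_freqs(toy_gt(g2), pm)
  expect_equal(window_dxy(fr2, one_window(1000), "A", "B")$dxy, 0)

  co <- random_cohort(n_sites = 100, seed = 5)
  fr <- pop_freqs(co$gt, co$pm)
  len <- max(co$gt$pos) + 10
  res <- window_dxy(fr, one_window(len), "pop1", "pop2")
  expect_equal(res$dxy,
               oracle_dxy(fr$p[, "pop1"], fr$n[, "pop1"],
                          fr$p[, "pop2"], fr$n[, "pop2"], len),
               tolerance = 1e-12)
  # symmetry
  expect_equal(res$dxy, window_dxy(fr, one_window(len), "pop2", "pop1")$dxy)
})

test_that("Hudson FST matches the independent per-site oracle and limits", {
  co <- random_cohort(n_sites = 150, seed = 9)
  fr <- pop_freqs(co$gt, co$pm)
  len <- max(co$gt$pos) + 10
  res <- window_fst(fr, one_window(len), "pop1", "pop2")
  expect_equal(res$fst,
               oracle_fst(fr$p[, "pop1"], fr$n[, "pop1"],
                          fr$p[, "pop2"], fr$n[, "pop2"]),
               tolerance = 1e-12)
  expect_equal(res$fst, window_fst(fr, one_window(len), "pop2", "pop1")$fst)
  expect_equal(res$fst, hudson_fst(fr, "pop1", "pop2"), tolerance = 1e-12)

  # fixed difference with many samples: FST -> 1
  g <- cbind(matrix(0L, 1, 20), matrix(2L, 1, 20))
  gt <- toy_gt(g, pos = 100L)
  fr1 <- pop_freqs(gt, toy_pm(gt$samples, c(20, 20), c("A", "B")))
  expect_equal(window_fst(fr1, one_window(1000), "A", "B")$fst, 1)

  # identical frequencies, large n: FST ~ 0
  set.seed(2)
  p <- stats::rbeta(80, 2, 2)
  gA <- matrix(stats::rbinom(80 * 50, 2, p), 80)
  gB <- matrix(stats::rbinom(80 * 50, 2, p), 80)
  gt2 <- toy_gt(cbind(gA, gB))
  fr2 <- pop_freqs(gt2, toy_pm(gt2$samples, c(50, 50), c("A", "B")))
  f0 <- window_fst(fr2, one_window(max(gt2$pos) + 1), "A", "B")$fst
  expect_lt(abs(f0), 0.05)

  # no variation at all: undefined
  gmono <- toy_gt(matrix(0L, 3, 8))
  frm <- pop_freqs(gmono, toy_pm(gmono$samples, c(4, 4), c("A", "B")))
  expect_true(is.na(window_fst(frm, one_window(1000), "A", "B")$fst))
})

test_that("ratio-of-averages FST equals the per-site formula for one SNP", {
  g <- rbind(c(0L, 1L, 2L, 2L, 2L, 1L))
  gt <- toy_gt(g)
  fr <- pop_freqs(gt, toy_pm(gt$samples, c(3, 3), c("A", "B")))
  w <- window_fst(fr, one_window(100), "A", "B")$fst
  expect_equal(w, unname(oracle_fst(fr$p[, "A"], fr$n[, "A"],
                                    fr$p[, "B"], fr$n[, "B"])),
               tolerance = 1e-12)
})

test_that("windowed FST on a split panmictic population centres on zero", {
  set.seed(41)
  cfg <- sim_config(seed = 41, contigs = c(chr1 = 12e6),
                    site_density = 1e-3,
                    populations = data.frame(label = c("X", "Y"),
                                             n = c(10L, 10L),
                                             F = c(0, 0)))
  co <- simulate_cohort(cfg)
  fr <- pop_freqs(co$gt, co$popmap)
  grid <- make_windows(c(chr1 = 12e6), 20000, 20000)  # 600 windows
  fst <- window_fst(fr, grid, "X", "Y")$fst
  expect_gte(sum(!is.na(fst)), 500)
  expect_lt(abs(mean(fst, na.rm = TRUE)), 0.01)
})

test_that("LD r2 handles perfect LD, sign-invariance and random pairs", {
  set.seed(3)
  g1 <- stats::rbinom(12, 2, 0.5)
  g2 <- 2L - g1                       # complement: r2 must be 1
  g3 <- stats::rbinom(12, 2, 0.4)
  gt <- toy_gt(rbind(g1, g1, g2, g3), pos = c(100L, 600L, 1100L, 1850L))
  pm <- toy_pm(gt$samples, 12, "A")
  curve <- ld_decay(gt, pm, "A", max_dist = 2000, bin_width = 500)
  # duplicated site at distance 500 and complement at distance 1000
  expect_equal(curve$mean_r2[curve$bin_start == 0], 1, tolerance = 1e-12)
  r13 <- stats::cor(g1, g2)^2
  expect_equal(r13, 1, tolerance = 1e-12)
  # every binned mean equals the direct genotype correlation oracle
  pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4))
  g <- rbind(g1, g1, g2, g3); pos <- c(100, 600, 1100, 1850)
  ora <- data.frame(d = sapply(pairs, function(ij) pos[ij[2]] - pos[ij[1]]),
                    r2 = sapply(pairs, function(ij)
                      stats::cor(g[ij[1], ], g[ij[2], ])^2))
  for (b in which(curve$n_pairs > 0)) {
    sel <- ora$d > curve$bin_start[b] & ora$d <= curve$bin_end[b]
    expect_equal(curve$mean_r2[b], mean(ora$r2[sel]), tolerance = 1e-12)
  }
})
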