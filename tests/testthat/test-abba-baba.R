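# frequency table built directly from a matrix of derived frequencies,
# bypassing genotype sampling (all sites fully called, n alleles each)
freq_fixture <- function(p, n = 20L, pos = NULL, chrom = NULL) {
  p <- as.matrix(p)
  ns <- nrow(p)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  structure(list(chrom = chrom, pos = as.integer(pos),
                 populations = colnames(p), p = p,
                 n = matrix(n, ns, ncol(p), dimnames = list(NULL, colnames(p))),
                 usable = rep(TRUE, ns),
                 ancestral = rep("ref", ns), polarized = TRUE),
            class = "freq_table")
}

quartet <- c("P1", "P2", "P3", "OG")

test_that("site patterns match the ABBA/BABA definitions and an enumeration", {
  p <- rbind(c(0, 1, 1), c(1, 0, 1))
  colnames(p) <- quartet[1:3]
  sp <- site_patterns(freq_fixture(p), quartet)
  expect_equal(sp$abba, c(1, 0))
  expect_equal(sp$baba, c(0, 1))

  set.seed(8)
  pr <- matrix(stats::runif(60), 20, 3, dimnames = list(NULL, quartet[1:3]))
  sp <- site_patterns(freq_fixture(pr), quartet)
  pd <- pmax(pr[, 2], pr[, 3])
  expect_equal(sp$abba, unname((1 - pr[, 1]) * pr[, 2] * pr[, 3]),
               tolerance = 1e-12)
  expect_equal(sp$baba, unname(pr[, 1] * (1 - pr[, 2]) * pr[, 3]),
               tolerance = 1e-12)
  expect_equal(sp$abba_d, unname((1 - pr[, 1]) * pd * pd), tolerance = 1e-12)
  expect_equal(sp$baba_d, unname(pr[, 1] * (1 - pd) * pd), tolerance = 1e-12)
})

test_that("genome-wide D hits its boundaries and flips sign with P1/P2", {
  p <- matrix(rep(c(0, 1, 1), each = 50), 50, 3,
              dimnames = list(NULL, quartet[1:3]))
  sp <- site_patterns(freq_fixture(p, pos = seq_len(50) * 1000L), quartet)
  expect_equal(genome_wide_d(sp, block_size = 10000)$D, 1)

  set.seed(12)
  pr <- matrix(stats::runif(900), 300, 3, dimnames = list(NULL, quartet[1:3]))
  fr <- freq_fixture(pr, pos = seq_len(300) * 500L)
  d12 <- genome_wide_d(site_patterns(fr, quartet), block_size = 10000)
  fr_swap <- fr
  colnames(fr_swap$p) <- c("P2", "P1", "P3")
  colnames(fr_swap$n) <- c("P2", "P1", "P3")
  fr_swap$populations <- c("P2", "P1", "P3")
  d21 <- genome_wide_d(site_patterns(fr_swap, quartet), block_size = 10000)
  expect_equal(d12$D, -d21$D, tolerance = 1e-12)
  expect_lte(abs(d12$D), 1)
})

test_that("weighted jackknife gives SE 0 on blocks with constant D", {
  # 30 blocks, each with the same abba/baba profile -> leave-one-out
  # estimates identical -> SE exactly 0
  p_block <- rbind(c(0.2, 0.8, 0.9), c(0.1, 0.3, 0.5), c(0, 0.9, 0.4))
  p <- do.call(rbind, rep(list(p_block), 30))
  colnames(p) <- quartet[1:3]
  pos <- as.integer(outer(c(100, 200, 300), (0:29) * 10000, "+"))
  fr <- freq_fixture(p[order(rep(0:29, each = 3)), ], pos = sort(pos))
  d <- genome_wide_d(site_patterns(fr, quartet), block_size = 10000)
  expect_equal(d$n_blocks, 30)
  expect_equal(d$se, 0)
})

test_that("null simulation gives |D| near 0 and |Z| < 3", {
  set.seed(99)
  pr <- matrix(stats::rbeta(3000, 2, 2), 1000, 3,
               dimnames = list(NULL, quartet[1:3]))
  # P2 and P3 exchangeable: symmetric abba/baba in expectation
  fr <- freq_fixture(pr, pos = sort(sample.int(30000000L, 1000)))
  d <- genome_wide_d(site_patterns(fr, quartet))
  expect_lt(abs(d$D), 0.1)
  expect_lt(abs(d$Z), 3)
})

test_that("f3 matches its per-site oracle and detects a seeded mixture", {
  co <- random_cohort(n_sites = 400, n_pops = 3, n_dip = 8, seed = 21)
  fr <- pop_freqs(co$gt, co$pm)
  res <- f3_statistic(fr, "pop1", "pop2", "pop3", block_size = 200000)
  pC <- fr$p[, "pop1"]; pA <- fr$p[, "pop2"]; pB <- fr$p[, "pop3"]
  nC <- fr$n[, "pop1"]
  ok <- !is.na(pC) & !is.na(pA) & !is.na(pB) & nC >= 2
  ora <- mean(((pC - pA) * (pC - pB) - pC * (1 - pC) / (nC - 1))[ok])
  expect_equal(res$f3, ora, tolerance = 1e-12)
  # symmetric in the two sources
  swapped <- f3_statistic(fr, "pop1", "pop3", "pop2", block_size = 200000)
  expect_equal(res$f3, swapped$f3, tolerance = 1e-12)

  # target = 50/50 frequency mixture of two diverged sources: f3 < 0, Z < -3
  set.seed(77)
  ns <- 4000
  pA2 <- stats::rbeta(ns, 0.5, 0.5)
  pB2 <- stats::rbeta(ns, 0.5, 0.5)
  pC2 <- 0.5 * pA2 + 0.5 * pB2
  gC <- matrix(stats::rbinom(ns * 12, 2, pC2), ns)
  gA <- matrix(stats::rbinom(ns * 12, 2, pA2), ns)
  gB <- matrix(stats::rbinom(ns * 12, 2, pB2), ns)
  gt <- toy_gt(cbind(gC, gA, gB), pos = sort(sample.int(40000000L, ns)))
  pm <- toy_pm(gt$samples, c(12, 12, 12), c("C", "A", "B"))
  fr2 <- pop_freqs(gt, pm)
  mix <- f3_statistic(fr2, "C", "A", "B")
  expect_lt(mix$f3, 0)
  expect_lt(mix$Z, -3)
})

test_that("BH adjustment matches the step-up definition and flags", {
  # brute-force BH: q_i = min over j >= rank(i) of p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  p <- c(0.01, 0.02, 0.30, 0.80)
  res <- fdr_bh(p)
  expect_equal(res$q, c(0.04, 0.04, 0.40, 0.80), tolerance = 1e-12)
  expect_equal(res$q, bh_oracle(p), tolerance = 1e-12)
  expect_equal(fdr_bh(1)$q, 1)
  expect_equal(fdr_bh(0.01)$q, 0.01)        # m = 1 identity
  expect_false(any(fdr_bh(rep(1, 10))$discovery))
  set.seed(4)
  pr <- stats::runif(200)
  expect_equal(fdr_bh(pr)$q, bh_oracle(pr), tolerance = 1e-12)
  expect_true(all(fdr_bh(pr)$q >= pr))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fd saturates at 1 for complete sharing and is NA without donor variation", {
  # p2 = p3 everywhere, p1 = 0: numerator equals donor-maximized denominator
  set.seed(5)
  ns <- 60
  p23 <- stats::runif(ns, 0.3, 0.9)
  p <- cbind(P1 = 0, P2 = p23, P3 = p23)
  fr <- freq_fixture(p, pos = seq_len(ns) * 100L)
  grid <- make_windows(c(chr1 = 6000), 6000, 6000)
  scan <- suppressWarnings(window_fd_scan(fr, grid, quartet, min_sites = 5))
  expect_equal(scan$fd, 1, tolerance = 1e-12)

  # donor invariant: no informative sites, fd undefined
  p0 <- cbind(P1 = stats::runif(ns), P2 = stats::runif(ns), P3 = 0)
  fr0 <- freq_fixture(p0, pos = seq_len(ns) * 100L)
  scan0 <- suppressWarnings(window_fd_scan(fr0, grid, quartet, min_sites = 5))
  expect_true(is.na(scan0$fd))
  expect_equal(scan0$n_sites, 0)
})

test_that("fd scan agrees with a straight-from-formula recomputation per window", {
  set.seed(31)
  ns <- 800
  pr <- matrix(stats::rbeta(ns * 3, 0.8, 0.8), ns, 3,
               dimnames = list(NULL, quartet[1:3]))
  pos <- sort(sample.int(2000000L, ns))
  fr <- freq_fixture(pr, pos = pos)
  grid <- make_windows(c(chr1 = 2000000), 100000, 20000)
  scan <- window_fd_scan(fr, grid, quartet, min_sites = 10)
  # independent recomputation: loop windows, loop sites, raw formulas
  for (w in sample(seq_len(nrow(grid)), 25)) {
    sel <- pos - 1 >= grid$start[w] & pos - 1 < grid$end[w]
    abba <- (1 - pr[sel, 1]) * pr[sel, 2] * pr[sel, 3]
    baba <- pr[sel, 1] * (1 - pr[sel, 2]) * pr[sel, 3]
    inf <- abba + baba > 0
    pd <- pmax(pr[sel, 2], pr[sel, 3])
    abba_d <- (1 - pr[sel, 1]) * pd * pd
    baba_d <- pr[sel, 1] * (1 - pd) * pd
    num <- sum(abba - baba); dden <- sum(abba + baba)
    fden <- sum(abba_d - baba_d)
    D <- num / dden
    fd <- if (D > 0 && fden > 0 && sum(inf) >= 10) num / fden else NA_real_
    expect_equal(scan$n_sites[w], sum(inf))
    expect_equal(scan$D[w], D, tolerance = 1e-12)
    expect_equal(scan$fd[w], fd, tolerance = 1e-12)
  }
  # fd bounded in [0, 1] whenever defined
  expect_true(all(scan$fd >= 0 & scan$fd <= 1, na.rm = TRUE))
  expect_true(all(scan$q >= scan$p, na.rm = TRUE))
})

test_that("tract calling merges overlapping windows and preserves gaps", {
  mk <- function(start, end, q, D = 0.5, fd = 0.6) {
    data.frame(chrom = "chr1", start = start, end = end, partial = FALSE,
               n_sites = 50, D = D, fd = fd, Z = 1, p = q, q = q)
  }
  recs <- rbind(mk(0, 100000, 0.01), mk(20000, 120000, 0.01),
                mk(200000, 300000, 0.01), mk(400000, 500000, 0.5))
  tr <- call_introgressed_tracts(recs, alpha = 0.05)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, c(0, 200000))
  expect_equal(tr$end, c(120000, 300000))
  expect_equal(tr$n_windows, c(2L, 1L))
  # windows with D <= 0 never enter tracts
  recs2 <- rbind(mk(0, 100000, 0.01, D = -0.2), mk(200000, 300000, 0.01))
  tr2 <- call_introgressed_tracts(recs2)
  expect_equal(tr2$start, 200000)
  # idempotence on merged output: disjoint and sorted
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(tr$end[-nrow(tr)] < tr$start[-1]))
  # min_windows drops singleton runs; edge_trim shrinks symmetric overhang
  tr3 <- call_introgressed_tracts(recs, min_windows = 2)
  expect_equal(nrow(tr3), 1L)
  tr4 <- call_introgressed_tracts(recs, edge_trim = 10000)
  expect_equal(tr4$start[1], 10000)
  expect_equal(tr4$end[1], 110000)
  # a singleton window is never trimmed below one window length
  expect_equal(tr4$start[2], 200000)
  expect_equal(tr4$end[2], 300000)
})
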