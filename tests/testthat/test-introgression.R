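# Patterson's D, f4-ratio, block jackknife and the fd/fdM window scan.

test_that("site patterns reproduce the ABBA/BABA definitions", {
  p <- site_patterns(0, 1, 1, 0)
  expect_equal(p$abba, 1)
  expect_equal(p$baba, 0)
  # p1 = p2 contributes nothing to the D numerator
  p <- site_patterns(0.3, 0.3, 0.7, 0.1)
  expect_equal(p$abba, p$baba)
  # arbitrary frequencies vs the independent pattern-probability oracle
  p <- site_patterns(0.2, 0.8, 0.6, 0.1)
  expect_equal(p$abba, oracle_pattern_prob("ABBA", c(0.2, 0.8, 0.6, 0.1)))
  expect_equal(p$baba, oracle_pattern_prob("BABA", c(0.2, 0.8, 0.6, 0.1)))
  expect_error(site_patterns(1.2, 0, 0, 0), "\\[0, 1\\]")
})

test_that("D is zero when P1 equals P2 and antisymmetric under their swap", {
  withr::with_seed(5, {
    p1 <- runif(200); p3 <- runif(200); pO <- runif(200, 0, 0.4)
    ft_eq <- freqs_from_p(p1, p1, p3, pO)
    expect_equal(d_statistic(ft_eq, canonical_trio(), 10)$D, 0)

    p2 <- runif(200)
    ft <- freqs_from_p(p1, p2, p3, pO)
    d_fwd <- d_statistic(ft, canonical_trio(), 10)
    d_rev <- d_statistic(ft, trio("P2", "P1", "P3", "O"), 10)
    expect_identical(d_fwd$D, -d_rev$D)
    expect_equal(abs(d_fwd$Z_D), abs(d_rev$Z_D))
  })
})

test_that("D and its jackknife SE match the brute-force oracle", {
  withr::with_seed(11, {
    n <- 1000
    p1 <- runif(n); p2 <- runif(n); p3 <- runif(n); pO <- runif(n, 0, 0.5)
    ft <- freqs_from_p(p1, p2, p3, pO)
    res <- d_statistic(ft, canonical_trio(), block_count = 20)
    expect_lt(abs(res$D - oracle_D(p1, p2, p3, pO)), 1e-12)
    expect_lt(abs(res$SE_D - oracle_D_jackknife_se(p1, p2, p3, pO, 20)),
              1e-12)
    expect_lte(abs(res$D), 1)
  })
})

test_that("genome-wide D equals the recombination of per-block sums", {
  withr::with_seed(12, {
    n <- 500
    ft <- freqs_from_p(runif(n), runif(n), runif(n), runif(n, 0, 0.5))
    tf <- interflow:::trio_freqs(ft, canonical_trio())
    pat <- site_patterns(tf$p1, tf$p2, tf$p3, tf$pO)
    inf <- (pat$abba + pat$baba) > 0
    jk <- interflow:::jackknife_ratio((pat$abba - pat$baba)[inf],
                                      (pat$abba + pat$baba)[inf], 20)
    expect_equal(sum(jk$block_num) / sum(jk$block_den),
                 d_statistic(ft, canonical_trio())$D)
  })
})

test_that("D handles degenerate inputs explicitly", {
  ft <- freqs_from_p(rep(0, 30), rep(0, 30), rep(0, 30), rep(0, 30))
  res <- d_statistic(ft, canonical_trio())
  expect_true(is.na(res$D))
  expect_match(res$status, "no informative")
  ft2 <- freqs_from_p(runif(10), runif(10), runif(10), rep(0, 10))
  expect_error(d_statistic(ft2, canonical_trio(), block_count = 20),
               "fewer informative")
})

test_that("f4-ratio hits its analytic limits", {
  # receptor identical to donor, both donor halves equal -> f = 1
  withr::with_seed(3, {
    n <- 60
    base <- matrix(rbinom(n * 2, 2, 0.5), n, 2)
    dos <- cbind(base[, 1], base[, 1],      # P1 pair
                 base[, 2], base[, 2],      # P2 pair, = P3 below
                 base[, 2], base[, 2],      # P3: two identical samples
                 matrix(0L, n, 2))          # outgroup fixed REF
    colnames(dos) <- c("a1", "a2", "b1", "b2", "c1", "c2", "o1", "o2")
    gm <- gm_from_dosages(dos, pops = c("P1", "P1", "P2", "P2",
                                        "P3", "P3", "O", "O"))
    ft <- allele_frequencies(gm, outgroup = "O")
    res <- f4_ratio(ft, canonical_trio(), seed = 1, block_count = 5)
    expect_equal(res$f4_ratio, 1)

    # receptor identical to P1 -> numerator 0 -> f = 0
    dos0 <- dos; dos0[, c("b1", "b2")] <- base[, 1]
    gm0 <- gm_from_dosages(dos0, pops = c("P1", "P1", "P2", "P2",
                                          "P3", "P3", "O", "O"))
    ft0 <- allele_frequencies(gm0, outgroup = "O")
    expect_equal(f4_ratio(ft0, canonical_trio(), seed = 1,
                          block_count = 5)$f4_ratio, 0)
  })
})

test_that("f4-ratio requires a splittable donor and flags bad denominators", {
  dos <- cbind(matrix(1L, 30, 3), matrix(0L, 30, 1), matrix(0L, 30, 2))
  colnames(dos) <- c("a", "b", "c", "d", "o1", "o2")
  gm <- gm_from_dosages(dos, pops = c("P1", "P2", "P3", "P3", "O", "O"))
  ft <- allele_frequencies(gm, outgroup = "O")
  gm1 <- gm_from_dosages(dos[, -4], pops = c("P1", "P2", "P3", "O", "O"))
  ft1 <- allele_frequencies(gm1, outgroup = "O")
  expect_error(f4_ratio(ft1, canonical_trio(), seed = 1, block_count = 5),
               "at least 2 samples")
  # monomorphic data: denominator sum is zero -> undefined with status
  res <- f4_ratio(ft, canonical_trio(), seed = 1, block_count = 5)
  expect_true(is.na(res$f4_ratio))
  expect_match(res$status, "denominator")
})

test_that("the donor half-split is fixed by the seed", {
  cfg <- sim_config(n_sites = 2000, chrom_length = 1e6,
                    samples_per_pop = 6, seed = 9)
  sl <- sim_lineage(cfg)
  r1 <- f4_ratio(sl$freqs, canonical_trio(), seed = 4)
  r2 <- f4_ratio(sl$freqs, canonical_trio(), seed = 4)
  expect_identical(r1$f4_ratio, r2$f4_ratio)
})

test_that("window arithmetic produces the expected sliding grid", {
  withr::with_seed(2, {
    ft <- freqs_from_p(runif(50), runif(50), runif(50), runif(50, 0, .4),
                       pos = sort(sample(25000, 50)))
    sc <- window_scan(ft, canonical_trio(), window = 10000, step = 1000,
                      chrom_lengths = c(chr1 = 25000))
    expect_equal(nrow(sc), 16L)
    expect_equal(sc$start, seq(0, 15000, 1000))
    expect_equal(sc$end, sc$start + 10000)
  })
  expect_error(window_scan(freqs_from_p(.5, .5, .5, .1),
                           canonical_trio(), window = 0), "positive")
})

test_that("fdM is zero under the P1 = P2 symmetry null", {
  withr::with_seed(8, {
    p1 <- runif(40); p3 <- runif(40); pO <- runif(40, 0, 0.4)
    ft <- freqs_from_p(p1, p1, p3, pO, pos = seq(100, 4000, 100))
    sc <- window_scan(ft, canonical_trio(), window = 4000, step = 4000,
                      min_sites = 1, chrom_lengths = c(chr1 = 4000))
    expect_equal(sc$fdM[1], 0)
  })
})

test_that("window fd and fdM match the site-by-site oracle", {
  withr::with_seed(21, {
    n <- 200
    p1 <- runif(n); p2 <- runif(n); p3 <- runif(n); pO <- runif(n, 0, .5)
    ft <- freqs_from_p(p1, p2, p3, pO, pos = seq_len(n) * 10L)
    sc <- window_scan(ft, canonical_trio(), window = n * 10, step = n * 10,
                      min_sites = 1, chrom_lengths = c(chr1 = n * 10))
    orc <- oracle_fd_fdm(p1, p2, p3, pO)
    expect_lt(abs(sc$fd[1] - orc$fd), 1e-12)
    expect_lt(abs(sc$fdM[1] - orc$fdm), 1e-12)
  })
})

test_that("fdM stays within [-1, 1] on valid windows of simulated data", {
  for (s in 1:3) {
    cfg <- sim_config(n_sites = 8000, chrom_length = 2e6,
                      samples_per_pop = 6,
                      f_target = c(0, 0.2, 0.4)[s], seed = s)
    sl <- sim_lineage(cfg)
    sc <- window_scan(sl$freqs, canonical_trio(),
                      chrom_lengths = sl$chrom_lengths)
    fdm <- sc$fdM[sc$valid]
    expect_true(all(fdm >= -1 & fdm <= 1))
  }
})

test_that("per-pair summaries keep separate provenance for D and f4 maxima", {
  res <- data.frame(P1 = c("a", "b"), P2 = "r", P3 = "d", O = "o",
                    D = c(0.05, 0.12), SE_D = 0.01, Z_D = c(5, 12),
                    significant_D = TRUE, f4_ratio = c(0.3, 0.1),
                    SE_f4 = 0.02, Z_f4 = c(15, 5), n_sites = 100,
                    n_blocks = 20)
  sm <- summarize_pairs(res)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$max_D, 0.12)
  expect_equal(sm$P1_for_D, "b")
  expect_equal(sm$max_f4, 0.3)
  expect_equal(sm$P1_for_f4, "a")
  # single P1 choice passes through
  sm1 <- summarize_pairs(res[1, ])
  expect_equal(sm1$max_D, 0.05)
  expect_equal(sm1$n_trios, 1L)
})
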