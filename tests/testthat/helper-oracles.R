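# Independent brute-force oracles. These deliberately take different
# computational routes from the package implementation (scalar loops,
# pattern-string expansion, allele-level enumeration) so agreement is a
# genuine cross-check rather than a tautology.

# Probability of a gene-tree site pattern (e.g. "ABBA") for taxa
# (P1, P2, P3, O): sum over which allele state plays "B", multiplying
# per-taxon frequencies.
oracle_pattern_prob <- function(pattern, p) {
  stopifnot(nchar(pattern) == 4, length(p) == 4)
  states <- strsplit(pattern, "")[[1]]
  total <- 0
  for (b_is_derived in c(TRUE, FALSE)) {
    prob <- 1
    for (i in 1:4) {
      pd <- if (states[i] == "B") p[i] else 1 - p[i]
      prob <- prob * (if (b_is_derived) pd else 1 - pd)
    }
    total <- total + prob
  }
  total
}

# Site-by-site D over a frequency table, scalar loop.
oracle_D <- function(p1, p2, p3, pO) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    abba <- oracle_pattern_prob("ABBA", c(p1[i], p2[i], p3[i], pO[i]))
    baba <- oracle_pattern_prob("BABA", c(p1[i], p2[i], p3[i], pO[i]))
    if (abba + baba > 0) {
      num <- num + (abba - baba)
      den <- den + (abba + baba)
    }
  }
  num / den
}

# Textbook delete-one block jackknife SE for D with equal-count
# contiguous blocks, recomputed from scratch per deleted block.
oracle_D_jackknife_se <- function(p1, p2, p3, pO, g) {
  abba <- baba <- numeric(length(p1))
  for (i in seq_along(p1)) {
    abba[i] <- oracle_pattern_prob("ABBA", c(p1[i], p2[i], p3[i], pO[i]))
    baba[i] <- oracle_pattern_prob("BABA", c(p1[i], p2[i], p3[i], pO[i]))
  }
  inf <- (abba + baba) > 0
  abba <- abba[inf]; baba <- baba[inf]
  n <- length(abba)
  blk <- as.integer(floor((seq_len(n) - 1) * g / n)) + 1L
  loo <- vapply(seq_len(g), function(j) {
    keep <- blk != j
    sum(abba[keep] - baba[keep]) / sum(abba[keep] + baba[keep])
  }, numeric(1))
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# fd and fdM for one window of sites, scalar loop with explicit branching.
oracle_fd_fdm <- function(p1, p2, p3, pO) {
  num <- den_fd <- den_fdm <- 0
  for (i in seq_along(p1)) {
    ab <- oracle_pattern_prob("ABBA", c(p1[i], p2[i], p3[i], pO[i]))
    ba <- oracle_pattern_prob("BABA", c(p1[i], p2[i], p3[i], pO[i]))
    num <- num + (ab - ba)
    pd <- max(p2[i], p3[i])
    abd <- oracle_pattern_prob("ABBA", c(p1[i], pd, pd, pO[i]))
    bad <- oracle_pattern_prob("BABA", c(p1[i], pd, pd, pO[i]))
    den_fd <- den_fd + (abd - bad)
    if (p2[i] >= p1[i]) {
      den_fdm <- den_fdm + (abd - bad)
    } else {
      pd1 <- max(p1[i], p3[i])
      ab1 <- oracle_pattern_prob("ABBA", c(pd1, p2[i], pd1, pO[i]))
      ba1 <- oracle_pattern_prob("BABA", c(pd1, p2[i], pd1, pO[i]))
      den_fdm <- den_fdm - (ab1 - ba1)
    }
  }
  list(fd = if (num <= 0) 0 else num / den_fd, fdm = num / den_fdm,
       num = num, den_fd = den_fd, den_fdm = den_fdm)
}

# Nucleotide diversity of one window by explicit pairwise allele
# comparison: for each site, count unequal pairs among the called alleles.
oracle_pi_window <- function(dosages, window_len) {
  total <- 0
  for (i in seq_len(nrow(dosages))) {
    d <- dosages[i, ]
    d <- d[!is.na(d)]
    alleles <- c(rep(1, sum(d)), rep(0, 2 * length(d) - sum(d)))
    m <- length(alleles)
    if (m < 2) next
    diffs <- 0
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) diffs <- diffs + (alleles[a] != alleles[b])
    }
    # mean pairwise difference; equals (m/(m-1)) 2p(1-p)
    total <- total + diffs / choose(m, 2)
  }
  total / window_len
}

# Dxy of one window by pairwise comparison across populations.
oracle_dxy_window <- function(dosA, dosB, window_len) {
  total <- 0
  for (i in seq_len(nrow(dosA))) {
    a <- dosA[i, ]; a <- a[!is.na(a)]
    b <- dosB[i, ]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) next
    alA <- c(rep(1, sum(a)), rep(0, 2 * length(a) - sum(a)))
    alB <- c(rep(1, sum(b)), rep(0, 2 * length(b) - sum(b)))
    diffs <- 0
    for (x in alA) for (y in alB) diffs <- diffs + (x != y)
    total <- total + diffs / (length(alA) * length(alB))
  }
  total / window_len
}

# Weir & Cockerham Fst via the allele-level ANOVA route (mean squares for
# populations / individuals-within-populations / genotypes-within-
# individuals), the method-of-moments formulation the 1984 estimator is
# derived from. Ratio of summed variance components over sites.
oracle_fst_window <- function(dosA, dosB) {
  sum_a <- sum_abc <- 0
  for (i in seq_len(nrow(dosA))) {
    a <- dosA[i, ]; a <- a[!is.na(a)]
    b <- dosB[i, ]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    p1 <- sum(a) / (2 * n1); p2 <- sum(b) / (2 * n2)
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    # sums of squares from individual allele indicators
    ind_means <- c(a / 2, b / 2)
    pop_of <- rep(1:2, c(n1, n2))
    pop_mean <- c(p1, p2)
    SSG <- sum(c(a, b) == 1) * 0.5        # within-individual
    SSI <- 2 * sum((ind_means - pop_mean[pop_of])^2)
    SSP <- 2 * (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)
    MSG <- SSG / (n1 + n2)
    MSI <- SSI / (n1 + n2 - 2)
    MSP <- SSP / 1
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / 1
    s2G <- MSG
    s2I <- (MSI - MSG) / 2
    s2P <- (MSP - MSI) / (2 * nc)
    if (!is.finite(s2P + s2I + s2G)) next
    sum_a <- sum_a + s2P
    sum_abc <- sum_abc + s2P + s2I + s2G
  }
  if (sum_abc == 0) return(NA_real_)
  sum_a / sum_abc
}

# Exact hypergeometric tail probabilities by explicit enumeration with
# binomial coefficients (log scale for stability).
oracle_hyper <- function(k, n, K, N) {
  kmin <- max(0, n + K - N)
  kmax <- min(n, K)
  supp <- kmin:kmax
  logp <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
  d <- exp(logp)
  d_obs <- d[supp == k]
  c(one = sum(d[supp >= k]), two = sum(d[d <= d_obs * (1 + 1e-7)]))
}

# Exact one-sided Mann-Whitney p-value by full enumeration of group-label
# assignments.
oracle_mw_exact_greater <- function(v_in, v_out) {
  pooled <- c(v_in, v_out)
  n1 <- length(v_in)
  U_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U_obs <- U_of(seq_len(n1))
  combos <- combn(length(pooled), n1)
  U_all <- apply(combos, 2, U_of)
  mean(U_all >= U_obs - 1e-9)
}

# Monte-Carlo renewal-process coverage (independent of the generator):
# expected tract coverage of an alternating exponential process.
oracle_renewal_coverage <- function(f, tract_mean, L, n_rep, seed) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_rep), function(i) {
      gap_mean <- tract_mean * (1 - f) / f
      covered <- 0; x <- 0
      in_tract <- runif(1) < f
      while (x < L) {
        len <- rexp(1, 1 / (if (in_tract) tract_mean else gap_mean))
        if (in_tract) covered <- covered + min(len, L - x)
        x <- x + len
        in_tract <- !in_tract
      }
      covered / L
    }, numeric(1)))
  })
}
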