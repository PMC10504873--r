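# Windowed diversity/divergence statistics and in/out-region contrasts.

feature_window_values <- function(gm, site_values, site_ok, window,
                                  chrom_lengths, name, units) {
  chrom <- gm$sites$chrom[site_ok]
  pos0 <- gm$sites$pos[site_ok] - 1L
  vals <- site_values[site_ok]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  win <- tile_windows(chrom_lengths, window)
  out <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    ch <- win$chrom[idx[1]]
    sel <- chrom == ch
    ws <- window_sums(pos0[sel], cbind(v = vals[sel]),
                      win$start[idx], win$end[idx])
    data.frame(chrom = ch, start = win$start[idx], end = win$end[idx],
               value = ws$sums[, "v"] / (win$end[idx] - win$start[idx]),
               n_sites = ws$n, stringsAsFactors = FALSE)
  })
  feature_track(do.call(rbind, out), name = name, units = units)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, `pi_site = (n/(n-1)) * 2 p (1-p)` with `n` the number of
#' called alleles; the window value is the sum of site values divided by
#' the full window length in bp (monomorphic and unobserved bases
#' contribute 0 to the numerator and full length to the denominator, the
#' convention of windowed-diversity tools). Sites with fewer than 2 called
#' alleles are skipped.
#'
#' @param gm A [genotype_matrix].
#' @param pop Population name.
#' @param window Window size in bp (non-overlapping).
#' @param chrom_lengths Optional named chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @return A [feature_track()] (per-bp diversity).
#' @export
pi_windows <- function(gm, pop, window = 10000L, chrom_lengths = NULL) {
  g <- gm$geno[, gm_samples_of(gm, pop), drop = FALSE]
  if (ncol(g) == 0L) stop("population has no samples: ", pop)
  called <- rowSums(!is.na(g))
  n <- 2 * called
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  pi_site <- ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), NA_real_)
  feature_window_values(gm, pi_site, !is.na(pi_site), window,
                        chrom_lengths, paste0("pi_", pop), "per-bp")
}

#' Windowed absolute divergence (Dxy)
#'
#' Window value `sum(pA (1-pB) + pB (1-pA)) / window_length`.
#'
#' @inheritParams pi_windows
#' @param popA,popB The two populations.
#' @return A [feature_track()].
#' @export
dxy_windows <- function(gm, popA, popB, window = 10000L,
                        chrom_lengths = NULL) {
  pf <- function(pop) {
    g <- gm$geno[, gm_samples_of(gm, pop), drop = FALSE]
    if (ncol(g) == 0L) stop("population has no samples: ", pop)
    n <- 2 * rowSums(!is.na(g))
    ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  }
  pA <- pf(popA); pB <- pf(popB)
  dxy_site <- pA * (1 - pB) + pB * (1 - pA)
  feature_window_values(gm, dxy_site, !is.na(dxy_site), window,
                        chrom_lengths, paste0("dxy_", popA, "_", popB),
                        "per-bp")
}

# Per-site Weir & Cockerham (1984) two-population variance components for
# diploid data: a (among populations), b (between individuals within
# populations), c (within individuals). Returns NA components for sites
# where the estimator is undefined.
wc_site_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  sum_n <- n1 + n2
  nc <- (sum_n - (n1^2 + n2^2) / sum_n) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / sum_n
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  undef <- n1 < 1 | n2 < 1 | nbar <= 1 | nc <= 0
  a[undef] <- NA_real_; b[undef] <- NA_real_; cc[undef] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst (ratio of sums)
#'
#' Per-site variance components a/b/c are summed over the window and the
#' window value is `sum(a) / sum(a + b + c)` (the "weighted" estimator,
#' stable at low per-site information; small negative values are
#' admissible under no differentiation). Windows with a zero denominator
#' are missing.
#'
#' @inheritParams dxy_windows
#' @return A [feature_track()] (dimensionless).
#' @export
fst_wc_windows <- function(gm, popA, popB, window = 10000L,
                           chrom_lengths = NULL) {
  comp_pop <- function(pop) {
    g <- gm$geno[, gm_samples_of(gm, pop), drop = FALSE]
    if (ncol(g) == 0L) stop("population has no samples: ", pop)
    n <- rowSums(!is.na(g))
    p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- comp_pop(popA); B <- comp_pop(popB)
  wc <- wc_site_components(A$n, A$p, A$h, B$n, B$p, B$h)
  ok <- !is.na(wc$a)

  chrom <- gm$sites$chrom[ok]
  pos0 <- gm$sites$pos[ok] - 1L
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  win <- tile_windows(chrom_lengths, window)
  out <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    ch <- win$chrom[idx[1]]
    sel <- chrom == ch
    ws <- window_sums(pos0[sel],
                      cbind(a = wc$a[ok][sel],
                            abc = (wc$a + wc$b + wc$c)[ok][sel]),
                      win$start[idx], win$end[idx])
    denom <- ws$sums[, "abc"]
    data.frame(chrom = ch, start = win$start[idx], end = win$end[idx],
               value = ifelse(denom != 0, ws$sums[, "a"] / denom, NA_real_),
               n_sites = ws$n, stringsAsFactors = FALSE)
  })
  feature_track(do.call(rbind, out),
                name = paste0("fst_", popA, "_", popB), units = "")
}

#' Compare a feature between introgressed and non-introgressed windows
#'
#' Classifies the track windows against the regions (midpoint rule by
#' default) and runs a Mann-Whitney (Wilcoxon rank-sum) test: exact when
#' both groups have at most 20 windows and the values are untied, the
#' tie-corrected normal approximation otherwise. The one-sided p-value
#' tests "in" greater than "out".
#'
#' @param track A [feature_track()].
#' @param regions A [region_set()].
#' @param rule Window classification rule (see [classify_windows()]).
#' @return A list of class `in_out_comparison`: group sizes and medians,
#'   `U`, `p_one_sided` (in > out), `p_two_sided`, `direction` and the
#'   percent difference of means.
#' @export
compare_in_out <- function(track, regions, rule = "midpoint") {
  lab <- classify_windows(track, regions, rule = rule)
  v <- track$value
  keep <- !is.na(v)
  v_in <- v[keep & lab == "in"]
  v_out <- v[keep & lab == "out"]
  if (length(v_in) == 0L || length(v_out) == 0L) {
    stop("empty group in in/out comparison (n_in = ", length(v_in),
         ", n_out = ", length(v_out), ")")
  }
  exact <- length(v_in) <= 20 && length(v_out) <= 20 &&
    !anyDuplicated(c(v_in, v_out))
  wt_g <- suppressWarnings(
    wilcox.test(v_in, v_out, alternative = "greater", exact = exact,
                correct = !exact))
  wt_t <- suppressWarnings(
    wilcox.test(v_in, v_out, alternative = "two.sided", exact = exact,
                correct = !exact))
  structure(list(
    n_in = length(v_in), n_out = length(v_out),
    median_in = median(v_in), median_out = median(v_out),
    U = unname(wt_g$statistic),
    p_one_sided = wt_g$p.value, p_two_sided = wt_t$p.value,
    direction = if (median(v_in) >= median(v_out)) "in>out" else "in<out",
    percent_mean_diff = 100 * (mean(v_in) - mean(v_out)) / mean(v_out)),
    class = "in_out_comparison")
}

#' @export
print.in_out_comparison <- function(x, ...) {
  cat(sprintf(
    "<in_out_comparison> n=%d/%d  median in=%.4g out=%.4g  U=%g\n",
    x$n_in, x$n_out, x$median_in, x$median_out, x$U))
  cat(sprintf("  one-sided (in>out) p=%.3g  two-sided p=%.3g  %s (%+.1f%%)\n",
              x$p_one_sided, x$p_two_sided, x$direction,
              x$percent_mean_diff))
  invisible(x)
}

#' Assign values of a coarse track to query windows
#'
#' Each query window takes the value of the track window containing its
#' midpoint (the containing-window rule for comparing grids of different
#' resolution), `NA` when none does.
#'
#' @param track A [feature_track()].
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @return Numeric vector of values, one per query window.
#' @export
track_values_at <- function(track, windows) {
  mid <- floor((windows$start + windows$end) / 2)
  idx <- point_in_interval(track, windows$chrom, mid)
  track$value[idx]
}
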