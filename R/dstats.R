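# Patterson's D, the f4-ratio admixture proportion and block-jackknife
# significance under the fixed four-population topology ([{P1,P2},P3],O).

#' Define a population trio (plus outgroup)
#'
#' @param p1,p2,p3,outgroup Population names; P2 is the candidate receptor,
#'   P3 the candidate donor, and the topology is `([{P1,P2},P3],O)`.
#' @return Named character vector of class `trio`.
#' @export
trio <- function(p1, p2, p3, outgroup) {
  v <- c(P1 = p1, P2 = p2, P3 = p3, O = outgroup)
  if (anyDuplicated(v)) stop("trio populations must be distinct")
  structure(v, class = "trio")
}

#' ABBA and BABA site-pattern probabilities from allele frequencies
#'
#' The frequency-based estimator: at a site with derived-allele
#' frequencies `(p1, p2, p3, pO)`,
#' `ABBA = (1-p1) p2 p3 (1-pO) + p1 (1-p2)(1-p3) pO` and
#' `BABA = p1 (1-p2) p3 (1-pO) + (1-p1) p2 (1-p3) pO`. Including the
#' outgroup terms keeps the statistics well behaved when the outgroup is
#' not perfectly fixed ancestral.
#'
#' @param p1,p2,p3,pO Derived-allele frequency vectors in `[0, 1]`.
#' @return List with numeric vectors `abba` and `baba`.
#' @export
site_patterns <- function(p1, p2, p3, pO) {
  rng <- range(c(p1, p2, p3, pO), na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  list(abba = (1 - p1) * p2 * p3 * (1 - pO) + p1 * (1 - p2) * (1 - p3) * pO,
       baba = p1 * (1 - p2) * p3 * (1 - pO) + (1 - p1) * p2 * (1 - p3) * pO)
}

# Contiguous equal-count block assignment (genome order) for n sites.
jackknife_blocks <- function(n, block_count) {
  as.integer(floor((seq_len(n) - 1L) * block_count / n)) + 1L
}

# Delete-one block jackknife for a ratio statistic sum(num)/sum(den).
# Returns the estimate, jackknife SE and Z, plus per-block sums.
jackknife_ratio <- function(num, den, block_count) {
  g <- block_count
  blk <- jackknife_blocks(length(num), g)
  num_b <- tapply(num, blk, sum)
  den_b <- tapply(den, blk, sum)
  S_num <- sum(num_b); S_den <- sum(den_b)
  est <- S_num / S_den
  loo <- (S_num - num_b) / (S_den - den_b)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(estimate = est, se = se,
       z = if (se > 0) est / se else NA_real_,
       block_num = as.numeric(num_b), block_den = as.numeric(den_b))
}

trio_freqs <- function(freqs, tr) {
  stopifnot(inherits(freqs, "freq_table"), inherits(tr, "trio"))
  data.frame(p1 = freq_col(freqs, tr[["P1"]]),
             p2 = freq_col(freqs, tr[["P2"]]),
             p3 = freq_col(freqs, tr[["P3"]]),
             pO = freq_col(freqs, tr[["O"]]))
}

#' Patterson's D with block-jackknife significance
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` over informative sites
#' (`ABBA + BABA > 0`), with the standard error from a delete-one jackknife
#' over `block_count` contiguous blocks of equal informative-site count.
#' `D > 0` indicates allele sharing between P2 and P3 (introgression),
#' `D < 0` between P1 and P3; `|Z| > 4` is flagged significant, the
#' conventional threshold for genome-scale scans.
#'
#' @param freqs A [allele_frequencies()] table.
#' @param tr A [trio()].
#' @param block_count Number of jackknife blocks (default 20).
#' @return A list of class `trio_result` with elements `D`, `SE_D`, `Z_D`,
#'   `significant_D`, `n_sites_used`, `n_blocks`, `status`.
#' @export
d_statistic <- function(freqs, tr, block_count = 20L) {
  tf <- trio_freqs(freqs, tr)
  ok <- complete.cases(tf)
  n_skipped <- sum(!ok)
  tf <- tf[ok, , drop = FALSE]
  pat <- site_patterns(tf$p1, tf$p2, tf$p3, tf$pO)
  informative <- (pat$abba + pat$baba) > 0
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    return(structure(list(trio = tr, D = NA_real_, SE_D = NA_real_,
                          Z_D = NA_real_, significant_D = NA,
                          n_sites_used = 0L, n_blocks = 0L,
                          n_skipped = n_skipped,
                          status = "no informative sites"),
                     class = "trio_result"))
  }
  if (n_inf < block_count) {
    stop("fewer informative sites (", n_inf, ") than jackknife blocks (",
         block_count, ")")
  }
  num <- (pat$abba - pat$baba)[informative]
  den <- (pat$abba + pat$baba)[informative]
  jk <- jackknife_ratio(num, den, block_count)
  structure(list(trio = tr, D = jk$estimate, SE_D = jk$se, Z_D = jk$z,
                 significant_D = !is.na(jk$z) && abs(jk$z) > 4,
                 n_sites_used = n_inf, n_blocks = as.integer(block_count),
                 n_skipped = n_skipped,
                 status = if (is.na(jk$z)) "zero jackknife SE" else "ok"),
            class = "trio_result")
}

# Fixed, seeded half-split of the donor population's samples; split once
# and reused across sites so the two halves are independent draws from the
# same population.
split_donor <- function(samples, seed) {
  if (length(samples) < 2L) stop("P3 must contain at least 2 samples")
  with_seed(substream_seed(seed, "p3-split"), {
    perm <- sample(samples)
    half <- floor(length(perm) / 2)
    list(a = perm[seq_len(half)], b = perm[-seq_len(half)])
  })
}

#' f4-ratio estimate of the admixture proportion
#'
#' Estimates the fraction of the P2 genome derived from the donor P3 as
#' `f = sum num(p1, p2, p3a, pO) / sum num(p1, p3b, p3a, pO)` with
#' `num = ABBA - BABA`, where `p3a` and `p3b` are derived-allele
#' frequencies computed from a fixed, seeded half-split of the P3 samples.
#' Substituting one donor half for P2 in the denominator gives the
#' full-replacement reference, making the ratio an unbiased small-sample
#' estimator of the admixture proportion. SE and Z come from the same
#' block jackknife as [d_statistic()].
#'
#' @inheritParams d_statistic
#' @param seed Integer seed fixing the donor half-split.
#' @return A list of class `trio_result` with elements `f4_ratio`, `SE_f4`,
#'   `Z_f4`, `n_sites_used`, `n_blocks`, `status`.
#' @export
f4_ratio <- function(freqs, tr, seed = 1L, block_count = 20L) {
  stopifnot(inherits(freqs, "freq_table"), inherits(tr, "trio"))
  gm <- attr(freqs, "gm")
  if (is.null(gm)) {
    stop("frequency table lacks the attached genotype matrix needed ",
         "for the donor half-split")
  }
  p3_samples <- gm_samples_of(gm, tr[["P3"]])
  halves <- split_donor(p3_samples, seed)
  derived_is_alt <- freqs$derived == freqs$alt
  half_freq <- function(cols) {
    g <- gm$geno[, cols, drop = FALSE]
    n <- 2L * rowSums(!is.na(g))
    p_alt <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
    ifelse(derived_is_alt, p_alt, 1 - p_alt)
  }
  p3a <- half_freq(halves$a)
  p3b <- half_freq(halves$b)
  tf <- trio_freqs(freqs, tr)
  ok <- complete.cases(tf) & !is.na(p3a) & !is.na(p3b)
  n_skipped <- sum(!ok)
  p1 <- tf$p1[ok]; p2 <- tf$p2[ok]; pO <- tf$pO[ok]
  p3a <- p3a[ok]; p3b <- p3b[ok]
  pat_num <- site_patterns(p1, p2, p3a, pO)
  pat_den <- site_patterns(p1, p3b, p3a, pO)
  num <- pat_num$abba - pat_num$baba
  den <- pat_den$abba - pat_den$baba
  if (length(num) < block_count) {
    stop("fewer usable sites (", length(num), ") than jackknife blocks (",
         block_count, ")")
  }
  if (sum(den) <= 0) {
    return(structure(list(trio = tr, f4_ratio = NA_real_, SE_f4 = NA_real_,
                          Z_f4 = NA_real_, n_sites_used = length(num),
                          n_blocks = as.integer(block_count),
                          n_skipped = n_skipped,
                          status = "non-positive denominator"),
                     class = "trio_result"))
  }
  jk <- jackknife_ratio(num, den, block_count)
  structure(list(trio = tr, f4_ratio = jk$estimate, SE_f4 = jk$se,
                 Z_f4 = jk$z,
                 significant_f4 = !is.na(jk$z) && abs(jk$z) > 4,
                 n_sites_used = length(num),
                 n_blocks = as.integer(block_count),
                 n_skipped = n_skipped,
                 status = if (is.na(jk$z)) "zero jackknife SE" else "ok"),
            class = "trio_result")
}

#' @export
print.trio_result <- function(x, ...) {
  tr <- x$trio
  cat("<trio_result> (", tr[["P1"]], ",", tr[["P2"]], ";", tr[["P3"]],
      "|", tr[["O"]], ")\n", sep = " ")
  if (!is.null(x$D)) {
    cat(sprintf("  D = %.4f (SE %.4f, Z %.2f)%s\n", x$D, x$SE_D, x$Z_D,
                if (isTRUE(x$significant_D)) " *" else ""))
  }
  if (!is.null(x$f4_ratio)) {
    cat(sprintf("  f4-ratio = %.4f (SE %.4f, Z %.2f)\n", x$f4_ratio,
                x$SE_f4, x$Z_f4))
  }
  cat("  sites:", x$n_sites_used, " blocks:", x$n_blocks, " status:",
      x$status, "\n")
  invisible(x)
}

#' D and f4-ratio for one trio as a one-row data.frame
#'
#' @inheritParams f4_ratio
#' @return One-row data.frame with the trio names, D, f4-ratio, their SEs,
#'   Z-scores and significance flags.
#' @export
trio_stats <- function(freqs, tr, seed = 1L, block_count = 20L) {
  d <- d_statistic(freqs, tr, block_count)
  f <- f4_ratio(freqs, tr, seed, block_count)
  data.frame(P1 = tr[["P1"]], P2 = tr[["P2"]], P3 = tr[["P3"]],
             O = tr[["O"]], D = d$D, SE_D = d$SE_D, Z_D = d$Z_D,
             significant_D = d$significant_D, f4_ratio = f$f4_ratio,
             SE_f4 = f$SE_f4, Z_f4 = f$Z_f4,
             n_sites = d$n_sites_used, n_blocks = d$n_blocks,
             stringsAsFactors = FALSE)
}

#' Summarize trio results per (P2, P3) pair
#'
#' For each ordered receptor-donor pair, reports the maximum D and the
#' maximum f4-ratio across the P1 choices, each with its provenance trio
#' and significance flag (the two maxima may come from different trios).
#'
#' @param results data.frame of [trio_stats()] rows.
#' @return data.frame with one row per (P2, P3) pair.
#' @export
summarize_pairs <- function(results) {
  stopifnot(all(c("P1", "P2", "P3", "D", "f4_ratio") %in% names(results)))
  pairs <- unique(results[, c("P2", "P3")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- results[results$P2 == pairs$P2[i] & results$P3 == pairs$P3[i], ,
                   drop = FALSE]
    # undefined estimates rank lowest; an all-NA pair keeps NA maxima
    iD <- which.max(ifelse(is.na(sub$D), -Inf, sub$D))
    iF <- which.max(ifelse(is.na(sub$f4_ratio), -Inf, sub$f4_ratio))
    if (length(iD) == 0L) iD <- 1L
    if (length(iF) == 0L) iF <- 1L
    data.frame(P2 = pairs$P2[i], P3 = pairs$P3[i],
               max_D = sub$D[iD], P1_for_D = sub$P1[iD],
               Z_D = sub$Z_D[iD], significant_D = sub$significant_D[iD],
               max_f4 = sub$f4_ratio[iF], P1_for_f4 = sub$P1[iF],
               Z_f4 = sub$Z_f4[iF],
               n_trios = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
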