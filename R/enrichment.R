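# Sweep-window selection, gene/region intersection, Fisher-exact
# enrichment and circular-permutation overlap nulls.

#' Select top-percentile windows of a score track
#'
#' Windows with value strictly greater than the `q`-quantile (inverse-ECDF
#' quantile, type 1) of the non-missing values are selected and merged
#' into regions. Strict ">" means ties at the threshold are excluded and a
#' constant track selects nothing; with all-distinct values exactly
#' `floor((1-q) * m)` of the `m` windows are selected.
#'
#' @param track A [feature_track()] (e.g. averaged XP-CLR or XP-EHH
#'   scores).
#' @param q Quantile, default 0.95 (the conventional top-5% rule).
#' @return A [region_set()] with attributes `threshold` and `n_selected`.
#' @export
top_percentile_windows <- function(track, q = 0.95) {
  v <- track$value
  if (all(is.na(v))) stop("track has no non-missing values")
  threshold <- quantile(v, q, na.rm = TRUE, type = 1, names = FALSE)
  sel <- !is.na(v) & v > threshold
  region_set(track[sel, c("chrom", "start", "end"), drop = FALSE],
             threshold = threshold, n_selected = sum(sel))
}

#' Candidate sweep regions supported by two selection scans
#'
#' The base-pair intersection of the top-percentile regions of two score
#' tracks (e.g. XP-CLR and XP-EHH), keeping only signals identified by
#' both methods.
#'
#' @param track_a,track_b [feature_track()] objects on the same coordinate
#'   frame.
#' @param q Quantile passed to [top_percentile_windows()].
#' @return A [region_set()].
#' @export
sweep_regions <- function(track_a, track_b, q = 0.95) {
  ra <- top_percentile_windows(track_a, q)
  rb <- top_percentile_windows(track_b, q)
  if (nrow(ra) > 0 && nrow(rb) > 0 &&
      length(intersect(unique(ra$chrom), unique(rb$chrom))) == 0L) {
    stop("sweep tracks share no chromosome names")
  }
  region_set(intersect_intervals(ra, rb))
}

#' Gene models table
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (0-based half-open coordinates).
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  if (any(df$end <= df$start)) stop("gene with end <= start")
  if (!"strand" %in% names(df)) df$strand <- "+"
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_table", "data.frame"))
}

#' Read gene models from a BED or TSV file
#'
#' BED: chrom, start, end, name\[, score, strand\]. TSV: gene_id, chrom,
#' start, end\[, strand\] with no header. Coordinates 0-based half-open.
#'
#' @param path File path (`.bed` treated as BED, otherwise TSV).
#' @return A [gene_table()].
#' @export
read_gene_models <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gene_table(data.frame(gene_id = as.character(raw[[4]]),
                          chrom = as.character(raw[[1]]),
                          start = raw[[2]], end = raw[[3]],
                          strand = if (ncol(raw) >= 6) raw[[6]] else "+",
                          stringsAsFactors = FALSE))
  } else {
    gene_table(data.frame(gene_id = as.character(raw[[1]]),
                          chrom = as.character(raw[[2]]),
                          start = raw[[3]], end = raw[[4]],
                          strand = if (ncol(raw) >= 5) raw[[5]] else "+",
                          stringsAsFactors = FALSE))
  }
}

#' Genes overlapping a region set
#'
#' A gene is affected iff its span overlaps any region by at least 1 bp
#' (half-open coordinates: a gene abutting a region end does not overlap).
#'
#' @param genes A [gene_table()].
#' @param regions A [region_set()].
#' @return Character vector of gene ids, deduplicated and sorted.
#' @export
genes_in_regions <- function(genes, regions) {
  hit <- overlaps_any(genes, regions)
  sort(unique(genes$gene_id[hit]))
}

# One-sided P(X >= k) and minimum-likelihood two-sided p for a
# hypergeometric 2x2 table, computed from the exact distribution.
hyper_pvals <- function(k, n, K, N) {
  p_one <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  kmin <- max(0, n + K - N)
  kmax <- min(n, K)
  d <- dhyper(kmin:kmax, K, N - K, n)
  d_obs <- dhyper(k, K, N - K, n)
  p_two <- sum(d[d <= d_obs * (1 + 1e-7)])
  c(one = p_one, two = min(p_two, 1))
}

#' Fisher's exact enrichment test for a 2x2 gene-set table
#'
#' Builds the table `[[k, n-k], [K-k, N-n-(K-k)]]` -- `k` annotated genes
#' among `n` selected, against `K` annotated among `N` background -- and
#' computes the exact hypergeometric one-sided enrichment p-value
#' `P(X >= k)` and the minimum-likelihood two-sided p-value, with the
#' conditional maximum-likelihood odds ratio.
#'
#' @param k Annotated genes in the selected set.
#' @param n Selected set size.
#' @param K Annotated genes in the background.
#' @param N Background size.
#' @return A list of class `contingency_result`: `table`, `odds_ratio`,
#'   `p_one_sided`, `p_two_sided`, `orientation`.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0)
  if (k > min(n, K) || n > N || K > N || k < n + K - N) {
    stop("inconsistent 2x2 margins: k=", k, " n=", n, " K=", K, " N=", N)
  }
  tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2, byrow = TRUE,
                dimnames = list(c("selected", "background"),
                                c("annotated", "other")))
  p <- hyper_pvals(k, n, K, N)
  or <- unname(fisher.test(tab)$estimate)
  structure(list(table = tab, odds_ratio = or,
                 p_one_sided = unname(p["one"]),
                 p_two_sided = unname(p["two"]),
                 orientation = "enrichment (P(X >= k))"),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>\n")
  print(x$table)
  cat(sprintf("  OR = %.3f  one-sided p = %.4g  two-sided p = %.4g\n",
              x$odds_ratio, x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Bonferroni correction for a family of enrichment tests
#'
#' Convenience wrapper for user-supplied gene-set families: runs
#' [fisher_enrichment()] per row and Bonferroni-adjusts the one-sided
#' p-values.
#'
#' @param sets data.frame with columns `set`, `k`, `n`, `K`, `N`.
#' @return data.frame with per-set odds ratio, raw and Bonferroni-adjusted
#'   p-values.
#' @export
enrichment_family <- function(sets) {
  stopifnot(all(c("set", "k", "n", "K", "N") %in% names(sets)))
  res <- lapply(seq_len(nrow(sets)), function(i) {
    fe <- fisher_enrichment(sets$k[i], sets$n[i], sets$K[i], sets$N[i])
    data.frame(set = sets$set[i], odds_ratio = fe$odds_ratio,
               p_one_sided = fe$p_one_sided, p_two_sided = fe$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- p.adjust(out$p_one_sided, method = "bonferroni")
  out
}

# Circularly rotate a region set on each chromosome by the given offsets.
rotate_regions <- function(regions, chrom_lengths, offsets) {
  if (nrow(regions) == 0L) return(regions)
  rows <- lapply(unique(regions$chrom), function(ch) {
    L <- chrom_lengths[[ch]]
    off <- offsets[[ch]]
    sub <- regions[regions$chrom == ch, , drop = FALSE]
    s <- (sub$start + off) %% L
    e <- s + (sub$end - sub$start)
    wrap <- e > L
    out <- data.frame(chrom = ch,
                      start = c(s[!wrap], s[wrap], rep(0, sum(wrap))),
                      end = c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L))
    out[out$end > out$start, , drop = FALSE]
  })
  region_set(do.call(rbind, rows))
}

#' Circular-permutation test of region overlap
#'
#' Rotates set `b` circularly and independently on each chromosome by
#' uniform offsets `n_perm` times and compares the permuted base-pair
#' overlaps with the observed one. Unlike a window-level Fisher test, the
#' rotation null preserves the autocorrelation (size and spacing) of both
#' region sets. The empirical p-value is
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @param a,b [region_set()] objects.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Number of rotations (>= 1).
#' @param seed Integer seed.
#' @return List with `observed_bp`, `p_value`, `n_perm` and the permuted
#'   overlap vector `perm_bp`.
#' @export
permutation_overlap <- function(a, b, chrom_lengths, n_perm = 999L,
                                seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  missing_chr <- setdiff(unique(c(a$chrom, b$chrom)), names(chrom_lengths))
  if (length(missing_chr)) {
    stop("chromosome lengths missing for: ",
         paste(missing_chr, collapse = ", "))
  }
  obs <- interval_span(intersect_intervals(a, b))
  perm_bp <- with_seed(substream_seed(seed, "rotation"), {
    vapply(seq_len(n_perm), function(i) {
      offs <- lapply(chrom_lengths, function(L) runif(1, 0, L))
      interval_span(intersect_intervals(a, rotate_regions(b, chrom_lengths,
                                                          offs)))
    }, numeric(1))
  })
  list(observed_bp = obs,
       p_value = (1 + sum(perm_bp >= obs)) / (n_perm + 1),
       n_perm = n_perm, perm_bp = perm_bp)
}
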