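# In-code fixture builders shared across test files.

# A genotype matrix from a dosage matrix; populations given per sample.
gm_from_dosages <- function(dos, pops, chrom = "chr1",
                            pos = NULL, ref = "A", alt = "T", dp = NULL) {
  n <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(colnames(dos))) {
    colnames(dos) <- paste0("s", seq_len(ncol(dos)))
  }
  storage.mode(dos) <- "integer"
  genotype_matrix(
    data.frame(chrom = rep(chrom, length.out = n), pos = pos,
               ref = rep(ref, length.out = n),
               alt = rep(alt, length.out = n), stringsAsFactors = FALSE),
    dos, dp = dp,
    popmap = data.frame(sample = colnames(dos), population = pops,
                        stringsAsFactors = FALSE))
}

# A frequency table built directly from per-population frequencies
# (no attached genotype matrix; enough for D and window scans).
freqs_from_p <- function(p1, p2, p3, pO, chrom = "chr1", pos = NULL) {
  n <- length(p1)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  out <- data.frame(chrom = rep(chrom, length.out = n), pos = pos,
                    ref = "A", alt = "T", derived = "T", tie = FALSE,
                    p_P1 = p1, n_P1 = 20L, p_P2 = p2, n_P2 = 20L,
                    p_P3 = p3, n_P3 = 20L, p_O = pO, n_O = 20L,
                    stringsAsFactors = FALSE)
  attr(out, "populations") <- c("P1", "P2", "P3", "O")
  attr(out, "outgroup") <- "O"
  class(out) <- c("freq_table", "data.frame")
  out
}

# Full in-memory synthetic analysis path: simulate, merge across ploidy,
# polarized frequencies. Returns the pieces used by most experiments.
sim_lineage <- function(cfg) {
  f <- sample_tree_frequencies(cfg)
  tr <- place_introgression_tracts(cfg)
  s <- sample_genotypes(f, tr, cfg)
  m1 <- merge_lineage(s$cohorts$donor, s$cohorts$outgroup, NULL)
  m2 <- merge_lineage(m1, s$cohorts$tetraploid,
                      synteny_invert(s$synteny))
  list(cfg = cfg, truth_freqs = f, tracts = tr, sim = s, merged = m2,
       freqs = allele_frequencies(m2, outgroup = "O"),
       chrom_lengths = stats::setNames(rep(cfg$chrom_length,
                                           cfg$n_chromosomes),
                                       paste0("chr",
                                              seq_len(cfg$n_chromosomes))))
}

canonical_trio <- function() trio("P1", "P2", "P3", "O")

# A small window-scores object built by hand for region-calling tests.
scores_from_fdm <- function(fdm, chrom = "chr1", start = NULL,
                            width = 10000L, valid = TRUE) {
  n <- length(fdm)
  if (is.null(start)) start <- (seq_len(n) - 1L) * width
  out <- data.frame(chrom = rep(chrom, length.out = n), start = start,
                    end = start + width, n_sites = 10L, D_window = 0,
                    fd = 0, fd_zeroed = FALSE, fdM = fdm,
                    valid = rep(valid, length.out = n),
                    stringsAsFactors = FALSE)
  class(out) <- c("window_scores", "data.frame")
  out
}
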