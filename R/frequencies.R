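# Per-site, per-population derived-allele frequencies: the substrate of
# all four-taxon introgression statistics.

#' Derived-allele frequency table
#'
#' The derived allele at each site is the allele that is *minor in the
#' outgroup* (ties broken toward ALT, with the tie recorded); frequencies
#' and called-allele counts are computed per population ignoring missing
#' genotypes. Sites whose outgroup genotypes are all missing are dropped
#' and counted.
#'
#' @param gm A [genotype_matrix].
#' @param populations Populations to tabulate; defaults to every
#'   population in the popmap.
#' @param outgroup Name of the outgroup population (must be non-empty).
#' @return A data.frame of class `freq_table` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `derived`, `tie` and, per population `P`, `p_P`
#'   (derived-allele frequency, `NA` when no alleles called) and `n_P`
#'   (called allele count). The source genotype matrix is attached as
#'   attribute `gm` (used by [f4_ratio()] for the donor half-split);
#'   attribute `n_dropped_outgroup` counts dropped sites.
#' @export
allele_frequencies <- function(gm, populations = NULL, outgroup) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- populations %||% unique(gm$popmap$population)
  if (!outgroup %in% gm$popmap$population) {
    stop("outgroup population not present: ", outgroup)
  }
  pops <- union(pops, outgroup)
  for (p in pops) {
    if (length(gm_samples_of(gm, p)) == 0L) {
      stop("population with zero samples: ", p)
    }
  }
  alt_freq <- function(pop) {
    g <- gm$geno[, gm_samples_of(gm, pop), drop = FALSE]
    called <- rowSums(!is.na(g))
    n <- 2L * called
    p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
    list(p = p, n = n)
  }
  og <- alt_freq(outgroup)
  keep <- og$n > 0
  n_drop <- sum(!keep)

  pO_alt <- og$p[keep]
  derived_is_alt <- pO_alt <= 0.5 # tie (0.5) broken toward ALT
  tie <- pO_alt == 0.5

  out <- data.frame(chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
                    ref = gm$sites$ref[keep], alt = gm$sites$alt[keep],
                    derived = ifelse(derived_is_alt, gm$sites$alt[keep],
                                     gm$sites$ref[keep]),
                    tie = tie, stringsAsFactors = FALSE)
  for (p in pops) {
    af <- alt_freq(p)
    pk <- af$p[keep]
    out[[paste0("p_", p)]] <- ifelse(derived_is_alt, pk, 1 - pk)
    out[[paste0("n_", p)]] <- af$n[keep]
  }
  attr(out, "populations") <- pops
  attr(out, "outgroup") <- outgroup
  attr(out, "gm") <- gm_subset_sites(gm, which(keep))
  attr(out, "n_dropped_outgroup") <- n_drop
  class(out) <- c("freq_table", "data.frame")
  out
}

freq_col <- function(freqs, pop, what = "p") {
  col <- paste0(what, "_", pop)
  if (!col %in% names(freqs)) {
    stop("population not tabulated in frequency table: ", pop)
  }
  freqs[[col]]
}
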