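# Site-level quality filters mirroring a standard VCFtools-style pipeline.

#' Site filter specification
#'
#' Defaults follow common resequencing practice: biallelic SNPs only,
#' missing rate at most 15%, minor allele count at least 3, site mean depth
#' within \[3, 40\], and genotype-level depth within \[3, 40\] (genotypes
#' outside the range are set missing before the missing-rate rule, the
#' VCFtools order).
#'
#' @param biallelic_only Drop multi-allelic records.
#' @param max_missing Maximum tolerated per-site missing genotype fraction;
#'   sites with missing rate strictly greater are removed.
#' @param min_mac Minimum minor-allele count over called genotypes.
#' @param min_mean_dp,max_mean_dp Bounds on per-site mean depth (inclusive).
#' @param min_dp,max_dp Genotype-level depth bounds; genotypes outside are
#'   recoded missing. Set to `NULL` to disable.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(biallelic_only = TRUE, max_missing = 0.15,
                        min_mac = 3L, min_mean_dp = 3, max_mean_dp = 40,
                        min_dp = 3, max_dp = 40) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_mac >= 0,
            min_mean_dp <= max_mean_dp)
  structure(list(biallelic_only = biallelic_only, max_missing = max_missing,
                 min_mac = as.integer(min_mac), min_mean_dp = min_mean_dp,
                 max_mean_dp = max_mean_dp, min_dp = min_dp,
                 max_dp = max_dp),
            class = "filter_spec")
}

#' Apply site filters to a genotype matrix
#'
#' Rules are applied per site: biallelic, missing rate, minor-allele count,
#' and mean-depth bounds (skipped with a warning when no depth is stored).
#' Removal counts are attributed to the first failing rule in that order,
#' so they sum to the number of removed sites; they are returned in the
#' `removal_counts` attribute of the result.
#'
#' @param gm A [genotype_matrix].
#' @param spec A [filter_spec()].
#' @return The filtered [genotype_matrix] with attribute `removal_counts`.
#' @export
apply_site_filters <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "filter_spec"))
  geno <- gm$geno
  dp <- gm$dp
  # genotype-level depth recode first (mirrors --minDP/--maxDP)
  if (!is.null(dp) && !is.null(spec$min_dp)) {
    bad <- !is.na(dp) & (dp < spec$min_dp | dp > spec$max_dp)
    geno[bad] <- NA_integer_
  }
  n_samp <- ncol(geno)
  called <- rowSums(!is.na(geno))
  miss_frac <- 1 - called / n_samp
  alt <- rowSums(geno, na.rm = TRUE)
  mac <- pmin(alt, 2L * called - alt)

  ok_bi <- gm$sites$biallelic | !spec$biallelic_only
  ok_miss <- miss_frac <= spec$max_missing
  ok_mac <- mac >= spec$min_mac
  if (is.null(dp)) {
    warning("no genotype depths stored; mean-depth filter skipped")
    ok_dp <- rep(TRUE, nrow(geno))
  } else {
    mean_dp <- rowMeans(dp, na.rm = TRUE)
    ok_dp <- !is.na(mean_dp) & mean_dp >= spec$min_mean_dp &
      mean_dp <= spec$max_mean_dp
  }

  first_fail <- rep(NA_character_, nrow(geno))
  first_fail[!ok_dp] <- "mean_depth"
  first_fail[!ok_mac] <- "mac"
  first_fail[!ok_miss] <- "missing_rate"
  first_fail[!ok_bi] <- "not_biallelic"
  keep <- is.na(first_fail)
  counts <- c(input = nrow(geno),
              not_biallelic = sum(first_fail == "not_biallelic", na.rm = TRUE),
              missing_rate = sum(first_fail == "missing_rate", na.rm = TRUE),
              mac = sum(first_fail == "mac", na.rm = TRUE),
              mean_depth = sum(first_fail == "mean_depth", na.rm = TRUE),
              output = sum(keep))
  if (!any(keep)) warning("all sites removed by filters")
  out <- genotype_matrix(gm$sites[keep, , drop = FALSE],
                         geno[keep, , drop = FALSE],
                         dp = if (!is.null(dp)) dp[keep, , drop = FALSE],
                         popmap = gm$popmap)
  attr(out, "removal_counts") <- counts
  out
}
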