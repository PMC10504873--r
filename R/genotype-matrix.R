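# GenotypeMatrix: sites x samples diploid allele-dosage matrix with
# per-site metadata and a sample -> population map.

#' Construct a genotype matrix
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; an optional logical `biallelic` column flags multi-allelic
#'   records passed through for the filter stage.
#' @param geno Integer matrix (sites x samples) of ALT-allele dosages in
#'   `{0, 1, 2}` with `NA` for missing genotypes; column names are sample
#'   names.
#' @param dp Optional numeric matrix of per-genotype read depths with the
#'   same dimensions as `geno`.
#' @param popmap data.frame with columns `sample`, `population` covering
#'   every column of `geno` exactly once.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, dp = NULL, popmap) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites),
            !is.null(colnames(geno)))
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(geno)))
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  if (anyDuplicated(popmap$sample)) {
    stop("popmap assigns a sample to more than one population")
  }
  missing_pop <- setdiff(colnames(geno), popmap$sample)
  if (length(missing_pop)) {
    stop("samples without population assignment: ",
         paste(missing_pop, collapse = ", "))
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("duplicate sites in genotype matrix")
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) {
    sites <- sites[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[o, , drop = FALSE]
  }
  if (!"biallelic" %in% names(sites)) sites$biallelic <- TRUE
  rownames(sites) <- NULL
  popmap <- popmap[match(colnames(geno), popmap$sample), , drop = FALSE]
  rownames(popmap) <- NULL
  structure(list(sites = sites, geno = geno, dp = dp, popmap = popmap),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", ncol(x$geno),
      " samples (", length(unique(x$popmap$population)), " populations: ",
      paste(unique(x$popmap$population), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

gm_samples_of <- function(gm, pop) {
  gm$popmap$sample[gm$popmap$population == pop]
}

# per-site mean depth over called genotypes; NA when depth is absent
gm_mean_depth <- function(gm) {
  if (is.null(gm$dp)) return(rep(NA_real_, nrow(gm$sites)))
  rowMeans(gm$dp, na.rm = TRUE)
}

gm_subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE],
                  gm$geno[idx, , drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[idx, , drop = FALSE],
                  popmap = gm$popmap)
}
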