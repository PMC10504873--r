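# VCF and table I/O for cohort data.

#' Read a population map
#'
#' Two-column TSV (sample TAB population), no header.
#'
#' @param path File path.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  if (anyDuplicated(pm$sample)) {
    stop("popmap contains duplicate sample names: ", path)
  }
  pm
}

#' Read a cohort VCF into a genotype matrix
#'
#' Parses GT into ALT-allele dosages (missing genotypes preserved as `NA`)
#' and per-genotype DP when present. Multi-allelic records are passed
#' through flagged `biallelic = FALSE` for [apply_site_filters()]. Samples
#' absent from the population map are dropped with a warning.
#'
#' @param path VCF file (plain or gzipped).
#' @param popmap Either a path to a popmap TSV or a data.frame as returned
#'   by [read_popmap()].
#' @return A [genotype_matrix].
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch])) stop("VCF not sorted within ", ch)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = number of '1' alleles; genotypes containing '.' are missing;
  # alleles > 1 (multi-allelic calls) are kept as allele-1 counts and the
  # record is flagged non-biallelic for the filter stage
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dosage <- (a1 == "1") + (a2 == "1")
  dosage[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- NULL

  dp <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    rownames(dp) <- NULL
  }

  keep <- colnames(dosage) %in% popmap$sample
  if (any(!keep)) {
    warning(sum(!keep), " VCF sample(s) absent from popmap dropped: ",
            paste(head(colnames(dosage)[!keep], 5), collapse = ", "))
  }
  if (!any(keep)) stop("no VCF sample is present in the popmap")
  dosage <- dosage[, keep, drop = FALSE]
  if (!is.null(dp)) dp <- dp[, keep, drop = FALSE]

  alt <- fix[, "ALT"]
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = fix[, "REF"], alt = alt,
                      biallelic = !grepl(",", alt) & alt != ".",
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, dosage, dp = dp,
                  popmap = popmap[popmap$sample %in% colnames(dosage), ,
                                  drop = FALSE])
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT (unphased) and, when depths are present, per-genotype DP.
#' Output is deterministic (no timestamps), so identical matrices yield
#' byte-identical files.
#'
#' @param gm A [genotype_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  has_dp <- !is.null(gm$dp)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=interflow",
    paste0("##contig=<ID=", unique(gm$sites$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$geno)), collapse = "\t"))
  writeLines(header, con)
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt[is.na(gm$geno)] <- "./."
  if (has_dp) {
    gt <- matrix(paste0(gt, ":", ifelse(is.na(gm$dp), ".", gm$dp)),
                 nrow = nrow(gt))
  }
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".",
                if (has_dp) "GT:DP" else "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a windowed feature track
#'
#' Expects a headerless 4- or 5-column TSV/BED (`chrom`, `start`, `end`,
#' `value`[, `n_sites`]) with 0-based half-open coordinates. Unsorted input
#' is sorted with a warning; overlapping windows are rejected when the
#' feature is declared non-overlapping.
#'
#' @param path File path.
#' @param name Feature name stored on the track.
#' @param nonnegative Reject negative values (appropriate for rates such as
#'   the population recombination rate rho).
#' @param nonoverlapping Reject overlapping windows.
#' @return A data.frame of class `feature_track`.
#' @export
load_track <- function(path, name = basename(path), nonnegative = TRUE,
                       nonoverlapping = TRUE) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("track needs >= 4 columns: ", path)
  trk <- data.frame(chrom = as.character(raw[[1]]),
                    start = raw[[2]], end = raw[[3]], value = raw[[4]],
                    n_sites = if (ncol(raw) >= 5) raw[[5]] else NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.numeric(trk$start) || !is.numeric(trk$end) ||
      !is.numeric(trk$value)) {
    stop("non-numeric coordinates or values in track: ", path)
  }
  if (nonnegative && any(trk$value < 0, na.rm = TRUE)) {
    stop("negative values in track declared non-negative: ", path)
  }
  o <- order(trk$chrom, trk$start)
  if (is.unsorted(o)) {
    warning("track not sorted; sorting: ", path)
    trk <- trk[o, , drop = FALSE]
  }
  if (nonoverlapping) {
    for (ch in unique(trk$chrom)) {
      s <- trk[trk$chrom == ch, ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("overlapping windows in non-overlapping track: ", path)
      }
    }
  }
  feature_track(trk, name = name)
}

#' Construct a feature track from a data.frame
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value` and
#'   optionally `n_sites`.
#' @param name,units Feature name and units metadata.
#' @return A data.frame of class `feature_track`.
#' @export
feature_track <- function(df, name = "feature", units = "") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (!"n_sites" %in% names(df)) df$n_sites <- NA_integer_
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, units = units,
            class = c("feature_track", "data.frame"))
}

#' Write a feature track as a 5-column TSV
#' @param track A [feature_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "value", "n_sites")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
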