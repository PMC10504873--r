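# One-to-one syntenic blocks: strand-aware cross-ploidy coordinate mapping
# between the diploid genome frame and the tetraploid subgenome frame.

#' Construct and validate a syntenic block map
#'
#' Blocks are one-to-one interval pairs in 0-based half-open coordinates:
#' no overlaps on either side, equal src/dst lengths per pair and strand in
#' `{+,-}`.
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `dst_chrom`, `dst_start`, `dst_end`, `strand`.
#' @return A data.frame of class `synteny_map`.
#' @export
synteny_map <- function(blocks) {
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start",
            "dst_end", "strand")
  stopifnot(is.data.frame(blocks), all(need %in% names(blocks)))
  if (!all(blocks$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  src_len <- blocks$src_end - blocks$src_start
  dst_len <- blocks$dst_end - blocks$dst_start
  if (any(src_len <= 0) || any(dst_len <= 0)) stop("empty or inverted block")
  if (any(src_len != dst_len)) {
    stop("src and dst lengths differ for ", sum(src_len != dst_len),
         " block(s)")
  }
  check_disjoint <- function(chrom, start, end, side) {
    for (ch in unique(chrom)) {
      i <- chrom == ch
      o <- order(start[i])
      s <- start[i][o]; e <- end[i][o]
      if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
        stop("overlapping ", side, " blocks on ", ch)
      }
    }
  }
  check_disjoint(blocks$src_chrom, blocks$src_start, blocks$src_end, "src")
  check_disjoint(blocks$dst_chrom, blocks$dst_start, blocks$dst_end, "dst")
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), need]
  rownames(blocks) <- NULL
  structure(blocks, class = c("synteny_map", "data.frame"))
}

#' Read / write the 7-column syntenic block TSV
#'
#' Columns: src_chrom, src_start, src_end, dst_chrom, dst_start, dst_end,
#' strand; 0-based half-open; no header.
#'
#' @param path File path.
#' @return [read_synteny()] returns a [synteny_map()]; [write_synteny()]
#'   returns `path` invisibly.
#' @export
read_synteny <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("src_chrom", "src_start", "src_end",
                                "dst_chrom", "dst_start", "dst_end",
                                "strand"),
                  stringsAsFactors = FALSE)
  synteny_map(b)
}

#' @rdname read_synteny
#' @param map A [synteny_map()].
#' @export
write_synteny <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Swap the two sides of a syntenic block map
#'
#' @param map A [synteny_map()].
#' @return A [synteny_map()] mapping in the opposite direction.
#' @export
synteny_invert <- function(map) {
  synteny_map(data.frame(src_chrom = map$dst_chrom,
                         src_start = map$dst_start, src_end = map$dst_end,
                         dst_chrom = map$src_chrom,
                         dst_start = map$src_start, dst_end = map$src_end,
                         strand = map$strand, stringsAsFactors = FALSE))
}

#' Map positions through syntenic blocks
#'
#' Positions are 0-based. Inside a block the mapping is by offset on the
#' `+` strand and reflected, `dst_end - (pos - src_start) - 1`, on the `-`
#' strand; positions outside all blocks map to `NA`.
#'
#' @param map A [synteny_map()].
#' @param chrom,pos Vectors of source-frame chromosome names and 0-based
#'   positions.
#' @return data.frame with columns `chrom`, `pos`, `strand` (`NA` rows for
#'   unmapped positions).
#' @export
map_position <- function(map, chrom, pos) {
  stopifnot(inherits(map, "synteny_map"), length(chrom) == length(pos))
  sub <- data.frame(chrom = map$src_chrom, start = map$src_start,
                    end = map$src_end)
  idx <- point_in_interval(sub, chrom, pos)
  out <- data.frame(chrom = rep(NA_character_, length(pos)),
                    pos = rep(NA_real_, length(pos)),
                    strand = rep(NA_character_, length(pos)),
                    stringsAsFactors = FALSE)
  hit <- !is.na(idx)
  if (any(hit)) {
    b <- map[idx[hit], , drop = FALSE]
    plus <- b$strand == "+"
    mapped <- ifelse(plus,
                     b$dst_start + (pos[hit] - b$src_start),
                     b$dst_end - (pos[hit] - b$src_start) - 1)
    out$chrom[hit] <- b$dst_chrom
    out$pos[hit] <- mapped
    out$strand[hit] <- b$strand
  }
  out
}

complement_allele <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Merge diploid and tetraploid-subgenome cohorts into one lineage dataset
#'
#' Maps `gm_other`'s site coordinates into `gm_ref`'s frame through the
#' syntenic block map (whose src side must be `gm_other`'s frame; see
#' [synteny_invert()]), keeps only sites present in both cohorts, and
#' reconciles alleles: on `-` strand blocks `gm_other`'s alleles are
#' complemented; sites whose REF/ALT pair matches are kept as is, swapped
#' pairs are kept with dosages flipped, anything else is dropped and
#' counted. The merged sample set is the union of both cohorts.
#'
#' @param gm_ref [genotype_matrix] already on the target coordinate frame.
#' @param gm_other [genotype_matrix] to be mapped across; pass
#'   `blocks = NULL` when both cohorts share a frame (identity mapping).
#' @param blocks A [synteny_map()] from `gm_other`'s frame to `gm_ref`'s
#'   frame, or `NULL`.
#' @return The merged [genotype_matrix] on `gm_ref`'s frame, with attribute
#'   `merge_counts` (sites unmapped / allele-dropped / flipped / kept).
#' @export
merge_lineage <- function(gm_ref, gm_other, blocks = NULL) {
  stopifnot(inherits(gm_ref, "genotype_matrix"),
            inherits(gm_other, "genotype_matrix"))
  if (!is.null(blocks)) {
    stopifnot(inherits(blocks, "synteny_map"))
    if (nrow(blocks) == 0L) stop("empty syntenic block map")
  }
  dup <- intersect(colnames(gm_ref$geno), colnames(gm_other$geno))
  if (length(dup)) {
    stop("duplicate sample names across cohorts: ",
         paste(head(dup, 5), collapse = ", "))
  }
  sites_o <- gm_other$sites
  if (is.null(blocks)) {
    mapped <- data.frame(chrom = sites_o$chrom, pos = sites_o$pos - 1,
                         strand = "+", stringsAsFactors = FALSE)
  } else {
    mapped <- map_position(blocks, sites_o$chrom, sites_o$pos - 1)
  }
  n_unmapped <- sum(is.na(mapped$pos))
  keep_o <- which(!is.na(mapped$pos))

  ref_o <- sites_o$ref[keep_o]
  alt_o <- sites_o$alt[keep_o]
  minus <- mapped$strand[keep_o] == "-"
  ref_o[minus] <- complement_allele(ref_o[minus])
  alt_o[minus] <- complement_allele(alt_o[minus])
  valid_nuc <- !minus | (ref_o %in% c("A", "C", "G", "T") &
                           alt_o %in% c("A", "C", "G", "T"))

  key_ref <- paste(gm_ref$sites$chrom, gm_ref$sites$pos)
  key_o <- paste(mapped$chrom[keep_o], mapped$pos[keep_o] + 1)
  m <- match(key_o, key_ref)
  shared <- !is.na(m) & valid_nuc

  i_ref <- m[shared]
  i_o <- keep_o[shared]
  same <- gm_ref$sites$ref[i_ref] == ref_o[shared] &
    gm_ref$sites$alt[i_ref] == alt_o[shared]
  swapped <- gm_ref$sites$ref[i_ref] == alt_o[shared] &
    gm_ref$sites$alt[i_ref] == ref_o[shared] & !same
  usable <- same | swapped
  n_allele_drop <- sum(!usable) + sum(!is.na(m) & !valid_nuc)

  i_ref <- i_ref[usable]
  i_o <- i_o[usable]
  flip <- swapped[usable]

  if (length(i_ref) == 0L) {
    warning("no shared sites after coordinate mapping and allele ",
            "reconciliation; merge is empty")
  }
  geno_o <- gm_other$geno[i_o, , drop = FALSE]
  if (any(flip)) {
    geno_o[flip, ] <- 2L - geno_o[flip, , drop = FALSE]
  }
  geno <- cbind(gm_ref$geno[i_ref, , drop = FALSE], geno_o)
  dp <- if (!is.null(gm_ref$dp) && !is.null(gm_other$dp)) {
    cbind(gm_ref$dp[i_ref, , drop = FALSE],
          gm_other$dp[i_o, , drop = FALSE])
  }
  popmap <- rbind(gm_ref$popmap, gm_other$popmap)
  out <- genotype_matrix(gm_ref$sites[i_ref, , drop = FALSE], geno,
                         dp = dp, popmap = popmap)
  attr(out, "merge_counts") <- c(
    other_sites = nrow(sites_o), unmapped = n_unmapped,
    allele_dropped = n_allele_drop, flipped = sum(flip),
    merged = length(i_ref))
  out
}
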