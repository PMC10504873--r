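# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' One master seed drives a run; every stochastic stage derives its own seed
#' from `(seed, label)` so stages are independently reproducible and
#' reordering stages cannot silently change results.
#'
#' @param seed Integer master seed.
#' @param label Character stage label, e.g. `"tracts"`.
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps everything in 32-bit integer range
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Non-overlapping windows [start, end) covering each chromosome; the last
# window is truncated at the chromosome end.
tile_windows <- function(chrom_lengths, window) {
  stopifnot(window > 0, !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, L - 1), by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sliding window starts: 0, step, ..., last start with start + window <= L.
# A chromosome shorter than `window` yields a single window [0, L).
sliding_starts <- function(L, window, step) {
  if (L < window) return(0)
  seq(0, L - window, by = step)
}

# Sum per-site values over half-open windows [start, end) given 0-based
# site coordinates `pos0` (sorted). Returns a matrix with one column per
# value vector plus a site count. O(n log n) via cumulative sums.
window_sums <- function(pos0, values, starts, ends) {
  stopifnot(!is.unsorted(pos0))
  values <- as.matrix(values)
  cs <- apply(values, 2, function(v) cumsum(ifelse(is.na(v), 0, v)))
  cs <- rbind(0, cs)
  lo <- findInterval(starts - 1L, pos0)
  hi <- findInterval(ends - 1L, pos0)
  sums <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  colnames(sums) <- colnames(values)
  list(sums = sums, n = hi - lo)
}

# chrom-aware interval algebra on data.frames with 0-based half-open
# chrom/start/end columns, built on IRanges per chromosome.

df_to_ir <- function(df) {
  # IRanges is 1-based closed; [start, end) -> start+1 .. end
  split(IRanges::IRanges(start = df$start + 1L, end = df$end),
        factor(df$chrom, levels = unique(df$chrom)))
}

ir_to_df <- function(irl) {
  rows <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

reduce_intervals <- function(df, min_gap = 0L) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  irl <- df_to_ir(df)
  red <- lapply(irl, IRanges::reduce, min.gapwidth = min_gap + 1L)
  ir_to_df(red)
}

intersect_intervals <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  rows <- lapply(chroms, function(ch) {
    ia <- IRanges::IRanges(a$start[a$chrom == ch] + 1L, a$end[a$chrom == ch])
    ib <- IRanges::IRanges(b$start[b$chrom == ch] + 1L, b$end[b$chrom == ch])
    ovl <- IRanges::intersect(ia, ib)
    if (length(ovl) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ovl) - 1L,
               end = IRanges::end(ovl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

interval_span <- function(df) sum(as.numeric(df$end) - as.numeric(df$start))

# For each query interval, does it overlap any subject interval by >= 1 bp?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  hit <- rep(FALSE, nrow(query))
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    iq <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    is <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    hit[qi] <- IRanges::overlapsAny(iq, is)
  }
  hit
}

# Point-in-interval lookup: index of the subject interval containing each
# 0-based point, NA when none (subject intervals assumed disjoint).
point_in_interval <- function(subject, chrom, point) {
  idx <- rep(NA_integer_, length(point))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    ip <- IRanges::IRanges(point[qi] + 1L, width = 1L)
    is <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    ovl <- IRanges::findOverlaps(ip, is, select = "first")
    idx[qi] <- si[ovl]
  }
  idx
}

file_checksums <- function(paths) {
  data.frame(file = basename(paths),
             bytes = as.integer(file.size(paths)),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
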