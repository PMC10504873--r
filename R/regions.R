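# Region calling from window scores and the interval algebra used by all
# downstream contrasts. Coordinates are 0-based half-open throughout.

#' Construct a region set
#'
#' Intervals are sorted and merged (overlapping or bookended intervals
#' coalesce), so construction is idempotent and the total span equals the
#' span of the input union.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param ... Provenance fields stored as attributes (e.g. `threshold`,
#'   `trio`, `source`).
#' @param min_gap Merge intervals separated by at most this many bp
#'   (default 0: only overlapping/bookended intervals merge).
#' @return data.frame of class `region_set`.
#' @export
region_set <- function(df, ..., min_gap = 0L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$end < df$start)) stop("interval with end < start")
  merged <- reduce_intervals(df, min_gap = min_gap)
  prov <- list(...)
  for (nm in names(prov)) attr(merged, nm) <- prov[[nm]]
  class(merged) <- c("region_set", "data.frame")
  merged
}

#' Total base-pair span of a region set
#' @param regions A [region_set()].
#' @return Numeric span in bp.
#' @export
region_span <- function(regions) interval_span(regions)

#' Call putative introgressed regions from windowed fdM scores
#'
#' Selects the highest-`x` fraction of valid windows by fdM -- the
#' threshold is the `ceiling(x * m)`-th largest fdM value over the `m`
#' valid windows and every window with `fdM >= threshold` is selected
#' (ties included) -- then merges selected windows (overlapping or
#' bookended) into regions. `x` is normally set to the f4-ratio estimate
#' for the trio, which calibrates the called span to the estimated
#' admixture proportion.
#'
#' @param windows A [window_scan()] result.
#' @param x Fraction of valid windows to select, in `(0, 1]`.
#' @param min_gap Merge gap passed to [region_set()].
#' @return A [region_set()] with attributes `threshold`, `x`,
#'   `n_selected`, `trio`.
#' @export
call_introgressed <- function(windows, x, min_gap = 0L) {
  stopifnot(inherits(windows, "window_scores"))
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1) {
    stop("x must be a fraction in (0, 1]")
  }
  valid <- windows[windows$valid, , drop = FALSE]
  if (nrow(valid) == 0L) {
    warning("no valid windows; returning an empty region set")
    return(region_set(valid[, c("chrom", "start", "end")],
                      threshold = NA_real_, x = x, n_selected = 0L,
                      trio = attr(windows, "trio")))
  }
  k <- ceiling(x * nrow(valid))
  threshold <- sort(valid$fdM, decreasing = TRUE)[k]
  sel <- valid[valid$fdM >= threshold, , drop = FALSE]
  region_set(sel[, c("chrom", "start", "end")], min_gap = min_gap,
             threshold = threshold, x = x, n_selected = nrow(sel),
             trio = attr(windows, "trio"))
}

#' Overlap two region sets
#'
#' @param a,b [region_set()] objects on the same coordinate frame (an
#'   error is raised when their chromosome namespaces are disjoint).
#' @return List with `intersection` (a [region_set()]), `n_a_touching`,
#'   `n_b_touching` (regions of one set overlapping the other) and the
#'   base-pair `jaccard` index.
#' @export
regions_overlap <- function(a, b) {
  if (nrow(a) > 0 && nrow(b) > 0 &&
      length(intersect(unique(a$chrom), unique(b$chrom))) == 0L) {
    stop("region sets share no chromosome names; ",
         "are they on the same coordinate frame?")
  }
  inter <- intersect_intervals(a, b)
  union_span <- region_span(region_set(rbind(a[, c("chrom", "start", "end")],
                                             b[, c("chrom", "start", "end")])))
  list(intersection = region_set(inter),
       n_a_touching = sum(overlaps_any(a, b)),
       n_b_touching = sum(overlaps_any(b, a)),
       jaccard = if (union_span > 0) interval_span(inter) / union_span else 0)
}

#' Classify windows as inside/outside a region set
#'
#' Default rule: a window is "in" iff its midpoint lies inside a region,
#' which avoids double-counting windows that straddle region edges;
#' `rule = "any"` labels a window "in" on any >= 1 bp overlap.
#'
#' @param windows data.frame with `chrom`, `start`, `end` columns
#'   (window scores or a feature track).
#' @param regions A [region_set()].
#' @param rule `"midpoint"` (default) or `"any"`.
#' @return Factor of labels `"in"`/`"out"` with a `counts` attribute.
#' @export
classify_windows <- function(windows, regions, rule = c("midpoint", "any")) {
  rule <- match.arg(rule)
  if (nrow(windows) == 0L) {
    return(structure(factor(character(), levels = c("in", "out")),
                     counts = c(`in` = 0L, out = 0L)))
  }
  if (nrow(regions) == 0L) {
    inside <- rep(FALSE, nrow(windows))
  } else if (rule == "midpoint") {
    mid <- floor((windows$start + windows$end) / 2)
    inside <- !is.na(point_in_interval(regions, windows$chrom, mid))
  } else {
    inside <- overlaps_any(windows, regions)
  }
  lab <- factor(ifelse(inside, "in", "out"), levels = c("in", "out"))
  attr(lab, "counts") <- c(`in` = sum(inside), out = sum(!inside))
  lab
}

#' Base-pair precision and recall of called regions against truth
#'
#' @param called A [region_set()] of called regions.
#' @param truth A [region_set()] (e.g. [truth_regions()]).
#' @return List with `precision`, `recall` and `jaccard`.
#' @export
region_precision_recall <- function(called, truth) {
  inter <- interval_span(intersect_intervals(called, truth))
  sc <- region_span(called)
  st <- region_span(truth)
  list(precision = if (sc > 0) inter / sc else NA_real_,
       recall = if (st > 0) inter / st else NA_real_,
       jaccard = if (sc + st - inter > 0) inter / (sc + st - inter)
                 else NA_real_)
}

#' Collapse truth tracts into a region set
#'
#' Unions the introgressed segments over all receptor haplotypes.
#'
#' @param tracts A [place_introgression_tracts()] result.
#' @return A [region_set()].
#' @export
truth_regions <- function(tracts) {
  region_set(tracts[, c("chrom", "start", "end")])
}

#' Read / write region sets as BED3+
#'
#' Provenance (threshold, x) is carried in columns 4-5 when present.
#'
#' @param path File path.
#' @return [read_regions()] returns a [region_set()]; [write_regions()]
#'   returns `path` invisibly.
#' @export
read_regions <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  region_set(data.frame(chrom = as.character(raw[[1]]), start = raw[[2]],
                        end = raw[[3]], stringsAsFactors = FALSE))
}

#' @rdname read_regions
#' @param regions A [region_set()].
#' @export
write_regions <- function(regions, path) {
  df <- as.data.frame(regions)[, c("chrom", "start", "end")]
  thr <- attr(regions, "threshold")
  x <- attr(regions, "x")
  if (!is.null(thr)) {
    df$threshold <- thr
    df$x <- x %||% NA_real_
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
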