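# Sliding-window fd / fdM introgression scan.

#' Sliding-window D, fd and fdM
#'
#' Scans the genome in windows of `window` bp advanced by `step` bp
#' (half-open coordinates; starts 0, step, ..., the last start with
#' `start + window <= L`). Per window, with `num = ABBA - BABA`:
#'
#' * `D_window = sum(num) / sum(ABBA + BABA)`;
#' * `fd = sum(num) / sum(num_D)` where `num_D` substitutes, at each site,
#'   both the P2 and P3 frequencies by the dynamic donor
#'   `pD = max(p2, p3)`; windows with `sum(num) <= 0` report `fd = 0` with
#'   the `fd_zeroed` flag (fd is defined only for P2-P3 excess);
#' * `fdM` is the symmetric extension: sites with `p2 >= p1` use the
#'   (P2,P3) dynamic donor in the denominator, sites with `p2 < p1` use the
#'   (P1,P3) dynamic donor with reversed sign, bounding `fdM` in `[-1, 1]`
#'   and making it suitable for scanning introgression in both directions.
#'
#' Windows with fewer than `min_sites` informative sites, or with a
#' non-positive fdM denominator, are flagged invalid.
#'
#' @inheritParams d_statistic
#' @param window,step Window and step size in bp.
#' @param min_sites Minimum informative sites per valid window.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @return data.frame of class `window_scores` with columns `chrom`,
#'   `start`, `end`, `n_sites`, `D_window`, `fd`, `fd_zeroed`, `fdM`,
#'   `valid`.
#' @export
window_scan <- function(freqs, tr, window = 10000L, step = 1000L,
                        min_sites = 5L, chrom_lengths = NULL) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  tf <- trio_freqs(freqs, tr)
  ok <- complete.cases(tf)
  chrom <- freqs$chrom[ok]
  pos0 <- freqs$pos[ok] - 1L
  p1 <- tf$p1[ok]; p2 <- tf$p2[ok]; p3 <- tf$p3[ok]; pO <- tf$pO[ok]

  pat <- site_patterns(p1, p2, p3, pO)
  num <- pat$abba - pat$baba
  denD <- pat$abba + pat$baba

  pd23 <- pmax(p2, p3)
  pat23 <- site_patterns(p1, pd23, pd23, pO)
  den_fd <- pat23$abba - pat23$baba

  pd13 <- pmax(p1, p3)
  pat13 <- site_patterns(pd13, p2, pd13, pO)
  den_fdm <- ifelse(p2 >= p1, den_fd, -(pat13$abba - pat13$baba))

  informative <- as.numeric(denD > 0)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(pos0 + 1L, chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    sel <- chrom == ch
    starts <- sliding_starts(chrom_lengths[[ch]], window, step)
    ends <- pmin(starts + window, chrom_lengths[[ch]])
    vals <- cbind(num = num[sel], denD = denD[sel], den_fd = den_fd[sel],
                  den_fdm = den_fdm[sel], informative = informative[sel])
    ws <- window_sums(pos0[sel], vals, starts, ends)
    s <- ws$sums
    n_inf <- s[, "informative"]
    D_win <- ifelse(s[, "denD"] > 0, s[, "num"] / s[, "denD"], NA_real_)
    fd_zeroed <- s[, "num"] <= 0
    fd <- ifelse(fd_zeroed, 0,
                 ifelse(s[, "den_fd"] > 0, s[, "num"] / s[, "den_fd"],
                        NA_real_))
    fdM <- ifelse(s[, "den_fdm"] > 0, s[, "num"] / s[, "den_fdm"],
                  NA_real_)
    data.frame(chrom = ch, start = starts, end = ends, n_sites = n_inf,
               D_window = D_win, fd = fd, fd_zeroed = fd_zeroed, fdM = fdM,
               valid = n_inf >= min_sites & !is.na(fdM),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "trio") <- tr
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_scores", "data.frame")
  out
}

#' Write window scores as a TSV/BED-graph style table
#' @param scores A [window_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
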