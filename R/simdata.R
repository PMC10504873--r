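# Synthetic allopolyploid cohort generator.
#
# Emulates the statistical structure the introgression analysis assumes:
# a four-population tree ([{P1,P2},P3],O) with Balding-Nichols drift per
# branch, tract-based introgression from the diploid donor P3 into the
# tetraploid receptor P2 with known ground truth, and the receptor
# subgenome living on shifted coordinates linked by a synteny table.

#' Configuration for the synthetic allopolyploid cohort generator
#'
#' The defaults define the study conditions used throughout the package's
#' validation experiments: one 5 Mb chromosome carrying ~50,000 SNPs
#' (about one SNP per 100 bp, the density of a dense resequencing panel),
#' twenty diploid samples per population (the scale of a morphotype panel),
#' and introgressed tracts of mean length 50 kb covering 20% of each
#' receptor haplotype. The default drift parameters mirror the structure of
#' a diploid-tetraploid crop system: symmetric light drift on the two
#' receptor morphotype branches (P1, P2: 0.05), a strong founder bottleneck
#' on the receptor stem (P12: 0.2, the allopolyploid origin), moderate
#' drift on the diploid donor morphotype branch (P3: 0.15) and a deeply
#' diverged outgroup species (O: 0.4).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @param n_sites Target number of segregating sites (duplicate positions
#'   are removed, so the realized count can be marginally smaller).
#' @param drift Named vector of Balding-Nichols drift parameters `F` in
#'   `[0, 1)` for branches `P123`, `P12`, `P1`, `P2`, `P3`, `O` of the tree
#'   `(((P1,P2),P3),O)`. Missing branches default to 0 (no drift).
#' @param f_target Expected fraction of each receptor (P2) haplotype genome
#'   covered by donor tracts, in `[0, 1]`.
#' @param tract_mean Mean introgressed tract length in bp (exponential).
#' @param carrier_freq Frequency at which receptor haplotypes carry each
#'   tract of the shared introgression template, in `(0, 1]`. Values below 1
#'   leave tracts segregating inside the receptor population (an ancestry
#'   mixture that raises local diversity); 1 models a fully swept event.
#' @param samples_per_pop Diploid samples per population.
#' @param missing_rate Per-genotype missing probability (i.i.d.).
#' @param depth_mean Mean of the per-genotype Poisson read-depth model.
#' @param recomb_bias Non-negative weight biasing tract start positions
#'   toward high-recombination windows of the emitted rho track; 0 disables
#'   the bias.
#' @param coord_offset Coordinate shift applied to the tetraploid subgenome
#'   frame (bp); syntenic blocks linking the two frames are emitted.
#' @param rho_window Window size of the emitted recombination (rho) track.
#' @param rho_high_fraction Fraction of rho windows designated
#'   high-recombination.
#' @param sweep_window Window size of the emitted synthetic sweep-score
#'   tracks.
#' @param seed Master integer seed; all stages derive sub-stream seeds from
#'   it, so identical configurations reproduce outputs byte-identically.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 1000, samples_per_pop = 4)
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 5e6,
                       n_sites = 50000L,
                       drift = c(P123 = 0.05, P12 = 0.20, P1 = 0.05,
                                 P2 = 0.05, P3 = 0.15, O = 0.40),
                       f_target = 0.2,
                       tract_mean = 5e4,
                       carrier_freq = 1,
                       samples_per_pop = 20L,
                       missing_rate = 0.02,
                       depth_mean = 8,
                       recomb_bias = 0,
                       coord_offset = 1e6,
                       rho_window = 5e4,
                       rho_high_fraction = 0.5,
                       sweep_window = 1e4,
                       seed = 1L) {
  branches <- c("P123", "P12", "P1", "P2", "P3", "O")
  full <- setNames(rep(0, length(branches)), branches)
  if (length(drift) > 0) {
    if (is.null(names(drift)) || !all(names(drift) %in% branches)) {
      stop("`drift` must be named with a subset of: ",
           paste(branches, collapse = ", "))
    }
    full[names(drift)] <- drift
  }
  if (any(full < 0 | full >= 1)) stop("all drift F must lie in [0, 1)")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (n_sites > n_chromosomes * chrom_length) {
    stop("n_sites exceeds the total genome length")
  }
  if (f_target < 0 || f_target > 1) stop("f_target must lie in [0, 1]")
  if (tract_mean <= 0) stop("tract_mean must be > 0")
  if (carrier_freq <= 0 || carrier_freq > 1) {
    stop("carrier_freq must lie in (0, 1]")
  }
  if (f_target > carrier_freq) {
    stop("f_target cannot exceed carrier_freq ",
         "(template coverage would exceed the chromosome)")
  }
  if (recomb_bias < 0) stop("recomb_bias must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (samples_per_pop < 2) stop("samples_per_pop must be >= 2")
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_sites = as.integer(n_sites),
              drift = full,
              f_target = f_target,
              tract_mean = tract_mean,
              carrier_freq = carrier_freq,
              samples_per_pop = as.integer(samples_per_pop),
              missing_rate = missing_rate,
              depth_mean = depth_mean,
              recomb_bias = recomb_bias,
              coord_offset = coord_offset,
              rho_window = rho_window,
              rho_high_fraction = rho_high_fraction,
              sweep_window = sweep_window,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

sim_chrom_lengths <- function(cfg) {
  setNames(rep(cfg$chrom_length, cfg$n_chromosomes), sim_chrom_names(cfg))
}

# Balding-Nichols drift: child ~ Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 is the
# exact identity (the Beta parameters diverge).
bn_drift <- function(p, F) {
  if (F == 0) return(p)
  k <- (1 - F) / F
  out <- rbeta(length(p), p * k, (1 - p) * k)
  # rbeta returns NaN for zero shape (p exactly 0 or 1): fixed stays fixed
  fixed <- p <= 0 | p >= 1
  out[fixed] <- p[fixed]
  pmin(pmax(out, 0), 1)
}

#' Simulate per-population derived-allele frequencies on the four-taxon tree
#'
#' Root frequencies are drawn from Uniform(0.05, 0.95) (avoiding near-fixed
#' sites whose pattern sums are degenerate), then Balding-Nichols drift is
#' applied along each branch of `(((P1,P2),P3),O)`. Sites are placed
#' uniformly at random, de-duplicated and sorted.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to the config master seed.
#' @return A data.frame of class `pop_freqs` with columns `chrom`, `pos`
#'   (1-based), `anc`, `der` (ancestral/derived alleles) and truth
#'   frequencies `p_P1`, `p_P2`, `p_P3`, `p_O`.
#' @export
sample_tree_frequencies <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(seed, "frequencies"), {
    chroms <- sim_chrom_names(cfg)
    chrom <- sample(chroms, cfg$n_sites, replace = TRUE)
    pos <- sample.int(cfg$chrom_length, cfg$n_sites, replace = TRUE)
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    o <- order(match(chrom, chroms), pos)
    chrom <- chrom[o]; pos <- pos[o]
    n <- length(pos)

    p0 <- runif(n, 0.05, 0.95)
    F <- cfg$drift
    anc123 <- bn_drift(p0, F[["P123"]])
    anc12 <- bn_drift(anc123, F[["P12"]])
    p1 <- bn_drift(anc12, F[["P1"]])
    p2 <- bn_drift(anc12, F[["P2"]])
    p3 <- bn_drift(anc123, F[["P3"]])
    pO <- bn_drift(p0, F[["O"]])

    nuc <- c("A", "C", "G", "T")
    anc <- sample(nuc, n, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(nuc, a), 1L), "")

    out <- data.frame(chrom = chrom, pos = pos, anc = anc, der = unname(der),
                      p_P1 = p1, p_P2 = p2, p_P3 = p3, p_O = pO,
                      stringsAsFactors = FALSE)
    class(out) <- c("pop_freqs", "data.frame")
    out
  })
}

# Recombination-rate (rho = 4*Ne*r) track: non-overlapping windows, a
# sampled high/low designation and log-normal window values. The same
# sub-stream seed is used wherever the track is needed, so tract placement
# and the emitted file always agree.
make_rho_track <- function(cfg, seed = cfg$seed) {
  with_seed(substream_seed(seed, "rho"), {
    win <- tile_windows(sim_chrom_lengths(cfg), cfg$rho_window)
    win$high <- runif(nrow(win)) < cfg$rho_high_fraction
    win$value <- rlnorm(nrow(win),
                        meanlog = ifelse(win$high, log(20), log(5)),
                        sdlog = 0.3)
    win
  })
}

# Alternating gap/tract renewal process on one chromosome. Gap proposals
# are exponential and thinned so the *effective* tract-start rate is
# (1 + recomb_bias)-fold higher inside high-rho windows, with the base rate
# rescaled so the expected coverage stays at `coverage`.
simulate_tract_template <- function(L, coverage, tract_mean, bias, rho_chr) {
  if (coverage <= 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  if (coverage >= 1) return(data.frame(start = 0, end = L))
  gap_mean <- tract_mean * (1 - coverage) / coverage
  q <- if (nrow(rho_chr)) {
    sum((rho_chr$end - rho_chr$start) * rho_chr$high) /
      sum(rho_chr$end - rho_chr$start)
  } else 0
  wmax <- 1 + bias
  # proposal rate so that the average accepted rate equals 1/gap_mean
  accept_mean <- (q * wmax + (1 - q)) / wmax
  prop_rate <- 1 / (gap_mean * accept_mean)
  in_high <- function(x) {
    if (bias == 0 || nrow(rho_chr) == 0L) return(rep(FALSE, length(x)))
    !is.na(point_in_interval(rho_chr[rho_chr$high, , drop = FALSE],
                             rep(rho_chr$chrom[1], length(x)), floor(x)))
  }
  starts <- numeric(0); ends <- numeric(0)
  x <- 0
  # stationary start: begin inside a tract with probability `coverage`
  if (runif(1) < coverage) {
    len <- rexp(1, 1 / tract_mean)
    starts <- 0; ends <- min(len, L)
    x <- len
  }
  while (x < L) {
    repeat {
      x <- x + rexp(1, prop_rate)
      if (x >= L) break
      w <- if (in_high(x)) wmax else 1
      if (runif(1) < w / wmax) break
    }
    if (x >= L) break
    len <- rexp(1, 1 / tract_mean)
    starts <- c(starts, x); ends <- c(ends, min(x + len, L))
    x <- x + len
  }
  data.frame(start = floor(starts), end = ceiling(ends))
}

#' Place introgressed donor tracts on the receptor haplotypes
#'
#' A per-chromosome renewal template of alternating exponential gap/tract
#' segments (expected coverage `f_target / carrier_freq`) is drawn once,
#' and every P2 haplotype carries each template tract independently with
#' probability `carrier_freq`. Each haplotype therefore sees an
#' alternating-exponential tract structure with expected coverage
#' `f_target`, while tracts are shared across haplotypes as expected for a
#' historical introgression event. With `recomb_bias > 0` tract starts are
#' re-weighted toward high-recombination windows of the rho track.
#'
#' @inheritParams sample_tree_frequencies
#' @return A data.frame of class `truth_tracts` with columns `sample`,
#'   `haplotype` (0/1), `chrom`, `start`, `end` (0-based half-open), plus
#'   attributes `coverage` (realized base-pair fraction over all P2
#'   haplotypes) and `template` (the shared tract template).
#' @export
place_introgression_tracts <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  rho <- make_rho_track(cfg, seed)
  with_seed(substream_seed(seed, "tracts"), {
    chroms <- sim_chrom_names(cfg)
    samples <- sprintf("P2_%02d", seq_len(cfg$samples_per_pop))
    cov_template <- if (cfg$f_target == 0) 0 else
      cfg$f_target / cfg$carrier_freq
    template <- do.call(rbind, lapply(chroms, function(ch) {
      seg <- simulate_tract_template(cfg$chrom_length, cov_template,
                                     cfg$tract_mean, cfg$recomb_bias,
                                     rho[rho$chrom == ch, , drop = FALSE])
      if (nrow(seg)) cbind(chrom = ch, seg) else NULL
    }))
    if (is.null(template)) {
      template <- data.frame(chrom = character(), start = numeric(),
                             end = numeric())
    }
    rows <- list()
    for (s in samples) {
      for (h in 0:1) {
        if (nrow(template)) {
          carry <- runif(nrow(template)) < cfg$carrier_freq
          if (any(carry)) {
            seg <- template[carry, , drop = FALSE]
            rows[[length(rows) + 1L]] <-
              data.frame(sample = s, haplotype = h, chrom = seg$chrom,
                         start = seg$start, end = seg$end,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
    tracts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample = character(), haplotype = integer(),
                 chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    rownames(tracts) <- NULL
    n_hap <- 2L * cfg$samples_per_pop
    genome <- cfg$n_chromosomes * cfg$chrom_length
    attr(tracts, "coverage") <-
      sum(tracts$end - tracts$start) / (n_hap * genome)
    attr(tracts, "template") <- template
    class(tracts) <- c("truth_tracts", "data.frame")
    tracts
  })
}

sim_sample_names <- function(pop, n) sprintf("%s_%02d", pop, seq_len(n))

# Draw one population's diploid dosage matrix (sites x samples) from
# per-site frequencies; returns the two haplotype matrices as well so the
# receptor tracts can overwrite individual haplotypes.
draw_haplotypes <- function(p, n_samples) {
  n <- length(p)
  h1 <- matrix(runif(n * n_samples) < p, nrow = n)
  h2 <- matrix(runif(n * n_samples) < p, nrow = n)
  list(h1 = h1, h2 = h2)
}

#' Sample cohort genotypes from truth frequencies and tracts
#'
#' Diploid dosages are Binomial(2, p_pop) per site, except receptor (P2)
#' haplotype-site pairs inside introgressed tracts, which draw the allele
#' with the donor frequency p_P3. Missingness is applied i.i.d.;
#' per-genotype depth follows a Poisson model. The tetraploid cohort
#' (populations P1 and P2, the receptor species) is re-addressed onto a
#' shifted subgenome coordinate frame and the corresponding syntenic block
#' table is emitted.
#'
#' @param freqs Output of [sample_tree_frequencies()].
#' @param tracts Output of [place_introgression_tracts()].
#' @param cfg The [sim_config()] the inputs were generated under.
#' @param seed Integer seed; defaults to the config master seed.
#' @return A list of class `sim_cohorts` with elements `cohorts` (named
#'   list of [genotype_matrix] objects: `tetraploid` on subgenome
#'   coordinates with populations P1 and P2, `donor` with P3 and `outgroup`
#'   with O on donor coordinates), `synteny` (a [synteny_map] from the
#'   donor frame to the subgenome frame) and `popmap`.
#' @export
sample_genotypes <- function(freqs, tracts, cfg, seed = cfg$seed) {
  stopifnot(inherits(freqs, "pop_freqs"), inherits(cfg, "sim_config"))
  chroms <- sim_chrom_names(cfg)
  if (nrow(tracts)) {
    if (!all(tracts$chrom %in% chroms)) {
      stop("tract references unknown chromosome")
    }
    p2_names <- sim_sample_names("P2", cfg$samples_per_pop)
    if (!all(tracts$sample %in% p2_names)) {
      stop("tract references unknown sample")
    }
  }
  with_seed(substream_seed(seed, "genotypes"), {
    n <- nrow(freqs)
    nS <- cfg$samples_per_pop
    pops <- c("P1", "P2", "P3", "O")
    pcol <- c(P1 = "p_P1", P2 = "p_P2", P3 = "p_P3", O = "p_O")
    haps <- lapply(pops, function(pop) draw_haplotypes(freqs[[pcol[[pop]]]], nS))
    names(haps) <- pops

    # overwrite receptor haplotypes inside tracts with donor-frequency draws
    if (nrow(tracts)) {
      p3 <- freqs$p_P3
      p2_names <- sim_sample_names("P2", nS)
      for (k in seq_len(nrow(tracts))) {
        tr <- tracts[k, ]
        j <- match(tr$sample, p2_names)
        in_tract <- freqs$chrom == tr$chrom &
          freqs$pos - 1L >= tr$start & freqs$pos - 1L < tr$end
        if (!any(in_tract)) next
        draw <- runif(sum(in_tract)) < p3[in_tract]
        if (tr$haplotype == 0L) {
          haps$P2$h1[in_tract, j] <- draw
        } else {
          haps$P2$h2[in_tract, j] <- draw
        }
      }
    }

    geno <- lapply(pops, function(pop) {
      m <- haps[[pop]]$h1 + haps[[pop]]$h2
      storage.mode(m) <- "integer"
      colnames(m) <- sim_sample_names(pop, nS)
      m
    })
    names(geno) <- pops

    all_geno <- do.call(cbind, geno)
    dp <- matrix(rpois(length(all_geno), cfg$depth_mean),
                 nrow = n, dimnames = dimnames(all_geno))
    if (cfg$missing_rate > 0) {
      all_geno[matrix(runif(length(all_geno)) < cfg$missing_rate,
                      nrow = n)] <- NA_integer_
    }

    popmap <- data.frame(
      sample = colnames(all_geno),
      population = rep(pops, each = nS),
      stringsAsFactors = FALSE)

    sites_dip <- data.frame(chrom = freqs$chrom, pos = freqs$pos,
                            ref = freqs$anc, alt = freqs$der,
                            stringsAsFactors = FALSE)
    sub_chrom <- paste0(freqs$chrom, "_sub")
    sites_sub <- data.frame(chrom = sub_chrom,
                            pos = freqs$pos + cfg$coord_offset,
                            ref = freqs$anc, alt = freqs$der,
                            stringsAsFactors = FALSE)

    pick <- function(pops_keep, sites) {
      cols <- popmap$sample[popmap$population %in% pops_keep]
      genotype_matrix(sites, all_geno[, cols, drop = FALSE],
                      dp = dp[, cols, drop = FALSE],
                      popmap = popmap[popmap$sample %in% cols, , drop = FALSE])
    }
    cohorts <- list(
      tetraploid = pick(c("P1", "P2"), sites_sub),
      donor = pick("P3", sites_dip),
      outgroup = pick("O", sites_dip))

    # syntenic blocks: each chromosome split into 4 equal-length blocks,
    # donor frame -> subgenome frame, strand +
    blocks <- do.call(rbind, lapply(chroms, function(ch) {
      bounds <- round(seq(0, cfg$chrom_length, length.out = 5))
      data.frame(src_chrom = ch,
                 src_start = bounds[-5], src_end = bounds[-1],
                 dst_chrom = paste0(ch, "_sub"),
                 dst_start = bounds[-5] + cfg$coord_offset,
                 dst_end = bounds[-1] + cfg$coord_offset,
                 strand = "+", stringsAsFactors = FALSE)
    }))
    out <- list(cohorts = cohorts, synteny = synteny_map(blocks),
                popmap = popmap)
    class(out) <- "sim_cohorts"
    out
  })
}

# Synthetic sweep-score tracks (XP-CLR / XP-EHH style). Sweeps are sparse:
# each introgressed template tract carries a planted sweep with probability
# 0.2, so a few percent of the genome is under selection, as in real
# genome-wide scans. Both tracks see the same underlying per-window sweep
# strength (the two methods respond to the same events) on top of
# independent method noise.
make_sweep_tracks <- function(cfg, tracts, seed = cfg$seed) {
  with_seed(substream_seed(seed, "sweeps"), {
    win <- tile_windows(sim_chrom_lengths(cfg), cfg$sweep_window)
    template <- attr(tracts, "template") %||%
      data.frame(chrom = character(), start = numeric(), end = numeric())
    planted <- template[runif(nrow(template)) < 0.2, , drop = FALSE]
    mid <- floor((win$start + win$end) / 2)
    in_planted <- if (nrow(planted)) {
      !is.na(point_in_interval(planted, win$chrom, mid))
    } else rep(FALSE, nrow(win))
    strength <- rep(1, nrow(win))
    strength[in_planted] <- 8 * rlnorm(sum(in_planted), 0, 0.5)
    make1 <- function() {
      v <- rlnorm(nrow(win), 0, 0.5) * strength
      data.frame(chrom = win$chrom, start = win$start, end = win$end,
                 value = v, stringsAsFactors = FALSE)
    }
    list(xpclr = make1(), xpehh = make1(), planted = planted)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the full generator and writes per-species VCFs, the population map,
#' the syntenic block table, truth tracts (BED), a windowed recombination
#' track and synthetic sweep-score tracks, plus a manifest with checksums.
#' Identical `(cfg, seed)` reproduce every file byte-identically.
#'
#' @inheritParams sample_tree_frequencies
#' @param out_dir Writable output directory (created if absent).
#' @return A data.frame manifest (`file`, `bytes`, `md5`), invisibly
#'   carrying the generated objects in attribute `objects`.
#' @export
emit_dataset <- function(cfg, out_dir, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- sample_tree_frequencies(cfg, seed)
  tracts <- place_introgression_tracts(cfg, seed)
  sim <- sample_genotypes(freqs, tracts, cfg, seed)
  rho <- make_rho_track(cfg, seed)
  sweeps <- make_sweep_tracks(cfg, tracts, seed)

  paths <- c(tetraploid = file.path(out_dir, "tetraploid.vcf"),
             donor = file.path(out_dir, "donor.vcf"),
             outgroup = file.path(out_dir, "outgroup.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"),
             synteny = file.path(out_dir, "synteny_blocks.tsv"),
             truth = file.path(out_dir, "truth_tracts.bed"),
             rho = file.path(out_dir, "rho_track.tsv"),
             xpclr = file.path(out_dir, "xpclr_track.tsv"),
             xpehh = file.path(out_dir, "xpehh_track.tsv"))

  write_vcf(sim$cohorts$tetraploid, paths[["tetraploid"]])
  write_vcf(sim$cohorts$donor, paths[["donor"]])
  write_vcf(sim$cohorts$outgroup, paths[["outgroup"]])
  write.table(sim$popmap, paths[["popmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_synteny(sim$synteny, paths[["synteny"]])
  truth_bed <- data.frame(chrom = tracts$chrom, start = tracts$start,
                          end = tracts$end,
                          name = paste0(tracts$sample, ":", tracts$haplotype))
  write.table(truth_bed, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (nm in c("rho", "xpclr", "xpehh")) {
    trk <- switch(nm, rho = rho[, c("chrom", "start", "end", "value")],
                  xpclr = sweeps$xpclr, xpehh = sweeps$xpehh)
    write.table(trk, paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  manifest <- file_checksums(unname(paths))
  attr(manifest, "objects") <- list(freqs = freqs, tracts = tracts,
                                    sim = sim, rho = rho, sweeps = sweeps)
  attr(manifest, "paths") <- paths
  invisible(manifest)
}
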