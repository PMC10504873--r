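# End-to-end orchestration: simulate (optional) -> read/filter -> merge ->
# trio statistics -> window scan -> region calling -> feature contrasts ->
# sweep-overlap enrichment, with a machine-readable run manifest.

#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir Output directory for all stage TSV/BED files.
#' @param simulate Either `NULL` (analyse existing files) or a
#'   [sim_config()]; when given, the synthetic dataset is written to
#'   `out_dir/sim` and used as input, exercising the full file-based path.
#' @param vcfs Named character vector of input VCF paths (ignored when
#'   `simulate` is given). The element named by `tetraploid` is mapped
#'   through the synteny table; the others are on the reference frame.
#' @param popmap_path,synteny_path Input file paths (ignored when
#'   simulating).
#' @param tetraploid Name of the VCF element on the subgenome frame.
#' @param trios List of [trio()] objects to test; when `NULL` and
#'   simulating, the canonical `(P1, P2; P3 | O)` trio is used.
#' @param outgroup Outgroup population name.
#' @param filter A [filter_spec()].
#' @param window,step,min_sites Window-scan parameters.
#' @param block_count Jackknife blocks.
#' @param x_override Optional region-calling fraction overriding the
#'   f4-ratio calibration (recorded in the manifest).
#' @param q Sweep top-percentile quantile.
#' @param rho_track,xpclr_track,xpehh_track Optional track file paths
#'   (defaults to the simulated ones when simulating).
#' @param chrom_lengths Named chromosome lengths of the reference frame
#'   (derived from the simulation config when simulating).
#' @param seed Master seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, vcfs = NULL,
                       popmap_path = NULL, synteny_path = NULL,
                       tetraploid = "tetraploid", trios = NULL,
                       outgroup = "O", filter = filter_spec(),
                       window = 10000L, step = 1000L, min_sites = 5L,
                       block_count = 20L, x_override = NULL, q = 0.95,
                       rho_track = NULL, xpclr_track = NULL,
                       xpehh_track = NULL, chrom_lengths = NULL,
                       seed = 1L) {
  if (is.null(simulate)) {
    for (p in c(vcfs, popmap_path, synteny_path)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(out_dir = out_dir, simulate = simulate, vcfs = vcfs,
                 popmap_path = popmap_path, synteny_path = synteny_path,
                 tetraploid = tetraploid, trios = trios,
                 outgroup = outgroup, filter = filter, window = window,
                 step = step, min_sites = min_sites,
                 block_count = block_count, x_override = x_override,
                 q = q, rho_track = rho_track, xpclr_track = xpclr_track,
                 xpehh_track = xpehh_track, chrom_lengths = chrom_lengths,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(...) message("[interflow] ", ...)

#' Run the full introgression pipeline
#'
#' Executes every stage and writes per-stage TSV/BED outputs plus a run
#' manifest (parameters, seeds, output checksums). Stages:
#' simulate (optional), read + filter each cohort, cross-ploidy merge,
#' per-trio D and f4-ratio, fd/fdM window scan for the best-supported
#' trio, region calling at `x = f4-ratio` (or `x_override`), diversity
#' contrast (receptor pi in/out), recombination contrast when a rho track
#' is available, and sweep-overlap enrichment when sweep tracks are
#' available.
#'
#' @param config A [run_config()].
#' @return A list of class `run_manifest`: `params`, `site_counts`,
#'   `trios` (per-trio table), `pair_summary`, `regions`, `contrasts`,
#'   `enrichment`, `files` (checksummed outputs).
#' @export
run_introgression_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (!is.null(config$simulate)) {
    pipeline_log("simulating dataset")
    sim_dir <- file.path(config$out_dir, "sim")
    man <- emit_dataset(config$simulate, sim_dir, seed = seed)
    paths <- attr(man, "paths")
    config$vcfs <- c(tetraploid = unname(paths[["tetraploid"]]),
                     donor = unname(paths[["donor"]]),
                     outgroup = unname(paths[["outgroup"]]))
    config$popmap_path <- unname(paths[["popmap"]])
    config$synteny_path <- unname(paths[["synteny"]])
    config$rho_track <- config$rho_track %||% unname(paths[["rho"]])
    config$xpclr_track <- config$xpclr_track %||% unname(paths[["xpclr"]])
    config$xpehh_track <- config$xpehh_track %||% unname(paths[["xpehh"]])
    config$chrom_lengths <- sim_chrom_lengths(config$simulate)
    truth_path <- unname(paths[["truth"]])
  } else {
    truth_path <- NULL
  }

  pipeline_log("reading cohorts")
  popmap <- read_popmap(config$popmap_path)
  cohorts <- lapply(config$vcfs, read_vcf, popmap = popmap)
  blocks <- read_synteny(config$synteny_path)

  # depth and biallelic rules are per-cohort; the missing-rate and
  # minor-allele-count rules act on the joint lineage callset after the
  # merge, where rarity is defined across all species together
  pipeline_log("filtering sites (per-cohort quality rules)")
  spec <- config$filter
  cohort_spec <- filter_spec(biallelic_only = spec$biallelic_only,
                             max_missing = 1, min_mac = 0L,
                             min_mean_dp = spec$min_mean_dp,
                             max_mean_dp = spec$max_mean_dp,
                             min_dp = spec$min_dp, max_dp = spec$max_dp)
  filtered <- lapply(cohorts, apply_site_filters, spec = cohort_spec)
  site_counts <- lapply(filtered, attr, "removal_counts")

  pipeline_log("merging lineage across ploidy")
  ref_names <- setdiff(names(filtered), config$tetraploid)
  merged <- filtered[[ref_names[1]]]
  for (nm in ref_names[-1]) {
    merged <- merge_lineage(merged, filtered[[nm]], blocks = NULL)
  }
  merged <- merge_lineage(merged, filtered[[config$tetraploid]],
                          blocks = synteny_invert(blocks))

  pipeline_log("filtering sites (joint missing-rate and MAC rules)")
  joint_spec <- filter_spec(biallelic_only = FALSE,
                            max_missing = spec$max_missing,
                            min_mac = spec$min_mac,
                            min_mean_dp = -Inf, max_mean_dp = Inf,
                            min_dp = NULL)
  merged <- apply_site_filters(merged, joint_spec)
  site_counts$joint <- attr(merged, "removal_counts")

  pipeline_log("computing allele frequencies")
  freqs <- allele_frequencies(merged, outgroup = config$outgroup)

  trios <- config$trios
  if (is.null(trios)) {
    pops <- setdiff(unique(merged$popmap$population), config$outgroup)
    if (!all(c("P1", "P2", "P3") %in% pops)) {
      stop("no trios given and populations are not the canonical P1/P2/P3")
    }
    trios <- list(trio("P1", "P2", "P3", config$outgroup))
  }
  pipeline_log("trio statistics (", length(trios), " trios)")
  trio_tab <- do.call(rbind, lapply(trios, function(tr) {
    trio_stats(freqs, tr, seed = seed, block_count = config$block_count)
  }))
  pair_tab <- summarize_pairs(trio_tab)

  best <- which.max(ifelse(is.na(trio_tab$D), -Inf, trio_tab$D))
  best_trio <- trios[[best]]
  pipeline_log("window scan for best trio (P2=", best_trio[["P2"]],
               ", P3=", best_trio[["P3"]], ")")
  scores <- window_scan(freqs, best_trio, window = config$window,
                        step = config$step, min_sites = config$min_sites,
                        chrom_lengths = config$chrom_lengths)

  x_used <- config$x_override %||% trio_tab$f4_ratio[best]
  x_source <- if (is.null(config$x_override)) "f4_ratio" else "x_override"
  regions <- if (!is.na(x_used) && x_used > 0) {
    call_introgressed(scores, x = min(x_used, 1))
  } else {
    region_set(data.frame(chrom = character(), start = integer(),
                          end = integer()))
  }

  pipeline_log("feature contrasts")
  contrasts <- list()
  if (nrow(regions) > 0) {
    pi_trk <- pi_windows(merged, best_trio[["P2"]],
                         chrom_lengths = config$chrom_lengths)
    contrasts$pi <- tryCatch(compare_in_out(pi_trk, regions),
                             error = function(e) NULL)
    if (!is.null(config$rho_track) && file.exists(config$rho_track)) {
      rho <- load_track(config$rho_track, name = "rho")
      contrasts$rho <- tryCatch(compare_in_out(rho, regions),
                                error = function(e) NULL)
    }
  }

  enrich <- NULL
  if (!is.null(config$xpclr_track) && file.exists(config$xpclr_track) &&
      !is.null(config$xpehh_track) && file.exists(config$xpehh_track) &&
      nrow(regions) > 0) {
    pipeline_log("sweep-overlap enrichment")
    xpclr <- load_track(config$xpclr_track, name = "xpclr")
    xpehh <- load_track(config$xpehh_track, name = "xpehh")
    sweeps <- sweep_regions(xpclr, xpehh, q = config$q)
    in_sweep <- classify_windows(xpclr, sweeps) == "in"
    in_intro <- classify_windows(xpclr, regions) == "in"
    fe <- fisher_enrichment(sum(in_sweep & in_intro), sum(in_intro),
                            sum(in_sweep), length(in_sweep))
    perm <- if (!is.null(config$chrom_lengths)) {
      permutation_overlap(regions, sweeps, config$chrom_lengths,
                          n_perm = 199L, seed = seed)
    }
    enrich <- list(sweeps = sweeps, fisher = fe, permutation = perm)
  }

  truth_eval <- NULL
  if (!is.null(truth_path) && nrow(regions) > 0) {
    truth <- read_regions(truth_path)
    truth_eval <- region_precision_recall(regions, truth)
  }

  files <- c(trios = file.path(config$out_dir, "trio_stats.tsv"),
             pairs = file.path(config$out_dir, "pair_summary.tsv"),
             windows = file.path(config$out_dir, "window_scores.tsv"),
             regions = file.path(config$out_dir, "introgressed_regions.bed"))
  write.table(trio_tab, files[["trios"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pair_tab, files[["pairs"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_window_scores(scores, files[["windows"]])
  write_regions(regions, files[["regions"]])

  manifest <- structure(list(
    params = list(seed = seed, window = config$window, step = config$step,
                  min_sites = config$min_sites,
                  block_count = config$block_count,
                  x_used = x_used, x_source = x_source, q = config$q),
    site_counts = site_counts,
    trios = trio_tab, pair_summary = pair_tab,
    scores = scores, regions = regions,
    contrasts = contrasts, enrichment = enrich,
    truth_eval = truth_eval,
    files = file_checksums(unname(files))),
    class = "run_manifest")
  manifest
}

#' Summarize a pipeline run
#'
#' @param manifest A [run_introgression_pipeline()] result.
#' @return A character vector of report lines (also printed), invisibly.
#' @export
report_run <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  tt <- manifest$trios
  lines <- c(
    "== interflow run report ==",
    sprintf("trios tested: %d (significant D: %d)", nrow(tt),
            sum(tt$significant_D, na.rm = TRUE)),
    sprintf("  max D = %.4f (Z = %.2f), max f4-ratio = %.4f",
            max(tt$D, na.rm = TRUE), tt$Z_D[which.max(tt$D)],
            max(tt$f4_ratio, na.rm = TRUE)),
    sprintf("regions called: %d spanning %.2f Mb (x = %.3f from %s)",
            nrow(manifest$regions), region_span(manifest$regions) / 1e6,
            manifest$params$x_used, manifest$params$x_source))
  if (!is.null(manifest$contrasts$pi)) {
    cp <- manifest$contrasts$pi
    lines <- c(lines, sprintf(
      "pi in/out: %.4g / %.4g (one-sided p = %.3g, %+.1f%%)",
      cp$median_in, cp$median_out, cp$p_one_sided, cp$percent_mean_diff))
  } else {
    lines <- c(lines, "pi contrast: not run")
  }
  if (!is.null(manifest$contrasts$rho)) {
    cr <- manifest$contrasts$rho
    lines <- c(lines, sprintf(
      "rho in/out medians: %.4g / %.4g (one-sided p = %.3g)",
      cr$median_in, cr$median_out, cr$p_one_sided))
  }
  if (!is.null(manifest$enrichment)) {
    fe <- manifest$enrichment$fisher
    lines <- c(lines, sprintf(
      "sweep overlap: %d/%d windows (Fisher one-sided p = %.3g)",
      fe$table[1, 1], sum(fe$table[1, ]), fe$p_one_sided))
  } else {
    lines <- c(lines, "sweep enrichment: not run")
  }
  if (!is.null(manifest$truth_eval)) {
    te <- manifest$truth_eval
    lines <- c(lines, sprintf(
      "truth recovery: precision %.3f, recall %.3f", te$precision,
      te$recall))
  }
  writeLines(lines)
  invisible(lines)
}
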