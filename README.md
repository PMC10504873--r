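# interflow

Detection and characterization of **interploidy introgression** — gene
flow from diploid donor species into the matching subgenome of an
allopolyploid receptor — from cohort VCFs.

Allopolyploid crops (an AACC oilseed grown beside its AA and CC
progenitors, for instance) keep exchanging genes with their diploid
relatives through triploid bridges and backcrossing. The receptor
subgenome and the donor genome live on different reference assemblies,
so detecting this flow requires a cross-ploidy pipeline: map the
subgenome onto the diploid frame through one-to-one syntenic blocks,
merge the callsets, and test four-population allele-sharing asymmetries.
interflow implements that pipeline end to end, together with a synthetic
allopolyploid cohort generator with known ground truth used to validate
every stage.

## What it computes

For populations arranged as `([{P1, P2}, P3], O)` (P2 the candidate
receptor, P3 the candidate donor, O the outgroup), with derived-allele
frequencies `p1, p2, p3, pO` per site:

- **Patterson's D** (ABBA-BABA):
  `D = Σ(ABBA−BABA) / Σ(ABBA+BABA)` with
  `ABBA−BABA = (p2−p1)(p3−pO)`; standard errors and Z-scores from a
  delete-one block jackknife over contiguous equal-count blocks
  (`|Z| > 4` flagged significant).
- **f4-ratio** admixture proportion:
  `f̂ = Σ num(p1, p2, p3a, pO) / Σ num(p1, p3b, p3a, pO)` using a fixed,
  seeded half-split `(p3a, p3b)` of the donor samples — an unbiased
  small-sample estimator of the fraction of the P2 genome of donor
  origin.
- **fd / fdM sliding-window scans** (10 kb windows, 1 kb steps) with the
  dynamic-donor denominator `pD = max(p2, p3)`; fdM is the symmetric
  variant bounded in [−1, 1].
- **Region calling** calibrated by the f4-ratio: the highest-x% of
  windows by fdM with `x = f̂`, merged into putative introgressed
  regions.
- **Genomic-feature contrasts**: windowed nucleotide diversity π,
  Dxy, Weir–Cockerham Fst (ratio-of-sums), external recombination (ρ)
  and sweep-score tracks, compared between introgressed and
  non-introgressed regions by Mann–Whitney tests.
- **Enrichment**: top-5%-window sweep selection (XP-CLR ∩ XP-EHH style),
  exact Fisher tests for sweep/region and gene-set overlap, and a
  circular-permutation overlap null.

Standard site filters (biallelic only, missing rate ≤ 15%, minor allele
count ≥ 3, genotype and site mean depth in [3, 40]) are built in, with
depth rules applied per cohort and rarity/missingness rules applied to
the merged lineage callset.

## Worked example

A complete synthetic run: simulate a receptor cohort with 20% of each
receptor haplotype introgressed from the donor, write VCFs + tracks,
re-read them, filter, merge across ploidy, and run the analysis (about a
minute on one CPU):

```r
library(interflow)

cfg <- sim_config(seed = 1)           # 5 Mb, ~50k SNPs, f_target = 0.2
rc  <- run_config(out_dir = "demo_run", simulate = cfg, seed = 1)
man <- run_introgression_pipeline(rc)
report_run(man)
```

```
== interflow run report ==
trios tested: 1 (significant D: 1)
  max D = 0.0376 (Z = 5.03), max f4-ratio = 0.1778
regions called: 43 spanning 1.42 Mb (x = 0.178 from f4_ratio)
pi in/out: 0.002814 / 0.002606 (one-sided p = 7.24e-07, +6.8%)
rho in/out medians: 10.93 / 14.24 (one-sided p = 0.526)
sweep overlap: 16/140 windows (Fisher one-sided p = 9.63e-09)
truth recovery: precision 0.678, recall 0.980
```

Reading the output: the receptor–donor trio shows a significantly
positive D (Z = 5.0 > 4), i.e. excess allele sharing between P2 and P3;
the f4-ratio estimates that ≈ 17.8% of the receptor genome derives from
the donor (truth: 20% of each haplotype); calling regions at x = f̂
recovers the planted tracts with base-pair precision 0.68 and recall
0.98; nucleotide diversity is 6.8% higher inside the called regions
(the donor lineage is less bottlenecked than the receptor, so
introgression restores diversity); and the planted sweeps overlap the
called regions far beyond chance (Fisher p ≈ 1e-8). Per-stage TSV/BED
outputs and a checksummed manifest are written to `demo_run/`.

Lower-level building blocks are exported individually:
`read_vcf()`, `apply_site_filters()`, `map_position()`,
`merge_lineage()`, `allele_frequencies()`, `d_statistic()`,
`f4_ratio()`, `window_scan()`, `call_introgressed()`, `pi_windows()`,
`fst_wc_windows()`, `compare_in_out()`, `fisher_enrichment()`,
`permutation_overlap()`, and the generator functions
(`sample_tree_frequencies()`, `place_introgression_tracts()`,
`sample_genotypes()`, `emit_dataset()`).

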