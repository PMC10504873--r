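---
title: "Detecting interploidy introgression: models, parameters and design choices"
author: "interflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interploidy introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An allopolyploid crop grown alongside its diploid progenitors can keep
receiving genetic material from them: hybridization across the ploidy
barrier followed by backcrossing leaves *introgressed tracts* of diploid
ancestry inside the tetraploid's matching subgenome. interflow detects and
characterizes such interploidy gene flow from cohort VCFs. The receptor
subgenome and the diploid donor genome live on different reference
coordinate systems, so the first task is purely structural: one-to-one
syntenic blocks map the subgenome onto the diploid frame, and only sites
present in both callsets after mapping (with reconcilable REF/ALT alleles)
enter the joint lineage dataset.

All statistics operate on the four-population topology
`([{P1, P2}, P3], O)`: two morphotypes of the receptor species (P1, P2),
a candidate diploid donor (P3), and a distant outgroup (O).

## Statistics

**Site patterns.** With derived-allele frequencies `p1, p2, p3, pO`
(derived = allele minor in the outgroup, ties broken toward ALT),

```
ABBA = (1-p1) p2 p3 (1-pO) + p1 (1-p2)(1-p3) pO
BABA = p1 (1-p2) p3 (1-pO) + (1-p1) p2 (1-p3) pO
```

Note `ABBA - BABA = (p2 - p1)(p3 - pO)`. The outgroup terms keep the
estimator usable when O is not perfectly fixed ancestral; every statistic
below is invariant to a global complement of the polarization, so the
ALT-ward tie-break cannot bias results.

**Patterson's D.** `D = sum(ABBA-BABA) / sum(ABBA+BABA)` over informative
sites. Under the null of no gene flow the two sister lineages share
alleles with the donor symmetrically and `E[D] = 0`; `D > 0` indicates
P2-P3 sharing, `D < 0` P1-P3 sharing. Significance uses a delete-one
block jackknife over contiguous blocks of equal informative-site count
(default 20 blocks; the equal-count rule keeps the leave-one-out
estimates comparable), with `|Z| > 4` flagged, the conventional
genome-scan threshold.

**f4-ratio.** The admixture proportion is estimated by substituting one
half of the donor sample for P2:

```
f = sum num(p1, p2,  p3a, pO) / sum num(p1, p3b, p3a, pO)
```

where `(p3a, p3b)` are frequencies from a fixed, seeded half-split of the
P3 samples (split once, reused across all sites). Because the two halves
are independent draws from the same population, the denominator is an
unbiased small-sample estimate of the numerator under full replacement,
and the ratio estimates the fraction of the P2 genome of donor origin.

**Window scan (fd / fdM).** Windows of 10 kb advanced by 1 kb (the scan
used for localization). `fd` divides the window numerator by the same sum
with both P2 and P3 replaced by the dynamic donor `pD = max(p2, p3)`;
windows with non-positive numerator report 0 with a flag, as `fd` is only
defined for P2-P3 excess. `fdM` is the symmetric extension: sites with
`p2 >= p1` use the (P2,P3) dynamic donor, sites with `p2 < p1` use the
(P1,P3) dynamic donor with reversed sign, which bounds the statistic in
`[-1, 1]` and makes both directions of flow scannable. Windows with fewer
than `min_sites = 5` informative sites (or a non-positive fdM
denominator) are flagged invalid and excluded from both thresholding and
selection; this guards against near-empty windows dominating the top-x%
call. Note that with tens of samples per population fdM is strongly
attenuated relative to the true local admixture fraction (the `max` of
two noisy frequencies is upward-biased, inflating the denominator), so
fdM is used only as a *ranking*, never as a proportion estimate - the
proportion comes from the f4-ratio.

**Region calling.** Putative introgressed regions are the highest-`x`
fraction of valid windows by fdM, where `x` is the trio's f4-ratio
estimate: the called span is thereby calibrated to the estimated
admixture proportion. The threshold is the `ceiling(x*m)`-th largest fdM
value with ties included (this reproduces "top x% of windows" exactly
when scores are distinct); selected windows that overlap or are bookended
merge into regions. A `min_gap` parameter can bridge small gaps but is
off by default, the conservative reading of "merge the filtered
windows".

**Feature contrasts.** Windowed nucleotide diversity
(`pi_site = n/(n-1) * 2p(1-p)`, window value normalized by the full
window length, the convention of windowed-diversity tools), absolute
divergence Dxy, and Weir-Cockerham Fst (per-site variance components
a/b/c, window value `sum(a)/sum(a+b+c)` - the ratio-of-sums form, stable
at low per-site information). Windows are classified in/out of the called
regions by the midpoint rule (avoiding double counting of straddling
windows; an any-overlap rule is available) and compared by Mann-Whitney:
exact when both groups have at most 20 untied values, tie-corrected
normal approximation otherwise.

**Enrichment.** Sweep tracks (e.g. XP-CLR, XP-EHH) are thresholded at the
95th percentile with strict `>` (ties at the threshold excluded; the
inverse-ECDF quantile makes "floor((1-q)m) windows when distinct" exact);
candidate sweeps are the base-pair intersection of the two methods' top
sets. Sweep/introgression overlap is tested two ways: a Fisher exact test
with scan windows as sampling units (exact hypergeometric one-sided
`P(X >= k)`; two-sided by minimum likelihood), and a circular-permutation
null that rotates one region set per chromosome - the rotation null
preserves the autocorrelation that the window-level Fisher test ignores,
and is reported alongside it. Gene-region overlap uses >= 1 bp in
half-open coordinates. A Bonferroni helper covers user-supplied gene-set
families.

## The synthetic cohort generator

`sim_config()` defines the study conditions; the defaults are fixed and
used by the validation experiments throughout:

* **Genome / sites**: one 5 Mb chromosome, ~50,000 SNPs (one per 100 bp,
  a dense resequencing panel's SNP density).
* **Samples**: 20 diploids per population - the scale of a morphotype
  panel in a crop resequencing study (panels of this kind typically hold
  between a handful and a few dozen accessions per group).
* **Drift** (Balding-Nichols per branch,
  `child ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, root frequencies
  Uniform(0.05, 0.95) to avoid degenerate pattern sums): P1 = P2 = 0.05
  (recent, symmetric morphotype divergence - symmetry is what makes the
  no-introgression null of D exact), P12 = 0.2 (the allopolyploid origin
  is a severe founder bottleneck on the receptor stem), P3 = 0.15 (donor
  morphotype domestication), P123 = 0.05, O = 0.4 (the outgroup is a
  separate species). F = 0 is handled as exact identity since the Beta
  parameters diverge.
* **Tracts**: a per-chromosome renewal template of alternating
  exponential segments (tract mean 50 kb; gap mean `tract_mean(1-f)/f`,
  giving expected coverage `f_target = 0.2`), shared by all receptor
  haplotypes. Sharing models a *historical* introgression event whose
  tracts segregate or are fixed in the receptor population; fully
  independent per-haplotype tracts would place ~20% donor ancestry in
  every window of every individual, a spatially uniform signal that no
  window statistic could localize and that does not correspond to any
  real introgression history. `carrier_freq` sets the frequency at which
  haplotypes carry each template tract: 1 (default) is a swept event;
  values below 1 leave an ancestry mixture inside tracts, which raises
  local heterozygosity - the generator's mechanism for the
  diversity-contrast experiments (run at 0.6). Within tracts, receptor
  haplotypes draw alleles from the donor frequency p3.
* **Recombination bias**: the emitted rho track (50 kb windows,
  log-normal values, a sampled high/low designation) can re-weight tract
  starts: gap proposals are thinned so the effective tract-start rate is
  `(1 + recomb_bias)`-fold higher inside high-rho windows, with the base
  rate rescaled to preserve the target coverage. This reproduces the
  qualitative association of introgression with high-recombination
  regions when switched on (the feature experiments use 2).
* **Sweep tracks**: sweeps are planted in 20% of template tracts (a few
  percent of the genome - genome scans find sweeps to be sparse), with a
  per-window strength shared between the XP-CLR-like and XP-EHH-like
  tracks (the two methods respond to the same events) plus independent
  method noise.
* **Depth / missingness**: per-genotype depth ~ Poisson(8) (a typical
  effective mapped depth), i.i.d. missingness 2%.
* **Coordinates**: the tetraploid cohort (P1 and P2) is emitted on a
  subgenome frame shifted by 1 Mb, with the 7-column syntenic block table
  linking the frames - so every downstream analysis must pass through the
  cross-ploidy merge, as with real data.
* **Seeds**: one master seed; each stage derives a labelled sub-stream,
  so any stage is independently reproducible and identical
  `(config, seed)` reproduce all files byte-identically.

**What the generator does not emulate.** Sites are independent given the
tree (no linkage disequilibrium or recombination map beyond the tract
process and the optional bias weights), there is no selection dynamics,
no homoeologous exchange, no reference or mapping bias, and genotype
errors beyond random missingness are absent. Passing the validation
experiments therefore demonstrates that the *estimators and their
calibration* behave as designed under the assumed generative model - not
that real cohorts satisfy that model. In particular the block jackknife
is validated here only in its SE arithmetic; its robustness to linkage is
the reason it is used on real data, not something independent sites can
test.

## Pipeline ordering and numerical choices

* Genotype-level depth bounds (3-40) recode genotypes to missing
  *before* the missing-rate rule, the VCFtools order. Depth and
  biallelic rules are applied per cohort VCF; the missing-rate (<= 15%)
  and minor-allele-count (>= 3) rules are applied to the merged lineage
  matrix, where rarity is defined across all species jointly - applying
  MAC per species would silently drop every site monomorphic in any one
  species and condition the joint frequency spectrum.
* Internal interval coordinates are 0-based half-open everywhere (VCF
  I/O converts to/from 1-based; BED is native), which removes off-by-one
  ambiguity from the window/region algebra; minus-strand block mapping is
  `dst_end - (pos - src_start) - 1`.
* Allele reconciliation at the merge: minus-strand alleles are
  complemented; swapped REF/ALT pairs are kept with flipped dosages;
  anything else is dropped and counted (the conservative policy for
  conflicts between independently called cohorts).
* Sites where any trio population has zero called alleles are skipped
  per-statistic and counted; an all-uninformative trio yields an explicit
  `NA`-with-status result, never a silent zero. A zero jackknife SE flags
  Z as undefined.
* Quantile conventions: region calling uses the k-th-largest rule with
  ties *included* (>=); sweep selection uses the type-1 quantile with
  strict `>` (ties excluded). Both rules are documented at their
  functions and chosen to make the respective count identities exact.

## Problem sizes of the validation experiments

The bundled experiments run on one CPU in a few minutes: null calibration
(20 replicates at 50k sites), f4 recovery (4 admixture levels x 10
replicates), localization (5 replicates with the 10 kb / 1 kb scan over
5 Mb), feature contrasts (10 replicates under the diversity-contrast
condition), plus exhaustive oracle checks (all 2x2 tables with N <= 60;
full permutation enumeration of small Mann-Whitney problems; 1,000-site
brute-force recomputation of D, fd, fdM, pi, Dxy and Fst).

## Known limitations

* fdM attenuation means the fdM *value* of a called region understates
  the local admixture fraction; only its rank order is used.
* The f4-ratio assumes the donor sample is exchangeable; strong internal
  structure in P3 would bias the half-split denominator.
* The window-level Fisher overlap test treats sliding windows as
  independent units; use the circular-permutation p-value when the
  autocorrelation matters.
* With very small outgroup samples the polarization becomes noisy;
  statistics remain consistent (they are complement-invariant) but
  per-site derived labels should not be over-interpreted.
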