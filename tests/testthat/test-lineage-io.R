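# VCF reading, site filters, synteny mapping, cross-ploidy merge and
# derived-allele frequency tables.

test_that("VCF write/read round-trips the dosage matrix exactly", {
  dos <- matrix(c(0L, 1L, 2L, NA, 1L, 0L, 2L, 2L, NA, 0L, 1L, 1L),
                nrow = 4, dimnames = list(NULL, c("a", "b", "c")))
  dp <- matrix(8L, 4, 3, dimnames = dimnames(dos))
  gm <- gm_from_dosages(dos, pops = c("X", "X", "Y"), dp = dp)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, gm$popmap)
  expect_identical(back$geno, gm$geno)
  expect_equal(back$dp, gm$dp)
  expect_equal(back$sites$pos, gm$sites$pos)
})

test_that("samples absent from the popmap are dropped with a warning", {
  dos <- matrix(1L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  gm <- gm_from_dosages(dos, pops = c("X", "X", "Y"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  pm <- data.frame(sample = c("a", "b"), population = "X")
  expect_warning(back <- read_vcf(path, pm), "absent from popmap")
  expect_equal(colnames(back$geno), c("a", "b"))
})

test_that("missing genotypes and multi-allelic records survive parsing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.",
    "chr1\t200\t.\tG\tC,T\t.\tPASS\t.\tGT\t1/2\t0/0"), path)
  pm <- data.frame(sample = c("a", "b"), population = "X")
  gm <- read_vcf(path, pm)
  expect_true(is.na(gm$geno[1, "b"]))
  expect_equal(gm$geno[1, "a"], c(a = 1L))
  expect_false(gm$sites$biallelic[2])
})

test_that("site filters implement the standard removal rules", {
  # 10 samples; craft one failure per rule
  n_samp <- 10
  dos <- matrix(1L, 5, n_samp,
                dimnames = list(NULL, paste0("s", 1:n_samp)))
  dos[1, ] <- c(rep(NA, 2), rep(0L, 4), rep(1L, 4))   # 20% missing
  dos[2, ] <- c(rep(1L, 2), rep(0L, 8))               # mac = 2
  dos[3, ] <- rep(0:1, 5)                             # fine, mac = 5
  dos[4, ] <- rep(0:1, 5)                             # depth fail below
  dos[5, ] <- rep(0:1, 5)                             # multi-allelic below
  dp <- matrix(10, 5, n_samp)
  # one outlier genotype drives the site mean above 40 while the other
  # genotypes stay inside the per-genotype bounds
  dp[4, ] <- c(rep(10, 9), 500)
  gm <- gm_from_dosages(dos, pops = rep("X", n_samp), dp = dp)
  gm$sites$biallelic[5] <- FALSE
  out <- apply_site_filters(gm, filter_spec())
  counts <- attr(out, "removal_counts")
  expect_equal(nrow(out$sites), 1L)
  expect_equal(out$sites$pos, gm$sites$pos[3])
  expect_equal(unname(counts["missing_rate"]), 1L)
  expect_equal(unname(counts["mac"]), 1L)
  expect_equal(unname(counts["mean_depth"]), 1L)
  expect_equal(unname(counts["not_biallelic"]), 1L)
  # removal counts sum to input - output
  expect_equal(unname(counts["input"] - counts["output"]),
               sum(counts[c("not_biallelic", "missing_rate", "mac",
                            "mean_depth")]))
})

test_that("genotype-level depth recode happens before the missing-rate rule", {
  n_samp <- 10
  dos <- matrix(rep(0:1, 5 * n_samp / 2), 5, n_samp,
                dimnames = list(NULL, paste0("s", 1:n_samp)))
  dp <- matrix(10, 5, n_samp)
  dp[1, 1:2] <- 1 # two genotypes below minDP -> 20% missing at site 1
  gm <- gm_from_dosages(dos, pops = rep("X", n_samp), dp = dp)
  out <- apply_site_filters(gm, filter_spec())
  expect_false(gm$sites$pos[1] %in% out$sites$pos)
})

test_that("depth filter is skipped with a warning when DP is absent", {
  dos <- rbind(rep(0:1, 5), rep(1:0, 5))
  colnames(dos) <- paste0("s", 1:10)
  gm <- gm_from_dosages(dos, pops = rep("X", 10))
  expect_warning(out <- apply_site_filters(gm, filter_spec()),
                 "depth filter skipped")
  expect_equal(nrow(out$sites), 2L)
})

test_that("syntenic position mapping is offset arithmetic on + strand", {
  map <- synteny_map(data.frame(src_chrom = "A", src_start = 1000,
                                src_end = 2000, dst_chrom = "B",
                                dst_start = 5000, dst_end = 6000,
                                strand = "+"))
  expect_equal(map_position(map, "A", 1500)$pos, 5500)
  expect_true(is.na(map_position(map, "A", 999)$pos))
  expect_true(is.na(map_position(map, "A", 2000)$pos)) # half-open end
  expect_equal(map_position(map, "A", 1000)$pos, 5000)
})

test_that("minus-strand mapping is a reflected bijection on the block", {
  map <- synteny_map(data.frame(src_chrom = "A", src_start = 100,
                                src_end = 110, dst_chrom = "B",
                                dst_start = 500, dst_end = 510,
                                strand = "-"))
  src <- 100:109
  dst <- map_position(map, rep("A", 10), src)$pos
  expect_equal(dst, 509:500) # dst_end - (pos - src_start) - 1
  expect_equal(sort(dst), 500:509) # bijective onto the block
  # inverse map restores the original positions
  inv <- map_position(synteny_invert(map), rep("B", 10), dst)$pos
  expect_equal(inv, src)
})

test_that("malformed synteny blocks are rejected at load", {
  expect_error(synteny_map(data.frame(
    src_chrom = "A", src_start = 0, src_end = 10, dst_chrom = "B",
    dst_start = 0, dst_end = 20, strand = "+")), "lengths differ")
  expect_error(synteny_map(data.frame(
    src_chrom = c("A", "A"), src_start = c(0, 5), src_end = c(10, 15),
    dst_chrom = "B", dst_start = c(0, 20), dst_end = c(10, 30),
    strand = "+")), "overlapping src")
})

test_that("identity merge duplicates genotypes per sample pair", {
  dos <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3,
                dimnames = list(NULL, c("a", "b")))
  gm1 <- gm_from_dosages(dos, pops = c("X", "X"))
  dos2 <- dos; colnames(dos2) <- c("c", "d")
  gm2 <- gm_from_dosages(dos2, pops = c("Y", "Y"))
  merged <- merge_lineage(gm1, gm2, NULL)
  expect_equal(nrow(merged$sites), 3L)
  expect_equal(ncol(merged$geno), 4L)
  expect_identical(unname(merged$geno[, "a"]), unname(merged$geno[, "c"]))
})

test_that("merge reconciles alleles and drops inconsistent sites", {
  # 4 sites; tetraploid frame shifted +1000 on a - strand block is tested
  # separately; here: same frame, one swapped REF/ALT, one mismatched
  sites1 <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                       ref = c("A", "A", "A", "A"),
                       alt = c("T", "T", "T", "T"))
  dos1 <- matrix(1L, 4, 2, dimnames = list(NULL, c("a", "b")))
  gm1 <- genotype_matrix(sites1, dos1,
                         popmap = data.frame(sample = c("a", "b"),
                                             population = "X"))
  sites2 <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                       ref = c("A", "T", "G", "A"),
                       alt = c("T", "A", "C", "T"))
  dos2 <- matrix(2L, 4, 1, dimnames = list(NULL, "c"))
  gm2 <- genotype_matrix(sites2, dos2,
                         popmap = data.frame(sample = "c",
                                             population = "Y"))
  merged <- merge_lineage(gm1, gm2, NULL)
  counts <- attr(merged, "merge_counts")
  expect_equal(nrow(merged$sites), 3L) # site 300 dropped (G/C vs A/T)
  expect_equal(unname(counts["allele_dropped"]), 1L)
  expect_equal(unname(counts["flipped"]), 1L)
  # swapped site 200: dosage complemented 2 -> 0
  expect_equal(unname(merged$geno[merged$sites$pos == 200, "c"]), 0L)
  expect_equal(unname(merged$geno[merged$sites$pos == 100, "c"]), 2L)
})

test_that("disjoint site sets merge to empty with a warning", {
  gm1 <- gm_from_dosages(matrix(1L, 2, 1, dimnames = list(NULL, "a")),
                         pops = "X", pos = c(100L, 200L))
  gm2 <- gm_from_dosages(matrix(1L, 2, 1, dimnames = list(NULL, "b")),
                         pops = "Y", pos = c(150L, 250L))
  expect_warning(merged <- merge_lineage(gm1, gm2, NULL), "empty")
  expect_equal(nrow(merged$sites), 0L)
})

test_that("merge rejects duplicate sample names and empty block maps", {
  gm <- gm_from_dosages(matrix(1L, 2, 1, dimnames = list(NULL, "a")),
                        pops = "X")
  expect_error(merge_lineage(gm, gm, NULL), "duplicate sample names")
})

test_that("merge symmetry: both directions retain the same site multiset", {
  cfg <- sim_config(n_sites = 300, chrom_length = 1e5,
                    samples_per_pop = 3, seed = 17)
  f <- sample_tree_frequencies(cfg)
  s <- sample_genotypes(f, place_introgression_tracts(cfg), cfg)
  dip <- s$cohorts$donor
  tet <- s$cohorts$tetraploid
  m_fwd <- merge_lineage(dip, tet, synteny_invert(s$synteny))
  m_rev <- merge_lineage(tet, dip, s$synteny)
  expect_equal(nrow(m_fwd$sites), nrow(m_rev$sites))
  expect_equal(m_fwd$sites$pos, m_rev$sites$pos - cfg$coord_offset)
})

test_that("derived alleles follow the outgroup-minor rule", {
  # outgroup fixed REF: derived = ALT; population dosages {0,1,1,2}
  dos <- cbind(matrix(c(0L, 1L, 1L, 2L), 1), matrix(0L, 1, 2))
  colnames(dos) <- c("p1", "p2", "p3", "p4", "o1", "o2")
  gm <- gm_from_dosages(dos, pops = c(rep("P", 4), rep("O", 2)))
  ft <- allele_frequencies(gm, outgroup = "O")
  expect_equal(ft$derived, "T")
  expect_equal(ft$p_P, 0.5)
  expect_equal(ft$n_P, 8L)

  # outgroup fixed ALT: derived = REF; frequencies complemented
  dos2 <- dos; dos2[, c("o1", "o2")] <- 2L
  gm2 <- gm_from_dosages(dos2, pops = c(rep("P", 4), rep("O", 2)))
  ft2 <- allele_frequencies(gm2, outgroup = "O")
  expect_equal(ft2$derived, "A")
  expect_equal(ft2$p_P, 0.5)
  expect_equal(ft2$p_O, 0)

  # 50/50 outgroup: tie broken toward ALT and recorded
  dos3 <- dos; dos3[, c("o1", "o2")] <- c(0L, 2L)
  gm3 <- gm_from_dosages(dos3, pops = c(rep("P", 4), rep("O", 2)))
  ft3 <- allele_frequencies(gm3, outgroup = "O")
  expect_equal(ft3$derived, "T")
  expect_true(ft3$tie)
})

test_that("all-missing outgroup sites are dropped and counted", {
  dos <- cbind(matrix(1L, 2, 2), matrix(c(NA, 0L, NA, 1L), 2, 2))
  colnames(dos) <- c("p1", "p2", "o1", "o2")
  gm <- gm_from_dosages(dos, pops = c("P", "P", "O", "O"))
  ft <- allele_frequencies(gm, outgroup = "O")
  expect_equal(nrow(ft), 1L)
  expect_equal(attr(ft, "n_dropped_outgroup"), 1L)
  expect_error(allele_frequencies(gm, outgroup = "Z"), "not present")
})

test_that("filtering is order-independent across rule application", {
  # same spec, sites failing multiple rules: output identical regardless
  # of which rule formally removes them
  withr::with_seed(31, {
    dos <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 20, 10,
                  dimnames = list(NULL, paste0("s", 1:10)))
    dp <- matrix(rpois(200, 8), 20, 10)
    gm <- gm_from_dosages(dos, pops = rep("X", 10), dp = dp)
    full <- apply_site_filters(gm, filter_spec())
    # apply mac-only, then the rest: same surviving site set
    only_mac <- apply_site_filters(gm, filter_spec(
      biallelic_only = FALSE, max_missing = 1, min_mac = 3,
      min_mean_dp = -Inf, max_mean_dp = Inf))
    then_rest <- apply_site_filters(only_mac, filter_spec())
    expect_equal(then_rest$sites$pos, full$sites$pos)
  })
})
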