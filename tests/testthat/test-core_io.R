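test_that("read_phased_vcf transcribes a phased toy VCF directly", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|1",
    "chr1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0"))
  p <- read_phased_vcf(path)
  expect_equal(dim(p$alleles), c(4L, 3L))
  expect_equal(unname(p$alleles),
               matrix(c(0L, 1L, 1L, 1L,  0L, 0L, 0L, 1L,  1L, 0L, 0L, 0L), 4L))
  expect_equal(rownames(p$alleles), c("s1_1", "s1_2", "s2_1", "s2_2"))
  expect_equal(p$sites$pos, c(100, 200, 300))
  expect_equal(p$sites$ancestral_state, c("ref", "alt", "unknown"))

  empty <- read_phased_vcf(path, region = "chr1:400-500")
  expect_equal(n_sites(empty), 0L)
  expect_equal(n_haplotypes(empty), 4L)
})

test_that("multiallelic records are retained at read time and flagged", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t2|0",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1"))
  p <- read_phased_vcf(path)
  expect_equal(n_sites(p), 2L)
  expect_equal(p$sites$multiallelic, c(TRUE, FALSE))
  expect_true(is.na(p$alleles["s2_1", 1L]))  # allele 2 not representable
})

test_that("unphased modern genotypes error naming sample and site", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t0/1"))
  expect_error(read_phased_vcf(path), "s2.*chr1:100")
  # the same genotype in a declared archaic sample is fine
  expect_silent(p <- read_phased_vcf(path, archaic_samples = "s2"))
  expect_equal(p$groups, c("modern_noncarrier", "modern_noncarrier",
                           "archaic", "archaic"))
})

test_that("filter_sites applies the merged-panel rules (hand enumeration)", {
  # 6 sites: outside mask / multiallelic / missing call / archaic-het /
  # two clean segregating -> 2 retained
  alleles <- rbind(
    m1_1 = c(1L, 1L, 1L, 0L, 1L, 0L),
    m1_2 = c(0L, 0L, NA, 0L, 0L, 1L),
    a1_1 = c(1L, 0L, 0L, 0L, 1L, 0L),
    a1_2 = c(1L, 0L, 0L, 1L, 1L, 0L))
  p <- make_panel(alleles, pos = c(50, 150, 250, 350, 450, 550),
                  groups = c("modern_noncarrier", "modern_noncarrier",
                             "archaic", "archaic"),
                  multi = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  mask <- region_mask("chr1", 100, 600)   # excludes pos 50
  f <- filter_sites(p, mask, drop_archaic_hets = TRUE)
  expect_equal(f$sites$pos, c(450, 550))
  # idempotence and order preservation
  expect_identical(filter_sites(f, mask, TRUE), f)
  # all-clean panel is untouched; empty panel passes through
  clean <- make_panel(rbind(c(0L, 1L), c(1L, 0L)))
  expect_identical(filter_sites(clean), clean)
  empty <- subset_panel(clean, sites = integer())
  expect_equal(n_sites(filter_sites(empty)), 0L)
})

test_that("archaic collapse requires het-free sites and keeps one row", {
  alleles <- rbind(m1_1 = c(0L, 1L), m1_2 = c(1L, 0L),
                   a1_1 = c(1L, 0L), a1_2 = c(1L, 1L))
  p <- make_panel(alleles, groups = c("modern_noncarrier", "modern_noncarrier",
                                      "archaic", "archaic"))
  expect_error(collapse_archaics(p), "heterozygous")
  f <- filter_sites(p, drop_archaic_hets = TRUE)
  cp <- collapse_archaics(f)
  expect_equal(n_haplotypes(cp), 3L)
  expect_true("a1" %in% rownames(cp$alleles))
})

test_that("haplotypes_to_fasta writes allele bases in site order", {
  sites <- data.frame(chrom = "chr1", pos = c(10, 20), id = c("a", "b"),
                      ref = c("A", "C"), alt = c("T", "G"),
                      ancestral_state = "ref", multiallelic = FALSE)
  p <- haplotype_panel(matrix(c(0L, 1L), nrow = 1L,
                              dimnames = list("h1", NULL)),
                       sites, "modern_noncarrier")
  expect_equal(unname(haplotypes_to_fasta(p)), "AG")

  X <- rbind(h1 = c(0L, 1L, 0L), h2 = c(0L, 1L, 0L), h3 = c(1L, 1L, 1L))
  p3 <- make_panel(X)
  seqs <- haplotypes_to_fasta(p3)
  expect_length(seqs, 3L)                       # one record per haplotype
  expect_identical(seqs[["h1"]], seqs[["h2"]])  # duplicates -> identical
  expect_true(all(nchar(seqs) == n_sites(p3)))  # length = retained sites
  path <- tempfile(fileext = ".fa")
  haplotypes_to_fasta(p3, path)
  expect_equal(sum(startsWith(readLines(path), ">")), 3L)
  pm <- make_panel(rbind(c(0L, NA)))
  expect_error(haplotypes_to_fasta(pm), "missing")
})

test_that("genetic map reader validates monotonicity and interpolates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tcM", "chr1\t1\t0", "chr1\t1000000\t1"), path)
  map <- read_genetic_map(path)
  expect_s3_class(map, "genetic_map")
  expect_equal(interpolate_cM(map, 500000.5), 0.5, tolerance = 1e-9)
  writeLines(c("chrom\tpos\tcM", "chr1\t1\t1", "chr1\t1000000\t0"), path)
  expect_error(read_genetic_map(path), "nondecreasing")
  expect_error(interpolate_cM(map, 2e6), "range")
})

test_that("BED masks merge touching intervals", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t100\t200", "chr1\t300\t400"), path)
  mask <- read_mask(path)
  expect_equal(nrow(mask$intervals), 2L)
  expect_equal(mask$intervals$end[1L], 200)
  expect_equal(in_mask(mask, "chr1", c(1, 200, 201, 300, 301)),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("fragment lists round-trip and reject bad input", {
  path <- tempfile(fileext = ".tsv")
  x <- c(0.01, 0.5, 1.2)
  write_fragments(x, path)
  expect_equal(read_fragments(path), x)
  writeLines(c("0.1", "-0.2"), path)
  expect_error(read_fragments(path), "nonnegative")
})

test_that("simulated panels round-trip through the VCF writer/reader", {
  sim <- simulate_panel(sim_config(n_modern_haplotypes = 12,
                                   region_length = 5e4, seed = 11))
  path <- tempfile(fileext = ".vcf")
  write_panel_vcf(sim$panel, path)
  back <- read_phased_vcf(path, archaic_samples = c("arch1", "arch2", "arch3"))
  expect_equal(unname(back$alleles), unname(sim$panel$alleles))
  expect_equal(back$sites$pos, sim$panel$sites$pos)
  expect_equal(back$sites$ancestral_state, sim$panel$sites$ancestral_state)
})
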