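test_that("read_vcf builds the expected dosage matrix from the toy fixture", {
  gm <- read_vcf(fixture_vcf_basic(), fixture_groups_3())
  expect_equal(n_sites(gm), 5L)
  expect_equal(n_samples(gm), 3L)
  expect_equal(gm$pos, c(100L, 200L, 300L, 400L, 500L))
  expected <- matrix(c(0L, 1L, NA, 2L, 0L,
                       1L, 1L, 0L, 2L, 0L,
                       2L, 0L, 1L, 2L, 1L), 5, 3)
  expect_equal(unname(gm$geno), expected)
  expect_equal(sum(is.na(gm$geno)), 1L)   # exactly one missing cell
  expect_false(gm$phased)
  expect_equal(gm$mean_dp, rep(30, 5))    # INFO/DP = 90 over 3 samples
  expect_equal(gm$pop_labels, c("Target", "Control", "Background"))
})

test_that("read_vcf records haplotypes for fully phased input", {
  gm <- read_vcf(fixture_vcf_phased(), fixture_groups_3())
  expect_true(gm$phased)
  expect_equal(unname(gm$haplotypes[1, ]), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(gm$haplotypes[2, ]), c(1L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(unname(gm$geno[, 1]), c(1L, 1L))
})

test_that("read_vcf refuses samples absent from the groups file", {
  g2 <- write_lines_tmp(c("S1\tTarget", "S2\tControl"), ".tsv")
  expect_error(read_vcf(fixture_vcf_basic(), g2), "missing from groups")
})

test_that("write_vcf / read_vcf round-trips the retained fields", {
  gm <- small_gm(n_sites = 25)
  gm$qual <- rep(60, 25); gm$mean_dp <- rep(20, 25)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  groups <- write_lines_tmp(paste(gm$sample_ids, gm$pop_labels, sep = "\t"),
                            ".tsv")
  back <- read_vcf(path, groups)
  expect_equal(back$geno, gm$geno)
  expect_equal(back$pos, gm$pos)
  expect_equal(back$ref, gm$ref)
  expect_equal(back$alt, gm$alt)
  expect_equal(back$qual, gm$qual)
  expect_equal(back$mean_dp, gm$mean_dp, tolerance = 0.02)
  # phased matrices round-trip through "|" genotypes
  wf <- simulate_wright_fisher(wf_spec(N_e = 8, L = 20000L, split_gens = 5L,
                                       burnin_gens = 40L, seed = 2))
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(wf$gm, p2)
  g3 <- write_lines_tmp(paste(wf$gm$sample_ids, wf$gm$pop_labels, sep = "\t"),
                        ".tsv")
  back2 <- read_vcf(p2, g3)
  expect_true(back2$phased)
  expect_equal(back2$haplotypes, wf$gm$haplotypes)
})

test_that("the 10-site filter fixture retains exactly the 5 hand-verified sites", {
  gm <- read_vcf(fixture_vcf_filter(), fixture_groups_3())
  out <- apply_filters(gm, filter_spec())
  expect_equal(n_sites(out), 5L)
  expect_equal(out$pos, c(100L, 200L, 800L, 900L, 1000L))
  rep <- attr(out, "filter_report")
  counts <- setNames(rep$removed, rep$criterion)
  expect_equal(unname(counts["min_qual"]), 1L)
  expect_equal(unname(counts["biallelic_only"]), 1L)
  expect_equal(unname(counts["min_nonref_allele_count"]), 1L)
  expect_equal(unname(counts["snps_only"]), 2L)
  expect_equal(sum(rep$removed), n_sites(gm) - n_sites(out))
})

test_that("filtering is idempotent and a disabled spec is the identity", {
  gm <- read_vcf(fixture_vcf_filter(), fixture_groups_3())
  off <- filter_spec(min_qual = NULL, biallelic_only = FALSE,
                     min_mean_dp = NULL, max_mean_dp = NULL,
                     max_missing_fraction = NULL,
                     min_nonref_allele_count = NULL, snps_only = FALSE)
  same <- apply_filters(gm, off)
  expect_equal(n_sites(same), n_sites(gm))
  once <- apply_filters(gm, filter_spec())
  twice <- apply_filters(once, filter_spec())
  expect_equal(twice$pos, once$pos)
  expect_equal(twice$geno, once$geno)
})

test_that("zero missing tolerance drops any site with a missing call", {
  gm <- read_vcf(fixture_vcf_basic(), fixture_groups_3())
  out <- apply_filters(gm, filter_spec(max_missing_fraction = 0,
                                       min_nonref_allele_count = NULL))
  expect_false(300L %in% out$pos)
  expect_equal(n_sites(out), 4L)
})

test_that("maf filter removes fixed and rare sites", {
  gm <- read_vcf(fixture_vcf_filter(), fixture_groups_3())
  out <- apply_filters(gm, filter_spec(maf_min = 0.05))
  # site 1000 is fixed alt (maf 0) -> now dropped too
  expect_false(1000L %in% out$pos)
  expect_equal(n_sites(out), 4L)
})

test_that("read_gff builds strand-aware gene models and handles empties", {
  models <- read_gff(fixture_gff_genes())
  expect_length(models, 2L)
  expect_equal(sort(names(models)), c("geneA", "geneB"))
  ga <- models$geneA
  expect_equal(ga$strand, "+")
  expect_equal(ga$cds$start, c(11L, 31L))
  gb <- models$geneB
  expect_equal(gb$strand, "-")
  expect_equal(gb$chrom, "chrT2")
  # empty file
  empty <- write_lines_tmp("##gff-version 3", ".gff3")
  expect_length(read_gff(empty), 0L)
  # CDS with unresolvable parent warns and is skipped
  orphan <- write_lines_tmp(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t1\t30\t.\t+\t.\tID=gx",
    "chrT\ttest\tCDS\t5\t10\t.\t+\t0\tID=cx;Parent=ghost"), ".gff3")
  expect_warning(m2 <- read_gff(orphan), "without a resolvable parent")
  expect_equal(nrow(m2$gx$cds), 0L)
})

test_that("read_fasta_region extracts exact intervals", {
  fa <- fixture_fasta_genes()
  expect_equal(read_fasta_region(fa, "chrT", 11, 19), "ATGCCTGGG")
  expect_equal(read_fasta_region(fa, "chrT", 14, 14), "C")
  expect_equal(nchar(read_fasta_region(fa, "chrT", 1, 120)), 120L)
  expect_error(read_fasta_region(fa, "chrT", 100, 130), "beyond contig end")
  expect_error(read_fasta_region(fa, "chrZ", 1, 10), "not found")
})

test_that("revcomp behaves, including on a palindrome", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAACCGTAA"), "TTACGGTTT")
})
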