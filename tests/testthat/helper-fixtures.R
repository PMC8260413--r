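# Hand-written plain-text fixtures, created in tempdir() at test time.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fixture_groups_3 <- function() {
  write_lines_tmp(c("S1\tTarget", "S2\tControl", "S3\tBackground"), ".tsv")
}

# 5-site, 3-sample VCF: dosages S1 = (0,1,NA,2,0), S2 = (1,1,0,2,0),
# S3 = (2,0,1,2,1); exactly one missing cell
fixture_vcf_basic <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=90\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t300\t.\tG\tA\t50\tPASS\tDP=90\tGT\t./.\t0/0\t0/1",
    "chr1\t400\t.\tT\tC\t50\tPASS\tDP=90\tGT\t1/1\t1/1\t1/1",
    "chr1\t500\t.\tA\tG\t50\tPASS\tDP=90\tGT\t0/0\t0/0\t0/1"), ".vcf")
}

fixture_vcf_phased <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "chr1\t200\t.\tC\tG\t50\tPASS\t.\tGT\t1|0\t0|1\t1|1"), ".vcf")
}

# 10-site filter fixture: hand-verified against the default filter chain.
# Expected fate, in criterion order:
#   site 3 (QUAL 10)        -> min_qual
#   site 4 (ALT "C,A")      -> biallelic_only
#   site 7 (singleton)      -> min_nonref_allele_count
#   sites 5, 6 (indels)     -> snps_only
#   sites 1, 2, 8, 9, 10    -> retained
fixture_vcf_filter <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t200\t.\tC\tG\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/1",
    "chr1\t300\t.\tG\tA\t10\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t400\t.\tT\tC,A\t50\tPASS\tDP=90\tGT\t0/1\t0/0\t0/2",
    "chr1\t500\t.\tA\tAT\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t600\t.\tCT\tC\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t700\t.\tG\tA\t50\tPASS\tDP=90\tGT\t0/1\t0/0\t0/0",
    "chr1\t800\t.\tA\tC\t50\tPASS\tDP=90\tGT\t0/1\t1/1\t0/1",
    "chr1\t900\t.\tT\tG\t50\tPASS\tDP=90\tGT\t0/1\t0/1\t0/0",
    "chr1\t1000\t.\tC\tT\t50\tPASS\tDP=90\tGT\t1/1\t1/1\t1/1"), ".vcf")
}

# Two-contig FASTA and matching GFF3 used by the annotation tests.
#
# geneA (chrT, + strand): CDS 11-19 = ATGCCTGGG, CDS 31-39 = AAACCGTAA
#   coding: ATG CCT GGG AAA CCG TAA -> M P G K P *
# geneB (chrT2, - strand): plus-strand CDS 11-19 = TTACGGTTT,
#   CDS 31-39 = CCCAGGCAT; revcomp of the concatenation is the same coding
#   sequence M P G K P *.
fixture_fasta_genes <- function() {
  pad <- function(...) paste0(...)
  chrT <- pad(strrep("A", 10), "ATGCCTGGG", strrep("A", 11), "AAACCGTAA",
              strrep("A", 81))
  chrT2 <- pad(strrep("A", 10), "TTACGGTTT", strrep("A", 11), "CCCAGGCAT",
               strrep("A", 81))
  stopifnot(nchar(chrT) == 120, nchar(chrT2) == 120)
  write_lines_tmp(c(">chrT", chrT, ">chrT2", chrT2), ".fa")
}

fixture_gff_genes <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t11\t39\t.\t+\t.\tID=geneA",
    "chrT\ttest\tmRNA\t11\t39\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chrT\ttest\tCDS\t11\t19\t.\t+\t0\tID=geneA.c1;Parent=geneA.t1",
    "chrT\ttest\tCDS\t31\t39\t.\t+\t0\tID=geneA.c2;Parent=geneA.t1",
    "chrT2\ttest\tgene\t11\t39\t.\t-\t.\tID=geneB",
    "chrT2\ttest\tmRNA\t11\t39\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chrT2\ttest\tCDS\t11\t19\t.\t-\t0\tID=geneB.c1;Parent=geneB.t1",
    "chrT2\ttest\tCDS\t31\t39\t.\t-\t0\tID=geneB.c2;Parent=geneB.t1"), ".gff3")
}

# small deterministic three-population matrix built directly (no VCF)
small_gm <- function(n_sites = 30, n_per_pop = c(4, 4, 4), seed = 7,
                     spacing = 1000L) {
  withr::with_seed(seed, {
    n <- sum(n_per_pop)
    g <- matrix(rbinom(n_sites * n, 2, 0.4), n_sites, n)
    genotype_matrix(chrom = "chr1",
                    pos = seq(1L, by = spacing, length.out = n_sites),
                    ref = rep("A", n_sites), alt = rep("C", n_sites),
                    geno = g, sample_ids = paste0("s", seq_len(n)),
                    pop_labels = rep(POP_ROLES, times = n_per_pop))
  })
}
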