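test_that("percentile_threshold uses the stated interpolation convention", {
  v <- 1:1000
  thr <- percentile_threshold(v, 0.99)
  expect_equal(thr, 990.01)
  expect_equal(sum(v > thr), 10L)
  expect_error(percentile_threshold(1:50), ">= 100")
})

test_that("outlier calling: constants, nesting, monotone updates, q = 0", {
  tbl <- data.frame(chrom = "chr1",
                    start = seq(1L, by = 25000L, length.out = 200),
                    end = seq(50001L, by = 25000L, length.out = 200))
  tbl$lsbl <- rep(0.3, 200); tbl$fst <- runif(200)
  # constant vector: nothing strictly above the threshold
  expect_equal(nrow(call_outlier_windows(tbl, "lsbl")), 0L)
  # one extreme value changes the outlier set by exactly that window
  tbl2 <- tbl; tbl2$lsbl[57] <- 5
  out2 <- call_outlier_windows(tbl2, "lsbl")
  expect_equal(out2$start, tbl$start[57])
  # nesting: q = 0.99 outliers are a subset of q = 0.95 outliers
  o99 <- call_outlier_windows(tbl2, "fst", 0.99)
  o95 <- call_outlier_windows(tbl2, "fst", 0.95)
  expect_true(all(o99$start %in% o95$start))
  # q = 0 returns all non-null windows
  tbl2$fst[3] <- NA
  expect_equal(nrow(call_outlier_windows(tbl2, "fst", 0)), 199L)
})

test_that("outlier fraction approximates 1 - q on continuous values", {
  tbl <- data.frame(chrom = "chr1",
                    start = seq(1L, by = 25000L, length.out = 500))
  tbl$end <- tbl$start + 50000L
  tbl$lsbl <- withr::with_seed(2, rnorm(500))
  out <- call_outlier_windows(tbl, "lsbl", 0.99)
  expect_lte(abs(nrow(out) - 0.01 * 500), 1)
})

test_that("merge_windows merges overlap and book-ends, keeps peaks", {
  w <- data.frame(chrom = "chr1", start = c(1L, 25001L),
                  end = c(50001L, 75001L),
                  fst = c(0.5, 0.7), lsbl = c(0.6, 0.4))
  r <- merge_windows(w)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1L, 75000L))
  expect_equal(r$peak_fst, 0.7); expect_equal(r$peak_lsbl, 0.6)
  # disjoint windows stay separate
  w2 <- data.frame(chrom = "chr1", start = c(1L, 200001L),
                   end = c(50001L, 250001L), fst = c(1, 2), lsbl = c(1, 2))
  expect_equal(nrow(merge_windows(w2)), 2L)
  # book-ended (end == next start) windows merge
  w3 <- data.frame(chrom = "chr1", start = c(1L, 50001L),
                   end = c(50001L, 100001L), fst = 1:2, lsbl = 1:2)
  expect_equal(nrow(merge_windows(w3)), 1L)
  # five staggered windows at 25 kb step form one region min-start..max-end
  w5 <- data.frame(chrom = "chr1",
                   start = seq(1L, by = 25000L, length.out = 5),
                   end = seq(50001L, by = 25000L, length.out = 5),
                   fst = runif(5), lsbl = runif(5))
  r5 <- merge_windows(w5)
  expect_equal(nrow(r5), 1L)
  expect_equal(c(r5$start, r5$end), c(1L, 150000L))
  expect_equal(r5$n_windows, 5L)
  # output regions are disjoint and sorted
  wmix <- rbind(w2, w5)
  rmix <- merge_windows(wmix)
  expect_true(all(diff(rmix$start) > 0))
  expect_true(all(rmix$start[-1] > rmix$end[-nrow(rmix)]))
})

test_that("genes_in_regions uses >= 1 bp overlap, hand-checked on 6 genes", {
  genes <- list(
    g1 = gene_model("g1", "chr1", "+", 10000, 20000, data.frame(start = 10000, end = 10300, phase = 0)),   # inside R1
    g2 = gene_model("g2", "chr1", "+", 49000, 50000, data.frame(start = 49000, end = 49300, phase = 0)),   # 1 bp overlap with R1 end
    g3 = gene_model("g3", "chr1", "+", 50001, 60000, data.frame(start = 50001, end = 50300, phase = 0)),   # just outside R1
    g4 = gene_model("g4", "chr1", "+", 199990, 200010, data.frame(start = 199990, end = 199992, phase = 0)), # spans R2 start
    g5 = gene_model("g5", "chr2", "+", 1, 1000, data.frame(start = 1, end = 300, phase = 0)),              # wrong chrom
    g6 = gene_model("g6", "chr1", "+", 300000, 310000, data.frame(start = 300000, end = 300300, phase = 0))) # beyond R2
  regions <- data.frame(chrom = "chr1", start = c(1L, 200000L),
                        end = c(50000L, 250000L))
  out <- genes_in_regions(regions, genes)
  expect_equal(out$gene_ids, c("g1,g2", "g4"))
  expect_equal(attr(out, "gene_set"), c("g1", "g2", "g4"))
})

test_that("outlier_gene_sets reports per-statistic and shared gene sets", {
  n <- 300
  tbl <- data.frame(chrom = "chr1",
                    start = seq(1L, by = 25000L, length.out = n))
  tbl$end <- tbl$start + 50000L
  tbl$fst <- withr::with_seed(8, runif(n, 0, 0.2))
  tbl$lsbl <- withr::with_seed(9, runif(n, 0, 0.2))
  tbl$fst[10] <- 0.9; tbl$lsbl[10] <- 0.9   # shared outlier window
  tbl$fst[50] <- 0.8                        # fst-only outlier
  tbl$lsbl[80] <- 0.8                       # lsbl-only outlier
  genes <- lapply(c(10, 50, 80), function(i)
    gene_model(paste0("g", i), "chr1", "+", tbl$start[i], tbl$start[i] + 100,
               data.frame(start = tbl$start[i], end = tbl$start[i] + 99,
                          phase = 0)))
  res <- outlier_gene_sets(tbl, genes, q = 0.99)
  expect_true("g10" %in% res$genes_fst && "g50" %in% res$genes_fst)
  expect_true("g10" %in% res$genes_lsbl && "g80" %in% res$genes_lsbl)
  expect_equal(res$genes_shared, "g10")
  expect_true(all(res$genes_shared %in% res$genes_fst))
  expect_true(all(res$genes_shared %in% res$genes_lsbl))
  # union regions cover all three spiked windows; intersection keeps only
  # windows outlying on both statistics (window 10; background draws can
  # also land above both 99th percentiles, so assert membership, not counts)
  covered <- function(regions, i)
    any(regions$start <= tbl$start[i] & regions$end >= tbl$start[i])
  expect_true(all(vapply(c(10, 50, 80), covered, TRUE, regions = res$regions)))
  res2 <- outlier_gene_sets(tbl, genes, q = 0.99, combine = "intersection")
  expect_true(covered(res2$regions, 10))
  expect_false(covered(res2$regions, 50))
  expect_false(covered(res2$regions, 80))
})

test_that("haplotype_pattern selects frequency-differential SNPs", {
  # saturated case: Target fixed alt, others absent
  g <- rbind(matrix(c(2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L), 1, 9),
             matrix(c(2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L), 1, 9),
             matrix(rep(1L, 9), 1, 9))  # third site fails the rule
  gm <- genotype_matrix("chr1", c(100L, 200L, 300L), rep("A", 3), rep("T", 3),
                        g, paste0("s", 1:9), rep(POP_ROLES, each = 3))
  hp <- haplotype_pattern(gm, "chr1", 1, 1000)
  expect_equal(hp$pos, c(100L, 200L))
  tg <- hp$matrix[hp$row_pop == "Target", ]
  expect_true(all(tg == 2L))
  expect_equal(nrow(hp$matrix), 9L)  # dosage rows when unphased
  # the reference-allele mirror rule also selects sites
  g2 <- g; g2[1, ] <- c(0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L, 2L)
  gm2 <- genotype_matrix("chr1", c(100L, 200L, 300L), rep("A", 3), rep("T", 3),
                         g2, paste0("s", 1:9), rep(POP_ROLES, each = 3))
  expect_true(100L %in% haplotype_pattern(gm2, "chr1", 1, 1000)$pos)
  # no qualifying SNP -> warning and empty pattern
  gm3 <- genotype_matrix("chr1", 100L, "A", "T", matrix(1L, 1, 9),
                         paste0("s", 1:9), rep(POP_ROLES, each = 3))
  expect_warning(hp3 <- haplotype_pattern(gm3, "chr1", 1, 1000),
                 "no SNP satisfies")
  expect_equal(length(hp3$pos), 0L)
  expect_error(haplotype_pattern(gm, "chr1", 5000, 6000), "no SNPs")
})

test_that("phased input yields two haplotype rows per sample", {
  sim <- simulate_wright_fisher(wf_spec(N_e = 6, L = 20000L, split_gens = 40L,
                                        burnin_gens = 60L, seed = 12))
  gm <- sim$gm
  hp <- tryCatch(haplotype_pattern(gm, "chr1", 1, 20000, freq_high = 0,
                                   freq_low = 1),
                 warning = function(w) NULL)
  # freq_high = 0 / freq_low = 1 accepts every SNP: rows = 2 x samples
  if (!is.null(hp)) expect_equal(nrow(hp$matrix), 2L * n_samples(gm))
})

test_that("neutral data almost never passes the strict 1.0/0.0 rule", {
  sim <- simulate_balding_nichols(bn_spec(F = 0.05, n_diploids = 20,
                                          n_sites = 2000, seed = 3))
  res <- tryCatch(haplotype_pattern(sim$gm, "chr1", 1, max(sim$gm$pos),
                                    freq_high = 1, freq_low = 0),
                  warning = function(w) "empty")
  expect_identical(res, "empty")
})
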