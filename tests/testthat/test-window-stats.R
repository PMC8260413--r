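test_that("site_pi matches the pairwise-difference definition", {
  # n = 4 alleles, j = 2: all 6 pairs, 4 differ -> 2/3
  expect_equal(site_pi(2, 4), 2 * 2 * 2 / (4 * 3))
  expect_equal(site_pi(0, 10), 0)       # monomorphic ref
  expect_equal(site_pi(10, 10), 0)      # monomorphic alt
  expect_true(is.na(site_pi(0, 1)))     # fewer than two alleles
  expect_equal(site_pi(3, 7), site_pi(4, 7))  # allele-label symmetry
})

test_that("window_pi follows the per-window-size convention", {
  # one SNP, two diploid hets: n = 4 alleles, j = 2, site pi = 2/3
  g <- matrix(c(1L, 1L), 1, 2)
  gm <- genotype_matrix("chr1", 10L, "A", "T", g, paste0("s", 1:2),
                        c("Target", "Control"))
  grid <- window_grid(c(chr1 = 10L))
  wp <- window_pi(gm, pop = NULL, grid = grid)
  expect_equal(wp$pi[1], (2 / 3) / 50000, tolerance = 1e-12)
  # empty window scores zero
  grid2 <- window_grid(c(chr1 = 60000L))
  wp2 <- window_pi(gm, pop = NULL, grid = grid2)
  expect_equal(wp2$pi[wp2$start == 50001], 0)
})

test_that("halving ancestral heterozygosity roughly halves windowed pi", {
  base <- bn_spec(F = 0.05, n_diploids = 20, n_sites = 8000, seed = 13)
  lowdiv <- bn_spec(F = 0.05, n_diploids = 20, n_sites = 8000, seed = 13,
                    ancestral_lo = 0.025, ancestral_hi = 0.105)
  # mean 2p(1-p): base (U(.05,.95)) vs narrow low band; compute both expectations
  epq <- function(lo, hi) {
    p <- seq(lo, hi, length.out = 10001); mean(2 * p * (1 - p))
  }
  target_ratio <- epq(0.025, 0.105) / epq(0.05, 0.95)
  pi_of <- function(s) {
    gm <- simulate_balding_nichols(s)$gm
    mean(window_pi(gm, "Target")$pi)
  }
  ratio <- pi_of(lowdiv) / pi_of(base)
  expect_lt(abs(ratio - target_ratio) / target_ratio, 0.1)
})

test_that("wc_fst_site reproduces hand-evaluated component values", {
  # fixed difference, n = 20 each: a = 0.5, b = 0, c = 0, theta = 1
  r <- wc_fst_site(20, 1, 0, 20, 0, 0)
  expect_equal(r$a, 0.5); expect_equal(r$b, 0); expect_equal(r$c, 0)
  expect_equal(r$theta, 1)
  # identical pops p = h = 0.5, n = 11: a = -0.0125, a+b = 0, c = 0.25
  r2 <- wc_fst_site(11, 0.5, 0.5, 11, 0.5, 0.5)
  expect_equal(r2$a, -0.0125)
  expect_equal(r2$a + r2$b, 0)
  expect_equal(r2$c, 0.25)
  expect_equal(r2$theta, -0.05)
  # both monomorphic ref: zero components, undefined theta
  r3 <- wc_fst_site(10, 0, 0, 12, 0, 0)
  expect_equal(c(r3$a, r3$b, r3$c), c(0, 0, 0))
  expect_true(is.na(r3$theta))
})

test_that("window_fst equals the literal-transcription oracle on random instances", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n_sites <- sample(5:50, 1)
      gm <- random_gm(n_sites, spacing = 100L)
      grid <- data.frame(chrom = "chr1", start = 1L,
                         end = max(gm$pos) + 1L)
      mine <- window_fst(gm, "Target", "Control", grid, min_snps = 1L)$fst
      g1 <- gm$geno[, gm$pop_labels == "Target", drop = FALSE]
      g2 <- gm$geno[, gm$pop_labels == "Control", drop = FALSE]
      expect_equal(mine, oracle_window_fst(g1, g2), tolerance = 1e-12)
    }
  })
})

test_that("window FST is symmetric in the pair and invariant to sample order", {
  gm <- small_gm(n_sites = 60)
  a <- window_fst(gm, "Target", "Control", min_snps = 1L)$fst
  b <- window_fst(gm, "Control", "Target", min_snps = 1L)$fst
  expect_equal(a, b)
  perm <- withr::with_seed(1, sample(n_samples(gm)))
  gmp <- subset_samples(gm, perm)
  expect_equal(window_fst(gmp, "Target", "Control", min_snps = 1L)$fst, a)
})

test_that("lsbl arithmetic, symmetry and linearity", {
  expect_equal(lsbl(0.3, 0.4, 0.1), 0.3)
  x <- runif(5)
  expect_equal(lsbl(x, x, x), x / 2)
  f <- runif(3); d <- 0.17
  expect_equal(lsbl(f[1] + d, f[2] + d, f[3] + d), lsbl(f[1], f[2], f[3]) + d / 2)
  expect_true(is.na(lsbl(NA, 0.1, 0.2)))
})

test_that("sweep_scan assembles a consistent window table", {
  gm <- small_gm(n_sites = 90, n_per_pop = c(5, 5, 5), spacing = 800L)
  tbl <- sweep_scan(gm, min_snps = 2L)
  expect_s3_class(tbl, "WindowStatTable")
  expect_equal(nrow(tbl), nrow(window_grid(c(chr1 = max(gm$pos)))))
  ok <- !is.na(tbl$lsbl)
  expect_true(any(ok))
  expect_equal(tbl$lsbl[ok],
               lsbl(tbl$fst_TC, tbl$fst_TB, tbl$fst_CB)[ok])
  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_window_table(tbl, path)
  back <- read_window_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  # per-site LSBL alternative runs and correlates with the windowed route
  tbl2 <- sweep_scan(gm, min_snps = 2L, per_site_lsbl = TRUE)
  expect_true(all(is.finite(tbl2$lsbl[!is.na(tbl2$lsbl)])))
})

test_that("sweep_scan rejects undersized populations", {
  gm <- small_gm(n_sites = 10, n_per_pop = c(4, 1, 4))
  expect_error(sweep_scan(gm), ">= 2 diploids")
})

test_that("mean window LSBL is monotone in the Target drift parameter", {
  ms <- vapply(c(0.05, 0.15), function(ft) {
    sim <- simulate_balding_nichols(
      bn_spec(F = c(Target = ft, Control = 0.05, Background = 0.05),
              n_diploids = 25, n_sites = 6000, seed = 77))
    mean(sweep_scan(sim$gm)$lsbl, na.rm = TRUE)
  }, numeric(1))
  expect_gt(ms[2], ms[1])
})
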