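# Independent oracles: literal transcriptions of the defining formulas,
# written as plain per-site loops with no shared code with the package.

# Weir-Cockerham (1984) two-population components for one site; scalar inputs.
oracle_wc_site <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 2) return(NULL)
  p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
  h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# ratio-of-sums window FST over dosage matrices (sites x samples), skipping
# sites monomorphic across the pooled pair
oracle_window_fst <- function(g1, g2) {
  A <- 0; ABC <- 0
  for (i in seq_len(nrow(g1))) {
    x1 <- g1[i, ]; x2 <- g2[i, ]
    xx <- c(x1, x2); xx <- xx[!is.na(xx)]
    if (!length(xx)) next
    ptot <- sum(xx) / (2 * length(xx))
    if (ptot == 0 || ptot == 1) next
    comp <- oracle_wc_site(x1, x2)
    if (is.null(comp)) next
    A <- A + comp$a
    ABC <- ABC + comp$a + comp$b + comp$c
  }
  if (ABC == 0) return(NA_real_)
  A / ABC
}

# Monte-Carlo expectation of the per-window ratio-of-sums FST under the
# Balding-Nichols sampling model (uniform ancestral frequency, Beta
# population frequencies, binomial genotypes)
oracle_mc_window_fst <- function(F1, F2, n1, n2, snps_per_window = 50,
                                 n_windows = 2000, seed = 20260910,
                                 lo = 0.05, hi = 0.95) {
  set.seed(seed)
  vals <- vapply(seq_len(n_windows), function(w) {
    S <- snps_per_window
    p <- runif(S, lo, hi)
    p1 <- rbeta(S, p * (1 - F1) / F1, (1 - p) * (1 - F1) / F1)
    p2 <- rbeta(S, p * (1 - F2) / F2, (1 - p) * (1 - F2) / F2)
    g1 <- matrix(rbinom(S * n1, 2, rep(p1, n1)), S, n1)
    g2 <- matrix(rbinom(S * n2, 2, rep(p2, n2)), S, n2)
    oracle_window_fst(g1, g2)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# same, for the per-window LSBL with shared ancestral frequencies
oracle_mc_window_lsbl <- function(FT, FC, FB, n = 50, snps_per_window = 50,
                                  n_windows = 2000, seed = 20260910,
                                  lo = 0.05, hi = 0.95) {
  set.seed(seed)
  vals <- vapply(seq_len(n_windows), function(w) {
    S <- snps_per_window
    p <- runif(S, lo, hi)
    draw <- function(FF) rbeta(S, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF)
    gen <- function(pf) matrix(rbinom(S * n, 2, rep(pf, n)), S, n)
    gT <- gen(draw(FT)); gC <- gen(draw(FC)); gB <- gen(draw(FB))
    (oracle_window_fst(gT, gC) + oracle_window_fst(gT, gB) -
        oracle_window_fst(gC, gB)) / 2
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# literal windowed nucleotide diversity: sum over sites of the mean pairwise
# difference among called alleles, divided by the window size
oracle_window_pi <- function(g, pos, start, end_excl, window_size) {
  tot <- 0
  for (i in seq_along(pos)) {
    if (pos[i] < start || pos[i] >= end_excl) next
    x <- g[i, ]; x <- x[!is.na(x)]
    n <- 2 * length(x); j <- sum(x)
    if (n < 2) next
    tot <- tot + 2 * j * (n - j) / (n * (n - 1))
  }
  tot / window_size
}

# full-enumeration exact HWE p-value (two-sided, conditional on allele counts)
oracle_hwe_p <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nm <- min(2 * naa + nab, 2 * nbb + nab)
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hs, function(h) {
    hom_min <- (nm - h) / 2
    hom_maj <- n - h - hom_min
    exp(h * log(2) + lfactorial(n) - lfactorial(h) -
          lfactorial(hom_min) - lfactorial(hom_maj))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == nab] + 1e-12])
}

# additive distance matrix of an unrooted 4-taxon tree
# ((A:a,B:b):m,(C:c,D:d)) with internal branch m
oracle_additive_4taxon <- function(a, b, c, d, m) {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- a + b
  D["A", "C"] <- D["C", "A"] <- a + m + c
  D["A", "D"] <- D["D", "A"] <- a + m + d
  D["B", "C"] <- D["C", "B"] <- b + m + c
  D["B", "D"] <- D["D", "B"] <- b + m + d
  D["C", "D"] <- D["D", "C"] <- c + d
  D
}

# random small genotype matrix for oracle-equivalence checks
random_gm <- function(n_sites, n_per_pop = c(5, 4, 6), miss_p = 0.05,
                      spacing = 500L) {
  n <- sum(n_per_pop)
  g <- matrix(sample(0:2, n_sites * n, replace = TRUE), n_sites, n)
  g[matrix(runif(n_sites * n) < miss_p, n_sites, n)] <- NA_integer_
  genotype_matrix(chrom = "chr1",
                  pos = seq(1L, by = spacing, length.out = n_sites),
                  ref = rep("A", n_sites), alt = rep("G", n_sites),
                  geno = g, sample_ids = paste0("s", seq_len(n)),
                  pop_labels = rep(POP_ROLES, times = n_per_pop))
}
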