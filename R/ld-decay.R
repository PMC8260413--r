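#' Site-filter specification for LD calculations
#'
#' Mirrors the usual LD-tool site filters: minor-allele-frequency floor,
#' maximum observed heterozygosity, maximum missingness, minimum exact
#' Hardy-Weinberg p-value, and the maximum pair distance considered.
#'
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param het_max maximum observed heterozygote proportion (default 0.88).
#' @param missing_max maximum fraction of missing calls (default 0.25).
#' @param hwe_p_min minimum exact HWE p-value (default 0.001).
#' @param max_pair_distance maximum pair distance in bp (default 500 kb).
#' @return a list of class `LdFilterSpec`.
#' @export
ld_filter_spec <- function(maf_min = 0.05, het_max = 0.88, missing_max = 0.25,
                           hwe_p_min = 0.001, max_pair_distance = 500000L) {
  vals <- c(maf_min, het_max, missing_max, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stop("fractions must lie in [0, 1]")
  structure(list(maf_min = maf_min, het_max = het_max,
                 missing_max = missing_max, hwe_p_min = hwe_p_min,
                 max_pair_distance = as.integer(max_pair_distance)),
            class = "LdFilterSpec")
}

#' Exact Hardy-Weinberg equilibrium test (two-sided, by enumeration)
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count (same parity as the minor-allele count) and sums the
#' probabilities of all configurations no more probable than the observed
#' one. Monomorphic sites return `p = 1`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major-hom, het, minor-hom); the
#'   labeling of the two alleles is irrelevant.
#' @return two-sided exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele counts) up to a shared constant
  lp <- h_log_prob(hets, n, n_minor)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  sum(pr[pr <= obs + 1e-12])
}

h_log_prob <- function(h, n, n_minor) {
  n_hom_min <- (n_minor - h) / 2
  n_hom_maj <- n - h - n_hom_min
  h * log(2) + lfactorial(n) -
    (lfactorial(h) + lfactorial(n_hom_min) + lfactorial(n_hom_maj))
}

# logical vector: which sites pass the LD site filter within `pop`
ld_site_pass <- function(gm, pop, spec = ld_filter_spec()) {
  cols <- pop_cols(gm, pop)
  g <- gm$geno[, cols, drop = FALSE]
  called <- !is.na(g)
  n <- rowSums(called)
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0, ac / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  het <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
  miss <- 1 - n / length(cols)
  pass <- !is.na(maf) & maf >= spec$maf_min & het <= spec$het_max &
    miss <= spec$missing_max & n >= 1
  if (spec$hwe_p_min > 0) {
    for (i in which(pass)) {
      gi <- g[i, ]
      pv <- hwe_exact_p(sum(gi == 0L, na.rm = TRUE),
                        sum(gi == 1L, na.rm = TRUE),
                        sum(gi == 2L, na.rm = TRUE))
      if (pv < spec$hwe_p_min) pass[i] <- FALSE
    }
  }
  pass
}

#' Squared allelic correlation between two sites
#'
#' Phased route: `r^2 = D^2 / (pA pa pB pb)` counted over haplotypes, which
#' equals the squared Pearson correlation of the two haplotype indicator
#' vectors. Unphased route: squared Pearson correlation of the dosage vectors
#' over samples called at both sites. Returns `NA` when either site is
#' monomorphic among the jointly called samples.
#'
#' @param a,b numeric vectors: haplotype indicators (phased) or dosages
#'   (unphased) for the two sites.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
pair_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Distance-binned LD decay curve with half-maximum decay distance
#'
#' All intra-chromosome site pairs within `max_pair_distance` (after the
#' [ld_filter_spec()] site filter) are binned by distance; the curve is the
#' mean r-squared per bin. The half-decay distance is the midpoint of the
#' first bin (in increasing distance) whose mean is at or below half the
#' maximum bin mean; `NA` when no bin crosses it. Phased input uses
#' haplotype r-squared, unphased input dosage r-squared.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pop population role.
#' @param spec an [ld_filter_spec()].
#' @param bin_width bin width in bp (default 1 kb, fine enough to resolve
#'   tens-of-kb half-distances).
#' @param use_phased use the haplotype route (default: whenever phase is
#'   available).
#' @param smooth `"none"` (default) or `"isotonic"`: pool-adjacent-violators
#'   monotone non-increasing smoothing of the bin means (pair-count
#'   weighted) before reading off the half-decay distance.
#' @return a `DecayCurve` data.frame (`bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs`) with attributes `r2_max` and `half_decay_bp`.
#' @export
decay_curve <- function(gm, pop, spec = ld_filter_spec(), bin_width = 1000L,
                        use_phased = gm$phased, smooth = c("none", "isotonic")) {
  smooth <- match.arg(smooth)
  pass <- ld_site_pass(gm, pop, spec)
  if (sum(pass) < 2) stop("fewer than two sites pass the LD site filter")
  cols <- pop_cols(gm, pop)
  dists <- numeric(0); r2s <- numeric(0)
  for (cc in unique(gm$chrom)) {
    idx <- which(pass & gm$chrom == cc)
    if (length(idx) < 2) next
    if (use_phased && !is.null(gm$haplotypes)) {
      hcols <- as.vector(rbind(2L * cols - 1L, 2L * cols))
      X <- t(gm$haplotypes[idx, hcols, drop = FALSE])
    } else {
      X <- t(gm$geno[idx, cols, drop = FALSE])
    }
    suppressWarnings(R <- stats::cor(X, use = "pairwise.complete.obs")^2)
    D <- outer(gm$pos[idx], gm$pos[idx], function(a, b) b - a)
    ut <- upper.tri(D)
    sel <- ut & D > 0 & D <= spec$max_pair_distance & !is.na(R)
    dists <- c(dists, D[sel]); r2s <- c(r2s, R[sel])
  }
  if (!length(dists)) stop("no qualifying site pairs")
  bin <- ceiling(dists / bin_width)
  mean_r2 <- tapply(r2s, bin, mean)
  n_pairs <- tapply(r2s, bin, length)
  bins <- as.integer(names(mean_r2))
  o <- order(bins)
  out <- data.frame(bin_start = (bins[o] - 1L) * as.integer(bin_width),
                    bin_end = bins[o] * as.integer(bin_width),
                    mean_r2 = as.numeric(mean_r2[o]),
                    n_pairs = as.integer(n_pairs[o]))
  curve <- out$mean_r2
  if (smooth == "isotonic") curve <- pava_decreasing(curve, out$n_pairs)
  attr(out, "r2_max") <- max(curve)
  attr(out, "half_decay_bp") <- half_decay_from_bins(curve, out$bin_start,
                                                     out$bin_end)
  attr(out, "smoothed") <- smooth
  class(out) <- c("DecayCurve", "data.frame")
  out
}

# first-bin-crossing rule for the half-maximum decay distance
half_decay_from_bins <- function(means, bin_start, bin_end) {
  r2max <- max(means)
  i <- which(means <= r2max / 2)
  if (!length(i)) return(NA_real_)
  i <- min(i)
  (bin_start[i] + bin_end[i]) / 2
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- as.numeric(w); sz <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; sz[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tw
      wt[m - 1L] <- tw; sz[m - 1L] <- sz[m - 1L] + sz[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = sz[seq_len(m)])
}

#' Half-maximum decay distance of a DecayCurve
#' @param curve a `DecayCurve`.
#' @return distance in bp, or `NA` when the curve never falls to half its
#'   maximum.
#' @export
half_decay_distance <- function(curve) attr(curve, "half_decay_bp")

#' Write a DecayCurve as TSV
#' @param curve a `DecayCurve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decay_curve <- function(curve, path) {
  utils::write.table(format_numeric_df(as.data.frame(curve)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Randomly subsample every population to a common size
#'
#' Removes sample-size bias between populations (e.g. before LD
#' comparisons): a uniform random subset without replacement of
#' `n_per_pop` samples per population, deterministic given `seed`. Sample
#' order within the matrix is preserved.
#'
#' @param gm a `GenotypeMatrix`.
#' @param n_per_pop target diploid count per population.
#' @param seed RNG seed.
#' @return the subsampled `GenotypeMatrix`.
#' @export
equalize_samples <- function(gm, n_per_pop, seed = 1L) {
  with_seed(seed, {
    keep <- integer(0)
    for (p in POP_ROLES) {
      cols <- pop_cols(gm, p)
      if (!length(cols)) next
      if (length(cols) < n_per_pop)
        stop("population ", p, " has fewer than ", n_per_pop, " samples")
      keep <- c(keep, sort(sample(cols, n_per_pop)))
    }
    subset_samples(gm, sort(keep))
  })
}
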