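#' Build a sliding-window grid
#'
#' Windows are anchored at position 1 on every chromosome and placed every
#' `step` bp; each spans `[start, start + window_size)` (1-based, half-open).
#' Every start position not beyond the chromosome length gets a window, so the
#' final window may extend past the last site.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window_size window span in bp (default 50 kb).
#' @param step distance between consecutive window starts (default 25 kb);
#'   must not exceed `window_size`.
#' @return data.frame with columns `chrom`, `start`, `end` (`end` exclusive).
#' @export
window_grid <- function(chrom_lengths, window_size = 50000L, step = 25000L) {
  if (step > window_size) stop("step must be <= window_size")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(cc) {
    starts <- seq(1L, max(1L, as.integer(chrom_lengths[[cc]])), by = as.integer(step))
    data.frame(chrom = cc, start = starts,
               end = starts + as.integer(window_size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# grid derived from the sites actually present in a GenotypeMatrix
grid_for_gm <- function(gm, window_size = 50000L, step = 25000L) {
  lens <- tapply(gm$pos, gm$chrom, max)
  window_grid(lens[unique(gm$chrom)], window_size, step)
}

#' Per-site nucleotide diversity
#'
#' The mean pairwise difference among the `n` called alleles at a site:
#' `2 j (n - j) / (n (n - 1))` with `j` the alternate-allele count. Returns
#' `NA` when fewer than two alleles are called.
#'
#' @param j alternate-allele count(s).
#' @param n called allele count(s) (2 x called diploids).
#' @return numeric vector of per-site pi values.
#' @export
site_pi <- function(j, n) {
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

# cumulative-sum windowed aggregation: for each grid row, sum `x` over the
# sites of that chromosome falling in [start, end)
window_sums <- function(grid, chrom, pos, x) {
  out <- numeric(nrow(grid))
  for (cc in unique(grid$chrom)) {
    gi <- which(grid$chrom == cc)
    si <- which(chrom == cc)
    if (!length(si)) next
    p <- pos[si]
    cs <- c(0, cumsum(x[si]))
    lo <- findInterval(grid$start[gi] - 0.5, p)
    hi <- findInterval(grid$end[gi] - 0.5, p)
    out[gi] <- cs[hi + 1L] - cs[lo + 1L]
  }
  out
}

#' Windowed nucleotide diversity (vcftools convention)
#'
#' Sums [site_pi()] over the SNPs of each window and divides by the window
#' size in bp (not by the number of SNPs), matching the windowed-pi
#' convention of standard VCF tooling. Windows without SNPs score 0.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pop population role (`NULL` = all samples).
#' @param grid a [window_grid()] data.frame (default: derived from `gm`).
#' @param window_size,step used when `grid` is `NULL`.
#' @return `grid` with an added `pi` column.
#' @export
window_pi <- function(gm, pop = NULL, grid = NULL,
                      window_size = 50000L, step = 25000L) {
  if (is.null(grid)) grid <- grid_for_gm(gm, window_size, step)
  sc <- site_counts(gm, pop)
  v <- site_pi(round(2 * sc$n * sc$p), 2 * sc$n)
  v[is.na(v)] <- 0
  wsize <- grid$end - grid$start
  grid$pi <- window_sums(grid, gm$chrom, gm$pos, v) / wsize
  grid
}

#' Weir-Cockerham (1984) variance components for one site, two populations
#'
#' Implements the two-population variance-components estimator: with `r = 2`
#' populations of `n1`, `n2` called diploids, alternate-allele frequencies
#' `p1`, `p2` and observed heterozygote proportions `h1`, `h2`, returns the
#' among-population (`a`), among-individual (`b`) and within-individual (`c`)
#' components plus the per-site estimate `theta = a / (a + b + c)` (NA when
#' the denominator is zero). Negative estimates are legitimate output of this
#' estimator and are not clamped. All arguments vectorize over sites.
#'
#' @param n1,n2 called diploid counts.
#' @param p1,p2 alternate-allele frequencies.
#' @param h1,h2 observed heterozygote proportions.
#' @return list with vectors `a`, `b`, `c`, `theta`.
#' @export
wc_fst_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  ok <- !is.na(n1) & !is.na(n2) & n1 >= 1 & n2 >= 1 & (n1 + n2) >= 2 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta)
}

# per-site WC components for a pair of population roles (either element may
# be a vector of roles, in which case those samples are pooled)
wc_components_for <- function(gm, pop1, pop2) {
  s1 <- site_counts(gm, pop1)
  s2 <- site_counts(gm, pop2)
  wc_fst_site(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
}

#' Windowed Weir-Cockerham FST (ratio-of-sums estimator)
#'
#' Per window, `sum(a) / sum(a + b + c)` over its SNPs -- the "weighted"
#' window FST of standard VCF tooling, which is stabler than averaging
#' per-site estimates. Windows with fewer than `min_snps` polymorphic sites,
#' or a zero denominator, get `NA`.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pop1,pop2 population roles (a vector pools samples, e.g.
#'   `c("Control", "Background")`).
#' @param grid a [window_grid()] (default: derived from `gm`).
#' @param min_snps minimum SNPs per window (default 10).
#' @param window_size,step used when `grid` is `NULL`.
#' @return `grid` with added `n_snps` and `fst` columns.
#' @export
window_fst <- function(gm, pop1 = "Target", pop2 = "Control", grid = NULL,
                       min_snps = 10L, window_size = 50000L, step = 25000L) {
  if (is.null(grid)) grid <- grid_for_gm(gm, window_size, step)
  comp <- wc_components_for(gm, pop1, pop2)
  scw <- site_counts(gm, c(pop1, pop2))
  poly <- !is.na(scw$p) & scw$p > 0 & scw$p < 1
  zero_na <- function(x) { x[is.na(x)] <- 0; x }
  a <- zero_na(comp$a) * poly
  abc <- zero_na(comp$a + comp$b + comp$c) * poly
  n_snps <- window_sums(grid, gm$chrom, gm$pos, as.numeric(poly))
  sa <- window_sums(grid, gm$chrom, gm$pos, a)
  sabc <- window_sums(grid, gm$chrom, gm$pos, abc)
  fst <- ifelse(n_snps >= min_snps & sabc != 0, sa / sabc, NA_real_)
  grid$n_snps <- as.integer(n_snps)
  grid$fst <- fst
  grid
}

#' Locus-specific branch length
#'
#' For a focal Target population T with references C (Control) and
#' B (Background), `LSBL = (FST(T,C) + FST(T,B) - FST(C,B)) / 2` isolates the
#' differentiation accumulated on T's branch. Computed here from windowed
#' pairwise FST values on an identical grid; any `NA` input propagates.
#'
#' @param fst_tc,fst_tb,fst_cb pairwise FST values (vectors).
#' @return numeric vector of LSBL values.
#' @export
lsbl <- function(fst_tc, fst_tb, fst_cb) {
  (fst_tc + fst_tb - fst_cb) / 2
}

#' Full sliding-window sweep scan
#'
#' Assembles, per window: SNP count, per-population nucleotide diversity,
#' the three pairwise Weir-Cockerham FSTs, the Target-vs-pooled
#' (Control + Background) FST track (`fst` column), and LSBL.
#'
#' @param gm a `GenotypeMatrix` containing samples of all three populations
#'   (>= 2 diploids each).
#' @param grid optional [window_grid()]; default derived from `gm`.
#' @param window_size,step grid parameters when `grid` is `NULL`.
#' @param min_snps windows with fewer polymorphic sites carry `NA` FST/LSBL
#'   (diversity is still reported).
#' @param fst_mode `"pooled"` (default): the `fst` column is Target vs pooled
#'   Control+Background; `"mean"`: the mean of the two Target pairwise FSTs.
#' @param per_site_lsbl if `TRUE`, LSBL is instead the window mean of
#'   per-site LSBL values computed from per-site FST estimates (the windowed
#'   ratio-of-sums route is the default because it is stabler).
#' @param clamp_negative_fst if `TRUE`, negative window FSTs are clamped to 0
#'   before LSBL (off by default: clamping biases LSBL upward; provided for
#'   sensitivity analysis).
#' @return a `WindowStatTable` data.frame with columns `chrom`, `start`,
#'   `end`, `n_snps`, `pi_T`, `pi_C`, `pi_B`, `fst_TC`, `fst_TB`, `fst_CB`,
#'   `fst`, `lsbl`.
#' @export
sweep_scan <- function(gm, grid = NULL, window_size = 50000L, step = 25000L,
                       min_snps = 10L, fst_mode = c("pooled", "mean"),
                       per_site_lsbl = FALSE, clamp_negative_fst = FALSE) {
  fst_mode <- match.arg(fst_mode)
  tab <- table(factor(gm$pop_labels, levels = POP_ROLES))
  if (any(tab < 2))
    stop("every population needs >= 2 diploids; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (is.null(grid)) grid <- grid_for_gm(gm, window_size, step)
  out <- grid
  for (p in POP_ROLES) {
    col <- paste0("pi_", substr(p, 1, 1))
    out[[col]] <- window_pi(gm, p, grid = grid)$pi
  }
  f_tc <- window_fst(gm, "Target", "Control", grid, min_snps)
  f_tb <- window_fst(gm, "Target", "Background", grid, min_snps)
  f_cb <- window_fst(gm, "Control", "Background", grid, min_snps)
  f_pool <- window_fst(gm, "Target", c("Control", "Background"), grid, min_snps)
  out$n_snps <- pmax(f_tc$n_snps, f_tb$n_snps, f_cb$n_snps)
  cl <- if (clamp_negative_fst) function(x) pmax(x, 0) else identity
  out$fst_TC <- cl(f_tc$fst); out$fst_TB <- cl(f_tb$fst); out$fst_CB <- cl(f_cb$fst)
  out$fst <- if (fst_mode == "pooled") cl(f_pool$fst)
             else (out$fst_TC + out$fst_TB) / 2
  if (per_site_lsbl) {
    c_tc <- wc_components_for(gm, "Target", "Control")
    c_tb <- wc_components_for(gm, "Target", "Background")
    c_cb <- wc_components_for(gm, "Control", "Background")
    ls <- lsbl(c_tc$theta, c_tb$theta, c_cb$theta)
    okv <- !is.na(ls)
    num <- window_sums(grid, gm$chrom, gm$pos, ifelse(okv, ls, 0))
    den <- window_sums(grid, gm$chrom, gm$pos, as.numeric(okv))
    out$lsbl <- ifelse(den >= min_snps, num / den, NA_real_)
  } else {
    out$lsbl <- lsbl(out$fst_TC, out$fst_TB, out$fst_CB)
  }
  cols <- c("chrom", "start", "end", "n_snps", "pi_T", "pi_C", "pi_B",
            "fst_TC", "fst_TB", "fst_CB", "fst", "lsbl")
  out <- out[, cols]
  class(out) <- c("WindowStatTable", "data.frame")
  out
}

#' Write / read a WindowStatTable as TSV
#' @param tbl a `WindowStatTable`.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_window_table <- function(tbl, path) {
  utils::write.table(format_numeric_df(tbl), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("WindowStatTable", "data.frame")
  out
}

# full-precision numeric formatting so TSV round-trips are exact
format_numeric_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
  df
}

#' Export grid windows or regions as BED (0-based, half-open)
#' @param df data.frame with `chrom`, `start`, `end` columns (1-based; `end`
#'   exclusive for windows, inclusive for regions -- set `closed = TRUE` for
#'   the latter).
#' @param path output path.
#' @param closed whether `end` is 1-based closed (regions) rather than
#'   exclusive (grid windows).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, closed = FALSE) {
  bed <- data.frame(df$chrom, df$start - 1L,
                    if (closed) df$end else df$end - 1L)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
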