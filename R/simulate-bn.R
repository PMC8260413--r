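#' Specification for the Balding-Nichols three-population generator
#'
#' Under the Balding-Nichols model each population's allele frequency at a
#' site is a Beta draw around a shared ancestral frequency `p`, with variance
#' `F * p * (1 - p)`; `F` is the per-population drift parameter and equals the
#' expected differentiation of that population from the ancestor. Sites are
#' unlinked, which makes windowed FST / LSBL / pi expectations computable in
#' closed form or by cheap Monte-Carlo -- the generator of choice for fast
#' statistical tests.
#'
#' @param F named numeric vector of drift parameters in (0, 1) for
#'   `Target`, `Control`, `Background` (unnamed length-3 vectors are taken in
#'   that order; a scalar is recycled). Order of names is irrelevant.
#' @param n_diploids per-population diploid sample size (scalar or named like
#'   `F`); must be >= 2.
#' @param n_sites number of unlinked SNP sites.
#' @param ancestral_lo,ancestral_hi bounds of the uniform ancestral-frequency
#'   distribution (default 0.05--0.95, avoiding near-fixed sites that make
#'   the Weir-Cockerham components degenerate).
#' @param chrom_name chromosome label of the emitted sites.
#' @param site_spacing_bp distance in bp between consecutive sites.
#' @param seed integer RNG seed; the simulation is deterministic given it.
#' @return a list of class `BaldingNicholsSpec`.
#' @export
bn_spec <- function(F = c(Target = 0.10, Control = 0.10, Background = 0.10),
                    n_diploids = 50, n_sites = 20000,
                    ancestral_lo = 0.05, ancestral_hi = 0.95,
                    chrom_name = "chr1", site_spacing_bp = 1000L, seed = 1L) {
  F <- canonical_pop_vector(F, "F")
  n_diploids <- canonical_pop_vector(n_diploids, "n_diploids")
  if (any(F <= 0 | F >= 1)) stop("F must lie strictly inside (0, 1)")
  if (any(n_diploids < 2)) stop("n_diploids must be >= 2 (FST undefined below)")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!(ancestral_lo > 0 && ancestral_hi < 1 && ancestral_lo < ancestral_hi))
    stop("ancestral frequency bounds must satisfy 0 < lo < hi < 1")
  if (site_spacing_bp < 1) stop("site_spacing_bp must be positive")
  structure(list(F = F, n_diploids = n_diploids, n_sites = as.integer(n_sites),
                 ancestral_lo = ancestral_lo, ancestral_hi = ancestral_hi,
                 chrom_name = chrom_name,
                 site_spacing_bp = as.integer(site_spacing_bp),
                 seed = as.integer(seed)),
            class = "BaldingNicholsSpec")
}

# normalize a scalar / unnamed / arbitrarily ordered named per-population
# vector into canonical (Target, Control, Background) order
canonical_pop_vector <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L) stop(what, " must have length 1 or 3")
  if (is.null(names(x))) names(x) <- POP_ROLES
  if (!setequal(names(x), POP_ROLES))
    stop(what, " names must be ", paste(POP_ROLES, collapse = ", "))
  x[POP_ROLES]
}

#' Simulate unlinked three-population genotypes (Balding-Nichols model)
#'
#' For each site an ancestral frequency `p ~ Uniform(lo, hi)` is drawn; each
#' population's frequency is a Beta draw with shape parameters
#' `p(1-F)/F` and `(1-p)(1-F)/F` (mean `p`, variance `F p (1-p)`); diploid
#' genotypes are two independent allele draws per individual. Sites are
#' unlinked and emitted unphased.
#'
#' @param spec a [bn_spec()].
#' @return list with elements `gm` (a `GenotypeMatrix`) and `truth`
#'   (a `SimTruth` holding the spec and the realized per-population
#'   allele-frequency table).
#' @export
simulate_balding_nichols <- function(spec) {
  stopifnot(inherits(spec, "BaldingNicholsSpec"))
  n_sites <- spec$n_sites
  with_seed(spec$seed, {
    p_anc <- stats::runif(n_sites, spec$ancestral_lo, spec$ancestral_hi)
    freqs <- matrix(NA_real_, n_sites, 3L, dimnames = list(NULL, POP_ROLES))
    geno_list <- vector("list", 3L)
    for (k in seq_len(3L)) {
      Fk <- spec$F[[k]]
      pk <- stats::rbeta(n_sites, p_anc * (1 - Fk) / Fk,
                         (1 - p_anc) * (1 - Fk) / Fk)
      freqs[, k] <- pk
      nk <- spec$n_diploids[[k]]
      geno_list[[k]] <- matrix(stats::rbinom(n_sites * nk, 2L, rep(pk, nk)),
                               nrow = n_sites, ncol = nk)
    }
    geno <- do.call(cbind, geno_list)
    ids <- unlist(lapply(seq_len(3L), function(k)
      sprintf("%s%02d", substr(POP_ROLES[k], 1, 1), seq_len(spec$n_diploids[[k]]))))
    pops <- rep(POP_ROLES, times = spec$n_diploids)
    pos <- seq(1L, by = spec$site_spacing_bp, length.out = n_sites)
    gm <- genotype_matrix(
      chrom = spec$chrom_name, pos = pos,
      ref = rep("A", n_sites), alt = rep("T", n_sites),
      geno = geno, sample_ids = ids, pop_labels = pops,
      qual = rep(100, n_sites), mean_dp = rep(30, n_sites), phased = FALSE)
    truth <- structure(list(model = "balding_nichols", spec = unclass(spec),
                            sweep = NULL, sweep_window_ids = integer(0),
                            pop_freqs = freqs),
                       class = "SimTruth")
    list(gm = gm, truth = truth)
  })
}

#' Push Target-population allele frequencies toward fixation in a region
#'
#' A cheap surrogate for a completed selective sweep: inside the region the
#' Target samples' genotypes are resampled from frequency
#' `min(p + delta, 1)`, where `p` is the observed Target alternate-allele
#' frequency at the site; all other populations are untouched. `delta = 0`
#' returns the input unchanged.
#'
#' @param gm a `GenotypeMatrix`.
#' @param chrom,start,end the region (1-based, closed) to perturb.
#' @param delta frequency shift in (0, 1].
#' @param seed RNG seed for the resampling.
#' @return the perturbed `GenotypeMatrix`.
#' @export
inject_sweep_differentiation <- function(gm, chrom, start, end, delta, seed = 1L) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  idx <- which(gm$chrom == chrom & gm$pos >= start & gm$pos <= end)
  if (!length(idx)) stop("empty region: no sites in ", chrom, ":", start, "-", end)
  if (delta == 0) return(gm)
  cols <- pop_cols(gm, "Target")
  with_seed(seed, {
    sc <- site_counts(gm, "Target")
    q <- pmin(sc$p[idx] + delta, 1)
    q[is.na(q)] <- 1  # nothing called: push to fixation outright
    nT <- length(cols)
    newg <- matrix(stats::rbinom(length(idx) * nT, 2L, rep(q, nT)),
                   nrow = length(idx), ncol = nT)
    miss <- is.na(gm$geno[idx, cols, drop = FALSE])
    newg[miss] <- NA_integer_
    gm$geno[idx, cols] <- newg
    if (!is.null(gm$haplotypes)) {
      hcols <- as.vector(rbind(2L * cols - 1L, 2L * cols))
      # keep haplotypes consistent with the resampled dosages
      for (r in seq_along(idx)) {
        d <- gm$geno[idx[r], cols]
        h1 <- ifelse(is.na(d), NA_integer_, as.integer(d == 2L | (d == 1L)))
        h2 <- ifelse(is.na(d), NA_integer_, as.integer(d == 2L))
        hh <- as.vector(rbind(h1, h2))
        gm$haplotypes[idx[r], hcols] <- hh
      }
    }
    gm
  })
}

#' Write a SimTruth record to a TSV file with a JSON header line
#'
#' The first line is `#` followed by a JSON object of the simulation spec and
#' sweep metadata; the body is a TSV of the realized per-population allele
#' frequencies. [read_truth()] inverts it losslessly.
#'
#' @param truth a `SimTruth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SimTruth"))
  head_obj <- truth[setdiff(names(truth), "pop_freqs")]
  hdr <- jsonlite::toJSON(head_obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  fr <- truth$pop_freqs
  writeLines(paste(c("site", colnames(fr)), collapse = "\t"), con)
  body <- sprintf("%d\t%.17g\t%.17g\t%.17g",
                  seq_len(nrow(fr)), fr[, 1], fr[, 2], fr[, 3])
  writeLines(body, con)
  invisible(path)
}

#' Read a SimTruth written by [write_truth()]
#' @param path file path.
#' @return a `SimTruth`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#")) stop("not a truth file: missing JSON header")
  head_obj <- jsonlite::fromJSON(sub("^#", "", lines[1]), simplifyVector = TRUE)
  body <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  fr <- as.matrix(body[, -1, drop = FALSE])
  dimnames(fr) <- list(NULL, colnames(body)[-1])
  out <- head_obj
  # fromJSON turns scalars into length-1 vectors; normalize a few fields
  if (!is.null(out$sweep) && length(out$sweep) == 0) out$sweep <- NULL
  out$sweep_window_ids <- as.integer(out$sweep_window_ids)
  out$pop_freqs <- fr
  structure(out, class = "SimTruth")
}
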