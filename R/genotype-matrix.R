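#' The three population roles used throughout the package
#'
#' Every sample must be assigned to one of these roles. In a sweep scan the
#' Target population carries the putative sweep; Control and Background are
#' the two reference populations of the LSBL design.
#' @export
POP_ROLES <- c("Target", "Control", "Background")

#' Construct a GenotypeMatrix
#'
#' The central container of the package: biallelic SNP sites in rows, diploid
#' samples in columns, genotypes stored as alternate-allele dosage
#' (0, 1, 2 or `NA` for missing). Optionally carries phased haplotypes
#' (two 0/1 columns per sample), per-site QUAL and mean depth.
#'
#' @param chrom character vector of chromosome names, one per site (a scalar
#'   is recycled). Sites must be grouped by chromosome.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-base allele strings per site (longer strings are
#'   allowed so that unfiltered indels can be represented; multiallelic ALT is
#'   a comma-separated string).
#' @param geno integer matrix, `length(pos)` x `length(sample_ids)`, values in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of sample names.
#' @param pop_labels character vector mapping each sample to one of
#'   `"Target"`, `"Control"`, `"Background"`.
#' @param qual optional numeric per-site quality.
#' @param mean_dp optional numeric per-site mean depth across samples.
#' @param haplotypes optional integer matrix, sites x (2 * samples), values in
#'   `{0, 1, NA}`; columns `2i-1, 2i` are the two haplotypes of sample `i`.
#' @param phased logical; `TRUE` when `haplotypes` reflect true phase.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, sample_ids, pop_labels,
                            qual = NULL, mean_dp = NULL, haplotypes = NULL,
                            phased = FALSE) {
  n_sites <- length(pos)
  n_samp <- length(sample_ids)
  if (length(chrom) == 1L) chrom <- rep(chrom, n_sites)
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites)
  geno <- as.matrix(geno)
  if (!all(dim(geno) == c(n_sites, n_samp)))
    stop("geno must be a ", n_sites, " x ", n_samp, " matrix")
  storage.mode(geno) <- "integer"
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  pop_labels <- as.character(pop_labels)
  if (length(pop_labels) != n_samp)
    stop("every sample needs a population label")
  if (!all(pop_labels %in% POP_ROLES))
    stop("population labels must be one of: ", paste(POP_ROLES, collapse = ", "))
  # positions strictly increasing within each chromosome, sites grouped
  if (anyDuplicated(rle(chrom)$values)) stop("sites must be grouped by chromosome")
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (!all(dim(haplotypes) == c(n_sites, 2L * n_samp)))
      stop("haplotypes must be sites x (2*samples)")
    storage.mode(haplotypes) <- "integer"
  }
  structure(list(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qual = if (is.null(qual)) NULL else as.numeric(qual),
    mean_dp = if (is.null(mean_dp)) NULL else as.numeric(mean_dp),
    geno = geno, haplotypes = haplotypes, phased = isTRUE(phased),
    sample_ids = as.character(sample_ids), pop_labels = pop_labels
  ), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d sites x %d samples (%s)\n",
              n_sites(x), n_samples(x),
              if (x$phased) "phased" else "unphased"))
  tab <- table(factor(x$pop_labels, levels = POP_ROLES))
  cat("  populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites / samples in a GenotypeMatrix
#' @param gm a `GenotypeMatrix`
#' @return integer count
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' Column indices of the samples belonging to one or more populations
#' @param gm a `GenotypeMatrix`
#' @param pop character vector of population roles
#' @keywords internal
pop_cols <- function(gm, pop) which(gm$pop_labels %in% pop)

#' Subset sites of a GenotypeMatrix
#' @param gm a `GenotypeMatrix`
#' @param i integer or logical index over sites
#' @return a `GenotypeMatrix`
#' @export
subset_sites <- function(gm, i) {
  gm$chrom <- gm$chrom[i]; gm$pos <- gm$pos[i]
  gm$ref <- gm$ref[i]; gm$alt <- gm$alt[i]
  if (!is.null(gm$qual)) gm$qual <- gm$qual[i]
  if (!is.null(gm$mean_dp)) gm$mean_dp <- gm$mean_dp[i]
  gm$geno <- gm$geno[i, , drop = FALSE]
  if (!is.null(gm$haplotypes)) gm$haplotypes <- gm$haplotypes[i, , drop = FALSE]
  gm
}

#' Subset samples of a GenotypeMatrix
#' @param gm a `GenotypeMatrix`
#' @param j integer index over samples
#' @return a `GenotypeMatrix`
#' @export
subset_samples <- function(gm, j) {
  j <- as.integer(j)
  gm$geno <- gm$geno[, j, drop = FALSE]
  if (!is.null(gm$haplotypes)) {
    hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
    gm$haplotypes <- gm$haplotypes[, hcols, drop = FALSE]
  }
  gm$sample_ids <- gm$sample_ids[j]
  gm$pop_labels <- gm$pop_labels[j]
  gm
}

#' Per-site allele-count summaries for a set of samples
#'
#' Returns, for the given population(s), the number of called diploids `n`,
#' alternate-allele frequency `p`, and observed heterozygote proportion `h`
#' at every site (NA frequencies where nothing is called).
#'
#' @param gm a `GenotypeMatrix`
#' @param pop population role(s), or `NULL` for all samples
#' @return list with numeric vectors `n`, `p`, `h`
#' @export
site_counts <- function(gm, pop = NULL) {
  cols <- if (is.null(pop)) seq_len(n_samples(gm)) else pop_cols(gm, pop)
  g <- gm$geno[, cols, drop = FALSE]
  called <- !is.na(g)
  n <- rowSums(called)
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0, ac / (2 * n), NA_real_)
  h <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

# run code with a temporary RNG state seeded from `seed`, restoring afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
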