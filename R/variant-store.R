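#' Read a sample-to-population assignment file
#'
#' Two-column TSV (no header): `sample_id<TAB>population`, population one of
#' `Target`, `Control`, `Background`.
#'
#' @param path file path.
#' @return named character vector, sample id -> population.
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "pop"),
                          stringsAsFactors = FALSE)
  if (!all(df$pop %in% POP_ROLES))
    stop("groups file contains populations outside ",
         paste(POP_ROLES, collapse = "/"))
  stats::setNames(df$pop, df$sample)
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Sites are kept in file order, including indels and multiallelic records
#' (they are removed later by [apply_filters()]); genotype dosage is the
#' count of `1` alleles in GT, `NA` for missing or non-biallelic calls.
#' Phase is recorded when every called GT uses the `|` separator. Per-site
#' mean depth is taken from FORMAT/DP (mean across called samples) or, when
#' absent, INFO/DP divided by the sample count; with neither, depth is left
#' unset and depth filters are skipped with a warning downstream.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param groups_path groups file (see [read_groups()]); every VCF sample
#'   must appear in it.
#' @return a `GenotypeMatrix`.
#' @export
read_vcf <- function(path, groups_path) {
  groups <- read_groups(groups_path)
  v <- VariantAnnotation::readVcf(path)
  samples <- colnames(v)
  missing_samples <- setdiff(samples, names(groups))
  if (length(missing_samples))
    stop("samples missing from groups file: ",
         paste(missing_samples, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_l <- VariantAnnotation::alt(v)
  alt <- vapply(as(alt_l, "CharacterList"), paste, "", collapse = ",")
  qual <- rr$QUAL
  gt <- VariantAnnotation::geno(v)$GT
  n_site <- nrow(gt); n_samp <- ncol(gt)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  sep <- substr(gt, 2, 2)
  h1 <- suppressWarnings(as.integer(a1)); h2 <- suppressWarnings(as.integer(a2))
  dos <- h1 + h2
  dos[(!is.na(h1) & h1 > 1L) | (!is.na(h2) & h2 > 1L)] <- NA_integer_  # beyond first ALT
  geno <- matrix(dos, n_site, n_samp)
  called <- !is.na(geno)
  phased <- all(sep[called] == "|") && any(called)
  haplotypes <- NULL
  if (phased) {
    haplotypes <- matrix(NA_integer_, n_site, 2L * n_samp)
    haplotypes[, seq(1L, 2L * n_samp, 2L)] <- matrix(h1, n_site, n_samp)
    haplotypes[, seq(2L, 2L * n_samp, 2L)] <- matrix(h2, n_site, n_samp)
  }
  mean_dp <- NULL
  gdp <- VariantAnnotation::geno(v)
  if ("DP" %in% names(gdp)) {
    dp <- gdp$DP
    mean_dp <- rowMeans(dp, na.rm = TRUE)
  } else {
    inf <- VariantAnnotation::info(v)
    if ("DP" %in% colnames(inf)) mean_dp <- as.numeric(inf$DP) / n_samp
  }
  genotype_matrix(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  geno = geno, sample_ids = samples,
                  pop_labels = unname(groups[samples]),
                  qual = as.numeric(qual), mean_dp = mean_dp,
                  haplotypes = haplotypes, phased = phased)
}

#' Write a GenotypeMatrix as VCF 4.2
#'
#' Emits contig header lines, `INFO/DP` (mean depth times sample count, when
#' known), and GT genotypes -- `|`-separated from phased haplotypes,
#' `/`-separated otherwise.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=sweepscan", con)
  lens <- tapply(gm$pos, gm$chrom, max)
  for (cc in unique(gm$chrom))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", cc, lens[[cc]]), con)
  writeLines('##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">', con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  n <- n_samples(gm)
  if (gm$phased && !is.null(gm$haplotypes)) {
    hh <- gm$haplotypes
    gt <- matrix(paste(ifelse(is.na(hh[, seq(1L, 2L * n, 2L)]), ".",
                              hh[, seq(1L, 2L * n, 2L)]),
                       ifelse(is.na(hh[, seq(2L, 2L * n, 2L)]), ".",
                              hh[, seq(2L, 2L * n, 2L)]), sep = "|"),
                 n_sites(gm), n)
    gt[gt == ".|."] <- "./."
  } else {
    g <- gm$geno
    gt <- matrix("./.", n_sites(gm), n)
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
  }
  qual <- if (is.null(gm$qual)) rep(".", n_sites(gm)) else
    ifelse(is.na(gm$qual), ".", format(gm$qual, trim = TRUE, scientific = FALSE))
  info <- if (is.null(gm$mean_dp)) rep(".", n_sites(gm)) else
    sprintf("DP=%d", as.integer(round(gm$mean_dp * n)))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, qual, "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' SNP filter specification
#'
#' Mirrors the vcftools-style site filter chain: site QUAL, biallelic-only,
#' mean-depth bounds, missingness, minimum non-reference allele count,
#' SNPs-only (indel removal) and an optional MAF floor. Note the missingness
#' convention: keeping sites with >= 90% called genotypes means
#' `max_missing_fraction = 0.1`.
#'
#' @param min_qual minimum site QUAL (default 30); `NULL` disables.
#' @param biallelic_only drop multiallelic records (default `TRUE`).
#' @param min_mean_dp,max_mean_dp mean-depth bounds (defaults 4.0 / 72.0);
#'   `NULL` disables.
#' @param max_missing_fraction maximum fraction of missing genotypes
#'   (default 0.1); `NULL` disables.
#' @param min_nonref_allele_count minimum count of non-reference alleles
#'   across called genotypes (default 2); `NULL` disables.
#' @param snps_only drop records whose REF or ALT is not a single base
#'   (default `TRUE`).
#' @param maf_min optional minor-allele-frequency floor (the scan applies
#'   0.05 where population-level statistics require it); `NULL` disables.
#' @return a list of class `FilterSpec`.
#' @export
filter_spec <- function(min_qual = 30, biallelic_only = TRUE,
                        min_mean_dp = 4.0, max_mean_dp = 72.0,
                        max_missing_fraction = 0.1,
                        min_nonref_allele_count = 2,
                        snps_only = TRUE, maf_min = NULL) {
  if (!is.null(max_missing_fraction) &&
      (max_missing_fraction < 0 || max_missing_fraction > 1))
    stop("max_missing_fraction must lie in [0, 1]")
  structure(list(min_qual = min_qual, biallelic_only = biallelic_only,
                 min_mean_dp = min_mean_dp, max_mean_dp = max_mean_dp,
                 max_missing_fraction = max_missing_fraction,
                 min_nonref_allele_count = min_nonref_allele_count,
                 snps_only = snps_only, maf_min = maf_min),
            class = "FilterSpec")
}

#' Apply the SNP filter chain to a GenotypeMatrix
#'
#' Retains exactly the sites passing every enabled criterion. The attached
#' `FilterReport` attribute counts removals per criterion; a site failing
#' several criteria is counted once, under the first failing criterion in
#' the [filter_spec()] argument order.
#'
#' @param gm a `GenotypeMatrix`.
#' @param spec a [filter_spec()].
#' @return the filtered `GenotypeMatrix`, with attribute `filter_report`
#'   (data.frame `criterion`, `removed`) and `n_input` / `n_output`.
#' @export
apply_filters <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(spec, "FilterSpec"))
  n <- n_sites(gm)
  fail <- rep(NA_character_, n)
  mark <- function(bad, why) fail[is.na(fail) & bad] <<- why

  if (!is.null(spec$min_qual)) {
    q <- if (is.null(gm$qual)) rep(NA_real_, n) else gm$qual
    mark(!is.na(q) & q < spec$min_qual, "min_qual")
  }
  if (isTRUE(spec$biallelic_only))
    mark(grepl(",", gm$alt, fixed = TRUE) | gm$alt %in% c("", "."), "biallelic_only")
  if (!is.null(spec$min_mean_dp) || !is.null(spec$max_mean_dp)) {
    if (is.null(gm$mean_dp)) {
      warning("no per-site depth available; depth criteria skipped")
    } else {
      if (!is.null(spec$min_mean_dp))
        mark(!is.na(gm$mean_dp) & gm$mean_dp < spec$min_mean_dp, "min_mean_dp")
      if (!is.null(spec$max_mean_dp))
        mark(!is.na(gm$mean_dp) & gm$mean_dp > spec$max_mean_dp, "max_mean_dp")
    }
  }
  called <- !is.na(gm$geno)
  if (!is.null(spec$max_missing_fraction)) {
    miss_frac <- 1 - rowMeans(called)
    mark(miss_frac > spec$max_missing_fraction, "max_missing_fraction")
  }
  if (!is.null(spec$min_nonref_allele_count)) {
    ac <- rowSums(gm$geno, na.rm = TRUE)
    mark(ac < spec$min_nonref_allele_count, "min_nonref_allele_count")
  }
  if (isTRUE(spec$snps_only))
    mark(nchar(gm$ref) != 1L |
           vapply(strsplit(gm$alt, ",", fixed = TRUE),
                  function(a) any(nchar(a) != 1L) || !length(a), TRUE),
         "snps_only")
  if (!is.null(spec$maf_min)) {
    nn <- rowSums(called)
    p <- rowSums(gm$geno, na.rm = TRUE) / pmax(2 * nn, 1)
    maf <- pmin(p, 1 - p)
    mark(nn == 0 | maf < spec$maf_min, "maf_min")
  }

  keep <- is.na(fail)
  out <- subset_sites(gm, keep)
  crit <- c("min_qual", "biallelic_only", "min_mean_dp", "max_mean_dp",
            "max_missing_fraction", "min_nonref_allele_count", "snps_only",
            "maf_min")
  report <- data.frame(criterion = crit,
                       removed = vapply(crit, function(k)
                         sum(fail == k, na.rm = TRUE), 1L),
                       row.names = NULL)
  attr(out, "filter_report") <- report
  attr(out, "n_input") <- n
  attr(out, "n_output") <- sum(keep)
  out
}

#' A single-transcript gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based closed gene span.
#' @param cds data.frame with `start`, `end`, `phase` for each CDS segment
#'   (1-based closed, non-overlapping, within the gene span).
#' @return a list of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, cds) {
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end", "phase") %in% names(cds)))
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(cds) > 1L && any(cds$start[-1] <= cds$end[-nrow(cds)]))
    stop("CDS intervals overlap in gene ", gene_id)
  if (any(cds$start < start | cds$end > end))
    stop("CDS outside gene span in gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 cds = data.frame(start = as.integer(cds$start),
                                  end = as.integer(cds$end),
                                  phase = as.integer(cds$phase))),
            class = "GeneModel")
}

#' Read gene models from a GFF3 file
#'
#' Builds one `GeneModel` per gene, attaching CDS features through their
#' `Parent` chain (direct CDS->gene or gene->mRNA->CDS; the first mRNA of a
#' gene is used when several exist). CDS without a resolvable parent gene
#' are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return named list of `GeneModel` objects (possibly empty).
#' @export
read_gff <- function(path) {
  nonempty <- any(!grepl("^#|^\\s*$", readLines(path)))
  if (!nonempty) return(stats::setNames(list(), character(0)))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  genes <- which(type == "gene")
  # map every feature ID to its owning gene ID
  owner <- stats::setNames(ids[genes], ids[genes])
  kids <- which(type %in% c("mRNA", "transcript"))
  for (k in kids) {
    par <- unlist(md$Parent[k])
    if (length(par) && par[1] %in% names(owner))
      owner[ids[k]] <- owner[[par[1]]]
  }
  models <- list()
  first_tx <- list()  # gene -> transcript whose CDS we keep
  cds_rows <- which(type == "CDS")
  cds_by_gene <- list()
  for (k in cds_rows) {
    par <- unlist(md$Parent[k])
    par <- par[par %in% names(owner)]
    if (!length(par)) {
      warning("CDS without a resolvable parent gene skipped at row ", k)
      next
    }
    g <- owner[[par[1]]]
    if (is.null(first_tx[[g]])) first_tx[[g]] <- par[1]
    if (!identical(first_tx[[g]], par[1])) next
    ph <- if (!is.null(md$phase)) md$phase[k] else NA
    cds_by_gene[[g]] <- rbind(cds_by_gene[[g]], data.frame(
      start = BiocGenerics::start(gr[k]), end = BiocGenerics::end(gr[k]),
      phase = if (is.na(ph)) 0L else as.integer(ph)))
  }
  for (k in genes) {
    g <- ids[k]
    cds <- cds_by_gene[[g]]
    if (is.null(cds)) cds <- data.frame(start = integer(0), end = integer(0),
                                        phase = integer(0))
    models[[g]] <- gene_model(
      gene_id = g, chrom = as.character(GenomeInfoDb::seqnames(gr[k])),
      strand = as.character(BiocGenerics::strand(gr[k])),
      start = BiocGenerics::start(gr[k]), end = BiocGenerics::end(gr[k]),
      cds = cds)
  }
  models
}

#' Extract a subsequence from a FASTA file
#'
#' @param path FASTA file (whole file is read into memory).
#' @param chrom sequence name (first whitespace-delimited token of the
#'   header line).
#' @param start,end 1-based closed interval.
#' @return uppercase character string of length `end - start + 1`.
#' @export
read_fasta_region <- function(path, chrom, start, end) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!chrom %in% names(seqs)) stop("sequence not found: ", chrom)
  s <- seqs[[chrom]]
  if (start < 1 || end > length(s)) stop("interval beyond contig end")
  toupper(as.character(Biostrings::subseq(s, start, end)))
}

#' Reverse complement of a DNA string
#' @param x character string of DNA bases.
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}
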