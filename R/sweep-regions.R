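#' Empirical percentile threshold
#'
#' The empirical `q`-quantile of the non-null values, using the linear
#' interpolation convention of `stats::quantile(type = 7)` (the R default:
#' the quantile interpolates between order statistics at
#' `1 + q (n - 1)`). Values strictly above the threshold are outliers; ties
#' at the threshold are excluded.
#'
#' @param values numeric vector (NAs dropped); at least 100 non-null values
#'   are required for a meaningful tail.
#' @param q quantile in (0, 1) (default 0.99, the top-1% rule).
#' @return the threshold.
#' @export
percentile_threshold <- function(values, q = 0.99) {
  v <- values[!is.na(values)]
  if (length(v) < 100) stop("need >= 100 non-null values for an empirical threshold")
  unname(stats::quantile(v, probs = q, type = 7))
}

#' Call empirical top-percentile outlier windows
#'
#' @param tbl a `WindowStatTable` from [sweep_scan()].
#' @param stat which statistic to threshold: `"lsbl"` or `"fst"` (the
#'   Target-vs-pooled track).
#' @param q quantile (default 0.99); `q = 0` returns every non-null window.
#' @return the outlier rows of `tbl`, with attribute `threshold`.
#' @export
call_outlier_windows <- function(tbl, stat = c("lsbl", "fst"), q = 0.99) {
  stat <- match.arg(stat)
  v <- tbl[[stat]]
  if (q == 0) {
    out <- tbl[!is.na(v), , drop = FALSE]
    attr(out, "threshold") <- -Inf
    return(out)
  }
  thr <- percentile_threshold(v, q)
  out <- tbl[!is.na(v) & v > thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Merge outlier windows into sweep regions
#'
#' Overlapping or book-ended windows on the same chromosome are merged;
#' peak statistics are maxima over the member windows. Input windows use the
#' grid convention (`end` exclusive); regions are reported 1-based closed.
#'
#' @param windows a data.frame of windows (e.g. from
#'   [call_outlier_windows()]) with `chrom`, `start`, `end` and optionally
#'   `fst` / `lsbl` columns.
#' @return a `SweepRegionTable` data.frame: `chrom`, `start`, `end` (closed),
#'   `n_windows`, `peak_fst`, `peak_lsbl`, sorted and pairwise disjoint.
#' @export
merge_windows <- function(windows) {
  if (!nrow(windows)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      peak_fst = numeric(0), peak_lsbl = numeric(0))
    class(out) <- c("SweepRegionTable", "data.frame")
    return(out)
  }
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start,
                                                windows$end - 1L))
  red <- GenomicRanges::reduce(gr)  # merges overlapping and adjacent
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)
  mx <- function(col) {
    if (is.null(windows[[col]])) return(rep(NA_real_, length(red)))
    as.numeric(tapply(windows[[col]][S4Vectors::queryHits(ov)], grp,
                      function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)))
  }
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
                    start = BiocGenerics::start(red),
                    end = BiocGenerics::end(red),
                    n_windows = as.integer(tabulate(grp, nbins = length(red))),
                    peak_fst = mx("fst"), peak_lsbl = mx("lsbl"))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SweepRegionTable", "data.frame")
  out
}

#' Genes overlapping sweep regions
#'
#' A gene is assigned to a region when its gene span overlaps the region by
#' at least 1 bp. Regions on chromosomes absent from the annotation simply
#' collect no genes (with a warning when no chromosome name matches at all).
#'
#' @param regions a `SweepRegionTable` (1-based closed coordinates).
#' @param genes a list of `GeneModel`s (from [read_gff()]).
#' @return `regions` with an added `gene_ids` column (comma-separated) and
#'   attribute `gene_set` (the union of assigned gene ids).
#' @export
genes_in_regions <- function(regions, genes) {
  if (!length(genes) || !nrow(regions)) {
    regions$gene_ids <- character(nrow(regions))
    attr(regions, "gene_set") <- character(0)
    return(regions)
  }
  gchrom <- vapply(genes, `[[`, "", "chrom")
  if (!any(gchrom %in% regions$chrom))
    warning("no chromosome names shared between regions and annotation")
  ggr <- GenomicRanges::GRanges(gchrom, IRanges::IRanges(
    vapply(genes, `[[`, 1L, "start"), vapply(genes, `[[`, 1L, "end")))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(rgr, ggr)
  ids <- vapply(genes, `[[`, "", "gene_id")
  lst <- split(ids[S4Vectors::subjectHits(ov)],
               factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(regions))))
  regions$gene_ids <- vapply(lst, function(x) paste(sort(unique(x)),
                                                    collapse = ","), "")
  attr(regions, "gene_set") <- sort(unique(ids[S4Vectors::subjectHits(ov)]))
  regions
}

#' Outlier regions and gene sets for both scan statistics
#'
#' Applies the top-percentile rule separately to the FST track and to LSBL,
#' merges each outlier set into regions, and reports the gene sets found by
#' each statistic plus their intersection (the "shared" genes). The combined
#' region set treats a window as outlying when it exceeds *either* threshold
#' (a flag switches to the intersection rule).
#'
#' @param tbl a `WindowStatTable`.
#' @param genes list of `GeneModel`s (may be empty).
#' @param q quantile (default 0.99).
#' @param combine `"union"` (default) or `"intersection"` of the two
#'   window outlier sets for the combined region list.
#' @return list with `regions` (combined, gene-annotated), `regions_fst`,
#'   `regions_lsbl`, `genes_fst`, `genes_lsbl`, `genes_shared`,
#'   `thresholds` (named vector).
#' @export
outlier_gene_sets <- function(tbl, genes = list(), q = 0.99,
                              combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  out_f <- call_outlier_windows(tbl, "fst", q)
  out_l <- call_outlier_windows(tbl, "lsbl", q)
  key <- function(w) paste(w$chrom, w$start)
  both <- if (combine == "union") {
    rbind(out_f, out_l[!key(out_l) %in% key(out_f), , drop = FALSE])
  } else {
    out_f[key(out_f) %in% key(out_l), , drop = FALSE]
  }
  reg_f <- genes_in_regions(merge_windows(out_f), genes)
  reg_l <- genes_in_regions(merge_windows(out_l), genes)
  reg_b <- genes_in_regions(merge_windows(both), genes)
  gf <- attr(reg_f, "gene_set"); gl <- attr(reg_l, "gene_set")
  list(regions = reg_b, regions_fst = reg_f, regions_lsbl = reg_l,
       genes_fst = gf, genes_lsbl = gl,
       genes_shared = intersect(gf, gl),
       thresholds = c(fst = attr(out_f, "threshold"),
                      lsbl = attr(out_l, "threshold")))
}

#' Haplotype pattern of a sweep region
#'
#' Selects the SNPs of a region whose alternate allele is at high frequency
#' (`>= freq_high`) in the Target population and low frequency
#' (`<= freq_low`) in the pooled Control+Background -- or the reference-
#' allele mirror of that rule, so that each selected site has *some* allele
#' that is high in Target and low elsewhere. The returned matrix keeps the
#' reference/alternate coding (0 = reference, 1 = alternate); rows are
#' phased haplotypes when phase is available, otherwise per-sample dosage
#' rows (0/1/2). Rows are grouped by population and ordered by similarity
#' (average-linkage clustering) within each population.
#'
#' @param gm a `GenotypeMatrix`.
#' @param chrom,start,end region (1-based closed).
#' @param freq_high,freq_low frequency cutoffs (defaults 0.7 / 0.3).
#' @return a `HaploPattern`: list with `pos`, `matrix` (rows = haplotypes or
#'   samples), `row_pop`, `phased`. Empty (0 columns) with a warning when no
#'   SNP satisfies the rule.
#' @export
haplotype_pattern <- function(gm, chrom, start, end,
                              freq_high = 0.7, freq_low = 0.3) {
  in_region <- which(gm$chrom == chrom & gm$pos >= start & gm$pos <= end)
  if (!length(in_region)) stop("region contains no SNPs")
  pT <- site_counts(gm, "Target")$p[in_region]
  pO <- site_counts(gm, c("Control", "Background"))$p[in_region]
  alt_rule <- !is.na(pT) & !is.na(pO) & pT >= freq_high & pO <= freq_low
  ref_rule <- !is.na(pT) & !is.na(pO) &
    (1 - pT) >= freq_high & (1 - pO) <= freq_low
  sel <- in_region[alt_rule | ref_rule]
  if (!length(sel)) warning("no SNP satisfies the frequency-differential rule")
  phased <- gm$phased && !is.null(gm$haplotypes)
  if (phased) {
    M <- t(gm$haplotypes[sel, , drop = FALSE])
    row_pop <- rep(gm$pop_labels, each = 2L)
    rownames(M) <- paste0(rep(gm$sample_ids, each = 2L), c("_1", "_2"))
  } else {
    M <- t(gm$geno[sel, , drop = FALSE])
    row_pop <- gm$pop_labels
    rownames(M) <- gm$sample_ids
  }
  colnames(M) <- gm$pos[sel]
  ord <- integer(0)
  for (p in POP_ROLES) {
    rows <- which(row_pop == p)
    if (length(rows) > 2 && ncol(M) > 1) {
      d <- stats::dist(M[rows, , drop = FALSE], method = "manhattan")
      d[is.na(d)] <- max(d, na.rm = TRUE) + 1
      rows <- rows[stats::hclust(stats::as.dist(d), method = "average")$order]
    }
    ord <- c(ord, rows)
  }
  structure(list(pos = gm$pos[sel], chrom = chrom,
                 matrix = M[ord, , drop = FALSE],
                 row_pop = row_pop[ord], phased = phased),
            class = "HaploPattern")
}

#' Write a HaploPattern as TSV
#'
#' First column is the row's population, remaining columns are the selected
#' site positions.
#' @param hp a `HaploPattern`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplo_pattern <- function(hp, path) {
  df <- data.frame(row = rownames(hp$matrix), pop = hp$row_pop,
                   hp$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
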