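#' Classify a coding SNP and name the amino-acid substitution
#'
#' Maps a genomic SNP into the coding sequence of a gene model (honoring
#' exon order, strand, and the GFF phase of the first CDS segment),
#' translates the affected codon before and after the substitution with the
#' standard genetic code, and returns the consequence class plus an
#' HGVS-like protein label such as `"P107T"`. Codons are numbered 1-based
#' from the annotated start codon.
#'
#' @param chrom,pos,ref,alt the SNP (single-base `ref`/`alt`, plus-strand
#'   VCF convention).
#' @param gene a `GeneModel`.
#' @param ref_seq reference sequence (character) covering the gene span.
#' @param ref_offset genomic coordinate of the first base of `ref_seq`
#'   (default 1, i.e. `ref_seq` is the whole chromosome).
#' @return list with `gene_id`, `class` (one of `synonymous`, `missense`,
#'   `stop_gained`, `stop_lost`, `non_coding`), and for coding SNPs
#'   `codon_number`, `ref_aa`, `alt_aa`, `ref_codon`, `alt_codon`, `label`.
#' @export
annotate_coding_snp <- function(chrom, pos, ref, alt, gene, ref_seq,
                                ref_offset = 1L) {
  stopifnot(inherits(gene, "GeneModel"))
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only single-nucleotide substitutions are supported")
  if (!identical(chrom, gene$chrom))
    stop("SNP chromosome does not match the gene model")
  ref_seq <- toupper(ref_seq)
  base_at <- function(p) substr(ref_seq, p - ref_offset + 1L, p - ref_offset + 1L)
  if (base_at(pos) != toupper(ref))
    stop(sprintf("reference allele mismatch at %s:%d (VCF %s, FASTA %s)",
                 chrom, pos, ref, base_at(pos)))
  cds <- gene$cds
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(seg))
    return(list(gene_id = gene$gene_id, class = "non_coding"))
  # position within the plus-strand concatenation of CDS segments
  lens <- cds$end - cds$start + 1L
  before <- if (seg > 1L) sum(lens[seq_len(seg - 1L)]) else 0L
  idx_plus <- before + (pos - cds$start[seg] + 1L)
  total <- sum(lens)
  parts <- vapply(seq_len(nrow(cds)), function(i)
    substr(ref_seq, cds$start[i] - ref_offset + 1L,
           cds$end[i] - ref_offset + 1L), "")
  coding <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    coding <- revcomp(coding)
    idx <- total - idx_plus + 1L
    ref_c <- revcomp(ref); alt_c <- revcomp(alt)
    phase <- cds$phase[nrow(cds)]  # first segment in transcription order
  } else {
    idx <- idx_plus
    ref_c <- toupper(ref); alt_c <- toupper(alt)
    phase <- cds$phase[1L]
  }
  coding <- substr(coding, phase + 1L, nchar(coding))
  idx <- idx - phase
  if (idx < 1L)
    return(list(gene_id = gene$gene_id, class = "non_coding"))
  codon_number <- (idx - 1L) %/% 3L + 1L
  cpos <- (idx - 1L) %% 3L + 1L
  codon <- substr(coding, 3L * (codon_number - 1L) + 1L, 3L * codon_number)
  if (nchar(codon) < 3L) {
    warning("SNP falls in an incomplete terminal codon")
    return(list(gene_id = gene$gene_id, class = "non_coding"))
  }
  if (substr(codon, cpos, cpos) != ref_c)
    stop("internal inconsistency mapping the SNP into the coding sequence")
  alt_codon <- codon
  substr(alt_codon, cpos, cpos) <- alt_c
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  class <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "missense"
  list(gene_id = gene$gene_id, class = class, codon_number = codon_number,
       ref_aa = ref_aa, alt_aa = alt_aa,
       ref_codon = codon, alt_codon = alt_codon,
       label = paste0(ref_aa, codon_number, alt_aa))
}

#' Report the variable columns of a pre-aligned protein set
#'
#' @param sequences named character vector of equal-length amino-acid
#'   strings (alignment itself is out of scope here).
#' @return data.frame with `column` plus one residue column per sequence,
#'   one row per alignment column at which at least two distinct residues
#'   occur. Empty when the sequences are identical.
#' @export
protein_alignment_view <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  M <- do.call(rbind, strsplit(sequences, ""))
  vary <- which(apply(M, 2L, function(col) length(unique(col)) >= 2L))
  out <- data.frame(column = vary)
  for (i in seq_along(sequences))
    out[[names(sequences)[i]]] <- M[i, vary]
  out
}
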