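#' Identity-by-state genetic distance matrix between samples
#'
#' `d(i, j) = mean(|dosage_i - dosage_j|) / 2` over the sites called in both
#' samples, i.e. one minus the proportion of shared alleles. Symmetric with
#' zero diagonal; entries lie in `[0, 1]`.
#'
#' @param gm a `GenotypeMatrix` with at least 2 samples.
#' @return numeric samples x samples matrix with sample ids as dimnames.
#' @export
ibs_distance_matrix <- function(gm) {
  n <- n_samples(gm)
  if (n < 2) stop("need at least two samples")
  G <- gm$geno
  D <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    gi <- G[, i]
    for (j in (i + 1L):n) {
      d <- abs(gi - G[, j])
      ok <- !is.na(d)
      if (!any(ok))
        stop("samples ", gm$sample_ids[i], " and ", gm$sample_ids[j],
             " share no called sites")
      D[i, j] <- D[j, i] <- mean(d[ok]) / 2
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum), with
#' branch lengths from the standard NJ formulas. Ties in `Q` are broken by
#' the lowest current-index pair, for determinism. Negative branch lengths
#' are clamped to zero with the deficit transferred to the sister branch, so
#' that the path length between the joined nodes is preserved (a common
#' convention). Additive matrices are recovered exactly.
#'
#' @param D symmetric numeric matrix with zero diagonal, >= 3 taxa.
#' @param labels tip labels (default: `rownames(D)`).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least three taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  safe <- gsub("[,():;\\s]", "_", labels, perl = TRUE)
  nodes <- safe  # newick fragment per active node
  repeat {
    m <- nrow(D)
    if (m == 3) break
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major over the upper triangle
    best <- c(NA, NA); bq <- Inf
    for (j in 2:m) for (i in 1:(j - 1)) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    newnode <- sprintf("(%s:%.17g,%s:%.17g)", nodes[i], bi, nodes[j], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    nodes <- c(nodes[keep], newnode)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (k in 1:3) {  # clamp the final star, preserving pairwise sums as far as possible
    bs <- c(b1, b2, b3)
    if (bs[k] < 0) {
      others <- setdiff(1:3, k)
      bs[others] <- bs[others] + bs[k] / 2
      bs[k] <- 0
      b1 <- bs[1]; b2 <- bs[2]; b3 <- bs[3]
    }
  }
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 nodes[1], b1, nodes[2], b2, nodes[3], b3)
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[match(tree$tip.label, safe)]
  tree
}

#' Build an NJ tree of all samples from genotypes
#'
#' Convenience wrapper: IBS distances then [neighbor_joining()].
#' @param gm a `GenotypeMatrix`.
#' @return an `ape::phylo` tree with sample-id tip labels.
#' @export
nj_tree <- function(gm) {
  neighbor_joining(ibs_distance_matrix(gm), labels = gm$sample_ids)
}
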