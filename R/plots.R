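#' Manhattan-style plot of a windowed scan statistic
#'
#' One point per window at the window midpoint, chromosomes laid out
#' end to end, with an optional horizontal threshold line.
#'
#' @param tbl a `WindowStatTable`.
#' @param stat column to plot (default `"lsbl"`).
#' @param threshold optional horizontal line (e.g. the top-1% threshold).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the x offsets used per chromosome.
#' @export
plot_manhattan <- function(tbl, stat = "lsbl", threshold = NULL, ...) {
  chroms <- unique(tbl$chrom)
  offs <- stats::setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (cc in chroms) {
    offs[cc] <- run
    run <- run + max(tbl$end[tbl$chrom == cc])
  }
  x <- offs[tbl$chrom] + (tbl$start + tbl$end) / 2
  cols <- (match(tbl$chrom, chroms) %% 2) + 1
  graphics::plot(x, tbl[[stat]], pch = 16, cex = 0.4,
                 col = c("grey40", "steelblue")[cols],
                 xlab = "genome position (bp)", ylab = stat, ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(offs)
}

#' Plot an LD decay curve
#'
#' @param curve a `DecayCurve`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_ld_decay <- function(curve, ...) {
  mid <- (curve$bin_start + curve$bin_end) / 2
  graphics::plot(mid / 1000, curve$mean_r2, type = "l",
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2), ...)
  hd <- attr(curve, "half_decay_bp")
  if (!is.na(hd)) graphics::abline(v = hd / 1000, col = "red", lty = 2)
  invisible(NULL)
}

#' Tile plot of a haplotype pattern
#'
#' Reference alleles light yellow, alternate alleles green; a side bar
#' marks the population of each row.
#'
#' @param hp a `HaploPattern`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `NULL`.
#' @export
plot_haplotype_pattern <- function(hp, ...) {
  M <- hp$matrix
  if (!ncol(M)) stop("empty haplotype pattern")
  pal <- c("lightyellow", "palegreen3", "forestgreen")
  zmax <- max(M, na.rm = TRUE)
  graphics::image(x = seq_len(ncol(M)), y = seq_len(nrow(M)),
                  z = t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = pal[seq_len(zmax + 1)], xlab = "SNP", ylab = "",
                  yaxt = "n", ...)
  popcol <- c(Target = "red", Control = "green3", Background = "blue")
  graphics::points(rep(0.25, nrow(M)), rev(seq_len(nrow(M))), pch = 15,
                   col = popcol[hp$row_pop], cex = 0.6, xpd = NA)
  invisible(NULL)
}
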