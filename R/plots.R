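#' Manhattan plot of a GWAS result
#'
#' Markers at cumulative genome position against -log10(p); chromosomes in
#' alternating shades; the FDR significance set highlighted.
#'
#' @param gwas a [weighted_gwas()] result.
#' @param q_threshold FDR threshold for highlighting (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(gwas, q_threshold = 0.05, ...) {
  chroms <- unique(gwas$chrom)
  offset <- 0
  xpos <- numeric(nrow(gwas))
  ticks <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    jj <- gwas$chrom == chroms[i]
    xpos[jj] <- gwas$bp[jj] + offset
    ticks[i] <- offset + max(gwas$bp[jj]) / 2
    offset <- offset + max(gwas$bp[jj])
  }
  col <- c("grey30", "grey60")[(match(gwas$chrom, chroms) %% 2L) + 1L]
  sig <- !is.na(gwas$q) & gwas$q < q_threshold
  graphics::plot(xpos, -log10(gwas$p), pch = 20, cex = 0.5, col = col,
                 xaxt = "n", xlab = "chromosome", ylab = expression(-log[10](p)), ...)
  graphics::axis(1, at = ticks, labels = chroms)
  if (any(sig)) graphics::points(xpos[sig], -log10(gwas$p[sig]), pch = 20,
                                 col = "red", cex = 0.8)
  invisible(NULL)
}

#' Quantile-quantile plot of GWAS p-values
#'
#' Observed against expected -log10(p) under the uniform null, with the
#' genomic inflation factor in the legend.
#'
#' @param p_values raw p-values.
#' @param ... passed to [graphics::plot()].
#' @export
plot_qq <- function(p_values, ...) {
  p <- sort(p_values[!is.na(p_values)])
  m <- length(p)
  exp_q <- -log10((seq_len(m) - 0.5) / m)
  graphics::plot(exp_q, -log10(p), pch = 20, cex = 0.5,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, col = "red")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("lambda = %.3f", inflation_factor(p)))
  invisible(NULL)
}

#' Local GWAS + eQTL track plot around a marker
#'
#' GWAS -log10(p) above, eQTL -log10(p) below (mirrored), for markers within
#' a window of a focal SNP.
#'
#' @param gwas a [weighted_gwas()] result.
#' @param eqtls a [cis_eqtl_scan()] result.
#' @param marker_id focal marker.
#' @param window_bp half-window (default 1e6).
#' @export
plot_local <- function(gwas, eqtls, marker_id, window_bp = 1e6) {
  i <- match(marker_id, gwas$marker_id)
  if (is.na(i)) stop("marker not in GWAS result")
  chr <- gwas$chrom[i]; pos <- gwas$bp[i]
  gg <- gwas[gwas$chrom == chr & abs(gwas$bp - pos) <= window_bp, ]
  ee <- eqtls[eqtls$marker_id %in% gg$marker_id, ]
  ee$bp <- gg$bp[match(ee$marker_id, gg$marker_id)]
  ylim <- c(-max(-log10(ee$p), 1, na.rm = TRUE), max(-log10(gg$p), 1, na.rm = TRUE))
  graphics::plot(gg$bp / 1e6, -log10(gg$p), pch = 20, ylim = ylim,
                 xlab = sprintf("position on chr %s (Mb)", chr),
                 ylab = expression(-log[10](p)))
  if (nrow(ee)) graphics::points(ee$bp / 1e6, log10(ee$p), pch = 17, col = "blue")
  graphics::abline(h = 0, col = "grey")
  graphics::abline(v = pos / 1e6, lty = 2, col = "red")
  invisible(NULL)
}
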