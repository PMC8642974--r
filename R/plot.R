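# Per-chromosome SNP-index / delta(SNP-index) curve plots.

#' Plot sliding-window SNP-index curves
#'
#' One panel per chromosome showing the high- and low-bulk SNP-index means,
#' the delta(SNP-index) curve, and (optionally) the null threshold band.
#'
#' @param windows output of [sliding_windows()].
#' @param curve optional `threshold_curve`; its 95% band at the median
#'   window depth is drawn as horizontal guides.
#' @return A ggplot object.
#' @export
plot_snp_index <- function(windows, curve = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_snp_index() needs the ggplot2 package", call. = FALSE)
  }
  w <- windows[!is.na(windows$delta), , drop = FALSE]
  w$mid_mb <- (w$start + w$end) / 2 / 1e6
  long <- rbind(
    data.frame(CHROM = w$CHROM, mid_mb = w$mid_mb, value = w$high_index,
               series = "high bulk"),
    data.frame(CHROM = w$CHROM, mid_mb = w$mid_mb, value = w$low_index,
               series = "low bulk"),
    data.frame(CHROM = w$CHROM, mid_mb = w$mid_mb, value = w$delta,
               series = "delta")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(mid_mb, value, colour = series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~CHROM, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SNP-index / delta(SNP-index)") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    dmed <- stats::median((w$high_depth + w$low_depth) / 2, na.rm = TRUE)
    ri <- which.min(abs(curve$depth - dmed))
    p <- p + ggplot2::geom_hline(yintercept = c(curve$lo95[ri], curve$hi95[ri]),
                                 linetype = "dashed", colour = "red") +
      ggplot2::geom_hline(yintercept = c(curve$lo99[ri], curve$hi99[ri]),
                          linetype = "dotted", colour = "darkgreen")
  }
  p
}

utils::globalVariables(c("mid_mb", "value", "series"))
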