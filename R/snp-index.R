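# SNP-index, delta(SNP-index) and sliding-window statistics for QTL-seq.

#' Per-SNP SNP-index and delta(SNP-index)
#'
#' The SNP-index of a bulk at a SNP is (alternate-read count) / (total read
#' count); with maize as REF and teosinte as ALT it is 1 when every read
#' carries the teosinte allele and 0 when every read carries the maize
#' allele.  SNPs whose depth in a bulk falls outside `[depth_min, depth_max]`
#' are masked in that bulk (`low_depth` / `high_depth`); the bounds
#' themselves pass.  delta(SNP-index) = high-bulk index minus low-bulk index,
#' defined only where both bulks pass.
#'
#' @param counts data.frame with columns `CHROM`, `POS`, `HIGH_REF`,
#'   `HIGH_ALT`, `LOW_REF`, `LOW_ALT` (see [read_allele_counts()]).
#' @param depth_min,depth_max inclusive depth pass band (default 4 and 32).
#' @return data.frame with per-bulk depth, SNP-index, filter status and
#'   `delta`.
#' @export
compute_snp_index <- function(counts, depth_min = 4, depth_max = 32) {
  need <- c("CHROM", "POS", "HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")
  if (!all(need %in% names(counts))) {
    stop("allele-count table lacks columns: ",
         paste(setdiff(need, names(counts)), collapse = ", "), call. = FALSE)
  }
  cnt <- counts[, c("HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")]
  if (any(cnt < 0)) stop("negative read counts", call. = FALSE)
  one_bulk <- function(ref, alt) {
    depth <- ref + alt
    status <- ifelse(depth < depth_min, "low_depth",
                     ifelse(depth > depth_max, "high_depth", "pass"))
    index <- ifelse(status == "pass", alt / depth, NA_real_)
    list(depth = depth, index = index, status = status)
  }
  hi <- one_bulk(counts$HIGH_REF, counts$HIGH_ALT)
  lo <- one_bulk(counts$LOW_REF, counts$LOW_ALT)
  data.frame(
    CHROM = counts$CHROM, POS = counts$POS,
    high_depth = hi$depth, high_index = hi$index, high_filter = hi$status,
    low_depth = lo$depth, low_index = lo$index, low_filter = lo$status,
    delta = hi$index - lo$index
  )
}

#' Sliding-window means of SNP-index and delta(SNP-index)
#'
#' Windows are anchored at position 0 of each chromosome and advance by
#' `step_bp`: window k covers `[k*step_bp, k*step_bp + window_bp)` (half
#' open, 1-based positions).  Means are arithmetic averages over SNPs whose
#' delta passed filtering; windows holding fewer than `min_snps` such SNPs
#' report missing means.
#'
#' @param snp_index output of [compute_snp_index()], sorted by
#'   (chromosome, position).
#' @param window_bp window size in bp (default 1 Mb).
#' @param step_bp window increment in bp (default 10 kb).
#' @param min_snps minimum passing SNPs for a window mean.
#' @return data.frame with one row per window: `CHROM`, `start`, `end`
#'   (1-based, end exclusive), `n_snps`, `high_index`, `low_index`, `delta`,
#'   `high_depth`, `low_depth`.
#' @export
sliding_windows <- function(snp_index, window_bp = 1e6, step_bp = 1e4,
                            min_snps = 3) {
  stopifnot(window_bp > 0, step_bp > 0)
  ord <- order(snp_index$CHROM, snp_index$POS)
  if (!identical(ord, seq_len(nrow(snp_index)))) {
    stop("input must be sorted by (CHROM, POS)", call. = FALSE)
  }
  out <- lapply(split(snp_index, snp_index$CHROM), function(df) {
    pass <- !is.na(df$delta)
    pos <- df$POS
    kmax <- floor(max(pos) / step_bp)
    starts <- (0:kmax) * step_bp
    ends <- starts + window_bp
    # passing SNPs only, via cumulative sums over sorted positions
    p_pos <- pos[pass]
    cum <- function(v) c(0, cumsum(v))
    cd <- cum(df$delta[pass])
    chi <- cum(df$high_index[pass])
    clo <- cum(df$low_index[pass])
    cdh <- cum(df$high_depth[pass])
    cdl <- cum(df$low_depth[pass])
    # window [s, e): SNPs with s <= pos <= e-1, i.e. pos in [s, e)
    i0 <- findInterval(starts - 0.5, p_pos)
    i1 <- findInterval(ends - 0.5, p_pos)
    n <- i1 - i0
    mean_of <- function(cs) ifelse(n >= min_snps, (cs[i1 + 1] - cs[i0 + 1]) / n, NA_real_)
    data.frame(
      CHROM = df$CHROM[1], start = starts, end = ends, n_snps = n,
      high_index = mean_of(chi), low_index = mean_of(clo),
      delta = mean_of(cd),
      high_depth = mean_of(cdh), low_depth = mean_of(cdl)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
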