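# Monte-Carlo null distribution of delta(SNP-index) and candidate-region
# calling against the simulated confidence bands.

#' Null distribution of delta(SNP-index)
#'
#' Simulates delta(SNP-index) at an unlinked locus for bulks of selected
#' plants: per replicate and bulk, individual genotypes are drawn from the
#' null design (F2-like dosage 0/1/2 with probability 1/4, 1/2, 1/4;
#' BC-like dosage 0/1 with probability 1/2, 1/2), the bulk allele frequency
#' is formed, read depth is Poisson truncated to the depth-filter pass band,
#' and the alternate count is binomial.  Two-sided 95% and 99% quantile
#' bands are tabulated per mean depth.
#'
#' @param design `"F2"` or `"BC"` null genotype distribution.
#' @param n_high,n_low bulk sizes.
#' @param depths integer vector of mean depths to tabulate.
#' @param n_reps Monte-Carlo replicates per depth (default 10000).
#' @param depth_min,depth_max depth pass band used to truncate the depth
#'   distribution (must match the SNP filtering).
#' @return A `threshold_curve`: data.frame with columns `depth`, `lo95`,
#'   `hi95`, `lo99`, `hi99`; metadata (design, bulk sizes, replicate count)
#'   in attributes.  A warning is recorded in the metadata when
#'   `n_reps < 1000` (unstable tail quantiles).
#' @export
null_delta_distribution <- function(design = c("F2", "BC"), n_high = 50,
                                    n_low = 50, depths = 4:32,
                                    n_reps = 10000, depth_min = 4,
                                    depth_max = 32) {
  design <- match.arg(design)
  unstable <- n_reps < 1000
  if (unstable) {
    warning("n_reps < 1000: tail quantiles will be unstable", call. = FALSE)
  }
  # bulk allele frequency under the null: sum of allele draws is binomial
  draw_freq <- function(n) {
    if (design == "F2") {
      stats::rbinom(n_reps, 2L * n, 0.5) / (2 * n)
    } else {
      stats::rbinom(n_reps, n, 0.5) / n
    }
  }
  rtrunc_pois <- function(lambda) {
    kk <- depth_min:depth_max
    w <- stats::dpois(kk, lambda)
    if (sum(w) <= 0) {
      stop("depth ", lambda, " has no mass inside the pass band", call. = FALSE)
    }
    sample(kk, n_reps, replace = TRUE, prob = w)
  }
  rows <- lapply(depths, function(dp) {
    d_hi <- rtrunc_pois(dp)
    d_lo <- rtrunc_pois(dp)
    idx_hi <- stats::rbinom(n_reps, d_hi, draw_freq(n_high)) / d_hi
    idx_lo <- stats::rbinom(n_reps, d_lo, draw_freq(n_low)) / d_lo
    delta <- idx_hi - idx_lo
    q <- stats::quantile(delta, c(0.025, 0.975, 0.005, 0.995), names = FALSE)
    data.frame(depth = dp, lo95 = q[1], hi95 = q[2], lo99 = q[3], hi99 = q[4])
  })
  out <- do.call(rbind, rows)
  structure(out,
            design = design, n_high = n_high, n_low = n_low,
            n_reps = n_reps, unstable_tails = unstable,
            class = c("threshold_curve", "data.frame"))
}

# Nearest tabulated depth for each window mean depth.
.nearest_depth_row <- function(curve, depth) {
  vapply(depth, function(d) {
    if (is.na(d)) NA_integer_ else which.min(abs(curve$depth - d))
  }, integer(1))
}

#' Call candidate genomic regions from window statistics
#'
#' A window is significant when its mean delta(SNP-index) lies strictly
#' outside the null band for its mean depth (nearest tabulated depth); ties
#' at the threshold are non-significant.  Runs of consecutive significant
#' windows of the same sign are merged into regions.  Each region reports
#' its delta range over member windows, the peak |delta|, the direction of
#' enrichment, and whether the peak window also clears the 99% band.
#'
#' @param windows output of [sliding_windows()].
#' @param curve a `threshold_curve` from [null_delta_distribution()].
#' @param alpha significance level, 0.05 or 0.01.
#' @return data.frame of regions: `CHROM`, `start`, `end`, `n_windows`,
#'   `delta_min`, `delta_max`, `peak_delta`, `direction`
#'   (`"teosinte_in_high"` or `"maize_in_high"`), `level`.
#' @export
call_candidate_regions <- function(windows, curve, alpha = 0.05) {
  if (!alpha %in% c(0.05, 0.01)) {
    stop("alpha must be 0.05 or 0.01", call. = FALSE)
  }
  empty <- data.frame(
    CHROM = integer(0), start = numeric(0), end = numeric(0),
    n_windows = integer(0), delta_min = numeric(0), delta_max = numeric(0),
    peak_delta = numeric(0), direction = character(0), level = numeric(0)
  )
  if (nrow(windows) == 0) return(empty)
  # window depth: average of the two bulk mean depths
  depth <- (windows$high_depth + windows$low_depth) / 2
  ri <- .nearest_depth_row(curve, depth)
  lo <- ifelse(alpha == 0.05, curve$lo95[ri], curve$lo99[ri])
  hi <- ifelse(alpha == 0.05, curve$hi95[ri], curve$hi99[ri])
  lo99 <- curve$lo99[ri]
  hi99 <- curve$hi99[ri]
  delta <- windows$delta
  sig <- !is.na(delta) & !is.na(lo) & (delta > hi | delta < lo)
  if (!any(sig)) return(empty)
  sgn <- sign(delta)
  regions <- list()
  # same-sign windows are chained by interval overlap; an interleaved
  # opposite-sign window forms its own region, so regions called at 0.01
  # are always contained in regions called at 0.05
  groups <- expand.grid(chr = unique(windows$CHROM[sig]), s = c(-1, 1))
  for (gi in seq_len(nrow(groups))) {
    chr <- groups$chr[gi]
    sel <- which(windows$CHROM == chr & sig & sgn == groups$s[gi])
    if (!length(sel)) next
    sel <- sel[order(windows$start[sel])]
    grp <- cumsum(c(1, windows$start[sel][-1] >
                      cummax(windows$end[sel][-length(sel)])))
    for (g in unique(grp)) {
      idx <- sel[grp == g]
      dd <- delta[idx]
      pk <- idx[which.max(abs(dd))]
      lvl <- if (delta[pk] > hi99[pk] || delta[pk] < lo99[pk]) 0.01 else 0.05
      regions[[length(regions) + 1]] <- data.frame(
        CHROM = chr,
        start = min(windows$start[idx]),
        end = max(windows$end[idx]),
        n_windows = length(idx),
        delta_min = min(dd), delta_max = max(dd),
        peak_delta = delta[pk],
        direction = if (delta[pk] > 0) "teosinte_in_high" else "maize_in_high",
        level = if (alpha == 0.01) 0.01 else lvl
      )
    }
  }
  out <- do.call(rbind, regions)
  out[order(out$CHROM, out$start), , drop = FALSE]
}
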