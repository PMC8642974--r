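# Direct simulation of F2-type marker genotypes along a genetic map.
#
# For scan-level work it is wasteful to carry whole-genome segment tilings;
# an F2 individual's genotypes along one chromosome are two independent
# gametes, each a Markov chain of founder alleles with transition
# probability equal to the Haldane recombination fraction between adjacent
# positions.  This is exactly the no-interference model used by the
# whole-genome simulator, restricted to the marker positions.

#' Simulate F2 genotypes at mapped positions
#'
#' @param map data.frame with columns `marker`, `chrom`, `pos_cM` (and
#'   optionally `pos_bp`), as used by the scans.
#' @param n number of individuals.
#' @return Character matrix (n x markers) of codes A/H/B, with column names
#'   from `map$marker`.
#' @export
sim_f2_genotypes <- function(map, n) {
  m <- nrow(map)
  out <- matrix(0L, nrow = n, ncol = m)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    idx <- idx[order(map$pos_cM[idx])]
    r <- .haldane_r(diff(map$pos_cM[idx]))
    gam <- function() {
      g <- matrix(0L, n, length(idx))
      g[, 1] <- stats::rbinom(n, 1, 0.5)
      if (length(idx) > 1) {
        for (k in 2:length(idx)) {
          flip <- stats::rbinom(n, 1, r[k - 1])
          g[, k] <- ifelse(flip == 1, 1L - g[, k - 1], g[, k - 1])
        }
      }
      g
    }
    out[, idx] <- gam() + gam()
  }
  colnames(out) <- map$marker
  matrix(c("A", "H", "B")[out + 1L], nrow = n,
         dimnames = list(NULL, map$marker))
}

#' Linear QTL phenotype on the transformed scale
#'
#' Generates a phenotype directly on the analysis (cube-root transformed)
#' scale as an additive/dominance/epistasis linear model of QTL dosages,
#' without censoring -- the generating model matched by the interval scans.
#' Used for scan calibration and planted-truth recovery.
#'
#' @param dosage integer matrix of teosinte dosages (individuals x loci).
#' @param a,d additive and dominance effects per locus (x = +1 for the
#'   maize homozygote, so negative `a` means teosinte increases the value).
#' @param aa optional data.frame `locus1`, `locus2`, `aa` of
#'   additive-by-additive effects between locus columns.
#' @param sigma_e residual standard deviation.
#' @param mu intercept.
#' @return Numeric phenotype vector.
#' @export
sim_linear_phenotype <- function(dosage, a, d, aa = NULL, sigma_e, mu = 0) {
  x <- 1 - dosage
  z <- (dosage == 1L) * 1
  g <- mu + x %*% a + z %*% d
  if (!is.null(aa) && nrow(aa)) {
    for (k in seq_len(nrow(aa))) {
      g <- g + aa$aa[k] * x[, aa$locus1[k]] * x[, aa$locus2[k]]
    }
  }
  as.numeric(g + stats::rnorm(nrow(dosage), 0, sigma_e))
}

#' Default local marker map for the scan arm
#'
#' A 31-marker map over the four QTL-bearing chromosomes (8 markers on
#' chromosome 1, 14 on 3, 4 on 6, 5 on 8), spans matching the local maps a
#' practitioner would genotype around QTL-seq candidate regions.
#'
#' @return data.frame `marker`, `chrom`, `pos_bp`, `pos_cM`.
#' @export
local_marker_map <- function() {
  mk <- function(chrom, n, span_cM, start_bp, span_bp) {
    data.frame(
      marker = sprintf("PM%d.%d", chrom, seq_len(n)),
      chrom = chrom,
      pos_bp = round(seq(start_bp, start_bp + span_bp, length.out = n)),
      pos_cM = round(seq(0, span_cM, length.out = n), 1)
    )
  }
  rbind(
    mk(1L, 8L, 70, 184e6, 98e6),
    mk(3L, 14L, 55, 1e6, 156e6),
    mk(6L, 4L, 35, 60e6, 40e6),
    mk(8L, 5L, 30, 120e6, 38e6)
  )
}
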