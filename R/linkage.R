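# Marker QC, two-point recombination estimation, Kosambi distances, and
# local genetic-map construction on physically anchored markers.
#
# Genotype codes throughout: A = maize homozygote, H = heterozygote,
# B = teosinte homozygote, "-" = missing.

#' Chi-square test for segregation distortion
#'
#' Pearson chi-square of observed (A, H, B) counts against the 1:2:1
#' Mendelian expectation of a codominant F2-type marker, 2 degrees of
#' freedom.
#'
#' @param counts numeric vector `c(n_A, n_H, n_B)`.
#' @return list with `chisq`, `p_value`, `n`.
#' @export
segregation_chi2 <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("marker has no scored genotypes", call. = FALSE)
  expected <- n * c(0.25, 0.5, 0.25)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 2, lower.tail = FALSE),
       n = n)
}

# F2 joint genotype probabilities for two codominant markers at
# recombination fraction r: 3x3 matrix over (A,H,B) x (A,H,B).  The
# double-heterozygote class mixes coupling and repulsion phases.
.f2_joint_probs <- function(r) {
  # gamete haplotype probabilities for an AB/ab F1
  # (parental (1-r)/2 each, recombinant r/2 each)
  hap <- c(AB = (1 - r) / 2, ab = (1 - r) / 2, Ab = r / 2, aB = r / 2)
  al1 <- c(AB = 1L, ab = 0L, Ab = 1L, aB = 0L) # maize allele at locus 1
  al2 <- c(AB = 1L, ab = 0L, Ab = 0L, aB = 1L)
  probs <- matrix(0, 3, 3)
  for (g1 in 1:4) {
    for (g2 in 1:4) {
      i <- 3L - (al1[g1] + al1[g2]) # 1=A (2 maize alleles), 2=H, 3=B
      j <- 3L - (al2[g1] + al2[g2])
      probs[i, j] <- probs[i, j] + hap[g1] * hap[g2]
    }
  }
  probs
}

#' Two-point recombination fraction for F2 codominant markers
#'
#' Maximum-likelihood estimate of the recombination fraction from the 3x3
#' joint genotype counts of two codominant markers in an F2-type
#' population, by bounded search on [0, 0.5]; the double-heterozygote class
#' correctly mixes the two phases.  LOD is the log10 likelihood ratio
#' against r = 0.5.
#'
#' @param g1,g2 character vectors of codes A/H/B/`-` for the two markers.
#' @param min_n minimum pairwise-complete individuals (default 20).
#' @return list with `r_hat`, `lod`, `n`.
#' @export
estimate_recfrac <- function(g1, g2, min_n = 20) {
  stopifnot(length(g1) == length(g2))
  lv <- c("A", "H", "B")
  ok <- g1 %in% lv & g2 %in% lv
  n <- sum(ok)
  if (n == 0) stop("no pairwise-complete individuals", call. = FALSE)
  if (n < min_n) {
    warning("only ", n, " pairwise-complete individuals", call. = FALSE)
  }
  cnt <- table(factor(g1[ok], lv), factor(g2[ok], lv))
  loglik <- function(r) sum(cnt * log(pmax(.f2_joint_probs(r), 1e-300)))
  opt <- stats::optimize(loglik, c(0, 0.5), maximum = TRUE, tol = 1e-8)
  r_hat <- min(opt$maximum, 0.5)
  lod <- (loglik(r_hat) - loglik(0.5)) / log(10)
  list(r_hat = r_hat, lod = max(lod, 0), n = n)
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance,
#' cM = 25 ln((1+2r)/(1-2r)).
#'
#' @param r recombination fraction in [0, 0.5).
#' @return Distance in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("r must lie in [0, 0.5): r = 0.5 maps to infinite distance",
         call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param cm map distance in cM (>= 0).
#' @return Recombination fraction r = tanh(cM/50)/2.
#' @export
kosambi_r <- function(cm) {
  if (any(cm < 0)) stop("map distance must be non-negative", call. = FALSE)
  tanh(cm / 50) / 2
}

#' Build a local genetic map from a genotype matrix
#'
#' Markers failing the 1:2:1 segregation screen at `alpha_distortion` are
#' removed; survivors are ordered by physical position (marker order is
#' taken from the genome assembly, not re-estimated), adjacent recombination
#' fractions are estimated by [estimate_recfrac()] and converted to Kosambi
#' cM, and positions are accumulated from 0 per chromosome.
#'
#' Markers that are (near-)monomorphic in the genotyped population carry no
#' linkage information and are always removed, whatever `alpha_distortion`;
#' setting `alpha_distortion = 0` skips the chi-square screen itself, for
#' populations (e.g. advanced backcrosses) where linked markers deviate
#' from 1:2:1 by construction and the screen has already been applied in an
#' F2.
#'
#' @param geno genotype matrix or data.frame (individuals x markers) of
#'   codes A/H/B/`-`.
#' @param marker_info data.frame with columns `marker`, `chrom`, `pos_bp`
#'   matching the columns of `geno`.
#' @param alpha_distortion screen level for the distortion chi-square.
#' @return A `genetic_map`: data.frame `marker`, `chrom`, `pos_bp`,
#'   `pos_cM`; dropped markers are recorded in attribute `dropped`.
#' @export
build_local_map <- function(geno, marker_info, alpha_distortion = 0.05) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(marker_info))
  colnames(geno) <- marker_info$marker
  keep <- apply(geno, 2, function(g) {
    cnt <- table(factor(g, c("A", "H", "B")))
    n <- sum(cnt)
    if (n == 0 || max(cnt) / n > 0.95) return(FALSE) # monomorphic/all-missing
    alpha_distortion <= 0 ||
      segregation_chi2(as.numeric(cnt))$p_value >= alpha_distortion
  })
  dropped <- marker_info$marker[!keep]
  info <- marker_info[keep, , drop = FALSE]
  geno <- geno[, keep, drop = FALSE]
  maps <- list()
  for (chr in unique(info$chrom)) {
    mi <- info[info$chrom == chr, , drop = FALSE]
    mi <- mi[order(mi$pos_bp), , drop = FALSE]
    if (nrow(mi) < 2) {
      warning("chromosome ", chr, " has fewer than 2 markers after QC; dropped",
              call. = FALSE)
      next
    }
    cm <- numeric(nrow(mi))
    for (k in 2:nrow(mi)) {
      est <- estimate_recfrac(geno[, mi$marker[k - 1]], geno[, mi$marker[k]])
      cm[k] <- cm[k - 1] + kosambi_cm(min(est$r_hat, 0.4999))
    }
    maps[[as.character(chr)]] <- data.frame(
      marker = mi$marker, chrom = chr, pos_bp = mi$pos_bp, pos_cM = cm
    )
  }
  if (!length(maps)) {
    stop("no chromosome retained at least 2 informative markers", call. = FALSE)
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  structure(out, dropped = dropped, class = c("genetic_map", "data.frame"))
}
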