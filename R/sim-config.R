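# Simulation configuration for the maize x teosinte backcross scheme.

#' Default chromosome table for the maize genome
#'
#' Ten chromosomes with physical lengths close to the B73 reference assembly
#' and genetic lengths of roughly 0.7 cM/Mb, giving a ~1500 cM genome.
#'
#' @return data.frame with columns `chrom`, `length_bp`, `length_cM`.
#' @export
maize_chromosomes <- function() {
  length_mb <- c(307, 244, 235, 247, 224, 174, 182, 181, 159, 151)
  data.frame(
    chrom = 1:10,
    length_bp = length_mb * 1e6,
    length_cM = round(length_mb * 0.7)
  )
}

#' Planted QTL models for the PEDS phenotype
#'
#' `"full"` plants the architecture the trait analysis is aimed at: one major
#' QTL on chromosome 3, minor QTL on chromosomes 1, 6 and 8, and
#' additive-by-additive epistasis between the major locus and each minor
#' locus.  `"major_only"` keeps the chromosome 3 locus alone, calibrated so
#' that its heritability on the cube-root-transformed scale is close to 0.35.
#'
#' Effects are on the latent liability scale of the censored phenotype model
#' (see [simulate_peds_phenotype()]).  Negative additive effects mean the
#' teosinte allele increases PEDS.
#'
#' @param model `"full"` or `"major_only"`.
#' @return list with data.frames `loci` (chrom, pos_cM, a, d) and
#'   `epistasis` (chrom1, pos1_cM, chrom2, pos2_cM, aa), plus the latent
#'   intercept `mu` and residual sd `sigma_e`.
#' @export
peds_qtl_model <- function(model = c("full", "major_only")) {
  model <- match.arg(model)
  chrom_tab <- maize_chromosomes()
  cm_at <- function(chrom, mb) {
    mb * 1e6 / chrom_tab$length_bp[chrom] * chrom_tab$length_cM[chrom]
  }
  if (model == "major_only") {
    # calibrated so the single-locus heritability on the cube-root scale is
    # ~0.35 and a few percent of an F2-like population exceed PEDS 90
    loci <- data.frame(
      chrom = 3L, pos_cM = cm_at(3L, 12), a = -0.45, d = -0.30
    )
    epi <- data.frame(
      chrom1 = integer(0), pos1_cM = numeric(0),
      chrom2 = integer(0), pos2_cM = numeric(0), aa = numeric(0)
    )
    mu <- -0.10
    sigma_e <- 0.50
  } else {
    # calibrated so a BC3F2 in which all four loci segregate 1:2:1 has a
    # PEDS>0 fraction near 1/14 (point mass at 0, long right tail) while
    # plants at PEDS = 100 remain available for recurrent selection
    loci <- data.frame(
      chrom = c(3L, 1L, 6L, 8L),
      pos_cM = c(cm_at(3L, 12), cm_at(1L, 200), cm_at(6L, 80), cm_at(8L, 130)),
      a = c(-0.40, -0.15, -0.15, -0.15),
      d = c(-0.32, -0.05, -0.05, -0.05)
    )
    epi <- data.frame(
      chrom1 = c(3L, 3L, 3L),
      pos1_cM = rep(cm_at(3L, 12), 3),
      chrom2 = c(1L, 6L, 8L),
      pos2_cM = c(cm_at(1L, 200), cm_at(6L, 80), cm_at(8L, 130)),
      aa = c(0.5, 0.5, 0.5)
    )
    mu <- -0.70
    sigma_e <- 0.30
  }
  list(loci = loci, epistasis = epi, mu = mu, sigma_e = sigma_e)
}

#' Build a simulation configuration
#'
#' @param seed mandatory integer seed; recorded in every simulator output.
#' @param chromosomes chromosome table as from [maize_chromosomes()].
#' @param qtl_model planted genetic architecture, see [peds_qtl_model()].
#' @param n_backcrosses number of backcross cycles (3 gives a BC3F2).
#' @param n_f2 size of the initial F2 and of each intermediate BCnF2.
#' @param n_bcf1 number of BCnF1 plants produced per backcross.
#' @param n_final size of the final BCnF2 mapping population.
#' @param selection_threshold PEDS value (percent) a plant must reach to be
#'   selected as a backcross parent; the field scheme used exactly 100.
#' @param n_bulk plants per sequencing bulk.
#' @param depth_lambda mean per-SNP bulk read depth (Poisson).
#' @param seq_error sequencing error rate per read.
#' @param snp_spacing_bp spacing of diagnostic SNPs along each chromosome.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chromosomes = maize_chromosomes(),
                       qtl_model = peds_qtl_model("full"),
                       n_backcrosses = 3L,
                       n_f2 = 2000L,
                       n_bcf1 = 100L,
                       n_final = 6000L,
                       selection_threshold = 100,
                       n_bulk = 50L,
                       depth_lambda = 19,
                       seq_error = 0.001,
                       snp_spacing_bp = 1e5) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a random seed is mandatory in sim_config()", call. = FALSE)
  }
  stopifnot(
    all(chromosomes$length_cM > 0), all(chromosomes$length_bp > 0),
    qtl_model$sigma_e > 0,
    seq_error >= 0, seq_error < 0.5,
    depth_lambda > 0,
    n_bulk >= 1
  )
  loci <- qtl_model$loci
  if (nrow(loci)) {
    len <- chromosomes$length_cM[match(loci$chrom, chromosomes$chrom)]
    if (any(is.na(len)) || any(loci$pos_cM < 0) || any(loci$pos_cM > len)) {
      stop("QTL positions must lie on declared chromosomes", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      chromosomes = chromosomes,
      qtl_model = qtl_model,
      n_backcrosses = as.integer(n_backcrosses),
      n_f2 = as.integer(n_f2),
      n_bcf1 = as.integer(n_bcf1),
      n_final = as.integer(n_final),
      selection_threshold = selection_threshold,
      n_bulk = as.integer(n_bulk),
      depth_lambda = depth_lambda,
      seq_error = seq_error,
      snp_spacing_bp = snp_spacing_bp
    ),
    class = "sim_config"
  )
}

#' Diagnostic SNP positions for a configuration
#'
#' Evenly spaced parent-diagnostic SNPs (maize allele = REF, teosinte allele
#' = ALT) at `snp_spacing_bp` along each chromosome.
#'
#' @param config a `sim_config`.
#' @return data.frame with columns `chrom`, `pos` (bp, 1-based), `pos_cM`.
#' @export
diagnostic_snps <- function(config) {
  tab <- config$chromosomes
  out <- lapply(seq_len(nrow(tab)), function(i) {
    pos <- seq(config$snp_spacing_bp, tab$length_bp[i], by = config$snp_spacing_bp)
    data.frame(
      chrom = tab$chrom[i],
      pos = as.integer(pos),
      pos_cM = pos / tab$length_bp[i] * tab$length_cM[i]
    )
  })
  do.call(rbind, out)
}
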