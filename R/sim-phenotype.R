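# Censored polygenic model of the PEDS phenotype.
#
# PEDS (percentage of cupules bearing a single spikelet) in maize x teosinte
# segregants has a large point mass at 0 and a long right tail.  The
# simulator produces it through a latent liability
#   G = mu + sum_j (a_j x_j + d_j z_j) + sum_kl aa_kl x_k x_l + e,
# with x = +1/0/-1 for maize-homozygote / heterozygote / teosinte-homozygote,
# z = 1 for heterozygotes, e ~ N(0, sigma_e^2), and
#   PEDS = 100 * min(1, max(0, G))
# (a tobit-like doubly censored link).

# Latent genetic value from a teosinte-dosage matrix whose columns match
# rbind-ed model loci (main loci first, in model$loci order).
.latent_genetic <- function(dosage, model) {
  n <- nrow(dosage)
  x <- 1 - dosage # +1 maize-hom, 0 het, -1 teosinte-hom
  z <- (dosage == 1L) * 1
  g <- rep(model$mu, n)
  loci <- model$loci
  for (j in seq_len(nrow(loci))) {
    g <- g + loci$a[j] * x[, j] + loci$d[j] * z[, j]
  }
  epi <- model$epistasis
  if (nrow(epi)) {
    key <- paste(loci$chrom, loci$pos_cM)
    for (k in seq_len(nrow(epi))) {
      j1 <- match(paste(epi$chrom1[k], epi$pos1_cM[k]), key)
      j2 <- match(paste(epi$chrom2[k], epi$pos2_cM[k]), key)
      if (is.na(j1) || is.na(j2)) {
        stop("epistatic locus not present among model loci", call. = FALSE)
      }
      g <- g + epi$aa[k] * x[, j1] * x[, j2]
    }
  }
  g
}

#' Simulate the PEDS phenotype
#'
#' Computes the censored-liability PEDS phenotype for a simulated population
#' (or, for calibration work, directly from a teosinte-dosage matrix whose
#' columns follow `qtl_model$loci`).
#'
#' @param population a population of individuals, or an integer dosage matrix.
#' @param qtl_model model as from [peds_qtl_model()].
#' @return If given a population, the population with `peds` filled in;
#'   if given a dosage matrix, a numeric vector of PEDS percentages.
#' @export
simulate_peds_phenotype <- function(population, qtl_model) {
  loci <- data.frame(chrom = qtl_model$loci$chrom, pos_cM = qtl_model$loci$pos_cM)
  if (is.matrix(population)) {
    dosage <- population
  } else {
    dosage <- population_dosage(population, loci)
  }
  g <- .latent_genetic(dosage, qtl_model) +
    stats::rnorm(nrow(dosage), 0, qtl_model$sigma_e)
  peds <- 100 * pmin(1, pmax(0, g))
  if (is.matrix(population)) {
    return(peds)
  }
  for (i in seq_along(population)) population[[i]]$peds <- peds[i]
  population
}

#' Run the full recurrent-selection backcross scheme
#'
#' Simulates F1 -> F2, then `n_backcrosses` cycles of (select plants at the
#' PEDS selection threshold, backcross to the maize parent, self) ending in a
#' BCnF2 mapping population of `n_final` plants with phenotypes assigned.
#'
#' @param config a [sim_config()].
#' @return list with elements `population` (the final BCnF2), `generation`
#'   (label such as `"BC3F2"`), `config`, and `truth` (the planted QTL).
#' @export
simulate_scheme <- function(config) {
  set.seed(config$seed)
  lens <- config$chromosomes$length_cM
  maize <- founder_genome(lens, "maize")
  teosinte <- founder_genome(lens, "teosinte")
  f1 <- .zip_gametes(simulate_meiosis(maize), simulate_meiosis(teosinte))
  f1_pop <- new_population(list(f1), "F1")

  sel <- function(peds) peds >= config$selection_threshold
  # F2 from selfing the F1
  pop <- advance_generation(f1_pop, "self", NULL, config$n_f2,
                            generation = "F2")
  pop <- simulate_peds_phenotype(pop, config$qtl_model)
  for (b in seq_len(config$n_backcrosses)) {
    n_f2 <- if (b == config$n_backcrosses) config$n_final else config$n_f2
    bcf1 <- advance_generation(pop, "backcross_to_maize", sel, config$n_bcf1,
                               chrom_lengths = lens,
                               generation = sprintf("BC%dF1", b))
    pop <- advance_generation(bcf1, "self", NULL, n_f2,
                              generation = sprintf("BC%dF2", b))
    pop <- simulate_peds_phenotype(pop, config$qtl_model)
  }
  list(
    population = pop,
    generation = attr(pop, "generation"),
    config = config,
    truth = sim_truth(config)
  )
}

#' Planted-truth table for a configuration
#'
#' @param config a [sim_config()].
#' @return list of data.frames `qtl` (chrom, pos_cM, pos_bp, a, d) and
#'   `epistasis`, convertible to the truth file written by the pipeline.
#' @export
sim_truth <- function(config) {
  tab <- config$chromosomes
  loci <- config$qtl_model$loci
  bp <- function(chrom, cm) {
    i <- match(chrom, tab$chrom)
    round(cm / tab$length_cM[i] * tab$length_bp[i])
  }
  qtl <- data.frame(
    chrom = loci$chrom, pos_cM = loci$pos_cM,
    pos_bp = bp(loci$chrom, loci$pos_cM),
    a = loci$a, d = loci$d
  )
  list(qtl = qtl, epistasis = config$qtl_model$epistasis, seed = config$seed)
}
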