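# Forward simulation of maize x teosinte genomes.
#
# A homolog is a run-length tiling of one chromosome: `brk` holds the cM end
# position of each segment (strictly increasing, last element = chromosome
# length) and `fdr` the founder of origin of each segment (0 = maize,
# 1 = teosinte).  A genome is a list with one element per chromosome, each a
# list of the two homologs `h1`, `h2`.

.FOUNDER_MAIZE <- 0L
.FOUNDER_TEOSINTE <- 1L

new_homolog <- function(length_cM, founder) {
  list(brk = as.numeric(length_cM), fdr = as.integer(founder))
}

#' Create a fully homozygous founder genome
#'
#' @param chrom_lengths numeric vector of chromosome lengths in cM.
#' @param founder `"maize"` or `"teosinte"`.
#' @return A genome: list of chromosomes, each holding homologs `h1`, `h2`.
#' @export
founder_genome <- function(chrom_lengths, founder = c("maize", "teosinte")) {
  founder <- match.arg(founder)
  code <- if (founder == "maize") .FOUNDER_MAIZE else .FOUNDER_TEOSINTE
  lapply(chrom_lengths, function(L) {
    list(h1 = new_homolog(L, code), h2 = new_homolog(L, code))
  })
}

# Splice two homologs at sorted crossover positions, starting from homolog
# `first` (1 or 2).  Crossovers strictly inside (0, L).
.splice_homologs <- function(h1, h2, xo, first) {
  hs <- list(h1, h2)
  L <- h1$brk[length(h1$brk)]
  cuts <- c(xo, L)
  src <- rep_len(if (first == 1L) c(1L, 2L) else c(2L, 1L), length(cuts))
  brk <- numeric(0)
  fdr <- integer(0)
  lo <- 0
  for (i in seq_along(cuts)) {
    hi <- cuts[i]
    if (hi <= lo) next
    h <- hs[[src[i]]]
    j1 <- findInterval(lo, h$brk) + 1L
    j2 <- findInterval(hi, h$brk, left.open = TRUE) + 1L
    ends <- pmin(h$brk[j1:j2], hi)
    labs <- h$fdr[j1:j2]
    ok <- ends > lo
    brk <- c(brk, ends[ok])
    fdr <- c(fdr, labs[ok])
    lo <- hi
  }
  # merge adjacent segments with identical founder
  n <- length(fdr)
  if (n > 1L) {
    keep <- c(fdr[-n] != fdr[-1L], TRUE)
    brk <- brk[keep]
    fdr <- fdr[keep]
  }
  list(brk = brk, fdr = fdr)
}

# One meiosis on a single chromosome: Poisson crossovers (mean = cM/100,
# no interference), uniform positions, random starting homolog.  The
# compiled routine is the workhorse; .meiose_chrom_r is the plain-R
# reference used to cross-check it.
.meiose_chrom <- function(pair, L) {
  .meiose_chrom_cpp(pair$h1$brk, pair$h1$fdr, pair$h2$brk, pair$h2$fdr)
}

.meiose_chrom_r <- function(pair, L) {
  n_xo <- stats::rpois(1L, L / 100)
  if (n_xo == 0L) {
    return(if (stats::runif(1L) < 0.5) pair$h1 else pair$h2)
  }
  xo <- sort(stats::runif(n_xo, 0, L))
  .splice_homologs(pair$h1, pair$h2, xo, sample.int(2L, 1L))
}

#' Simulate one meiosis
#'
#' Produces a single gamete (one homolog per chromosome) from a parental
#' genome.  The crossover count on each chromosome is Poisson with mean equal
#' to the map length in Morgans (no interference, i.e. Haldane model);
#' crossover positions are uniform along the chromosome.
#'
#' @param parent a genome as returned by [founder_genome()] or by crossing.
#' @return A gamete: list of one homolog per chromosome.
#' @export
simulate_meiosis <- function(parent) {
  lapply(parent, function(pair) {
    L <- pair$h1$brk[length(pair$h1$brk)]
    if (L <= 0) stop("zero-length chromosome in parent genome", call. = FALSE)
    .meiose_chrom(pair, L)
  })
}

# Combine two gametes into a genome.
.zip_gametes <- function(g1, g2) {
  mapply(function(a, b) list(h1 = a, h2 = b), g1, g2, SIMPLIFY = FALSE)
}

.homolog_at <- function(h, pos) {
  h$fdr[findInterval(pos, h$brk, left.open = TRUE) + 1L]
}

#' Teosinte-allele dosage at arbitrary positions
#'
#' @param genome a genome.
#' @param chrom chromosome index (single integer).
#' @param pos_cM numeric vector of positions in cM.
#' @return Integer vector of teosinte-allele counts in `{0, 1, 2}`.
#' @export
genome_dosage <- function(genome, chrom, pos_cM) {
  pair <- genome[[chrom]]
  .dosage_chrom_cpp(pair$h1$brk, pair$h1$fdr, pair$h2$brk, pair$h2$fdr,
                    as.numeric(pos_cM))
}

#' Dosage matrix for a population
#'
#' Teosinte-allele dosages (individuals x loci) at loci given as a
#' data.frame with columns `chrom`, `pos_cM`.
#'
#' @param population list of individuals.
#' @param loci data.frame with columns `chrom` and `pos_cM`.
#' @return Integer matrix, one row per individual.
#' @export
population_dosage <- function(population, loci) {
  n <- length(population)
  out <- matrix(0L, nrow = n, ncol = nrow(loci))
  split_idx <- split(seq_len(nrow(loci)), loci$chrom)
  for (ch_name in names(split_idx)) {
    ch <- as.integer(ch_name)
    idx <- split_idx[[ch_name]]
    pos <- loci$pos_cM[idx]
    for (i in seq_len(n)) {
      out[i, idx] <- genome_dosage(population[[i]]$genome, ch, pos)
    }
  }
  out
}

# Validate a homolog tiling; used by tests and by the tiling audit.
.valid_homolog <- function(h, L, tol = 1e-9) {
  n <- length(h$brk)
  n >= 1L &&
    length(h$fdr) == n &&
    all(diff(h$brk) > 0) &&
    h$brk[1] > 0 &&
    abs(h$brk[n] - L) < tol &&
    all(h$fdr %in% c(.FOUNDER_MAIZE, .FOUNDER_TEOSINTE))
}

#' Check that a genome is a valid segment tiling
#'
#' Audits every homolog of every chromosome: segments must tile
#' `[0, length]` with strictly increasing breakpoints and binary founder
#' labels.
#'
#' @param genome a genome.
#' @param chrom_lengths chromosome lengths in cM.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_genome <- function(genome, chrom_lengths) {
  stopifnot(length(genome) == length(chrom_lengths))
  for (c in seq_along(genome)) {
    L <- chrom_lengths[c]
    if (!.valid_homolog(genome[[c]]$h1, L) || !.valid_homolog(genome[[c]]$h2, L)) {
      stop("invalid segment tiling on chromosome ", c, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Cross two parental genomes
#'
#' @param mother,father genomes.
#' @return Offspring genome (one gamete from each parent).
#' @export
cross_genomes <- function(mother, father) {
  .zip_gametes(simulate_meiosis(mother), simulate_meiosis(father))
}

#' Wrap genomes into a population
#'
#' A population is a list of individuals, each
#' `list(genome = <genome>, peds = <phenotype or NA>)`, with the generation
#' label kept as an attribute.
#'
#' @param genomes list of genomes.
#' @param generation generation label.
#' @return A population.
#' @export
new_population <- function(genomes, generation = "F2") {
  pop <- lapply(genomes, function(g) list(genome = g, peds = NA_real_))
  attr(pop, "generation") <- generation
  pop
}

#' Advance a population by one generation
#'
#' Selects parents by a phenotype rule, then produces offspring either by
#' selfing the selected plants or by backcrossing them to the recurrent maize
#' parent.  Selection that matches no plant is an error, never a silent
#' fallback.
#'
#' @param population list of individuals with `peds` phenotypes assigned.
#' @param scheme `"self"` or `"backcross_to_maize"`.
#' @param selection_rule predicate on the PEDS phenotype (a function), or
#'   `NULL` for no selection.
#' @param n_offspring number of offspring to produce.
#' @param chrom_lengths chromosome lengths in cM (needed to build the
#'   recurrent maize parent for backcrossing).
#' @param generation label recorded on the returned population.
#' @return A new population.
#' @export
advance_generation <- function(population, scheme = c("self", "backcross_to_maize"),
                               selection_rule = NULL, n_offspring,
                               chrom_lengths = NULL, generation = NA_character_) {
  scheme <- match.arg(scheme)
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  if (is.null(selection_rule)) {
    parents <- population
  } else {
    peds <- vapply(population, function(ind) ind$peds, numeric(1))
    keep <- which(selection_rule(peds))
    if (length(keep) == 0L) {
      stop("selection produced no parents (rule matched no plant)", call. = FALSE)
    }
    parents <- population[keep]
  }
  np <- length(parents)
  genomes <- vector("list", n_offspring)
  if (scheme == "self") {
    for (i in seq_len(n_offspring)) {
      p <- parents[[sample.int(np, 1L)]]$genome
      genomes[[i]] <- .zip_gametes(simulate_meiosis(p), simulate_meiosis(p))
    }
  } else {
    if (is.null(chrom_lengths)) {
      stop("chrom_lengths required for backcrossing", call. = FALSE)
    }
    maize <- founder_genome(chrom_lengths, "maize")
    for (i in seq_len(n_offspring)) {
      p <- parents[[sample.int(np, 1L)]]$genome
      genomes[[i]] <- .zip_gametes(simulate_meiosis(p), simulate_meiosis(maize))
    }
  }
  new_population(genomes, generation = generation)
}

#' Teosinte-origin fraction of a genome
#'
#' cM-weighted fraction of the genome of teosinte origin, over both
#' homologs; monitors recovery of the recurrent maize background through
#' the backcross cycles.
#'
#' @param genome a genome.
#' @return Fraction in [0, 1].
#' @export
teosinte_genome_fraction <- function(genome) {
  tot <- 0
  teo <- 0
  for (pair in genome) {
    for (h in pair[c("h1", "h2")]) {
      w <- diff(c(0, h$brk))
      tot <- tot + sum(w)
      teo <- teo + sum(w[h$fdr == .FOUNDER_TEOSINTE])
    }
  }
  teo / tot
}
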