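# Bulk construction and pooled allele-depth simulation.

#' Select plants for extreme-phenotype bulks
#'
#' Samples `n_bulk` plant ids per bulk, uniformly without replacement among
#' the plants whose PEDS satisfies each rule.  Rules are predicates on PEDS,
#' e.g. `function(p) p > 90` for the high bulk and `function(p) p == 0` for
#' the low bulk; inequalities are taken exactly as given (a plant at
#' PEDS = 90 is excluded by `p > 90`).
#'
#' @param population population with phenotypes assigned.
#' @param high_rule,low_rule predicates on the PEDS percentage.
#' @param n_bulk plants per bulk (default 50).
#' @return list with integer id vectors `high` and `low`.
#' @export
build_bulks <- function(population, high_rule, low_rule, n_bulk = 50L) {
  peds <- vapply(population, function(ind) ind$peds, numeric(1))
  pick <- function(rule, label) {
    elig <- which(rule(peds))
    if (length(elig) < n_bulk) {
      stop(sprintf(
        "bulk '%s': only %d eligible plants for a bulk of %d",
        label, length(elig), n_bulk
      ), call. = FALSE)
    }
    sort(sample(elig, n_bulk))
  }
  list(high = pick(high_rule, "high"), low = pick(low_rule, "low"))
}

#' Build overlapping high bulks
#'
#' Reproduces the overlapping-bulk design in which several high bulks share a
#' common core: `n_shared` plants drawn once are combined with `n_unique`
#' fresh plants per bulk, all without replacement from the eligible pool.
#'
#' @param population population with phenotypes assigned.
#' @param rule predicate on PEDS defining eligibility.
#' @param n_bulks number of overlapping bulks.
#' @param n_shared plants common to every bulk.
#' @param n_unique additional plants specific to each bulk.
#' @return list of id vectors, one per bulk, each of length
#'   `n_shared + n_unique`.
#' @export
build_overlapping_bulks <- function(population, rule, n_bulks = 3L,
                                    n_shared = 25L, n_unique = 25L) {
  peds <- vapply(population, function(ind) ind$peds, numeric(1))
  elig <- which(rule(peds))
  need <- n_shared + n_bulks * n_unique
  if (length(elig) < need) {
    stop(sprintf(
      "overlapping bulks need %d eligible plants, only %d available",
      need, length(elig)
    ), call. = FALSE)
  }
  drawn <- sample(elig, need)
  shared <- drawn[seq_len(n_shared)]
  rest <- drawn[-seq_len(n_shared)]
  lapply(seq_len(n_bulks), function(b) {
    sort(c(shared, rest[((b - 1) * n_unique + 1):(b * n_unique)]))
  })
}

#' Simulate pooled sequencing read counts for two bulks
#'
#' At every diagnostic SNP (maize allele = REF, teosinte allele = ALT) the
#' true teosinte-allele frequency in a bulk is p = (sum of dosages)/(2 n).
#' Total depth is Poisson(`depth_lambda`) and the alternate-read count is
#' Binomial(D, p(1-e) + (1-p)e) with sequencing error rate e.
#'
#' @param population simulated population.
#' @param high,low integer id vectors from [build_bulks()].
#' @param snps data.frame from [diagnostic_snps()].
#' @param depth_lambda mean read depth per bulk and SNP.
#' @param seq_error per-read error rate.
#' @return data.frame in allele-count form: `CHROM`, `POS`, `REF`, `ALT`,
#'   `HIGH_REF`, `HIGH_ALT`, `LOW_REF`, `LOW_ALT`.
#' @export
simulate_bulk_counts <- function(population, high, low, snps,
                                 depth_lambda = 19, seq_error = 0.001) {
  stopifnot(depth_lambda > 0, seq_error >= 0, seq_error < 0.5)
  freq_of <- function(ids) {
    dos <- population_dosage(population[ids],
                             data.frame(chrom = snps$chrom, pos_cM = snps$pos_cM))
    colSums(dos) / (2 * length(ids))
  }
  m <- nrow(snps)
  draw <- function(p) {
    depth <- stats::rpois(m, depth_lambda)
    pe <- p * (1 - seq_error) + (1 - p) * seq_error
    alt <- stats::rbinom(m, depth, pe)
    list(ref = depth - alt, alt = alt)
  }
  hi <- draw(freq_of(high))
  lo <- draw(freq_of(low))
  data.frame(
    CHROM = snps$chrom, POS = snps$pos,
    REF = "A", ALT = "T",
    HIGH_REF = hi$ref, HIGH_ALT = hi$alt,
    LOW_REF = lo$ref, LOW_ALT = lo$alt
  )
}
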