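# Shared fixture builders for the test suite.

# Minimal single-chromosome configuration for crossing-scheme tests.
one_chrom_table <- function(length_cM = 100, length_bp = 1e8) {
  data.frame(chrom = 1L, length_bp = length_bp, length_cM = length_cM)
}

# An F1 individual (maize x teosinte) on the given chromosome lengths.
make_f1 <- function(chrom_lengths) {
  cross_genomes(founder_genome(chrom_lengths, "maize"),
                founder_genome(chrom_lengths, "teosinte"))
}

# Population of plants carrying only a PEDS value (sufficient for bulk
# construction, which never touches the genomes).
peds_only_population <- function(peds) {
  lapply(peds, function(p) list(genome = NULL, peds = p))
}

# Random allele-count fixture across two chromosomes, sorted.
random_count_fixture <- function(n = 400, seed = 99) {
  withr::with_seed(seed, {
    df <- data.frame(
      CHROM = sample(1:2, n, replace = TRUE),
      POS = sample.int(5e6, n),
      REF = "A", ALT = "T"
    )
    depth_h <- rpois(n, 19)
    depth_l <- rpois(n, 19)
    alt_h <- rbinom(n, depth_h, 0.5)
    alt_l <- rbinom(n, depth_l, 0.5)
    df$HIGH_REF <- depth_h - alt_h
    df$HIGH_ALT <- alt_h
    df$LOW_REF <- depth_l - alt_l
    df$LOW_ALT <- alt_l
    df[order(df$CHROM, df$POS), ]
  })
}

# A threshold curve with fixed symmetric bands, for region-calling tests
# with a known answer.
fixed_threshold_curve <- function(b95 = 0.3, b99 = 0.4, depths = 4:32) {
  structure(
    data.frame(depth = depths, lo95 = -b95, hi95 = b95,
               lo99 = -b99, hi99 = b99),
    design = "F2", n_high = 50, n_low = 50, n_reps = NA_integer_,
    class = c("threshold_curve", "data.frame")
  )
}

# Window table with constant depth and given per-window delta values.
window_fixture <- function(delta, chrom = 1L, step = 1e4, window = 1e6,
                           depth = 19) {
  starts <- (seq_along(delta) - 1) * step
  data.frame(
    CHROM = chrom, start = starts, end = starts + window,
    n_snps = 10, high_index = NA_real_, low_index = NA_real_,
    delta = delta, high_depth = depth, low_depth = depth
  )
}

# F2 genotypes at two markers r apart (direct two-point simulation).
two_marker_genotypes <- function(r, n) {
  cm <- -50 * log(1 - 2 * r) # Haldane inverse
  map <- data.frame(marker = c("m1", "m2"), chrom = 1L,
                    pos_bp = c(1e6, 2e6), pos_cM = c(0, cm))
  sim_f2_genotypes(map, n)
}
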