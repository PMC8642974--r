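# SNP-index computation, depth filtering and sliding windows.

test_that("SNP-index is alt/(ref+alt) with the 4x/32x pass band inclusive", {
  cnt <- data.frame(
    CHROM = 1L, POS = c(100L, 200L, 300L, 400L, 500L, 600L),
    REF = "A", ALT = "T",
    HIGH_REF = c(10L, 3L, 0L, 2L, 16L, 20L),
    HIGH_ALT = c(10L, 0L, 20L, 2L, 16L, 13L),
    LOW_REF = c(10L, 10L, 20L, 2L, 16L, 10L),
    LOW_ALT = c(10L, 10L, 0L, 1L, 17L, 10L)
  )
  si <- compute_snp_index(cnt)
  expect_equal(si$high_index[1], 0.5)
  expect_equal(si$high_filter[2], "low_depth") # depth 3 < 4
  expect_true(is.na(si$high_index[2]))
  expect_equal(si$delta[3], 1 - 0) # all teosinte vs all maize
  expect_equal(si$high_filter[4], "pass") # depth 4 is retained
  expect_equal(si$low_filter[4], "low_depth") # depth 3
  expect_true(is.na(si$delta[4])) # delta needs both bulks passing
  expect_equal(si$high_filter[5], "pass") # depth 32 is retained
  expect_equal(si$high_filter[6], "high_depth") # depth 33 > 32
  ok <- !is.na(si$delta)
  expect_equal(si$delta[ok],
               si$high_index[ok] - si$low_index[ok])
})

test_that("negative counts and missing columns are input errors", {
  cnt <- data.frame(CHROM = 1L, POS = 1L, HIGH_REF = -1L, HIGH_ALT = 2L,
                    LOW_REF = 1L, LOW_ALT = 1L)
  expect_error(compute_snp_index(cnt), "negative")
  expect_error(compute_snp_index(data.frame(CHROM = 1, POS = 1)), "columns")
})

test_that("three SNPs in one window average exactly", {
  cnt <- data.frame(
    CHROM = 1L, POS = c(1000L, 2000L, 3000L), REF = "A", ALT = "T",
    HIGH_REF = c(16L, 12L, 8L), HIGH_ALT = c(4L, 8L, 12L),
    LOW_REF = 20L, LOW_ALT = 0L
  )
  si <- compute_snp_index(cnt) # deltas 0.2, 0.4, 0.6
  win <- sliding_windows(si, window_bp = 1e6, step_bp = 1e4)
  expect_equal(win$delta[1], 0.4)
})

test_that("a SNP at the exact window end is excluded (half-open)", {
  cnt <- data.frame(
    CHROM = 1L, POS = c(500L, 1000L), REF = "A", ALT = "T",
    HIGH_REF = c(10L, 10L), HIGH_ALT = c(10L, 10L),
    LOW_REF = 10L, LOW_ALT = 10L
  )
  si <- compute_snp_index(cnt)
  win <- sliding_windows(si, window_bp = 1000, step_bp = 500, min_snps = 1)
  # window [0, 1000) holds only the SNP at 500
  expect_equal(win$n_snps[win$start == 0], 1)
  # window [500, 1500) holds both
  expect_equal(win$n_snps[win$start == 500], 2)
})

test_that("window means equal a brute-force oracle on a random fixture", {
  cnt <- random_count_fixture(n = 400, seed = 99)
  si <- compute_snp_index(cnt)
  window_bp <- 1e6
  step_bp <- 1e5
  win <- sliding_windows(si, window_bp, step_bp, min_snps = 3)
  for (k in sample(nrow(win), 50)) {
    inside <- si$CHROM == win$CHROM[k] &
      si$POS >= win$start[k] & si$POS < win$end[k] & !is.na(si$delta)
    if (sum(inside) >= 3) {
      expect_equal(win$delta[k], mean(si$delta[inside]))
      expect_equal(win$high_index[k], mean(si$high_index[inside]))
      expect_equal(win$n_snps[k], sum(inside))
    } else {
      expect_true(is.na(win$delta[k]))
    }
  }
})

test_that("windowing is translation-consistent by one full step", {
  cnt <- random_count_fixture(n = 200, seed = 100)
  step_bp <- 1e5
  si <- compute_snp_index(cnt)
  si2 <- si
  si2$POS <- si2$POS + step_bp
  w1 <- sliding_windows(si, 1e6, step_bp, min_snps = 1)
  w2 <- sliding_windows(si2, 1e6, step_bp, min_snps = 1)
  for (chr in 1:2) {
    a <- w1$delta[w1$CHROM == chr]
    b <- w2$delta[w2$CHROM == chr]
    expect_equal(b[-1][seq_along(a)], a)
  }
})

test_that("unsorted input is rejected, not silently sorted", {
  cnt <- random_count_fixture(n = 50)
  si <- compute_snp_index(cnt)
  expect_error(sliding_windows(si[rev(seq_len(nrow(si))), ]), "sorted")
})

test_that("identical bulk frequencies give mean delta near zero", {
  set.seed(101)
  n <- 10000
  depth_h <- rpois(n, 19)
  depth_l <- rpois(n, 19)
  cnt <- data.frame(
    CHROM = 1L, POS = sort(sample.int(1e8, n)), REF = "A", ALT = "T",
    HIGH_ALT = rbinom(n, depth_h, 0.5), LOW_ALT = rbinom(n, depth_l, 0.5)
  )
  cnt$HIGH_REF <- depth_h - cnt$HIGH_ALT
  cnt$LOW_REF <- depth_l - cnt$LOW_ALT
  si <- compute_snp_index(cnt)
  d <- si$delta[!is.na(si$delta)]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  expect_true(all(si$high_index >= 0 & si$high_index <= 1, na.rm = TRUE))
  expect_true(all(abs(d) <= 1))
})
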