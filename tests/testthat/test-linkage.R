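# Segregation screen, recombination estimation, Kosambi map function and
# local map construction.

test_that("segregation chi-square matches hand-computed values", {
  r <- segregation_chi2(c(9, 18, 9))
  expect_equal(r$chisq, 0)
  expect_equal(r$p_value, 1)
  r2 <- segregation_chi2(c(30, 40, 30))
  expect_equal(r2$chisq, 4.0) # (25/25 + 100/50 + 25/25)
  expect_equal(r2$p_value, pchisq(4, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(r2$p_value - 0.1353), 1e-3)
  r3 <- segregation_chi2(c(100, 0, 0))
  expect_lt(r3$p_value, 1e-20)
  expect_error(segregation_chi2(c(0, 0, 0)), "no scored genotypes")
})

test_that("Kosambi map function matches its closed form and round-trips", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi_cm(0.1), 10.1366, tolerance = 1e-4)
  expect_equal(kosambi_r(0), 0)
  for (r in c(0.05, 0.1, 0.25, 0.4, 0.49)) {
    expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-10)
  }
  expect_error(kosambi_cm(0.5), "infinite")
  expect_error(kosambi_r(-1), "non-negative")
})

test_that("Kosambi distance never exceeds Haldane distance", {
  haldane_cm <- function(r) -50 * log(1 - 2 * r)
  r <- seq(0.01, 0.45, by = 0.01)
  expect_true(all(kosambi_cm(r) < haldane_cm(r)))
})

test_that("identical markers estimate r = 0 with high LOD", {
  set.seed(80)
  g <- two_marker_genotypes(0.2, 200)
  est <- estimate_recfrac(g[, 1], g[, 1])
  expect_lt(est$r_hat, 1e-3)
  expect_gt(est$lod, 10)
})

test_that("independent markers estimate r = 0.5 with LOD near 0", {
  set.seed(81)
  map <- data.frame(marker = c("m1", "m2"), chrom = c(1L, 2L),
                    pos_bp = c(1e6, 1e6), pos_cM = c(0, 0))
  g <- sim_f2_genotypes(map, 1000)
  est <- estimate_recfrac(g[, 1], g[, 2])
  expect_lt(abs(est$r_hat - 0.5), 0.03)
  expect_lt(est$lod, 2)
})

test_that("recombination estimates recover the simulated truth", {
  set.seed(82)
  r_hats <- replicate(100, {
    g <- two_marker_genotypes(0.1, 500)
    estimate_recfrac(g[, 1], g[, 2])$r_hat
  })
  expect_lt(abs(mean(r_hats) - 0.10), 0.01)
})

test_that("two-point estimation handles missing codes and errors when
           nothing is complete", {
  set.seed(83)
  g <- two_marker_genotypes(0.1, 100)
  g1 <- g[, 1]
  g1[1:30] <- "-"
  est <- estimate_recfrac(g1, g[, 2])
  expect_equal(est$n, 70)
  expect_error(estimate_recfrac(rep("-", 50), g[, 2][1:50]), "pairwise")
  expect_warning(estimate_recfrac(g1[16:45], g[, 2][16:45]), "pairwise")
})

test_that("the estimator is consistent with Kosambi-generated two-point
           data", {
  # generate with the Kosambi r for 10 cM, estimate, convert back
  set.seed(84)
  r_true <- kosambi_r(10)
  spans <- replicate(60, {
    g <- two_marker_genotypes(r_true, 500)
    kosambi_cm(estimate_recfrac(g[, 1], g[, 2])$r_hat)
  })
  expect_equal(mean(spans), 10, tolerance = 0.6)
})

test_that("a local map spans roughly its simulated genetic length", {
  set.seed(85)
  g <- two_marker_genotypes(0.0906, 500) # Haldane r for 10 cM
  info <- data.frame(marker = c("m1", "m2"), chrom = 1L,
                     pos_bp = c(1e6, 2e6))
  map <- build_local_map(g, info)
  expect_gte(max(map$pos_cM), 7)
  expect_lte(max(map$pos_cM), 13)
  expect_equal(map$pos_cM[1], 0)
})

test_that("duplicate marker columns sit at distance 0", {
  set.seed(86)
  g <- two_marker_genotypes(0.2, 300)
  gg <- cbind(g[, 1], g[, 1])
  info <- data.frame(marker = c("d1", "d2"), chrom = 1L, pos_bp = c(1e6, 1.1e6))
  map <- build_local_map(gg, info)
  expect_lt(max(abs(diff(map$pos_cM))), 0.01)
})

test_that("distorted markers are screened out, others unchanged", {
  set.seed(87)
  map_in <- data.frame(marker = c("m1", "m2", "m3"), chrom = 1L,
                       pos_bp = c(1e6, 2e6, 3e6), pos_cM = c(0, 10, 20))
  g <- sim_f2_genotypes(map_in, 400)
  g[, 2] <- "A" # fully distorted 1:0:0
  map <- build_local_map(g, map_in[, c("marker", "chrom", "pos_bp")])
  expect_false("m2" %in% map$marker)
  expect_setequal(map$marker, c("m1", "m3"))
  expect_true("m2" %in% attr(map, "dropped"))
})

test_that("map construction is invariant under relabelling individuals", {
  set.seed(88)
  map_in <- data.frame(marker = c("m1", "m2", "m3"), chrom = 1L,
                       pos_bp = c(1e6, 2e6, 3e6), pos_cM = c(0, 12, 30))
  g <- sim_f2_genotypes(map_in, 300)
  m1 <- build_local_map(g, map_in[, c("marker", "chrom", "pos_bp")])
  m2 <- build_local_map(g[sample(nrow(g)), ],
                        map_in[, c("marker", "chrom", "pos_bp")])
  expect_equal(m1$pos_cM, m2$pos_cM)
})

test_that("map length estimates sharpen as the population grows", {
  set.seed(89)
  err_at <- function(n) {
    mean(abs(replicate(25, {
      g <- two_marker_genotypes(kosambi_r(20), n)
      kosambi_cm(estimate_recfrac(g[, 1], g[, 2])$r_hat) - 20
    })))
  }
  expect_lt(err_at(2000), err_at(200))
})
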