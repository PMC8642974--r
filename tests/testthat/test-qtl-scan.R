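# Interval-scan machinery: transformation, conditional QTL probabilities,
# stepwise background selection, ICIM-ADD and ICIM-EPI.

test_that("cube-root transform matches closed forms and validates input", {
  expect_equal(cube_root_transform(0), 0)
  expect_equal(cube_root_transform(100), 4.6416, tolerance = 1e-4)
  expect_equal(cube_root_transform(12.5), 2.3208, tolerance = 1e-4)
  expect_error(cube_root_transform(101), "\\[0, 100\\]")
  expect_error(cube_root_transform(-1), "\\[0, 100\\]")
})

test_that("QTL probabilities collapse to the flank at a typed marker", {
  p <- qtl_genotype_probs(c("A", "H", "B"), c("H", "H", "H"),
                          r_left = 0, r_right = 0.1)
  expect_equal(unname(p[1, ]), c(1, 0, 0))
  expect_equal(unname(p[2, "Qq"]), 1)
  expect_equal(unname(p[3, ]), c(0, 0, 1))
})

test_that("QTL probabilities with missing flanks fall back to the F2 prior", {
  p <- qtl_genotype_probs("-", "-", 0.1, 0.1)
  expect_equal(unname(p[1, ]), c(0.25, 0.5, 0.25))
})

test_that("midpoint probabilities sum to one with Qq modal for H/H flanks", {
  p <- qtl_genotype_probs("H", "H", .1, .1)
  expect_equal(sum(p), 1)
  expect_gt(p[1, "Qq"], p[1, "QQ"])
  expect_gt(p[1, "Qq"], p[1, "qq"])
  expect_equal(unname(p[1, "QQ"]), unname(p[1, "qq"])) # F2 symmetry
})

test_that("conditional probabilities match empirical frequencies from the
           gamete-level simulator", {
  set.seed(90)
  map3 <- data.frame(marker = c("L", "Q", "R"), chrom = 1L,
                     pos_bp = c(1e6, 2e6, 3e6), pos_cM = c(0, 8, 20))
  g <- sim_f2_genotypes(map3, 200000)
  r1 <- (1 - exp(-2 * 8 / 100)) / 2
  r2 <- (1 - exp(-2 * 12 / 100)) / 2
  pr <- qtl_genotype_probs(g[, "L"], g[, "R"], r1, r2)
  for (gl in c("A", "H", "B")) {
    for (gr in c("A", "H", "B")) {
      sel <- g[, "L"] == gl & g[, "R"] == gr
      emp <- prop.table(table(factor(g[sel, "Q"], c("A", "H", "B"))))
      theo <- pr[which(sel)[1], ]
      # absolute tolerance scaled to the binomial noise of the class size
      tol <- pmax(0.01, 4 * sqrt(theo * (1 - theo) / sum(sel)))
      expect_true(all(abs(as.numeric(emp) - theo) < tol))
    }
  }
})

test_that("invalid recombination fractions are rejected", {
  expect_error(qtl_genotype_probs("A", "A", 0.5, 0.1), "\\[0, 0.5\\)")
  expect_error(qtl_genotype_probs("A", "A", 0.1, -0.01), "\\[0, 0.5\\)")
})

test_that("stepwise selection finds a single causal marker", {
  set.seed(91)
  map <- local_marker_map()
  g <- sim_f2_genotypes(map, 300)
  x <- (g[, "PM3.3"] == "A") - (g[, "PM3.3"] == "B")
  y <- -0.3 * x + rnorm(300, 0, 0.01)
  sel <- stepwise_marker_selection(y, g, map[, c("marker", "chrom", "pos_bp")])
  expect_equal(sel$selected, "PM3.3")
})

test_that("among duplicated marker columns exactly one is selected", {
  set.seed(92)
  map <- data.frame(marker = c("a", "b", "c"), chrom = c(1L, 1L, 2L),
                    pos_bp = c(1e6, 2e6, 1e6), pos_cM = c(0, 5, 0))
  g <- sim_f2_genotypes(map, 300)
  g[, "b"] <- g[, "a"] # exact duplicate
  x <- (g[, "a"] == "A") - (g[, "a"] == "B")
  y <- 0.5 * x + rnorm(300, 0, 0.05)
  sel <- stepwise_marker_selection(y, g, map[, c("marker", "chrom", "pos_bp")])
  expect_equal(sum(c("a", "b") %in% sel$selected), 1)
  expect_true("a" %in% sel$selected) # tie broken by position
})

test_that("null stepwise selection rate is consistent with p_in", {
  set.seed(93)
  map <- data.frame(marker = sprintf("m%02d", 1:20),
                    chrom = rep(1:4, each = 5),
                    pos_bp = rep(seq(1e6, 5e6, 1e6), 4),
                    pos_cM = rep(seq(0, 80, 20), 4))
  hits <- replicate(200, {
    g <- sim_f2_genotypes(map, 150)
    y <- rnorm(150)
    length(stepwise_marker_selection(
      y, g, map[, c("marker", "chrom", "pos_bp")]
    )$selected) > 0
  })
  # family-wise entry probability is roughly 1 - (1 - p_in)^20 = 0.18
  p_fam <- 1 - (1 - 0.01)^20
  expect_lt(abs(mean(hits) - p_fam), 3 * sqrt(p_fam * (1 - p_fam) / 200) + 0.02)
})

test_that("sample size must exceed the candidate covariate count", {
  map <- local_marker_map()
  g <- sim_f2_genotypes(map, 40)
  expect_error(
    stepwise_marker_selection(rnorm(40), g, map[, c("marker", "chrom", "pos_bp")]),
    "too small"
  )
})

test_that("scan at a typed marker equals the direct regression oracle", {
  set.seed(94)
  map <- data.frame(marker = c("m1", "m2", "m3"), chrom = 1L,
                    pos_bp = c(1e6, 2e6, 3e6), pos_cM = c(0, 10, 20))
  g <- sim_f2_genotypes(map, 300)
  x2 <- (g[, "m2"] == "A") - (g[, "m2"] == "B")
  z2 <- (g[, "m2"] == "H") * 1
  y <- -0.2 * x2 - 0.1 * z2 + rnorm(300, 0, 0.3)
  # p_in = 0 forces an empty background so the scan is pure Haley-Knott
  res <- icim_add_scan(y, map, g, map[, c("marker", "chrom", "pos_bp")],
                       step_cM = 10, p_in = 0)
  at_m2 <- res$profile[res$profile$pos_cM == 10, ]
  fit1 <- lm(y ~ x2 + z2)
  fit0 <- lm(y ~ 1)
  lod_direct <- (300 / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
  expect_equal(at_m2$lod, lod_direct, tolerance = 1e-8)
  expect_equal(at_m2$add, unname(coef(fit1)["x2"]), tolerance = 1e-8)
  expect_equal(at_m2$dom, unname(coef(fit1)["z2"]), tolerance = 1e-8)
})

test_that("LOD profile is invariant under affine transformation of y", {
  set.seed(95)
  map <- local_marker_map()[1:8, ] # chromosome 1 only
  g <- sim_f2_genotypes(map, 200)
  x <- (g[, 3] == "A") - (g[, 3] == "B")
  y <- 0.4 * x + rnorm(200, 0, 0.4)
  info <- map[, c("marker", "chrom", "pos_bp")]
  r1 <- icim_add_scan(y, map, g, info, step_cM = 5)
  r2 <- icim_add_scan(3 * y + 7, map, g, info, step_cM = 5)
  expect_equal(r1$profile$lod, r2$profile$lod, tolerance = 1e-8)
  expect_equal(r1$profile$pve, r2$profile$pve, tolerance = 1e-8)
})

test_that("genome scans without a QTL rarely reach LOD 3", {
  set.seed(96)
  map <- local_marker_map()
  info <- map[, c("marker", "chrom", "pos_bp")]
  max_lods <- replicate(100, {
    g <- sim_f2_genotypes(map, 300)
    y <- rnorm(300)
    max(icim_add_scan(y, map, g, info, step_cM = 2)$profile$lod)
  })
  expect_gte(mean(max_lods < 3), 0.90)
})

test_that("epistasis scan is symmetric in the two loci", {
  set.seed(97)
  map <- local_marker_map()[local_marker_map()$chrom %in% c(1, 6), ]
  g <- sim_f2_genotypes(map, 400)
  x1 <- (g[, "PM1.3"] == "A") - (g[, "PM1.3"] == "B")
  x2 <- (g[, "PM6.2"] == "A") - (g[, "PM6.2"] == "B")
  y <- 0.25 * x1 * x2 + rnorm(400, 0, 0.2)
  info <- map[, c("marker", "chrom", "pos_bp")]
  res <- icim_epi_scan(y, map, g, info, lod_threshold = 3)
  # re-run with chromosome blocks supplied in the opposite order
  map_r <- map[rev(seq_len(nrow(map))), ]
  res_r <- icim_epi_scan(y, map_r, g[, rev(seq_len(nrow(map)))],
                         info[rev(seq_len(nrow(info))), ], lod_threshold = 3)
  expect_equal(res$lod[1], res_r$lod[1], tolerance = 1e-8)
  expect_equal(res$aa[1], res_r$aa[1], tolerance = 1e-8)
  expect_gt(res$aa[1], 0)
})

test_that("pure-noise epistasis false pairs match the chi-square null
           calibration", {
  set.seed(98)
  map <- local_marker_map()
  info <- map[, c("marker", "chrom", "pos_bp")]
  n_found <- replicate(60, {
    g <- sim_f2_genotypes(map, 300)
    nrow(icim_epi_scan(rnorm(300), map, g, info))
  })
  # a pair clears LOD 5 when its 4-df interaction block exceeds
  # 2 ln(10) * 5 on the chi-square scale: p ~ 1.2e-4 per pair, ~780 pairs
  per_pair <- pchisq(2 * log(10) * 5, df = 4, lower.tail = FALSE)
  expected <- 780 * per_pair * 60
  expect_lte(sum(n_found), qpois(0.999, expected))
  expect_gte(mean(n_found == 0), 0.85)
})
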