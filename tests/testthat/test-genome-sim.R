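# Meiosis, crossing and the recurrent-selection scheme.

test_that("meiosis on a homozygous parent returns a pure gamete", {
  set.seed(1)
  maize <- founder_genome(c(100, 80), "maize")
  for (i in 1:20) {
    gam <- simulate_meiosis(maize)
    for (h in gam) expect_true(all(h$fdr == 0L))
  }
})

test_that("zero-length chromosomes are rejected", {
  g <- founder_genome(c(100, 0), "maize")
  expect_error(simulate_meiosis(g), "zero-length")
})

test_that("crossover count is Poisson with mean = map length in Morgans", {
  set.seed(42)
  f1 <- make_f1(100)
  # on an F1 every crossover switches founder, so segments - 1 = crossovers
  n_seg <- replicate(10000, length(simulate_meiosis(f1)[[1]]$fdr))
  expect_equal(mean(n_seg - 1), 1.0, tolerance = 0.05)
})

test_that("recombinant fraction matches the Haldane expectation", {
  set.seed(43)
  f1 <- make_f1(100)
  pos <- c(45, 55) # 10 cM apart
  rec <- replicate(10000, {
    h <- simulate_meiosis(f1)[[1]]
    al <- h$fdr[findInterval(pos, h$brk, left.open = TRUE) + 1L]
    al[1] != al[2]
  })
  r_expected <- (1 - exp(-0.2)) / 2 # 0.0906
  expect_lt(abs(mean(rec) - r_expected), 0.01)
})

test_that("compiled and plain-R meiosis agree in distribution", {
  set.seed(44)
  f1 <- make_f1(100)
  pos <- c(20, 80)
  rec_cpp <- replicate(4000, {
    h <- simulate_meiosis(f1)[[1]]
    al <- h$fdr[findInterval(pos, h$brk, left.open = TRUE) + 1L]
    al[1] != al[2]
  })
  rec_r <- replicate(4000, {
    h <- pedsqtl:::.meiose_chrom_r(f1[[1]], 100)
    al <- h$fdr[findInterval(pos, h$brk, left.open = TRUE) + 1L]
    al[1] != al[2]
  })
  # both must match the closed-form Haldane fraction for 60 cM
  r_expected <- (1 - exp(-1.2)) / 2
  expect_lt(abs(mean(rec_cpp) - r_expected), 0.025)
  expect_lt(abs(mean(rec_r) - r_expected), 0.025)
})

test_that("segment tilings stay valid through many generations", {
  set.seed(45)
  lens <- c(60, 40)
  pop <- new_population(list(make_f1(lens)), "F1")
  for (gen in 1:5) {
    pop <- advance_generation(pop, "self", NULL, 30)
    for (ind in pop) validate_genome(ind$genome, lens)
  }
  succeed()
})

test_that("selfing a homozygous maize population breeds true", {
  set.seed(46)
  pop <- new_population(list(founder_genome(100, "maize")))
  off <- advance_generation(pop, "self", NULL, 50)
  d <- population_dosage(off, data.frame(chrom = 1, pos_cM = c(10, 50, 90)))
  expect_true(all(d == 0L))
})

test_that("F2 genotypes at a neutral locus segregate 1:2:1", {
  set.seed(47)
  pop <- new_population(list(make_f1(100)), "F1")
  f2 <- advance_generation(pop, "self", NULL, 5000)
  d <- population_dosage(f2, data.frame(chrom = 1, pos_cM = 50))
  cnt <- tabulate(d + 1L, 3L)
  p <- segregation_chi2(cnt)$p_value
  expect_gt(p, 0.001)
})

test_that("backcross offspring dosage is Mendelian {0,1} at 1:1", {
  set.seed(48)
  f1 <- make_f1(100)
  pop <- new_population(list(f1), "F1")
  pop <- lapply(pop, function(ind) { ind$peds <- 100; ind })
  bc <- advance_generation(pop, "backcross_to_maize",
                           selection_rule = function(p) p == 100,
                           n_offspring = 10000, chrom_lengths = 100)
  d <- population_dosage(bc, data.frame(chrom = 1, pos_cM = 50))
  expect_true(all(d %in% 0:1))
  expect_equal(mean(d), 0.5, tolerance = 0.02)
})

test_that("selection matching no plant raises an explicit error", {
  pop <- new_population(list(founder_genome(100, "maize")))
  pop <- lapply(pop, function(ind) { ind$peds <- 0; ind })
  expect_error(
    advance_generation(pop, "self", function(p) p == 100, 10),
    "selection produced no parents"
  )
})

test_that("recurrent selection keeps the QTL region segregating while the
           background drifts to maize", {
  cfg <- sim_config(
    seed = 901, n_f2 = 500, n_bcf1 = 30, n_final = 600,
    qtl_model = peds_qtl_model("major_only")
  )
  sim <- simulate_scheme(cfg)
  qtl <- cfg$qtl_model$loci
  d_qtl <- population_dosage(sim$population,
                             data.frame(chrom = qtl$chrom, pos_cM = qtl$pos_cM))
  # the selected locus still segregates near 1:2:1
  expect_gt(mean(d_qtl == 1L), 0.3)
  expect_gt(mean(d_qtl == 2L), 0.1)
  # unlinked chromosomes are rich in maize alleles: teosinte fraction on
  # chromosome 5 far below the unselected expectation of 1/16
  d_bg <- population_dosage(sim$population,
                            data.frame(chrom = 5, pos_cM = 60))
  expect_lt(mean(d_bg) / 2, 1 / 16)
})
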