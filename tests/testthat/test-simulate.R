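test_that("gametes from a zero-length chromosome are never recombinant", {
  map <- two_marker_map(0)
  haps <- f1_haps(map)
  set.seed(1)
  g <- simulate_gametes(haps, map, 500)
  expect_true(all(g[, 1] == g[, 2]))  # always one intact parental haplotype
})

test_that("recombinant fraction matches the no-interference closed form", {
  map <- two_marker_map(10)
  haps <- f1_haps(map)
  set.seed(42)
  n <- 100000
  g <- simulate_gametes(haps, map, n)
  rf <- mean(g[, 1] != g[, 2])
  expected <- (1 - exp(-0.2)) / 2        # 0.09063
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rf - expected), 3 * se)
})

test_that("pairwise recombinant fractions increase with cM separation", {
  map <- genetic_map("1", paste0("m", 1:5), c(0, 5, 15, 40, 80),
                     c(1, 2, 3, 4, 5) * 1e6)
  set.seed(7)
  g <- simulate_gametes(f1_haps(map), map, 10000)
  rf <- vapply(2:5, function(j) mean(g[, 1] != g[, j]), numeric(1))
  expect_true(all(diff(rf) > 0))
})

test_that("RIL heterozygosity decays as (1/2)^generations", {
  map <- small_map(1, 11, 50)
  g1 <- derive_ril_population(300, map, n_selfing = 1, seed = 3)
  expect_equal(mean(g1 == "H"), 0.5, tolerance = 0.05)
  g8 <- derive_ril_population(500, map, n_selfing = 8, seed = 4)
  expect_equal(mean(g8 == "H"), (1 / 2)^8, tolerance = 0.004)
  # no selection: allele A frequency ~ 1/2
  expect_lt(abs(mean(g8 == "A") - 0.5), 0.05)
})

test_that("progeny segregation follows Mendelian expectations", {
  map <- two_marker_map(0)
  # homozygous parent: progeny fixed under selfing
  prog <- derive_progeny(c("A", "A"), "self", 50, map, seed = 1)
  expect_true(all(prog == "A"))
  # backcross to B from a heterozygous parent never yields A
  progbc <- derive_progeny(c("H", "H"), "backcross_to_B", 400, map, seed = 2)
  expect_false(any(progbc == "A"))
  expect_equal(mean(progbc == "H"), 0.5, tolerance = 0.06)
  # selfing a heterozygote: 1:2:1 not rejected at alpha = 0.01 in
  # nearly all replicates
  set.seed(11)
  not_rejected <- vapply(1:30, function(i) {
    pr <- derive_progeny(c("H", "H"), "self", 4000, map)
    counts <- table(factor(pr[, 1], levels = c("A", "H", "B")))
    stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value > 0.01
  }, logical(1))
  expect_gte(sum(not_rejected), 28)
})

test_that("phenotype generator realises the additive/dominance model exactly", {
  map <- small_map(1, 5, 20)
  geno <- rbind(A1 = rep("A", 5), H1 = rep("H", 5), B1 = rep("B", 5))
  colnames(geno) <- map$marker
  des <- trial_design("T1", 1, c(45, 50),
                      data.frame(dap = c(45, 50), gwc = c(38, 32)))
  # null model: phenotype equals the baseline exactly
  t0 <- truth_model(qtl_chrom = "1", qtl_cM = 10, a = 0, d = 0,
                    sigma2_G = 0, sigma2_GxE = 0, sigma2_e = 0)
  ph0 <- simulate_phenotypes(geno, map, t0, list(des), seed = 1)
  expect_equal(ph0$gwc, ifelse(ph0$dap == 45, 38, 32))
  # semi-dominant QTL, no noise: homozygote gap is 2a at every DAP
  t1 <- truth_model(qtl_chrom = "1", qtl_cM = 10, a = 1.655, d = 0.075,
                    sigma2_G = 0, sigma2_GxE = 0, sigma2_e = 0)
  ph1 <- simulate_phenotypes(geno, map, t1, list(des), seed = 1)
  for (dd in c(45, 50)) {
    sub <- ph1[ph1$dap == dd, ]
    gap <- sub$gwc[sub$line == "A1"] - sub$gwc[sub$line == "B1"]
    expect_equal(gap, 3.31)
    mid <- (sub$gwc[sub$line == "A1"] + sub$gwc[sub$line == "B1"]) / 2
    expect_equal(sub$gwc[sub$line == "H1"] - mid, 0.075)
  }
})

test_that("emitted weights reproduce the simulated GWC through the formula", {
  map <- small_map(1, 5, 20)
  geno <- derive_ril_population(30, map, seed = 5)
  ph <- simulate_phenotypes(geno, map, truth_model(), default_trial_designs(),
                            seed = 6)
  expect_true(all(ph$fresh_g > ph$dry_g & ph$dry_g > 0))
  expect_true(all(ph$gwc > 0 & ph$gwc < 100))
  expect_lt(max(abs(compute_gwc(ph$fresh_g, ph$dry_g) - ph$gwc)), 1e-9)
})

test_that("identical seed and configuration reproduce identical tables", {
  map <- small_map(1, 8, 40)
  g1 <- derive_ril_population(25, map, seed = 99)
  g2 <- derive_ril_population(25, map, seed = 99)
  expect_identical(g1, g2)
  p1 <- simulate_phenotypes(g1, map, truth_model(), default_trial_designs(),
                            seed = 100)
  p2 <- simulate_phenotypes(g2, map, truth_model(), default_trial_designs(),
                            seed = 100)
  expect_identical(p1, p2)
})

test_that("genotype CSV round trips including missing calls", {
  map <- small_map(1, 6, 30)
  g <- derive_ril_population(10, map, seed = 2)
  g[1, 2] <- NA
  path <- tempfile(fileext = ".csv")
  write_genotypes_csv(g, path)
  expect_identical(read_genotypes_csv(path), g)
})
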