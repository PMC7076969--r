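scan_fixture <- function(n = 200, seed = 31, a = 2, sigma2_e = 1,
                         qtl_chrom = "2", qtl_cM = 40) {
  map <- synthetic_map(3, 26, 100)   # 3 chromosomes, 4 cM spacing
  geno <- derive_ril_population(n, map, seed = seed)
  truth <- truth_model(qtl_chrom = qtl_chrom, qtl_cM = qtl_cM, a = a, d = 0,
                       sigma2_G = 0, sigma2_GxE = 0, sigma2_e = sigma2_e)
  des <- trial_design("T1", 1, 45, data.frame(dap = c(45, 50), gwc = c(35, 30)))
  ph <- simulate_phenotypes(geno, map, truth, list(des), seed = seed + 1)
  y <- ph$gwc[match(rownames(geno), ph$line)]
  list(map = map, geno = geno, y = y)
}

test_that("conditional genotype probabilities behave at markers and gaps", {
  map <- genetic_map("1", paste0("m", 1:3), c(0, 5, 10), c(1, 2, 3) * 1e6)
  geno <- rbind(i1 = c("A", NA, "A"), i2 = c("A", "B", NA),
                i3 = c(NA, NA, NA))
  colnames(geno) <- map$marker
  gp <- genotype_probabilities(geno, map, step_cM = 5, population_type = "RIL")
  # typed marker: probability 1 on the observed class
  at_m2 <- which(gp$positions$cM == 5)
  expect_equal(gp$prob[2, at_m2, ], c(0, 1))
  # midpoint of a 10 cM bracket with both flanks A: P(A) > 0.99
  at_mid <- which(gp$positions$cM == 5)
  expect_gt(gp$prob[1, at_mid, 1], 0.99)
  # all flanks missing: prior frequencies
  expect_equal(gp$prob[3, at_mid, ], c(0.5, 0.5))
  # probabilities always sum to one
  expect_equal(apply(gp$prob, c(1, 2), sum),
               matrix(1, 3, nrow(gp$positions)), tolerance = 1e-12)
})

test_that("a phenotype equal to the genotype score gives R2 = 100 at that marker", {
  map <- small_map(1, 11, 50)
  geno <- derive_ril_population(60, map, seed = 12)
  gp <- genotype_probabilities(geno, map, step_cM = 5)
  mk_pos <- which(gp$positions$marker == map$marker[6])
  y <- gp$score[, mk_pos]
  sc <- interval_mapping_scan(gp, y)
  expect_equal(sc$r2[mk_pos], 100, tolerance = 1e-6)
  expect_equal(which.max(sc$lod), mk_pos)
})

test_that("interval mapping matches the closed-form single-marker regression", {
  fx <- scan_fixture(n = 120, seed = 41)
  fx$geno[fx$geno == "H"] <- "A"   # complete two-class data for the oracle
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 50)
  sc <- interval_mapping_scan(gp, fx$y)
  mk <- "S2_11"
  pos <- which(gp$positions$marker == mk)
  x <- ifelse(fx$geno[, mk] == "A", 1, -1)
  n <- length(fx$y)
  rss0 <- sum((fx$y - mean(fx$y))^2)
  fit <- stats::lm(fx$y ~ x)
  rss1 <- sum(stats::residuals(fit)^2)
  lod_oracle <- (n / 2) * log10(rss0 / rss1)
  expect_lt(abs(sc$lod[pos] - lod_oracle), 1e-8)
  expect_equal(sc$ae[pos], unname(stats::coef(fit)[2]), tolerance = 1e-8)
})

test_that("LOD is affine-invariant and label swap flips only the AE sign", {
  fx <- scan_fixture(n = 100, seed = 51)
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 10)
  sc1 <- interval_mapping_scan(gp, fx$y)
  sc2 <- interval_mapping_scan(gp, 3.2 * fx$y - 40)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-9)
  expect_equal(sc1$r2, sc2$r2, tolerance = 1e-9)
  swapped <- fx$geno
  swapped[fx$geno == "A"] <- "B"; swapped[fx$geno == "B"] <- "A"
  gp_sw <- genotype_probabilities(swapped, fx$map, step_cM = 10)
  sc3 <- interval_mapping_scan(gp_sw, fx$y)
  expect_equal(sc3$lod, sc1$lod, tolerance = 1e-9)
  expect_equal(sc3$ae, -sc1$ae, tolerance = 1e-9)
})

test_that("CIM with zero cofactors reduces to interval mapping", {
  fx <- scan_fixture(n = 100, seed = 61)
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 10)
  im <- interval_mapping_scan(gp, fx$y)
  cim0 <- cim_scan(gp, fx$y, n_cofactors = 0)
  expect_lt(max(abs(im$lod - cim0$lod)), 1e-9)
  expect_error(cim_scan(gp, fx$y, n_cofactors = 50), "n/5")
})

test_that("a cofactor inside the exclusion window is dropped at the test position", {
  fx <- scan_fixture(n = 100, seed = 71)
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 10)
  im <- interval_mapping_scan(gp, fx$y)
  cof <- which(gp$positions$marker == "S2_11")
  cim <- cim_scan(gp, fx$y, n_cofactors = 1, window_cM = 10, cofactors = cof)
  # at the cofactor's own position the model omits it: plain IM LOD
  expect_equal(cim$lod[cof], im$lod[cof], tolerance = 1e-9)
  # far away the cofactor absorbs QTL variance and lowers the LOD
  far <- which(gp$positions$chrom == "2" & gp$positions$cM == 90)
  expect_lt(cim$lod[far], im$lod[far])
})

test_that("permutation threshold is deterministic and alpha = 1 gives the minimum", {
  fx <- scan_fixture(n = 80, seed = 81)
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 20)
  t1 <- permutation_threshold(gp, fx$y, n_perm = 120, seed = 5)
  t2 <- permutation_threshold(gp, fx$y, n_perm = 120, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  tmin <- permutation_threshold(gp, fx$y, n_perm = 120, alpha = 1, seed = 5)
  expect_equal(as.numeric(tmin), min(attr(tmin, "maxima")))
  expect_error(permutation_threshold(gp, fx$y, n_perm = 50), ">= 100")
})

test_that("QTL calling segments peaks, snaps flanks and flags major QTL", {
  map <- small_map(1, 11, 100)
  scan <- data.frame(chrom = "1", cM = seq(0, 100, by = 10),
                     marker = map$marker,
                     lod = c(0, 1, 5, 1, 0, 0, 4, 4.5, 1, 0, 0),
                     ae = 1, r2 = c(0, 1, 16, 1, 0, 0, 8, 9, 1, 0, 0))
  calls <- call_qtl(scan, threshold = 2.5, map, trait = "Gwc")
  expect_equal(nrow(calls), 2)   # two peaks split by a sub-threshold valley
  expect_equal(calls$name, c("qGwc1.1", "qGwc1.2"))
  expect_true(calls$major[1])
  expect_false(calls$major[2])
  # support interval flanks bracket the 1.5-LOD drop
  expect_equal(calls$left_marker[1], map$marker[2])
  expect_equal(calls$right_marker[1], map$marker[4])
  # nothing above threshold: empty call set
  scan$lod <- 0.5
  expect_equal(nrow(call_qtl(scan, 2.5, map)), 0)
})

test_that("a strong simulated QTL is recovered near its true position", {
  fx <- scan_fixture(n = 200, seed = 91, a = 2, sigma2_e = 1)
  gp <- genotype_probabilities(fx$geno, fx$map, step_cM = 2)
  sc <- interval_mapping_scan(gp, fx$y)
  pk <- sc[which.max(sc$lod), ]
  expect_equal(pk$chrom, "2")
  expect_lt(abs(pk$cM - 40), 10)
  expect_lt(abs(pk$ae - 2) / 2, 0.25)
  expect_gt(pk$r2, 10)
})

test_that("CIM separates two linked QTL at least as often as plain IM", {
  map <- synthetic_map(1, 26, 100)
  des <- trial_design("T1", 1, 45, data.frame(dap = c(45, 50), gwc = c(35, 30)))
  detected_both <- function(scan) {
    near <- function(cm) {
      idx <- which(abs(scan$cM - cm) <= 10)
      any(scan$lod[idx] > 2.5) && scan$cM[which.max(scan$lod)] > 0
    }
    sub30 <- scan[abs(scan$cM - 30) <= 10, ]
    sub70 <- scan[abs(scan$cM - 70) <= 10, ]
    valley <- scan[scan$cM > 42 & scan$cM < 58, ]
    max(sub30$lod) > 2.5 && max(sub70$lod) > 2.5 &&
      min(valley$lod) < min(max(sub30$lod), max(sub70$lod))
  }
  set.seed(123)
  res <- vapply(1:8, function(i) {
    geno <- derive_ril_population(300, map)
    x1 <- ifelse(geno[, which.min(abs(map$cM - 30))] == "A", 1, -1)
    x2 <- ifelse(geno[, which.min(abs(map$cM - 70))] == "A", 1, -1)
    y <- 30 + 1.2 * x1 + 1.2 * x2 + rnorm(300, 0, 2)
    gp <- genotype_probabilities(geno, map, step_cM = 2)
    c(im = detected_both(interval_mapping_scan(gp, y)),
      cim = detected_both(cim_scan(gp, y, n_cofactors = 4, window_cM = 10)))
  }, logical(2))
  expect_gte(sum(res["cim", ]), sum(res["im", ]))
})
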