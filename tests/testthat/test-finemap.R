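mini_map <- function(mb = c(10, 20, 30, 40, 50)) {
  genetic_map("1", paste0("m", seq_along(mb)), (mb - min(mb)) / 1.4,
              mb * 1e6)
}

test_that("breakpoints fall between adjacent differing non-missing markers", {
  map <- mini_map()
  expect_equal(nrow(detect_breakpoints(rep("A", 5), map)), 0)
  bp <- detect_breakpoints(c("A", "A", "H", "H", "B"), map)
  expect_equal(bp$left_marker, c("m2", "m4"))
  expect_equal(bp$right_marker, c("m3", "m5"))
  # missing call: breakpoint localized to the bracketing non-missing pair
  bp2 <- detect_breakpoints(c("A", NA, "B"), mini_map(c(10, 20, 30)))
  expect_equal(nrow(bp2), 1)
  expect_equal(c(bp2$left_marker, bp2$right_marker), c("m1", "m3"))
  expect_error(detect_breakpoints(c("A", NA, NA), mini_map(c(10, 20, 30))),
               "non-missing")
})

test_that("recombination types group identical patterns and order by breakpoint", {
  ex <- finemap_example_round1()
  ty <- classify_recombination_types(ex$genotypes, ex$map)
  expect_equal(nrow(ty), 10)           # 11 plants, 10 distinct types
  expect_equal(sort(ty$n_R, decreasing = TRUE)[1], 2)
  expect_equal(sum(ty$n_R), 11)
  # all vectors identical -> a single type
  same <- matrix("H", 4, 5, dimnames = list(NULL, paste0("m", 1:5)))
  same[, 4:5] <- "B"
  expect_equal(nrow(classify_recombination_types(same, mini_map())), 1)
  # non-contiguous heterozygous segment is rejected with a diagnostic
  weird <- matrix(c("H", "A", "H", "B", "B"), 1, 5,
                  dimnames = list(NULL, paste0("m", 1:5)))
  tw <- classify_recombination_types(weird, mini_map())
  expect_false(tw$valid[1])
  expect_match(tw$reason[1], "contiguous")
})

test_that("missing-call patterns merge only into a uniquely compatible type", {
  map <- mini_map(c(10, 20, 30))
  # oracle by enumeration on 3-marker cases: a pattern with one NA joins
  # a complete pattern iff exactly one group matches its typed calls
  complete <- rbind(c("A", "H", "H"), c("A", "A", "H"))
  probe_unique <- c("A", NA, "H")      # matches both -> stays separate
  g1 <- rbind(complete, probe_unique)
  colnames(g1) <- map$marker
  expect_equal(nrow(classify_recombination_types(g1, map)), 3)
  probe_match <- c(NA, "H", "H")       # matches only the first
  g2 <- rbind(complete, probe_match)
  colnames(g2) <- map$marker
  ty2 <- classify_recombination_types(g2, map)
  expect_equal(nrow(ty2), 2)
  expect_equal(sort(ty2$n_R), c(1, 2))
})

test_that("progeny test verdicts follow the P <= 0.05 rule", {
  set.seed(13)
  codes <- rep(c("A", "H", "B"), times = c(25, 50, 25))
  # identical class distributions: NS
  same <- progeny_test(codes, rep(c(5, 6), 50), "self")
  expect_equal(same$verdict, "NS")
  # a compared class absent: undeterminable
  miss <- progeny_test(rep(c("H", "B"), 20), rnorm(40), "self")
  expect_true(is.na(miss$verdict))
  # clear separation at the observed effect scale: S essentially always
  hits <- vapply(1:30, function(i) {
    g <- rep(c("A", "H", "B"), times = c(90, 180, 90))
    y <- rnorm(360, mean = c(A = 36.5, H = 34.92, B = 33.19)[g], sd = 2)
    progeny_test(g, y, "self")$verdict == "S"
  }, logical(1))
  expect_equal(sum(hits), 30)
  # zero-variance guard
  exact <- progeny_test(rep(c("A", "B"), each = 5), rep(c(1, 2), each = 5),
                        "self")
  expect_equal(exact$p, 0)
  expect_equal(exact$verdict, "S")
})

test_that("narrowing the published round-1 verdicts delimits SSR-75.1/SSR-80.1", {
  ex <- finemap_example_round1()
  ty <- classify_recombination_types(ex$genotypes, ex$map)
  ty$verdict <- unname(ex$verdicts[ty$pattern])
  inf <- narrow_interval(ty, range(ex$map$bp), ex$map)
  expect_true(inf$narrowed)
  expect_true(inf$consistent)
  expect_equal(inf$left_marker, "SSR-75.1")
  expect_equal(inf$right_marker, "SSR-80.1")
  expect_equal(inf$length_mb, 5.0)
})

test_that("narrow_interval degenerate and boundary behaviour", {
  map <- mini_map()
  full <- range(map$bp)
  # one S type heterozygous over the whole interval: unchanged bounds
  ty <- data.frame(type = "I", het_lo_bp = map$bp[1], het_hi_bp = map$bp[5],
                   pos_lo_bp = map$bp[1], pos_hi_bp = map$bp[5],
                   valid = TRUE, verdict = "S", stringsAsFactors = FALSE)
  inf <- narrow_interval(ty, full, map)
  expect_equal(c(inf$lo_bp, inf$hi_bp), full)
  # no S type: interval returned unchanged with a warning
  ty$verdict <- "NS"
  expect_warning(inf2 <- narrow_interval(ty, full, map), "cannot be narrowed")
  expect_false(inf2$narrowed)
  expect_equal(c(inf2$lo_bp, inf2$hi_bp), full)
})

test_that("narrow_interval agrees with the brute-force bin oracle", {
  set.seed(99)
  mismatches <- 0L
  for (i in 1:200) {
    mb <- sort(sample(10:99, 8))
    map <- genetic_map("1", paste0("m", 1:8), (mb - mb[1]) / 1.4, mb * 1e6)
    ty <- random_types(map, sample(2:6, 1))
    interval <- range(map$bp)
    inf <- suppressWarnings(
      narrow_interval(ty, interval, map, resolve_conflicts = FALSE))
    impl <- pieces_to_units(inf$candidate, interval, map)
    orac <- oracle_narrow_units(ty, interval, map)
    if (!isTRUE(all.equal(impl, orac))) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("narrowing is monotone in added constraints and order-invariant", {
  set.seed(7)
  map <- mini_map(c(5, 15, 25, 35, 45, 55, 65, 75))
  for (i in 1:50) {
    ty <- random_types(map, 4)
    interval <- range(map$bp)
    width <- function(t) {
      inf <- suppressWarnings(narrow_interval(t, interval, map,
                                              resolve_conflicts = FALSE))
      sum(pmax(inf$candidate$hi - inf$candidate$lo, 0))
    }
    # adding one more constraint never widens the candidate
    extra <- random_types(map, 1)
    expect_lte(width(rbind(ty, extra)), width(ty) + 1e-9)
    # permutation of the types leaves the result unchanged
    inf_a <- suppressWarnings(narrow_interval(ty, interval, map))
    inf_b <- suppressWarnings(narrow_interval(ty[sample(nrow(ty)), ],
                                              interval, map))
    expect_equal(c(inf_a$lo_bp, inf_a$hi_bp), c(inf_b$lo_bp, inf_b$hi_bp))
  }
})

test_that("genetic effect estimates match the published per-generation means", {
  gens <- list(bc1f3 = c(A = 36.50, B = 33.19, H = 34.92),
               bc1f4 = c(A = 29.39, B = 26.08, H = 27.97),
               bc1f5 = c(A = 28.30, B = 26.81, H = 27.53),
               bc1f6 = c(A = 27.97, B = 25.44, H = 27.06))
  deltas <- c(3.31, 3.31, 1.49, 2.53)
  for (k in seq_along(gens)) {
    cs <- data.frame(class = names(gens[[k]]), mean = unname(gens[[k]]))
    ge <- estimate_genetic_effect(cs)
    expect_equal(ge$delta, deltas[k], tolerance = 1e-9)
    expect_true(ge$intermediate)
  }
  # heterozygote exactly at the midpoint: pure additivity
  mid <- estimate_genetic_effect(
    data.frame(class = c("A", "H", "B"), mean = c(30, 28.5, 27)))
  expect_equal(mid$d, 0)
  expect_equal(mid$action, "additive")
  # missing heterozygote class
  homo <- estimate_genetic_effect(
    data.frame(class = c("A", "B"), mean = c(30, 27)))
  expect_true(is.na(homo$d))
  expect_equal(homo$delta, 3)
})

test_that("label swap flips the additive effect sign but not the magnitude", {
  cs <- data.frame(class = c("A", "H", "B"), mean = c(36.5, 34.92, 33.19))
  sw <- data.frame(class = c("B", "H", "A"), mean = c(36.5, 34.92, 33.19))
  g1 <- estimate_genetic_effect(cs)
  g2 <- estimate_genetic_effect(sw)
  expect_equal(g2$a, -g1$a)
  expect_equal(g2$delta, g1$delta)
  expect_equal(g2$intermediate, g1$intermediate)
})

test_that("new recombinants require a breakpoint strictly inside the interval", {
  map <- mini_map(c(10, 20, 30, 40, 50))
  interval <- c(20e6, 40e6)
  g <- rbind(hom = rep("A", 5),
             inside = c("A", "A", "H", "H", "H"),   # breakpoint m2-m3
             boundary = c("A", "H", "H", "H", "H"), # breakpoint m1-m2, at the edge
             outside = c("H", "H", "H", "H", "B"))  # breakpoint m4-m5
  colnames(g) <- map$marker
  sel <- select_new_recombinants(g, map, interval)
  expect_equal(sel, "inside")
})

test_that("expected recombinant yield in a 5 cM window matches theory", {
  # selfing a plant heterozygous over ~5 cM: each progeny carries two
  # meioses, so P(breakpoint in window) ~ 1 - 0.95^2 ~ 0.0975
  mb <- seq(10, 24, by = 1.4)  # 1 cM spacing
  map <- genetic_map("1", paste0("m", seq_along(mb)), (mb - mb[1]) / 1.4,
                     mb * 1e6)
  het_lo <- 4L; het_hi <- 9L   # ~5 cM heterozygous segment
  codes <- rep("A", nrow(map)); codes[het_lo:het_hi] <- "H"
  prog <- derive_progeny(codes, "self", 800, map, seed = 17)
  sel <- select_new_recombinants(prog, map,
                                 c(map$bp[het_lo], map$bp[het_hi]))
  expected <- 800 * (1 - exp(-0.05)^2)
  se <- sqrt(800 * 0.0975 * (1 - 0.0975))
  expect_lt(abs(length(sel) - expected), 3 * se)
})

test_that("noise-free sequential fine-mapping lands on the truth bin", {
  fm <- suppressWarnings(run_sequential_finemap(
    sd_gwc = 1e-9, seed = 4, n_recombinants = 24,
    family_size = 150))
  expect_true(fm$contains_truth)
  rm <- finemap_region_map()
  bin <- c(max(rm$bp[rm$bp <= fm$qtl_bp]), min(rm$bp[rm$bp >= fm$qtl_bp]))
  expect_equal(fm$interval, bin)
})

test_that("a zero-effect QTL leaves the interval unchanged and flagged", {
  fm <- suppressWarnings(run_sequential_finemap(a = 0, d = 0, seed = 1))
  rm <- finemap_region_map()
  expect_equal(fm$interval, range(rm$bp))
  expect_true(all(!vapply(fm$trace, function(tr) tr$inference$narrowed,
                          logical(1))))
})

test_that("the fine-mapping table mirrors the per-type test summaries", {
  fm <- suppressWarnings(run_sequential_finemap(seed = 5, rounds = 2))
  tab <- finemap_table(fm)
  expect_true(all(c("round", "type", "n_R", "n_P", "marker", "mean_A",
                    "mean_H", "mean_B", "p", "verdict") %in% names(tab)))
  tested <- tab[!is.na(tab$verdict), ]
  expect_gt(nrow(tested), 0)
  expect_true(all(tested$verdict %in% c("S", "NS")))
  expect_true(all(tested$p[tested$verdict == "S"] <= 0.05))
  expect_true(all(tested$p[tested$verdict == "NS"] > 0.05))
})
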