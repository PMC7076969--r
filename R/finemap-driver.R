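# Round-by-round driver: simulate recombinant-derived progenies over a
# fine-mapping region with a hidden QTL, run the progeny tests, narrow
# the interval, and select new recombinants for the next round.

# insert a hidden QTL pseudo-marker into a region map
.augment_with_qtl <- function(map, qtl_bp) {
  if (qtl_bp < min(map$bp) || qtl_bp > max(map$bp))
    stop("QTL position outside the region map")
  qtl_cm <- stats::approx(map$bp, map$cM, xout = qtl_bp, ties = "ordered")$y
  genetic_map(chrom = c(map$chrom, map$chrom[1L]),
              marker = c(map$marker, "__QTL__"),
              cM = c(map$cM, qtl_cm), bp = c(map$bp, qtl_bp))
}

#' Sequential fine-mapping on a simulated region
#'
#' Runs the recombinant-derived progeny-test procedure end to end on a
#' simulated fine-mapping region with a known (hidden) QTL: starting
#' from plants heterozygous across the whole region, recombinants are
#' screened, classified into recombination types, each type's
#' representative is selfed (or backcrossed) to produce a progeny
#' family, the family is genotyped at one marker inside the parental
#' heterozygous segment and phenotyped for GWC at physiological
#' maturity, the segregation verdicts narrow the interval, and new
#' recombinants within the narrowed interval seed the next round.
#' The engine sees only marker genotypes and phenotypes; the QTL
#' position enters solely through phenotype simulation.
#'
#' @param region_map `genetic_map` of the target region (default
#'   [finemap_region_map()])
#' @param qtl_bp true QTL physical position (bp) within the region
#' @param a,d additive and dominance effects (GWC points)
#' @param sd_gwc residual phenotype sd within a family (GWC points)
#' @param baseline_gwc family mean GWC at sampling
#' @param rounds number of fine-mapping rounds
#' @param n_recombinants recombinants retained per round (recycled)
#' @param family_size progeny per recombinant family (recycled
#'   per round; later rounds use larger families, as advanced-generation
#'   progenies do)
#' @param scheme `"self"` or `"backcross"` progeny scheme
#' @param alpha verdict threshold passed to [progeny_test()]
#' @param seed optional integer seed
#' @return list of class `finemap_run`: per-round `trace` (each with
#'   the typed table, verdicts and the interval inference), the final
#'   `interval` (bp), flanking markers, `length_mb`, `contains_truth`,
#'   and `rounds_run`
#' @export
run_sequential_finemap <- function(region_map = finemap_region_map(),
                                   qtl_bp = 76.6e6, a = 1.655, d = 0.075,
                                   sd_gwc = 2.5, baseline_gwc = 30,
                                   rounds = 4,
                                   n_recombinants = c(11, 9, 18, 11),
                                   family_size = c(80, 80, 150, 200),
                                   scheme = c("self", "backcross"),
                                   alpha = 0.05, retest_p = 0.005,
                                   seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  validate_map(region_map)
  n_recombinants <- rep_len(n_recombinants, rounds)
  family_size <- rep_len(family_size, rounds)
  amap <- .augment_with_qtl(region_map, qtl_bp)
  obs <- which(amap$marker != "__QTL__")
  qcol <- which(amap$marker == "__QTL__")
  interval <- c(min(region_map$bp), max(region_map$bp))
  het_parent <- rbind(rep(1L, nrow(amap)), rep(2L, nrow(amap)))

  pheno_for <- function(qtl_codes, n) {
    x <- c(A = 1, H = 0, B = -1)[qtl_codes]
    z <- as.numeric(qtl_codes == "H")
    baseline_gwc + x * a + z * d + stats::rnorm(n, 0, sd_gwc)
  }
  # a usable recombinant carries a valid, partial heterozygous segment
  # (for the progeny test) and a breakpoint strictly inside the
  # current interval; genotypes are read over the full region panel
  pick_usable <- function(codes) {
    ids <- rownames(codes)
    sel <- vapply(seq_len(nrow(codes)), function(i) {
      v <- codes[i, ]
      if (sum(!is.na(v)) < 2L) return(FALSE)
      run <- .het_run(v)
      if (!run$ok || !any(!is.na(v) & v != "H")) return(FALSE)
      bp <- detect_breakpoints(v, region_map)
      any(bp$left_bp >= interval[1L] & bp$right_bp <= interval[2L])
    }, logical(1))
    ids[sel]
  }
  screen_recombinants <- function(n_target) {
    # BC1F2-style screening: self plants heterozygous across the region
    found <- list()
    for (batch in seq_len(60L)) {
      prog <- derive_progeny(het_parent, "self", 200L, amap,
                             keep_haplotypes = TRUE)
      haps <- attr(prog, "haplotypes")
      codes <- prog[, region_map$marker, drop = FALSE]
      sel <- pick_usable(codes)
      for (id in sel) found[[length(found) + 1L]] <- haps[[match(id, rownames(prog))]]
      if (length(found) >= n_target) break
    }
    found[seq_len(min(length(found), n_target))]
  }

  recombinants <- screen_recombinants(n_recombinants[1L])
  trace <- list()
  hist_types <- NULL  # verdicts accumulate across rounds
  contains <- NA
  for (rd in seq_len(rounds)) {
    if (length(recombinants) == 0L) break
    codes <- do.call(rbind, lapply(recombinants, function(h)
      .codes_from_haps(h)[match(region_map$marker, amap$marker)]))
    rownames(codes) <- sprintf("RG%d-%02d", rd, seq_len(nrow(codes)))
    colnames(codes) <- region_map$marker
    types <- classify_recombination_types(codes, region_map)
    types$verdict <- NA_character_
    types$p <- NA_real_
    types$n_P <- NA_integer_
    types$test_marker <- NA_character_
    members <- attr(types, "members")
    fam_haps <- list()
    fam_stats <- vector("list", nrow(types))
    for (ti in seq_len(nrow(types))) {
      if (!types$valid[ti]) next
      rep_id <- members[[ti]][1L]
      parent <- recombinants[[match(rep_id, rownames(codes))]]
      fs <- family_size[rd]
      prog <- derive_progeny(parent,
                             if (scheme == "self") "self" else "backcross_to_B",
                             fs, amap, keep_haplotypes = TRUE)
      fam_haps <- c(fam_haps, attr(prog, "haplotypes"))
      # test marker: heterozygous-run marker nearest the segment midpoint
      run_mk <- region_map$marker[region_map$bp >= types$het_lo_bp[ti] &
                                    region_map$bp <= types$het_hi_bp[ti]]
      mid <- (types$het_lo_bp[ti] + types$het_hi_bp[ti]) / 2
      tm <- run_mk[which.min(abs(region_map$bp[match(run_mk, region_map$marker)] - mid))]
      gwc <- pheno_for(prog[, qcol], fs)
      pt <- progeny_test(prog[, tm], gwc,
                         scheme = if (scheme == "self") "self" else "backcross",
                         alpha = alpha)
      n_p <- fs
      if (!is.na(pt$verdict) && pt$verdict == "S" && pt$p > retest_p) {
        # marginal segregation: confirm with an independent progeny
        # family before letting the verdict constrain the interval
        prog2 <- derive_progeny(parent,
                                if (scheme == "self") "self" else "backcross_to_B",
                                fs, amap, keep_haplotypes = TRUE)
        fam_haps <- c(fam_haps, attr(prog2, "haplotypes"))
        gwc2 <- pheno_for(prog2[, qcol], fs)
        pt2 <- progeny_test(prog2[, tm], gwc2,
                            scheme = if (scheme == "self") "self" else "backcross",
                            alpha = alpha)
        if (!is.na(pt2$verdict)) {
          pt$verdict <- pt2$verdict
          pt$p <- max(pt$p, pt2$p)
          n_p <- 2L * fs
        }
      }
      types$verdict[ti] <- pt$verdict
      types$p[ti] <- pt$p
      types$n_P[ti] <- n_p
      types$test_marker[ti] <- tm
      fam_stats[[ti]] <- pt$class_stats
    }
    # comparison of all recombination types observed so far: verdicts
    # accumulate across rounds, so later evidence can overturn a
    # borderline verdict from an earlier round via conflict resolution
    round_types <- types
    round_types$type <- paste0(rd, "-", round_types$type)
    hist_types <- if (is.null(hist_types)) round_types
                  else rbind(hist_types, round_types)
    inference <- narrow_interval(hist_types,
                                 c(min(region_map$bp), max(region_map$bp)),
                                 region_map)
    trace[[rd]] <- list(round = rd, interval_in = interval,
                        types = types, class_stats = fam_stats,
                        inference = inference)
    if (inference$narrowed)
      interval <- c(inference$lo_bp, inference$hi_bp)
    contains <- qtl_bp >= interval[1L] && qtl_bp <= interval[2L]
    if (rd == rounds) break
    nmap <- region_map[region_map$bp >= interval[1L] &
                         region_map$bp <= interval[2L], ]
    if (nrow(nmap) < 2L) break
    sel <- character(0)
    if (length(fam_haps) > 0L) {
      pool <- do.call(rbind, lapply(fam_haps, function(h)
        .codes_from_haps(h)[match(region_map$marker, amap$marker)]))
      rownames(pool) <- sprintf("P%d-%04d", rd, seq_len(nrow(pool)))
      colnames(pool) <- region_map$marker
      sel <- pick_usable(pool)
      if (length(sel) > n_recombinants[rd + 1L])
        sel <- sample(sel, n_recombinants[rd + 1L])
      recombinants <- fam_haps[match(sel, rownames(pool))]
      # control plant: heterozygous across the whole current interval,
      # its progeny test confirms (or challenges) the narrowed region
      ctrl <- which(vapply(seq_len(nrow(pool)), function(i) {
        v <- pool[i, ]
        run <- .het_run(v)
        run$ok && any(!is.na(v) & v != "H") &&
          region_map$bp[run$first] <= interval[1L] &&
          region_map$bp[run$last] >= interval[2L]
      }, logical(1)))
      if (length(ctrl)) {
        span <- vapply(ctrl, function(i) {
          run <- .het_run(pool[i, ])
          region_map$bp[run$last] - region_map$bp[run$first]
        }, numeric(1))
        best <- ctrl[which.min(span)]
        if (!rownames(pool)[best] %in% sel)
          recombinants <- c(recombinants, fam_haps[best])
      }
    }
    if (length(sel) == 0L)
      recombinants <- screen_recombinants(n_recombinants[rd + 1L])
  }
  fin <- if (length(trace)) trace[[length(trace)]]$inference else NULL
  structure(list(trace = trace,
                 interval = interval,
                 left_marker = if (!is.null(fin)) fin$left_marker else NA,
                 right_marker = if (!is.null(fin)) fin$right_marker else NA,
                 length_mb = (interval[2L] - interval[1L]) / 1e6,
                 contains_truth = contains,
                 qtl_bp = qtl_bp,
                 rounds_run = length(trace)),
            class = "finemap_run")
}

#' Publication-style fine-mapping table
#'
#' Flattens a [run_sequential_finemap()] trace into one row per tested
#' recombination type: round, type label, numbers of recombinants and
#' progeny, the test marker, the per-genotype class means, the P value
#' and the S/NS verdict.
#'
#' @param run a `finemap_run`
#' @return data.frame
#' @export
finemap_table <- function(run) {
  rows <- list()
  for (tr in run$trace) {
    ty <- tr$types
    for (i in seq_len(nrow(ty))) {
      cs <- tr$class_stats[[i]]
      g <- function(cl) if (is.null(cs)) NA_real_ else cs$mean[cs$class == cl]
      rows[[length(rows) + 1L]] <- data.frame(
        round = tr$round, type = ty$type[i], n_R = ty$n_R[i],
        n_P = ty$n_P[i], marker = ty$test_marker[i],
        mean_A = g("A"), mean_H = g("H"), mean_B = g("B"),
        p = ty$p[i], verdict = ty$verdict[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
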