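# Genotype codes: "A" = homozygous for the low-GWC parent ("844") allele,
# "B" = homozygous for the high-GWC parent ("807") allele, "H" =
# heterozygous, NA = missing.  Haplotypes are integer vectors over the
# map's markers with allele 1 (parent A) or 2 (parent B).

GENO_CODES <- c("A", "B", "H")

#' Phase a genotype vector into two haplotypes
#'
#' Minimal-recombination phasing used for recombinant plants whose
#' genotype is a mosaic of homozygous and heterozygous runs: one
#' haplotype carries the parent-A allele wherever the plant is "A" or
#' "H", the other carries it only where the plant is "A".
#'
#' @param codes character vector of genotype codes ("A"/"B"/"H"), no missing
#' @return integer matrix with two rows (haplotypes) and one column per marker
#' @export
phase_genotype <- function(codes) {
  if (anyNA(codes)) stop("cannot phase a genotype with missing calls")
  if (!all(codes %in% GENO_CODES)) stop("invalid genotype codes")
  h1 <- ifelse(codes == "B", 2L, 1L)
  h2 <- ifelse(codes == "A", 1L, 2L)
  rbind(h1, h2, deparse.level = 0)
}

# collapse two haplotypes to genotype codes
.codes_from_haps <- function(h) {
  s <- h[1L, ] + h[2L, ]
  c("A", "H", "B")[s - 1L]
}

#' Simulate gametes from a phased parent
#'
#' Meiosis under a no-interference crossover model: on each chromosome
#' the number of crossovers is Poisson with mean L/100 (L = genetic
#' length in cM) and crossover positions are uniform on the cM scale,
#' so the recombinant fraction between two loci d cM apart is
#' (1 - exp(-d/50))/2.
#'
#' @param haps integer 2 x m matrix of parental haplotypes (alleles 1/2)
#' @param map `genetic_map` with m markers (same order as `haps` columns)
#' @param n number of gametes to draw
#' @return integer n x m matrix of gamete alleles
#' @export
simulate_gametes <- function(haps, map, n = 1) {
  validate_map(map)
  if (ncol(haps) != nrow(map)) stop("parent genotype does not cover all markers")
  out <- matrix(NA_integer_, n, nrow(map))
  for (idx in .map_chrom_index(map)) {
    cm <- map$cM[idx]
    L <- max(cm) - min(cm)
    start <- sample.int(2L, n, replace = TRUE)
    k <- if (L > 0) stats::rpois(n, L / 100) else integer(n)
    seg <- matrix(0L, n, length(idx))
    for (g in which(k > 0L)) {
      cuts <- sort(stats::runif(k[g], min(cm), max(cm)))
      seg[g, ] <- findInterval(cm, cuts)
    }
    phase <- (start + seg - 1L) %% 2L + 1L  # 1 -> hap1, 2 -> hap2
    h1 <- haps[1L, idx]; h2 <- haps[2L, idx]
    out[, idx] <- ifelse(phase == 1L,
                         matrix(h1, n, length(idx), byrow = TRUE),
                         matrix(h2, n, length(idx), byrow = TRUE))
  }
  out
}

#' @rdname simulate_gametes
#' @param seed optional integer seed
#' @export
simulate_gamete <- function(haps, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop(simulate_gametes(haps, map, n = 1))
}

#' Derive a RIL population by single-seed descent
#'
#' Starting from the F1 of two fully inbred parents, each line is
#' advanced by `n_selfing` generations of selfing with a single seed
#' kept per generation.  Expected per-marker heterozygosity after g
#' selfing generations is (1/2)^g.
#'
#' @param n_lines number of lines (>= 1)
#' @param map `genetic_map`
#' @param n_selfing selfing generations (>= 1); default 8
#' @param seed optional integer seed
#' @param keep_haplotypes keep phased haplotypes as an attribute
#' @return character matrix (lines x markers) of codes "A"/"H"/"B",
#'   with `rownames` line ids and `colnames` marker names
#' @export
derive_ril_population <- function(n_lines, map, n_selfing = 8, seed = NULL,
                                  keep_haplotypes = FALSE) {
  if (n_lines < 1) stop("population size must be positive")
  if (n_selfing < 1) stop("n_selfing must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  validate_map(map)
  m <- nrow(map)
  f1 <- rbind(rep(1L, m), rep(2L, m))
  geno <- matrix(NA_character_, n_lines, m,
                 dimnames = list(sprintf("RIL%03d", seq_len(n_lines)), map$marker))
  haps <- if (keep_haplotypes) vector("list", n_lines) else NULL
  for (i in seq_len(n_lines)) {
    cur <- f1
    for (g in seq_len(n_selfing)) cur <- simulate_gametes(cur, map, n = 2)
    geno[i, ] <- .codes_from_haps(cur)
    if (keep_haplotypes) haps[[i]] <- cur
  }
  if (keep_haplotypes) attr(geno, "haplotypes") <- haps
  geno
}

#' Derive progeny from a recombinant plant
#'
#' Selfing of a (possibly recombinant) plant, or backcrossing to the
#' recurrent parent "B".  Markers homozygous in the parent stay fixed;
#' a heterozygous marker segregates 1:2:1 (A:H:B) under selfing and
#' 1:1 (H:B) under the backcross.
#'
#' @param parent either a character vector of genotype codes (phased by
#'   [phase_genotype()]) or an integer 2 x m haplotype matrix
#' @param scheme `"self"` or `"backcross_to_B"`
#' @param n_progeny number of progeny
#' @param map `genetic_map`
#' @param seed optional integer seed
#' @param keep_haplotypes keep phased haplotypes as an attribute
#' @return character matrix (progeny x markers) of genotype codes
#' @export
derive_progeny <- function(parent, scheme = c("self", "backcross_to_B"),
                           n_progeny, map, seed = NULL,
                           keep_haplotypes = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  validate_map(map)
  haps <- if (is.matrix(parent) && is.numeric(parent)) parent else phase_genotype(parent)
  g1 <- simulate_gametes(haps, map, n_progeny)
  g2 <- if (scheme == "self") simulate_gametes(haps, map, n_progeny)
        else matrix(2L, n_progeny, nrow(map))
  codes <- matrix(c("A", "H", "B")[g1 + g2 - 1L], n_progeny, nrow(map),
                  dimnames = list(sprintf("P%04d", seq_len(n_progeny)), map$marker))
  if (keep_haplotypes)
    attr(codes, "haplotypes") <- lapply(seq_len(n_progeny),
                                        function(i) rbind(g1[i, ], g2[i, ]))
  codes
}

#' Truth model for phenotype simulation
#'
#' Collects the simulated QTL (chromosome, cM position, additive effect
#' `a` and dominance effect `d`, both in GWC percentage points) and the
#' variance components of the line / trial / residual structure.  The
#' default effect sizes correspond to a semi-dominant QTL whose
#' homozygote classes differ by ~3.3 GWC points; default variances give
#' a broad-sense heritability near 0.75 in a three-trial design.
#'
#' @param qtl_chrom chromosome of the QTL
#' @param qtl_cM genetic position of the QTL (cM)
#' @param a additive effect (half the homozygote difference, GWC points)
#' @param d dominance effect (heterozygote deviation from the homozygote
#'   midpoint, GWC points); defaults satisfy |d| <= |a|
#' @param sigma2_G polygenic line variance
#' @param sigma2_GxE line-by-trial interaction variance
#' @param sigma2_e residual variance
#' @return a list of class `truth_model`
#' @export
truth_model <- function(qtl_chrom = "1", qtl_cM = 75, a = 1.655, d = 0.075,
                        sigma2_G = 4.5, sigma2_GxE = 3, sigma2_e = 3) {
  stopifnot(sigma2_G >= 0, sigma2_GxE >= 0, sigma2_e >= 0)
  structure(list(qtl_chrom = as.character(qtl_chrom), qtl_cM = qtl_cM,
                 a = a, d = d, sigma2_G = sigma2_G,
                 sigma2_GxE = sigma2_GxE, sigma2_e = sigma2_e),
            class = "truth_model")
}

#' Trial designs
#'
#' A trial design names the trial, its replicate count, the sampled
#' days-after-pollination (DAP), and the baseline GWC trajectory as
#' (DAP, GWC%) anchors interpolated piecewise-linearly.  Anchors must be
#' strictly decreasing in GWC: kernels only dry down after physiological
#' maturity.  `default_trial_designs()` mirrors a three-trial layout
#' (two summer trials sampled at 45/50 or 45-60 DAP and one winter
#' nursery trial) with trajectories matching typical trial means
#' (~38-39% at 45 DAP falling to ~23% at 60 DAP).
#'
#' @param trial trial label
#' @param reps number of replicates (>= 1)
#' @param daps strictly increasing sampling DAPs
#' @param anchors data.frame with columns `dap`, `gwc` (strictly
#'   decreasing gwc), covering the range of `daps`
#' @return a list of class `trial_design`
#' @export
trial_design <- function(trial, reps, daps, anchors) {
  stopifnot(reps >= 1, !is.unsorted(daps, strictly = TRUE),
            is.data.frame(anchors), all(c("dap", "gwc") %in% names(anchors)))
  if (any(diff(anchors$gwc) >= 0))
    stop("baseline GWC trajectory must be strictly decreasing in DAP")
  if (min(daps) < min(anchors$dap) || max(daps) > max(anchors$dap))
    stop("sampling DAP outside the baseline trajectory's domain")
  structure(list(trial = trial, reps = reps, daps = daps, anchors = anchors),
            class = "trial_design")
}

#' @rdname trial_design
#' @export
default_trial_designs <- function() {
  list(
    trial_design("SD2014", reps = 2, daps = c(45, 50),
                 anchors = data.frame(dap = c(45, 50), gwc = c(39.37, 31.62))),
    trial_design("HN2014", reps = 2, daps = c(45, 50),
                 anchors = data.frame(dap = c(45, 50), gwc = c(27.61, 18.87))),
    trial_design("SD2015", reps = 2, daps = c(45, 50, 55, 60),
                 anchors = data.frame(dap = c(45, 50, 55, 60),
                                      gwc = c(38.22, 32.78, 27.63, 23.47)))
  )
}

# piecewise-linear baseline evaluation
.baseline_gwc <- function(design, dap) {
  stats::approx(design$anchors$dap, design$anchors$gwc, xout = dap)$y
}

#' Simulate GWC phenotypes for a genotyped population
#'
#' Realises GWC(i, trial j, rep, DAP t) = baseline_j(t) + x_i a + z_i d
#' + G_i + (GxE)_ij + eps, with x = +1/0/-1 for QTL genotype A/H/B and
#' z = 1 for H.  Fresh and dry kernel weights are emitted such that the
#' GWC formula recovers the simulated GWC exactly (fresh weight fixed,
#' dry = fresh * (1 - GWC/100)).
#'
#' In the dehydration-coupled mode (`coupled = TRUE`), GWC values after
#' the first sampling are produced sequentially: the per-interval drop
#' (GDR) pulls lines above the baseline back towards it and carries its
#' own noise, which induces the negative correlation between GDR and
#' GWC at the later sampling seen in real dry-down data.  Off by
#' default.
#'
#' @param genotypes character matrix of codes (lines x markers)
#' @param map `genetic_map` matching the genotype columns
#' @param truth a [truth_model()]
#' @param designs list of [trial_design()]s
#' @param seed optional integer seed
#' @param qtl_codes optional character vector of true QTL genotypes per
#'   line; by default the genotype at the map marker nearest the QTL is
#'   used
#' @param n_pheno_lines optional vector (one per design) of how many
#'   lines are phenotyped per trial (sampled without replacement);
#'   default all
#' @param coupled enable the dehydration-coupled mode
#' @param coupling pull-back strength in (0, 1) for the coupled mode
#' @param gdr_noise_sd per-interval GDR noise sd (coupled mode);
#'   the default of 2 GWC points yields GDR-GWC(later) correlations
#'   near -0.6 under the default variances
#' @param fresh_g emitted fresh weight per sample (g)
#' @return data.frame of trait records: `line`, `trial`, `rep`, `dap`,
#'   `fresh_g`, `dry_g`, `gwc`
#' @export
simulate_phenotypes <- function(genotypes, map, truth, designs, seed = NULL,
                                qtl_codes = NULL, n_pheno_lines = NULL,
                                coupled = FALSE, coupling = 0.3,
                                gdr_noise_sd = 2, fresh_g = 30) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(designs, "trial_design")) designs <- list(designs)
  lines <- rownames(genotypes)
  if (is.null(lines)) lines <- sprintf("L%03d", seq_len(nrow(genotypes)))
  if (is.null(qtl_codes)) {
    on_chr <- which(map$chrom == truth$qtl_chrom)
    if (length(on_chr) == 0L) stop("QTL chromosome absent from map")
    near <- on_chr[which.min(abs(map$cM[on_chr] - truth$qtl_cM))]
    qtl_codes <- genotypes[, near]
  }
  x <- c(A = 1, H = 0, B = -1)[qtl_codes]
  z <- as.numeric(qtl_codes == "H")
  x[is.na(x)] <- 0; z[is.na(z)] <- 0
  G <- stats::rnorm(length(lines), 0, sqrt(truth$sigma2_G))
  names(G) <- lines

  out <- vector("list", length(designs))
  for (j in seq_along(designs)) {
    des <- designs[[j]]
    keep <- seq_along(lines)
    if (!is.null(n_pheno_lines)) {
      n_j <- min(n_pheno_lines[j], length(lines))
      keep <- sort(sample(seq_along(lines), n_j))
    }
    gxe <- stats::rnorm(length(keep), 0, sqrt(truth$sigma2_GxE))
    genet <- x[keep] * truth$a + z[keep] * truth$d + G[keep] + gxe
    recs <- expand.grid(li = keep, rep = seq_len(des$reps),
                        KEEP.OUT.ATTRS = FALSE)
    ndap <- length(des$daps)
    gwc <- matrix(NA_real_, nrow(recs), ndap)
    base <- .baseline_gwc(des, des$daps)
    if (!coupled) {
      for (k in seq_len(ndap))
        gwc[, k] <- base[k] + genet[match(recs$li, keep)] +
          stats::rnorm(nrow(recs), 0, sqrt(truth$sigma2_e))
    } else {
      gwc[, 1] <- base[1] + genet[match(recs$li, keep)] +
        stats::rnorm(nrow(recs), 0, sqrt(truth$sigma2_e))
      for (k in seq_len(ndap - 1L)) {
        drop_k <- (base[k] - base[k + 1L]) +
          coupling * (gwc[, k] - base[k]) +
          stats::rnorm(nrow(recs), 0, gdr_noise_sd)
        gwc[, k + 1L] <- gwc[, k] - drop_k
      }
    }
    df <- data.frame(
      line = rep(lines[recs$li], times = ndap),
      trial = des$trial,
      rep = rep(recs$rep, times = ndap),
      dap = rep(des$daps, each = nrow(recs)),
      gwc = as.vector(gwc), stringsAsFactors = FALSE)
    out[[j]] <- df
  }
  res <- do.call(rbind, out)
  if (any(res$gwc <= 0 | res$gwc >= 100)) {
    warning("simulated GWC outside (0, 100); clamping")
    res$gwc <- pmin(pmax(res$gwc, 0.01), 99.99)
  }
  res$fresh_g <- fresh_g
  res$dry_g <- fresh_g * (1 - res$gwc / 100)
  res[, c("line", "trial", "rep", "dap", "fresh_g", "dry_g", "gwc")]
}

#' Simulate a complete RIL study
#'
#' Convenience wrapper producing the map, RIL genotype matrix, trait
#' records and the truth sidecar in one call.
#'
#' @param n_lines number of RILs (default 362, thinned per trial by
#'   `n_pheno_lines`)
#' @param map `genetic_map`; default [synthetic_map()]
#' @param truth [truth_model()]
#' @param designs list of [trial_design()]s
#' @param n_selfing selfing generations
#' @param n_pheno_lines lines phenotyped per trial (default 84/119/117
#'   for the default three-trial design, all lines otherwise)
#' @param seed integer seed
#' @param ... passed to [simulate_phenotypes()]
#' @return list with `map`, `genotypes`, `phenotypes`, `truth`, `seed`
#' @export
simulate_ril_study <- function(n_lines = 362, map = synthetic_map(),
                               truth = truth_model(),
                               designs = default_trial_designs(),
                               n_selfing = 8, n_pheno_lines = NULL,
                               seed = 1, ...) {
  set.seed(seed)
  if (is.null(n_pheno_lines) && length(designs) == 3L)
    n_pheno_lines <- c(84, 119, 117)
  geno <- derive_ril_population(n_lines, map, n_selfing = n_selfing)
  phen <- simulate_phenotypes(geno, map, truth, designs,
                              n_pheno_lines = n_pheno_lines, ...)
  list(map = map, genotypes = geno, phenotypes = phen, truth = truth,
       seed = seed)
}

#' Read / write genotype matrices as CSV
#'
#' Rows are individuals, columns are markers; cells hold "A"/"B"/"H" or
#' are empty for missing.
#'
#' @param geno character genotype matrix
#' @param path file path
#' @return `read_genotypes_csv()` returns a character matrix
#' @export
write_genotypes_csv <- function(geno, path) {
  utils::write.csv(as.data.frame(geno), path, na = "", row.names = TRUE)
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, stringsAsFactors = FALSE,
                        check.names = FALSE)
  m <- as.matrix(df)
  m[m == ""] <- NA_character_
  if (!all(m[!is.na(m)] %in% GENO_CODES)) stop("invalid genotype codes in ", path)
  m
}
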