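# Genome scan machinery: conditional genotype probabilities on a cM
# grid, Haley-Knott style interval mapping, composite interval mapping
# with forward-selected marker cofactors, permutation thresholds, and
# QTL calling.

.scan_classes <- function(population_type) {
  switch(population_type, RIL = c("A", "B"), BC = c("H", "B"),
         F2 = c("A", "H", "B"))
}

.scan_prior <- function(population_type) {
  switch(population_type, RIL = c(0.5, 0.5), BC = c(0.5, 0.5),
         F2 = c(0.25, 0.5, 0.25))
}

# genotype-class transition matrix over d cM for the population type
.trans_matrix <- function(d, population_type, map_function) {
  r <- cm_to_rf(d, map_function)
  switch(population_type,
    RIL = {
      # two-state chain between fixed RIL genotypes; the observed
      # recombinant fraction between loci is R = 2r/(1+2r)
      R <- 2 * r / (1 + 2 * r)
      matrix(c(1 - R, R, R, 1 - R), 2, 2, byrow = TRUE)
    },
    BC = matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE),
    F2 = {
      # product of two independent gamete chains
      matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
               r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
               r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
    })
}

# map genotype codes to class indices (NA when uninformative)
.class_index <- function(codes, population_type) {
  cls <- .scan_classes(population_type)
  idx <- match(codes, cls)
  idx
}

#' Conditional genotype probabilities on a scan grid
#'
#' At every grid position (a step grid plus every marker) computes the
#' probability of each genotype class conditional on the nearest
#' flanking non-missing markers, under a Markov chain along the
#' chromosome with the configured map function.  At a typed marker the
#' probability is 1 on the observed class; with both flanks missing the
#' prior class frequencies are returned.
#'
#' @param genotypes character matrix (individuals x markers)
#' @param map `genetic_map` whose markers match the genotype columns
#' @param step_cM grid step in cM (> 0); markers are always evaluated
#' @param population_type `"RIL"`, `"F2"` or `"BC"`
#' @param map_function map function for cM-to-r conversion
#' @return object of class `geno_prob`: list with `positions`
#'   (data.frame `chrom`, `cM`, `marker`), `prob` (array individuals x
#'   positions x classes), `classes`, `score` (expected additive score
#'   with A = +1, H = 0, B = -1), `domz` (P(H), 3-class types only)
#' @export
genotype_probabilities <- function(genotypes, map, step_cM = 1,
                                   population_type = c("RIL", "F2", "BC"),
                                   map_function = c("kosambi", "haldane")) {
  population_type <- match.arg(population_type)
  map_function <- match.arg(map_function)
  if (step_cM <= 0) stop("step_cM must be > 0")
  validate_map(map)
  stopifnot(all(map$marker %in% colnames(genotypes)))
  geno <- genotypes[, map$marker, drop = FALSE]
  n <- nrow(geno)
  cls <- .scan_classes(population_type)
  K <- length(cls)
  prior <- .scan_prior(population_type)
  cidx <- matrix(.class_index(geno, population_type), n, ncol(geno))

  pos_list <- list()
  prob_list <- list()
  for (idx in .map_chrom_index(map)) {
    cm <- map$cM[idx]
    grid <- sort(unique(c(seq(min(cm), max(cm), by = step_cM), cm)))
    mk <- map$marker[idx][match(grid, cm)]
    P <- length(grid)
    mchr <- length(idx)
    prob <- array(NA_real_, c(n, P, K))
    ci <- cidx[, idx, drop = FALSE]
    info <- !is.na(ci)
    # per individual, index of the nearest informative marker at/left
    # (prev) and at/right (nxt) of each marker; 0 when none
    prev <- matrix(0L, n, mchr); nxt <- matrix(0L, n, mchr)
    for (i in seq_len(n)) {
      prev[i, ] <- cummax(ifelse(info[i, ], seq_len(mchr), 0L))
      nxt[i, ] <- rev(cummin(rev(ifelse(info[i, ], seq_len(mchr), mchr + 1L))))
    }
    nxt[nxt > mchr] <- 0L
    for (p in seq_len(P)) {
      pos <- grid[p]
      iL <- findInterval(pos, cm)  # last marker with cM <= pos
      iR <- iL + as.integer(iL == 0L || cm[max(iL, 1L)] < pos - 1e-9)
      if (iL >= 1L && abs(cm[iL] - pos) < 1e-9) iR <- iL
      li <- if (iL >= 1L) prev[, iL] else rep(0L, n)
      ri <- if (iR >= 1L && iR <= mchr) nxt[, iR] else rep(0L, n)
      typed <- li > 0L & abs(cm[pmax(li, 1L)] - pos) < 1e-9
      if (any(typed)) {
        w <- which(typed)
        pm <- matrix(0, length(w), K)
        pm[cbind(seq_along(w), ci[cbind(w, li[w])])] <- 1
        prob[w, p, ] <- pm
      }
      rest <- which(!typed)
      if (length(rest)) {
        key <- paste(li[rest], ri[rest])
        for (kk in unique(key)) {
          rows <- rest[key == kk]
          l1 <- li[rows[1L]]; r1 <- ri[rows[1L]]
          if (l1 > 0L && r1 > 0L) {
            TL <- .trans_matrix(pos - cm[l1], population_type, map_function)
            TR <- .trans_matrix(cm[r1] - pos, population_type, map_function)
            W <- TL[ci[cbind(rows, rep(l1, length(rows)))], , drop = FALSE] *
              t(TR)[ci[cbind(rows, rep(r1, length(rows)))], , drop = FALSE]
            prob[rows, p, ] <- W / rowSums(W)
          } else if (l1 > 0L) {
            TL <- .trans_matrix(pos - cm[l1], population_type, map_function)
            prob[rows, p, ] <- TL[ci[cbind(rows, rep(l1, length(rows)))], , drop = FALSE]
          } else if (r1 > 0L) {
            TR <- .trans_matrix(cm[r1] - pos, population_type, map_function)
            W <- matrix(prior, length(rows), K, byrow = TRUE) *
              t(TR)[ci[cbind(rows, rep(r1, length(rows)))], , drop = FALSE]
            prob[rows, p, ] <- W / rowSums(W)
          } else {
            prob[rows, p, ] <- matrix(prior, length(rows), K, byrow = TRUE)
          }
        }
      }
    }
    pos_list[[length(pos_list) + 1L]] <-
      data.frame(chrom = map$chrom[idx[1L]], cM = grid, marker = mk,
                 stringsAsFactors = FALSE)
    prob_list[[length(prob_list) + 1L]] <- prob
  }
  positions <- do.call(rbind, pos_list)
  prob <- array(NA_real_, c(n, nrow(positions), K))
  at <- 0L
  for (pl in prob_list) {
    prob[, at + seq_len(dim(pl)[2L]), ] <- pl
    at <- at + dim(pl)[2L]
  }
  score <- switch(population_type,
                  RIL = prob[, , 1L] - prob[, , 2L],
                  F2 = prob[, , 1L] - prob[, , 3L],
                  BC = -prob[, , 2L])
  score <- matrix(score, n, nrow(positions))
  domz <- if (K == 3L) matrix(prob[, , 2L], n, nrow(positions)) else NULL
  structure(list(positions = positions, prob = prob, classes = cls,
                 score = score, domz = domz,
                 population_type = population_type,
                 individuals = rownames(geno)),
            class = "geno_prob")
}

# complete-case alignment of a phenotype with a geno_prob object
.scan_cc <- function(gp, phenotype) {
  y <- as.numeric(phenotype)
  if (length(y) != dim(gp$prob)[1L])
    stop("phenotype length does not match the genotype probabilities")
  ok <- !is.na(y)
  list(y = y[ok], rows = which(ok))
}

#' Interval mapping genome scan
#'
#' Haley-Knott regression of the phenotype on the expected genotype
#' score (plus a dominance indicator for 3-class populations) at every
#' grid position.  LOD = (n/2) log10(RSS0/RSS1); the additive effect AE
#' is half the fitted difference between the homozygote classes,
#' positive when the parent-A ("844") allele increases the trait; R2 is
#' the percent phenotypic variance explained.
#'
#' @param gp a [genotype_probabilities()] object
#' @param phenotype numeric vector, one value per individual (NAs
#'   dropped listwise)
#' @return data.frame of class `qtl_scan` with columns `chrom`, `cM`,
#'   `marker`, `lod`, `ae`, `r2`
#' @export
interval_mapping_scan <- function(gp, phenotype) {
  cc <- .scan_cc(gp, phenotype)
  y <- cc$y
  n <- length(y)
  if (n < 30) warning("fewer than 30 phenotyped individuals")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  X <- gp$score[cc$rows, , drop = FALSE]
  P <- ncol(X)
  lod <- ae <- r2 <- numeric(P)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (is.null(gp$domz)) {
    xc <- sweep(X, 2, colMeans(X))
    sxx <- colSums(xc^2)
    sxy <- as.numeric(crossprod(xc, yc))
    ok <- sxx > 1e-12
    rr <- numeric(P)
    rr[ok] <- (sxy[ok]^2) / (sxx[ok] * syy)
    rr <- pmin(rr, 1 - 1e-12)
    lod <- ifelse(ok, -(n / 2) * log10(1 - rr), 0)
    ae <- ifelse(ok, sxy / sxx, 0)
    r2 <- ifelse(ok, rr * 100, 0)
  } else {
    Z <- gp$domz[cc$rows, , drop = FALSE]
    for (p in seq_len(P)) {
      xp <- X[, p]; zp <- Z[, p]
      D <- cbind(1, xp, zp)
      qrD <- qr(D)
      if (qrD$rank < 2L || stats::sd(xp) < 1e-9) { lod[p] <- 0; next }
      fit <- qr.fitted(qrD, y)
      rss1 <- sum((y - fit)^2)
      rss1 <- max(rss1, syy * 1e-12)
      lod[p] <- (n / 2) * log10(syy / rss1)
      ae[p] <- qr.coef(qrD, y)[2L]
      if (is.na(ae[p])) ae[p] <- 0
      r2[p] <- (1 - rss1 / syy) * 100
    }
  }
  res <- cbind(gp$positions,
               data.frame(lod = lod, ae = ae, r2 = r2))
  class(res) <- c("qtl_scan", "data.frame")
  res
}

# forward selection of marker cofactors by p-value of the added term
.select_cofactors <- function(gp, y, rows, n_cofactors, alpha_in = 0.05) {
  mk <- which(!is.na(gp$positions$marker))
  Xm <- gp$score[rows, mk, drop = FALSE]
  n <- length(y)
  chosen <- integer(0)
  design <- matrix(1, n, 1)
  repeat {
    if (length(chosen) >= n_cofactors) break
    rss0 <- sum(stats::lm.fit(design, y)$residuals^2)
    best_p <- Inf; best_k <- NA_integer_
    for (k in setdiff(seq_along(mk), chosen)) {
      xk <- Xm[, k]
      if (stats::sd(xk) < 1e-9) next
      fit <- stats::lm.fit(cbind(design, xk), y)
      if (fit$rank < ncol(design) + 1L) next
      rss1 <- sum(fit$residuals^2)
      df2 <- n - ncol(design) - 1L
      Fst <- (rss0 - rss1) / (rss1 / df2)
      p <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
      if (!is.na(p) && p < best_p) { best_p <- p; best_k <- k }
    }
    if (is.na(best_k) || best_p >= alpha_in) break
    chosen <- c(chosen, best_k)
    design <- cbind(design, Xm[, best_k])
  }
  mk[chosen]   # position indices of the chosen cofactor markers
}

#' Composite interval mapping scan
#'
#' As [interval_mapping_scan()], with background marker cofactors
#' (forward-selected by p-value, at most `n_cofactors`) included in
#' both the null and the alternative model.  Cofactors within
#' `window_cM` of the evaluated position (same chromosome) are excluded
#' from the model at that position.  With zero cofactors the scan
#' reduces exactly to plain interval mapping.
#'
#' @inheritParams interval_mapping_scan
#' @param n_cofactors maximum number of marker cofactors (default 5);
#'   must be < n/5
#' @param window_cM exclusion window around the test position (cM)
#' @param alpha_in forward-selection entry threshold
#' @param cofactors optional integer vector of position indices to use
#'   as cofactors, bypassing selection
#' @return data.frame of class `qtl_scan`; the chosen cofactor
#'   positions are stored in `attr(, "cofactors")`
#' @export
cim_scan <- function(gp, phenotype, n_cofactors = 5, window_cM = 10,
                     alpha_in = 0.05, cofactors = NULL) {
  cc <- .scan_cc(gp, phenotype)
  y <- cc$y
  n <- length(y)
  if (stats::sd(y) == 0) stop("phenotype is constant")
  if (n_cofactors >= n / 5) stop("cofactor count must be below n/5")
  if (is.null(cofactors))
    cofactors <- .select_cofactors(gp, y, cc$rows, n_cofactors, alpha_in)
  X <- gp$score[cc$rows, , drop = FALSE]
  Z <- if (!is.null(gp$domz)) gp$domz[cc$rows, , drop = FALSE] else NULL
  pos <- gp$positions
  P <- nrow(pos)
  lod <- ae <- r2 <- numeric(P)
  for (p in seq_len(P)) {
    use <- cofactors[!(pos$chrom[cofactors] == pos$chrom[p] &
                         abs(pos$cM[cofactors] - pos$cM[p]) <= window_cM)]
    C <- cbind(rep(1, n), if (length(use)) X[, use, drop = FALSE])
    alt <- cbind(C, X[, p], if (!is.null(Z)) Z[, p])
    f0 <- stats::lm.fit(C, y)
    rss0 <- sum(f0$residuals^2)
    f1 <- stats::lm.fit(alt, y)
    if (f1$rank <= f0$rank) { lod[p] <- 0; next }
    rss1 <- max(sum(f1$residuals^2), rss0 * 1e-12)
    lod[p] <- (n / 2) * log10(rss0 / rss1)
    b <- f1$coefficients[ncol(C) + 1L]
    ae[p] <- if (is.na(b)) 0 else b
    r2[p] <- (1 - rss1 / rss0) * 100
  }
  res <- cbind(pos, data.frame(lod = lod, ae = ae, r2 = r2))
  class(res) <- c("qtl_scan", "data.frame")
  attr(res, "cofactors") <- cofactors
  res
}

#' Permutation LOD threshold
#'
#' Permutes the phenotype `n_perm` times, records the genome-wide
#' maximum interval-mapping LOD of each permutation, and returns the
#' empirical (1 - alpha) quantile.  Deterministic under a fixed seed.
#'
#' @inheritParams interval_mapping_scan
#' @param n_perm number of permutations (>= 100; 1000 for production
#'   thresholds)
#' @param alpha genome-wide type-I level (default 0.05)
#' @param seed optional integer seed
#' @return the LOD threshold (numeric scalar); the permutation maxima
#'   are attached as `attr(, "maxima")`
#' @export
permutation_threshold <- function(gp, phenotype, n_perm = 1000, alpha = 0.05,
                                  seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  cc <- .scan_cc(gp, phenotype)
  y <- cc$y
  n <- length(y)
  X <- gp$score[cc$rows, , drop = FALSE]
  if (is.null(gp$domz)) {
    xc <- sweep(X, 2, colMeans(X))
    sxx <- colSums(xc^2)
    keep <- sxx > 1e-12
    xs <- sweep(xc[, keep, drop = FALSE], 2, sqrt(sxx[keep]), "/")
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    Yc <- sweep(Y, 2, colMeans(Y))
    Ys <- sweep(Yc, 2, sqrt(colSums(Yc^2)), "/")
    R <- crossprod(xs, Ys)                 # positions x permutations
    rmax2 <- apply(R^2, 2, max)
    maxima <- -(n / 2) * log10(1 - pmin(rmax2, 1 - 1e-12))
  } else {
    maxima <- vapply(seq_len(n_perm), function(i) {
      yp <- rep(NA_real_, dim(gp$prob)[1L])
      yp[cc$rows] <- sample(y)
      max(interval_mapping_scan(gp, yp)$lod)
    }, numeric(1))
  }
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 1, names = FALSE)
  attr(thr, "maxima") <- maxima
  thr
}

#' Call QTL from a scan
#'
#' Merges contiguous supra-threshold segments (LOD strictly above the
#' threshold) into one call per peak, computes the 1.5-LOD support
#' interval, snaps its flanks to the nearest bracketing map markers,
#' and names calls `q<Trait><chrom>.<k>` in genomic order.  A call is
#' flagged major when R2 > 10%.
#'
#' @param scan a `qtl_scan` data.frame
#' @param threshold declared LOD threshold (callers typically use
#'   `max(2.5, permutation_threshold(...))`)
#' @param map the `genetic_map` used for the scan (for flank snapping
#'   and physical coordinates)
#' @param trait trait tag used in QTL names (e.g. `"Gwc"`)
#' @param lod_drop support-interval drop (default 1.5 LOD)
#' @return data.frame of calls (possibly zero rows): `name`, `chrom`,
#'   `peak_cM`, `lod`, `ae`, `r2`, `left_marker`, `right_marker`,
#'   `left_bp`, `right_bp`, `interval_mb`, `major`
#' @export
call_qtl <- function(scan, threshold, map, trait = "Gwc", lod_drop = 1.5) {
  validate_map(map)
  calls <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    above <- s$lod > threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- 0L
    for (ri in which(runs$values)) {
      k <- k + 1L
      seg <- starts[ri]:ends[ri]
      peak <- seg[which.max(s$lod[seg])]
      cut <- s$lod[peak] - lod_drop
      lo <- peak; while (lo > 1L && s$lod[lo - 1L] >= cut) lo <- lo - 1L
      hi <- peak; while (hi < nrow(s) && s$lod[hi + 1L] >= cut) hi <- hi + 1L
      # extend one scan position past the drop so the flanking markers
      # bracket the support interval
      lo <- max(lo - 1L, 1L); hi <- min(hi + 1L, nrow(s))
      mk <- map[map$chrom == ch, ]
      lm_i <- which(mk$cM <= s$cM[lo]); lm_i <- if (length(lm_i)) max(lm_i) else 1L
      rm_i <- which(mk$cM >= s$cM[hi]); rm_i <- if (length(rm_i)) min(rm_i) else nrow(mk)
      calls[[length(calls) + 1L]] <- data.frame(
        name = sprintf("q%s%s.%d", trait, ch, k),
        chrom = ch, peak_cM = s$cM[peak], lod = s$lod[peak],
        ae = s$ae[peak], r2 = s$r2[peak],
        left_marker = mk$marker[lm_i], right_marker = mk$marker[rm_i],
        left_bp = mk$bp[lm_i], right_bp = mk$bp[rm_i],
        interval_mb = (mk$bp[rm_i] - mk$bp[lm_i]) / 1e6,
        major = s$r2[peak] > 10, stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(name = character(), chrom = character(),
                      peak_cM = numeric(), lod = numeric(), ae = numeric(),
                      r2 = numeric(), left_marker = character(),
                      right_marker = character(), left_bp = numeric(),
                      right_bp = numeric(), interval_mb = numeric(),
                      major = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
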