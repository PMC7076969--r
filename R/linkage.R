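#' Marker quality control
#'
#' Applies the marker filters in order: (1) drop markers that are not
#' polymorphic between the two parents; (2) drop markers whose missing
#' rate or heterozygous rate exceeds 20% (strictly more than the
#' threshold; a marker at exactly 20% is kept); (3) flag markers with
#' segregation distortion by chi-square test at `distortion_alpha`.
#' Each dropped marker carries exactly one primary reason, in that
#' order of precedence.
#'
#' @param genotypes character matrix (individuals x markers)
#' @param parent_genotypes 2 x m character matrix (rows: parent A and
#'   parent B codes at every marker), or NULL to skip the polymorphism
#'   check
#' @param population_type `"RIL"`, `"F2"` or `"BC"` (expected
#'   segregation ratio for the distortion test)
#' @param max_missing,max_het rate thresholds (default 0.20)
#' @param distortion_alpha significance level for the distortion test
#' @param bonferroni apply a Bonferroni correction to
#'   `distortion_alpha` across tested markers
#' @return data.frame of class `marker_qc`: per marker the polymorphism
#'   flag, missing and heterozygous rates, chi-square statistic and p,
#'   `keep` and `reason`
#' @export
filter_markers <- function(genotypes, parent_genotypes = NULL,
                           population_type = c("RIL", "F2", "BC"),
                           max_missing = 0.20, max_het = 0.20,
                           distortion_alpha = 0.05, bonferroni = FALSE) {
  population_type <- match.arg(population_type)
  if (nrow(genotypes) == 0L || ncol(genotypes) == 0L) stop("empty genotype matrix")
  m <- ncol(genotypes)
  markers <- colnames(genotypes)
  if (is.null(markers)) markers <- paste0("M", seq_len(m))
  poly <- rep(TRUE, m)
  if (!is.null(parent_genotypes)) {
    if (ncol(parent_genotypes) != m) stop("parents not genotyped at all markers")
    poly <- parent_genotypes[1L, ] != parent_genotypes[2L, ] &
      !is.na(parent_genotypes[1L, ]) & !is.na(parent_genotypes[2L, ])
  }
  miss <- colMeans(is.na(genotypes))
  het <- colMeans(genotypes == "H", na.rm = TRUE)
  het[is.nan(het)] <- 0
  chisq <- pval <- rep(NA_real_, m)
  alpha <- if (bonferroni) distortion_alpha / max(sum(poly), 1L) else distortion_alpha
  reason <- rep(NA_character_, m)
  keep <- rep(TRUE, m)
  for (k in seq_len(m)) {
    if (!poly[k]) { keep[k] <- FALSE; reason[k] <- "non_polymorphic"; next }
    if (miss[k] > max_missing) { keep[k] <- FALSE; reason[k] <- "missing_rate"; next }
    if (het[k] > max_het) { keep[k] <- FALSE; reason[k] <- "het_rate"; next }
    sd <- segregation_distortion_test(genotypes[, k], population_type)
    chisq[k] <- sd$statistic; pval[k] <- sd$p.value
    if (!is.na(sd$p.value) && sd$p.value < alpha) {
      keep[k] <- FALSE; reason[k] <- "distorted"
    }
  }
  structure(data.frame(marker = markers, polymorphic = poly,
                       missing_rate = miss, het_rate = het,
                       chisq = chisq, p = pval, keep = keep,
                       reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("marker_qc", "data.frame"))
}

#' Segregation distortion chi-square test
#'
#' Pearson chi-square of the observed genotype counts against the
#' Mendelian expectation for the population type: RIL homozygotes 1:1
#' (heterozygous calls excluded), F2 1:2:1 (A:H:B), BC 1:1 (H:B).
#' Computed on non-missing calls.
#'
#' @param marker_calls character vector of codes for one marker
#' @param population_type `"RIL"`, `"F2"` or `"BC"`
#' @return list with `statistic`, `df`, `p.value`, `distorted` is left
#'   to the caller's alpha
#' @export
segregation_distortion_test <- function(marker_calls,
                                        population_type = c("RIL", "F2", "BC")) {
  population_type <- match.arg(population_type)
  calls <- marker_calls[!is.na(marker_calls)]
  ratio <- switch(population_type,
                  RIL = list(classes = c("A", "B"), weights = c(1, 1)),
                  F2 = list(classes = c("A", "H", "B"), weights = c(1, 2, 1)),
                  BC = list(classes = c("H", "B"), weights = c(1, 1)))
  obs <- vapply(ratio$classes, function(cl) sum(calls == cl), numeric(1))
  n <- sum(obs)
  if (n == 0L) return(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_))
  expd <- n * ratio$weights / sum(ratio$weights)
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Recombination fraction between two markers
#'
#' Estimates the meiotic recombination fraction from the observed joint
#' genotype calls.  For selfing-derived RILs the observed fraction of
#' recombinant homozygote pairs R is corrected to the meiotic r via
#' r = R / (2 (1 - R)); for a backcross r = R directly.  Estimates are
#' capped at 0.4999.
#'
#' @param g_i,g_j character genotype vectors for the two markers
#' @param population_type `"RIL"` (selfing-derived) or `"BC"`
#' @param min_calls minimum informative joint calls (default 20)
#' @return recombination fraction in [0, 0.4999]
#' @export
estimate_rf <- function(g_i, g_j, population_type = c("RIL", "BC"),
                        min_calls = 20) {
  population_type <- match.arg(population_type)
  if (population_type == "RIL") {
    ok <- g_i %in% c("A", "B") & g_j %in% c("A", "B")
  } else {
    ok <- g_i %in% c("H", "B") & g_j %in% c("H", "B")
  }
  if (sum(ok) < min_calls)
    stop("fewer than ", min_calls, " informative joint calls")
  R <- mean(g_i[ok] != g_j[ok])
  r <- if (population_type == "RIL") R / (2 * (1 - R)) else R
  min(r, 0.4999)
}

#' Kosambi map function
#'
#' `kosambi_distance()` converts a recombination fraction to cM,
#' d = 25 log((1+2r)/(1-2r)); `kosambi_rf()` is its inverse,
#' r = tanh(d/50)/2.
#'
#' @param r recombination fraction in [0, 0.5)
#' @param d genetic distance in cM (>= 0)
#' @return the converted quantity
#' @export
kosambi_distance <- function(r) rf_to_cm(r, "kosambi")

#' @rdname kosambi_distance
#' @export
kosambi_rf <- function(d) cm_to_rf(d, "kosambi")

#' Recompute map distances from genotypes
#'
#' Keeps the input marker order (ordering is taken as given) and
#' replaces the cM coordinates with cumulative Kosambi distances
#' estimated from adjacent-marker recombination fractions.
#'
#' @param genotypes character genotype matrix (columns must match the
#'   map's markers)
#' @param map input `genetic_map` providing order and bp
#' @param population_type passed to [estimate_rf()]
#' @return a `genetic_map` with re-estimated cM
#' @export
rebuild_map <- function(genotypes, map, population_type = "RIL") {
  validate_map(map)
  stopifnot(all(map$marker %in% colnames(genotypes)))
  new_cm <- numeric(nrow(map))
  for (idx in .map_chrom_index(map)) {
    cm <- 0
    new_cm[idx[1L]] <- 0
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      r <- estimate_rf(genotypes[, map$marker[idx[k - 1L]]],
                       genotypes[, map$marker[idx[k]]],
                       population_type)
      cm <- cm + kosambi_distance(r)
      new_cm[idx[k]] <- cm
    }
  }
  genetic_map(map$chrom, map$marker, new_cm, map$bp)
}
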