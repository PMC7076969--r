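# ANOVA variance components for the all-random model
#   Y_ijk = mu + G_i + E_j + S_k + (G x E)_ij + e_ijk
# (G = line, E = environment/trial, S = the third stratum: sampling
# time for GWC, replicate for GDR), broad-sense heritability, and
# all-random multi-environment BLUP of line values.

#' ANOVA variance components
#'
#' Fits the all-random model Y_ijk = mu + G_i + E_j + S_k + (GxE)_ij +
#' e_ijk on one observation per (line, env, unit) cell and equates
#' observed to expected mean squares:
#' E(MS_G) = s2_e + r s2_GxE + l r s2_G;
#' E(MS_GxE) = s2_e + r s2_GxE; E(MS_res) = s2_e,
#' with l environments and r units.  Negative moment estimates are
#' truncated to zero and flagged.  When more than 10% of the
#' (line, env, unit) cells are missing the design is treated as
#' unbalanced and the components are estimated by REML
#' ([lme4::lmer()]) instead, with a warning.
#'
#' @param records data.frame with columns `line`, `env`, `unit`,
#'   `value` (one observation per cell; replicate observations within
#'   a cell are averaged with a message)
#' @return list of class `variance_components`: `sigma2_G`,
#'   `sigma2_GxE`, `sigma2_e`, `l`, `r`, `n`, `truncated`, `method`
#'   ("ems" or "reml"), and `anova_table` (for the balanced path)
#' @export
anova_components <- function(records) {
  stopifnot(all(c("line", "env", "unit", "value") %in% names(records)))
  records <- records[!is.na(records$value), , drop = FALSE]
  for (f in c("line", "env", "unit")) records[[f]] <- factor(records[[f]])
  if (nlevels(records$line) < 2L || nlevels(records$env) < 2L)
    stop("fewer than 2 levels of a random factor")
  n <- nlevels(records$line); l <- nlevels(records$env); r <- nlevels(records$unit)
  # collapse replicate observations within a cell
  agg <- stats::aggregate(value ~ line + env + unit, data = records, FUN = mean)
  if (nrow(agg) < nrow(records))
    message("averaged replicate observations within (line, env, unit) cells")
  n_cells <- n * l * r
  missing_frac <- 1 - nrow(agg) / n_cells
  truncated <- FALSE
  if (missing_frac > 0.10) {
    warning("design unbalanced (", round(100 * missing_frac),
            "% of cells missing); using REML estimation")
    fit <- suppressMessages(lme4::lmer(
      value ~ (1 | line) + (1 | env) + (1 | unit) + (1 | line:env),
      data = agg, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
    out <- list(sigma2_G = get("line"), sigma2_GxE = get("line:env"),
                sigma2_e = get("Residual"), l = l, r = r, n = n,
                truncated = FALSE, method = "reml", anova_table = NULL)
    class(out) <- "variance_components"
    return(out)
  }
  fit <- stats::aov(value ~ line + env + unit + line:env, data = agg)
  tab <- summary(fit)[[1L]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  ms_g <- ms[["line"]]
  ms_ge <- ms[["line:env"]]
  ms_e <- if ("Residuals" %in% names(ms)) ms[["Residuals"]] else 0
  s2_e <- ms_e
  s2_ge <- (ms_ge - ms_e) / r
  s2_g <- (ms_g - ms_ge) / (l * r)
  if (s2_ge < 0) { s2_ge <- 0; truncated <- TRUE }
  if (s2_g < 0) { s2_g <- 0; truncated <- TRUE }
  out <- list(sigma2_G = s2_g, sigma2_GxE = s2_ge, sigma2_e = s2_e,
              l = l, r = r, n = n, truncated = truncated, method = "ems",
              anova_table = tab)
  class(out) <- "variance_components"
  out
}

#' Broad-sense heritability
#'
#' h2 = s2_G / (s2_G + s2_GxE / l + s2_e / (l r)), with l environments
#' and r the number of sampling times (GWC) or replicates (GDR).
#' Returns NA when all components are zero.
#'
#' @param components a `variance_components` object, or a list with
#'   `sigma2_G`, `sigma2_GxE`, `sigma2_e`
#' @param l,r design constants; taken from `components` when omitted
#' @return heritability as a fraction in [0, 1] (NA if undefined)
#' @export
heritability <- function(components, l = components$l, r = components$r) {
  stopifnot(l >= 1, r >= 1)
  den <- components$sigma2_G + components$sigma2_GxE / l +
    components$sigma2_e / (l * r)
  if (den <= 1e-12) return(NA_real_)   # all components (numerically) zero
  components$sigma2_G / den
}

#' All-random BLUP of line GWC and GDR
#'
#' Fits, separately at each of two sampling times, the all-random model
#' y_ijk = mu + g_i + l_j + r_k(l_j) + (g x l)_ij + e_ijk and predicts
#' each line's value as the grand mean plus its BLUP.  The predicted
#' GDR is exactly the difference of the two predicted GWC values.
#'
#' @param records trait records (`line`, `trial`, `rep`, `dap`, `gwc`)
#' @param daps the two sampling times to predict (default 45 and 50)
#' @return data.frame with columns `line`, `gwc_early`, `gwc_late`,
#'   `gdr` (per-line predictions)
#' @export
blup_predict <- function(records, daps = c(45, 50)) {
  stopifnot(length(daps) == 2L,
            all(c("line", "trial", "rep", "dap", "gwc") %in% names(records)))
  if (length(unique(records$trial)) < 2L) stop("at least 2 environments required")
  pred_one <- function(dap) {
    sub <- records[records$dap == dap & !is.na(records$gwc), , drop = FALSE]
    if (nrow(sub) == 0L) stop("no records at DAP ", dap)
    sub$line <- factor(sub$line); sub$trial <- factor(sub$trial)
    sub$rep <- factor(sub$rep)
    # drop interaction/replicate strata that are confounded with the
    # residual (e.g. single-replicate data)
    terms <- c("(1 | line)", "(1 | trial)")
    if (nlevels(droplevels(interaction(sub$rep, sub$trial))) > nlevels(sub$trial))
      terms <- c(terms, "(1 | rep:trial)")
    if (nlevels(droplevels(interaction(sub$line, sub$trial))) < nrow(sub))
      terms <- c(terms, "(1 | line:trial)")
    fit <- suppressMessages(lme4::lmer(
      stats::as.formula(paste("gwc ~", paste(terms, collapse = " + "))),
      data = sub, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    mu <- lme4::fixef(fit)[["(Intercept)"]]
    re <- lme4::ranef(fit)$line
    data.frame(line = rownames(re), pred = mu + re[["(Intercept)"]],
               stringsAsFactors = FALSE)
  }
  p1 <- pred_one(daps[1L]); p2 <- pred_one(daps[2L])
  m <- merge(p1, p2, by = "line", suffixes = c("_early", "_late"))
  data.frame(line = m$line, gwc_early = m$pred_early, gwc_late = m$pred_late,
             gdr = m$pred_early - m$pred_late, stringsAsFactors = FALSE)
}

#' Reshape trait records for the GWC or GDR ANOVA
#'
#' For GWC the third stratum (`unit`) is the sampling time (DAP) and
#' replicates are averaged; for GDR the unit is the replicate and the
#' value is the GWC drop between the first two sampled DAPs.
#'
#' @param records trait records (`line`, `trial`, `rep`, `dap`, `gwc`)
#' @param trait `"GWC"` or `"GDR"`
#' @return data.frame with columns `line`, `env`, `unit`, `value`
#' @export
anova_records <- function(records, trait = c("GWC", "GDR")) {
  trait <- match.arg(trait)
  if (trait == "GWC") {
    agg <- stats::aggregate(gwc ~ line + trial + dap, data = records, FUN = mean)
    data.frame(line = agg$line, env = agg$trial, unit = agg$dap,
               value = agg$gwc, stringsAsFactors = FALSE)
  } else {
    daps <- sort(unique(records$dap))[1:2]
    e <- records[records$dap == daps[1L], c("line", "trial", "rep", "gwc")]
    l <- records[records$dap == daps[2L], c("line", "trial", "rep", "gwc")]
    m <- merge(e, l, by = c("line", "trial", "rep"), suffixes = c("_e", "_l"))
    data.frame(line = m$line, env = m$trial, unit = m$rep,
               value = m$gwc_e - m$gwc_l, stringsAsFactors = FALSE)
  }
}
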