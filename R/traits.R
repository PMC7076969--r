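#' Grain water content from kernel weights
#'
#' GWC (%) = (fresh weight - dry weight) / fresh weight x 100.
#'
#' @param fresh_g fresh weight in grams (> 0)
#' @param dry_g dry weight in grams (0 <= dry <= fresh)
#' @return GWC in percent, vectorized
#' @examples
#' compute_gwc(100, 60)   # 40
#' compute_gwc(13.50, 9.18)  # 32
#' @export
compute_gwc <- function(fresh_g, dry_g) {
  if (any(fresh_g <= 0)) stop("fresh weight must be positive")
  if (any(dry_g < 0)) stop("dry weight must be nonnegative")
  if (any(dry_g > fresh_g)) stop("dry weight exceeds fresh weight")
  100 * (fresh_g - dry_g) / fresh_g
}

#' Grain dehydration rate between two samplings
#'
#' GDR (%) = GWC(early sampling) - GWC(later sampling).  A negative
#' value (apparent re-wetting) is retained but raises a warning.
#'
#' @param gwc_early,gwc_later GWC percentages in [0, 100)
#' @return GDR in percentage points, vectorized
#' @export
compute_gdr <- function(gwc_early, gwc_later) {
  if (any(gwc_early < 0 | gwc_early >= 100) || any(gwc_later < 0 | gwc_later >= 100))
    stop("GWC values must lie in [0, 100)")
  gdr <- gwc_early - gwc_later
  if (any(gdr < 0)) warning("negative GDR (GWC increased between samplings)")
  gdr
}

#' Wide trait table per line / trial / replicate
#'
#' Builds the per-(line, trial, rep) table of GWC at each sampled DAP
#' and GDR for each pair of adjacent sampled DAPs, named `GWC45`,
#' `GWC50`, ..., `GDR45-50`, ....
#'
#' @param records trait records as returned by [simulate_phenotypes()]
#'   (columns `line`, `trial`, `rep`, `dap`, and `gwc` or weight
#'   columns `fresh_g`/`dry_g`)
#' @return data.frame with columns `line`, `trial`, `rep` and one
#'   column per trait
#' @export
trait_table <- function(records) {
  stopifnot(all(c("line", "trial", "rep", "dap") %in% names(records)))
  if (is.null(records$gwc))
    records$gwc <- compute_gwc(records$fresh_g, records$dry_g)
  out <- list()
  for (tr in unique(records$trial)) {
    sub <- records[records$trial == tr, ]
    daps <- sort(unique(sub$dap))
    wide <- stats::reshape(sub[, c("line", "rep", "dap", "gwc")],
                           idvar = c("line", "rep"), timevar = "dap",
                           direction = "wide")
    names(wide) <- sub("^gwc\\.", "GWC", names(wide))
    wide <- wide[order(wide$line, wide$rep), , drop = FALSE]
    if (length(daps) > 1L) {
      for (k in seq_len(length(daps) - 1L)) {
        nm <- sprintf("GDR%d-%d", daps[k], daps[k + 1L])
        e <- wide[[sprintf("GWC%d", daps[k])]]
        l <- wide[[sprintf("GWC%d", daps[k + 1L])]]
        wide[[nm]] <- suppressWarnings(compute_gdr(e, l))
      }
    }
    wide <- cbind(trial = tr, wide)
    out[[tr]] <- wide
  }
  # trials may be sampled at different DAP sets: bind with NA fill
  all_cols <- unique(unlist(lapply(out, names)))
  all_cols <- c(c("trial", "line", "rep"),
                setdiff(all_cols, c("trial", "line", "rep")))
  res <- do.call(rbind, lapply(out, function(d) {
    for (cl in setdiff(all_cols, names(d))) d[[cl]] <- NA_real_
    d[, all_cols]
  }))
  rownames(res) <- NULL
  res
}

#' Pairwise Pearson correlations with significance stars
#'
#' Pearson r for every pair of trait columns, with two-sided
#' significance from the t distribution marked `*` (P < 0.05), `**`
#' (P < 0.01) and `***` (P < 0.001).  Cells with fewer than 3 complete
#' pairs, or involving a constant column, are reported as missing.
#'
#' @param traits data.frame or matrix of numeric trait columns
#' @return list of class `correlation_table` with matrices `r`, `p`,
#'   `n`, character matrix `stars`, and `annotated` (r formatted with
#'   stars)
#' @export
correlation_table <- function(traits) {
  x <- as.matrix(traits)
  storage.mode(x) <- "double"
  p <- ncol(x)
  r <- pv <- nn <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- stats::complete.cases(x[, i], x[, j])
    nn[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; pv[i, j] <- 0; next }
    if (sum(ok) < 3L) next
    xi <- x[ok, i]; xj <- x[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    ct <- stats::cor.test(xi, xj)
    r[i, j] <- unname(ct$estimate)
    pv[i, j] <- ct$p.value
  }
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  diag(stars) <- ""
  ann <- matrix(ifelse(is.na(r), "",
                       paste0(formatC(r, digits = 2, format = "f"), " ", stars)),
                p, p, dimnames = dimnames(r))
  structure(list(r = r, p = pv, n = nn, stars = stars, annotated = ann),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  print(noquote(x$annotated), ...)
  invisible(x)
}

#' Read / write phenotype records as CSV
#'
#' Columns: `line`, `trial`, `rep`, `dap`, `fresh_g`, `dry_g` (a `gwc`
#' column, if present, is preserved).
#'
#' @param records trait record data.frame
#' @param path file path
#' @return `read_phenotypes_csv()` returns the records with `gwc`
#'   computed from the weights
#' @export
write_phenotypes_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "trial", "rep", "dap", "fresh_g", "dry_g") %in% names(df)))
  df$gwc <- compute_gwc(df$fresh_g, df$dry_g)
  df
}
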