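#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker carrying the
#' chromosome id, marker name, genetic position (cM) and physical position
#' (bp, 1-based).  Within a chromosome both coordinates must be
#' nondecreasing in marker order and marker names must be unique.
#'
#' @param chrom chromosome identifier (coerced to character)
#' @param marker marker name (unique across the map)
#' @param cM genetic position in centimorgans (>= 0)
#' @param bp physical position in base pairs (1-based integer)
#' @return a `data.frame` of class `genetic_map` with columns
#'   `chrom`, `marker`, `cM`, `bp`, ordered by chromosome and position
#' @export
genetic_map <- function(chrom, marker, cM, bp) {
  map <- data.frame(chrom = as.character(chrom), marker = as.character(marker),
                    cM = as.numeric(cM), bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$cM, map$bp), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  validate_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the map invariants: unique marker names, nonnegative cM, and
#' nondecreasing cM and bp within each chromosome.
#'
#' @param map a `genetic_map` (or compatible data frame)
#' @return the map, invisibly; errors on violation
#' @export
validate_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "marker", "cM", "bp") %in% names(map)))
  if (nrow(map) == 0L) stop("empty map")
  if (anyDuplicated(map$marker)) stop("marker names must be unique")
  if (any(map$cM < 0)) stop("cM positions must be >= 0")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$cM)) stop("cM not nondecreasing on chromosome ", ch)
    if (is.unsorted(sub$bp)) stop("bp not nondecreasing on chromosome ", ch)
  }
  invisible(map)
}

#' Default synthetic marker map
#'
#' Ten chromosomes of equally spaced markers totalling ~1522.5 cM, the
#' scale of a dense maize SNP linkage map.  Physical positions are laid
#' out at a constant 1.4 Mb/cM.
#'
#' @param n_chr number of chromosomes
#' @param markers_per_chr markers per chromosome
#' @param chr_length_cM genetic length of each chromosome (cM)
#' @param bp_per_cM physical bp per cM
#' @return a `genetic_map`
#' @export
synthetic_map <- function(n_chr = 10, markers_per_chr = 78,
                          chr_length_cM = 152.248, bp_per_cM = 1.4e6) {
  stopifnot(n_chr >= 1, markers_per_chr >= 2, chr_length_cM >= 0)
  pos <- seq(0, chr_length_cM, length.out = markers_per_chr)
  chrom <- rep(as.character(seq_len(n_chr)), each = markers_per_chr)
  marker <- paste0("S", chrom, "_", rep(seq_len(markers_per_chr), times = n_chr))
  genetic_map(chrom = chrom, marker = marker,
              cM = rep(pos, times = n_chr),
              bp = rep(round(pos * bp_per_cM) + 1, times = n_chr))
}

#' Map functions: cM to recombination fraction and back
#'
#' `cm_to_rf()` converts a genetic distance to a meiotic recombination
#' fraction under the Kosambi (default) or Haldane map function;
#' `rf_to_cm()` is the inverse.  Kosambi: r(d) = tanh(d/50)/2,
#' d(r) = 25 log((1+2r)/(1-2r)).  Haldane: r(d) = (1 - exp(-d/50))/2.
#'
#' @param d genetic distance in cM (>= 0)
#' @param r recombination fraction in [0, 0.5)
#' @param method `"kosambi"` or `"haldane"`
#' @return numeric vector of the converted quantity
#' @export
cm_to_rf <- function(d, method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  stopifnot(all(d >= 0))
  switch(method,
         kosambi = 0.5 * tanh(d / 50),
         haldane = 0.5 * (1 - exp(-d / 50)))
}

#' @rdname cm_to_rf
#' @export
rf_to_cm <- function(r, method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must lie in [0, 0.5)")
  switch(method,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' Read / write a marker map as TSV
#'
#' The TSV carries the header `chrom marker cM bp`.
#'
#' @param path file path
#' @param map a `genetic_map`
#' @return `read_map_tsv()` returns a `genetic_map`;
#'   `write_map_tsv()` returns `path` invisibly
#' @export
read_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "marker", "cM", "bp") %in% names(df)))
  genetic_map(df$chrom, df$marker, df$cM, df$bp)
}

#' @rdname read_map_tsv
#' @export
write_map_tsv <- function(map, path) {
  validate_map(map)
  utils::write.table(as.data.frame(map)[, c("chrom", "marker", "cM", "bp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split row indices of a map by chromosome, preserving order
.map_chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)
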