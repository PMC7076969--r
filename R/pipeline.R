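# End-to-end orchestration: a schema-validated run configuration, a
# single root seed fanned out to named per-stage substreams, and a run
# directory with stage outputs plus a reproducible manifest.

#' Default run configuration
#'
#' Every stage parameter defaults to the study-standard value where one
#' exists: LOD floor 2.5, 1000 permutations, 20% marker QC rates,
#' verdict threshold P <= 0.05, major-QTL rule R2 > 10%.
#'
#' @return nested named list understood by [run_pipeline()]
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, traits = TRUE, map_qc = TRUE,
                  scan = TRUE, variance = TRUE, finemap = TRUE),
    map = list(n_chr = 10L, markers_per_chr = 78L, chr_length_cM = 152.248),
    population = list(n_lines = 362L, n_selfing = 8L,
                      n_pheno_lines = c(84L, 119L, 117L)),
    truth = list(qtl_chrom = "1", qtl_cM = 75, a = 1.655, d = 0.075,
                 sigma2_G = 4.5, sigma2_GxE = 3, sigma2_e = 3),
    qc = list(max_missing = 0.2, max_het = 0.2, distortion_alpha = 0.05),
    scan = list(step_cM = 1, n_perm = 1000L, alpha = 0.05, lod_floor = 2.5,
                major_r2 = 10, trait_dap = 45),
    finemap = list(rounds = 4L, family_size = 80L,
                   n_recombinants = c(11L, 9L, 18L, 11L), alpha = 0.05,
                   scheme = "self", sd_gwc = 2.5, a = 1.655, d = 0.075,
                   qtl_mb = 76.6)
  )
}

# merge a user config onto the defaults, rejecting unknown keys
.merge_config <- function(user, template, path = "") {
  if (is.null(user)) return(template)
  if (!is.list(template)) return(user)
  if (!is.list(user)) stop("config entry '", path, "' must be a list")
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user))
    template[[k]] <- .merge_config(user[[k]], template[[k]],
                                   paste0(path, ".", k))
  template
}

#' Validate a run configuration
#'
#' Merges a partial configuration (a list, or a path to a YAML file)
#' onto [default_run_config()], rejecting unknown keys before any
#' stage runs.
#'
#' @param config partial configuration list or YAML file path
#' @return the complete, validated configuration list
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(config, default_run_config())
  stopifnot(cfg$seed == as.integer(cfg$seed))
  cfg
}

# named substream seeds derived from the root seed
.stage_seed <- function(root, stage) {
  offsets <- c(simulate = 1L, traits = 2L, map_qc = 3L, scan = 4L,
               variance = 5L, finemap = 6L)
  (as.integer(root) %% 2000000L) * 1000L + offsets[[stage]]
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order — simulate the
#' population, compute traits and correlations, marker QC and map
#' re-estimation, genome scan with permutation threshold and QTL
#' calls, variance components / heritability / BLUP, and sequential
#' fine-mapping — writing each stage's outputs and a manifest (file
#' checksums, record counts, the config and its hash) into `out_dir`.
#' Identical config and seed reproduce byte-identical outputs.
#'
#' @param config partial run configuration (see
#'   [validate_run_config()])
#' @param out_dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  counts <- list()
  add_file <- function(f) files <<- c(files, f)

  map <- synthetic_map(cfg$map$n_chr, cfg$map$markers_per_chr,
                       cfg$map$chr_length_cM)
  truth <- truth_model(cfg$truth$qtl_chrom, cfg$truth$qtl_cM, cfg$truth$a,
                       cfg$truth$d, cfg$truth$sigma2_G, cfg$truth$sigma2_GxE,
                       cfg$truth$sigma2_e)
  designs <- default_trial_designs()
  geno <- NULL; phen <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    set.seed(.stage_seed(cfg$seed, "simulate"))
    geno <- derive_ril_population(cfg$population$n_lines, map,
                                  n_selfing = cfg$population$n_selfing)
    phen <- simulate_phenotypes(geno, map, truth, designs,
                                n_pheno_lines = cfg$population$n_pheno_lines)
    add_file(write_map_tsv(map, file.path(out_dir, "map.tsv")))
    add_file(write_genotypes_csv(geno, file.path(out_dir, "genotypes.csv")))
    add_file(write_phenotypes_csv(phen, file.path(out_dir, "phenotypes.csv")))
    jsonlite::write_json(c(unclass(truth), list(seed = cfg$seed)),
                         file.path(out_dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    add_file(file.path(out_dir, "truth.json"))
    counts$lines <- nrow(geno); counts$phenotype_records <- nrow(phen)
  }

  if (isTRUE(cfg$stages$traits) && !is.null(phen)) {
    tt <- trait_table(phen)
    utils::write.csv(tt, file.path(out_dir, "traits.csv"), row.names = FALSE)
    add_file(file.path(out_dir, "traits.csv"))
    cors <- list()
    for (tr in unique(tt$trial)) {
      cols <- grep("^(GWC|GDR)", names(tt), value = TRUE)
      sub <- tt[tt$trial == tr, cols]
      sub <- sub[, colSums(!is.na(sub)) > 0, drop = FALSE]
      ct <- correlation_table(sub)
      idx <- which(upper.tri(ct$r), arr.ind = TRUE)
      cors[[tr]] <- data.frame(trial = tr,
                               trait1 = rownames(ct$r)[idx[, 1L]],
                               trait2 = colnames(ct$r)[idx[, 2L]],
                               r = ct$r[idx], p = ct$p[idx],
                               stars = ct$stars[idx],
                               stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, cors),
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    add_file(file.path(out_dir, "correlations.csv"))
    counts$trait_rows <- nrow(tt)
  }

  if (isTRUE(cfg$stages$map_qc) && !is.null(geno)) {
    parents <- rbind(rep("A", nrow(map)), rep("B", nrow(map)))
    colnames(parents) <- map$marker
    qc <- filter_markers(geno, parents, max_missing = cfg$qc$max_missing,
                         max_het = cfg$qc$max_het,
                         distortion_alpha = cfg$qc$distortion_alpha)
    utils::write.csv(qc, file.path(out_dir, "marker_qc.csv"), row.names = FALSE)
    add_file(file.path(out_dir, "marker_qc.csv"))
    kept <- map[map$marker %in% qc$marker[qc$keep], ]
    remap <- rebuild_map(geno, kept)
    add_file(write_map_tsv(remap, file.path(out_dir, "map_rebuilt.tsv")))
    counts$markers_kept <- sum(qc$keep)
  }

  scan_res <- NULL
  if (isTRUE(cfg$stages$scan) && !is.null(phen)) {
    set.seed(.stage_seed(cfg$seed, "scan"))
    tr1 <- designs[[1L]]$trial
    sub <- phen[phen$trial == tr1 & phen$dap == cfg$scan$trait_dap, ]
    yagg <- stats::aggregate(gwc ~ line, data = sub, FUN = mean)
    y <- yagg$gwc[match(rownames(geno), yagg$line)]
    gp <- genotype_probabilities(geno, map, step_cM = cfg$scan$step_cM)
    scan_res <- interval_mapping_scan(gp, y)
    thr <- permutation_threshold(gp, y, n_perm = cfg$scan$n_perm,
                                 alpha = cfg$scan$alpha)
    declared <- max(cfg$scan$lod_floor, thr)
    calls <- call_qtl(scan_res, declared, map)
    utils::write.csv(as.data.frame(scan_res), file.path(out_dir, "scan.csv"),
                     row.names = FALSE)
    utils::write.csv(calls, file.path(out_dir, "qtl_calls.csv"),
                     row.names = FALSE)
    add_file(file.path(out_dir, "scan.csv"))
    add_file(file.path(out_dir, "qtl_calls.csv"))
    counts$scan_positions <- nrow(scan_res)
    counts$qtl_calls <- nrow(calls)
    counts$lod_threshold <- as.numeric(declared)
  }

  if (isTRUE(cfg$stages$variance) && !is.null(phen)) {
    comps <- anova_components(anova_records(phen, "GWC"))
    h2 <- heritability(comps)
    blup <- blup_predict(phen)
    jsonlite::write_json(list(sigma2_G = comps$sigma2_G,
                              sigma2_GxE = comps$sigma2_GxE,
                              sigma2_e = comps$sigma2_e,
                              l = comps$l, r = comps$r,
                              method = comps$method, h2 = h2),
                         file.path(out_dir, "variance.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(blup, file.path(out_dir, "blup.csv"), row.names = FALSE)
    add_file(file.path(out_dir, "variance.json"))
    add_file(file.path(out_dir, "blup.csv"))
    counts$h2_gwc <- h2
  }

  if (isTRUE(cfg$stages$finemap)) {
    fm <- run_sequential_finemap(
      qtl_bp = cfg$finemap$qtl_mb * 1e6, a = cfg$finemap$a, d = cfg$finemap$d,
      sd_gwc = cfg$finemap$sd_gwc, rounds = cfg$finemap$rounds,
      n_recombinants = cfg$finemap$n_recombinants,
      family_size = cfg$finemap$family_size, scheme = cfg$finemap$scheme,
      alpha = cfg$finemap$alpha, seed = .stage_seed(cfg$seed, "finemap"))
    tab <- finemap_table(fm)
    utils::write.csv(tab, file.path(out_dir, "finemap_table.csv"),
                     row.names = FALSE)
    trace <- lapply(fm$trace, function(tr) list(
      round = tr$round, interval_in = tr$interval_in,
      interval_out = c(tr$inference$lo_bp, tr$inference$hi_bp),
      left_marker = tr$inference$left_marker,
      right_marker = tr$inference$right_marker,
      length_mb = tr$inference$length_mb,
      consistent = tr$inference$consistent,
      verdicts = stats::setNames(as.list(tr$types$verdict), tr$types$type)))
    jsonlite::write_json(list(rounds = trace,
                              final_interval_bp = fm$interval,
                              final_length_mb = fm$length_mb),
                         file.path(out_dir, "finemap_trace.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    add_file(file.path(out_dir, "finemap_table.csv"))
    add_file(file.path(out_dir, "finemap_trace.json"))
    counts$finemap_rounds <- fm$rounds_run
    counts$finemap_length_mb <- fm$length_mb
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  add_file(cfg_path)
  manifest <- list(
    package = "gwcqtl",
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = counts,
    files = lapply(stats::setNames(nm = sort(basename(files))), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
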