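## End-to-end orchestration: a YAML config drives simulate -> annotate ->
## normalize -> quantify -> dmr -> enrich -> structure -> inddiff ->
## network, writing tables, tracks and a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    outdir = "medipnet_run",
    seed = 1L,
    input = list(fixtures = NULL),      # NULL -> simulate from scratch
    simulate = list(),                  # overrides for sim_config()
    normalize = list(bin_size = 500L, step = 250L, max_distance = 500L,
                     min_bins_per_level = 10L),
    quantify = list(mode = "rms"),
    dmr = list(group_by = "tissue_group", top_k = 50L, cv_gt = 1.0),
    inddiff = list(ind_a = "ind1", ind_b = "ind2", reference = "blood",
                   n_perm = 1000L),
    network = list(beta = 6L, signed = TRUE, min_module_size = 30L,
                   cut_height = 0.95, max_features = 2000L,
                   pseudocount = 1))
}

known_keys <- function(defaults) {
  out <- character(0)
  for (k in names(defaults)) {
    out <- c(out, k)
    if (is.list(defaults[[k]]) && length(names(defaults[[k]])))
      out <- c(out, paste0(k, ".", names(defaults[[k]])))
  }
  c(out, paste0("simulate.", names(formals(sim_config))))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and collects every
#' problem - unknown keys (with a closest-match suggestion), type or range
#' errors, missing input paths - reporting them together.
#'
#' @param config path to a YAML file, or a named list.
#' @return the normalized config (class `pipeline_config`), or an error
#'   listing all problems.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- pipeline_defaults()
  errors <- character(0)
  ## unknown keys, with suggestions
  ok_keys <- known_keys(defaults)
  flat <- c(names(config),
            unlist(lapply(names(config), function(k)
              if (is.list(config[[k]]) && length(names(config[[k]])))
                paste0(k, ".", names(config[[k]])) else character(0))))
  for (k in setdiff(flat, ok_keys)) {
    sug <- agrep(k, ok_keys, max.distance = 0.3, value = TRUE)
    errors <- c(errors, sprintf("unknown key '%s'%s", k,
      if (length(sug)) sprintf(" (did you mean '%s'?)", sug[1]) else ""))
  }
  ## merge over defaults
  cfg <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]]) && is.list(config[[k]])) {
      for (kk in intersect(names(config[[k]]), c(names(defaults[[k]]),
                                                 names(formals(sim_config)))))
        cfg[[k]][[kk]] <- config[[k]][[kk]]
    } else cfg[[k]] <- config[[k]]
  }
  ## range checks
  nz <- cfg$normalize
  if (!is.numeric(nz$bin_size) || nz$bin_size <= 0)
    errors <- c(errors, "normalize.bin_size must be a positive number")
  if (is.numeric(nz$step) && is.numeric(nz$bin_size) &&
      nz$step > nz$bin_size)
    errors <- c(errors,
                "normalize.step must not exceed normalize.bin_size")
  if (!cfg$quantify$mode %in% c("rms", "rpkm"))
    errors <- c(errors, "quantify.mode must be 'rms' or 'rpkm'")
  if (cfg$network$cut_height <= 0 || cfg$network$cut_height > 1)
    errors <- c(errors, "network.cut_height must be in (0, 1]")
  if (!is.null(cfg$input$fixtures) && !dir.exists(cfg$input$fixtures))
    errors <- c(errors, sprintf("input.fixtures directory not found: %s",
                                cfg$input$fixtures))
  if (length(errors))
    stopf("invalid pipeline config:\n  - %s",
          paste(errors, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full methylome analysis pipeline
#'
#' Executes every stage under a validated config and writes all tables,
#' tracks and a manifest (seed, parameters, output checksums) to the run
#' directory. Reruns with the same config are byte-identical. On stage
#' failure, partial outputs are kept under a `failed/` marker file naming
#' the stage.
#'
#' @param config a path, list or `pipeline_config`.
#' @return (invisibly) a list with the in-memory results of each stage and
#'   the run directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- "setup"
  res <- list(outdir = outdir)
  on.exit({
    if (!identical(stage, "done")) {
      writeLines(sprintf("pipeline failed at stage: %s", stage),
                 file.path(outdir, "failed"))
    }
  })
  log_line <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                                 stage, ...))

  ## --- inputs -------------------------------------------------------
  stage <- "simulate"
  sim_args <- cfg$simulate
  sim_args$seed <- sim_args$seed %||% cfg$seed
  scfg <- do.call(sim_config, sim_args)
  if (!is.null(cfg$input$fixtures)) {
    fx <- read_fixtures(cfg$input$fixtures)
    genome <- fx$genome
    counts <- fx$counts; bins <- fx$bins; metadata <- fx$metadata
    log_line("loaded fixtures from %s", cfg$input$fixtures)
  } else {
    study <- simulate_study(scfg)
    genome <- study$genome
    counts <- study$experiment$counts
    bins <- study$experiment$bins
    metadata <- study$experiment$metadata
    res$methylome <- study$methylome
    write_fixtures(genome, study$experiment, file.path(outdir, "fixtures"))
    log_line("simulated %d bins x %d samples", nrow(counts), ncol(counts))
  }
  res$genome <- genome

  stage <- "annotate"
  features <- annotate_features(genome)
  fdf <- data.frame(feature_id = mcols(features)$feature_id,
                    chrom = as.character(seqnames(features)),
                    start = start0(features), end = end0(features),
                    class = mcols(features)$class,
                    gene_id = mcols(features)$gene_id)
  write_tsv(fdf, file.path(outdir, "features.tsv"))
  res$features <- features

  stage <- "normalize"
  norm <- medip_normalize(counts, bins, genome$cpg,
                          max_distance = cfg$normalize$max_distance,
                          min_bins = cfg$normalize$min_bins_per_level)
  res$norm <- norm
  rms_df <- data.frame(bin = rownames(norm$rms), cf = norm$cf, norm$rms,
                       check.names = FALSE)
  write_tsv(rms_df, file.path(outdir, "bin_rms.tsv"))
  trackdir <- file.path(outdir, "tracks")
  dir.create(trackdir, showWarnings = FALSE)
  for (s in colnames(norm$rms))
    write_bedgraph(norm$rms[, s], bins,
                   file.path(trackdir, paste0(s, ".bedGraph")))

  stage <- "quantify"
  qx <- if (cfg$quantify$mode == "rms") norm$rms else counts
  se <- quantify_features(qx, bins, features, metadata,
                          mode = cfg$quantify$mode)
  res$se <- se
  write_tsv(data.frame(feature_id = rownames(fmm_values(se)),
                       fmm_values(se), check.names = FALSE),
            file.path(outdir, "feature_matrix.tsv"))

  stage <- "dmr"
  records <- cv_rank(se, group_by = cfg$dmr$group_by)
  write_tsv(records, file.path(outdir, "cv_ranked.tsv"))
  dmrs <- select_dmrs(records, top_k = cfg$dmr$top_k)
  write_tsv(dmrs, file.path(outdir, "top_dmrs.tsv"))
  res$records <- records; res$dmrs <- dmrs

  stage <- "enrich"
  cgi_rec <- records[grepl("^CGI_", records$class), ]
  enr_set <- select_dmrs(cgi_rec, top_k = min(cfg$dmr$top_k, nrow(cgi_rec)))
  enr <- enrichment_oe(enr_set, cgi_rec)
  write_tsv(enr$table, file.path(outdir, "enrichment.tsv"))
  res$enrichment <- enr

  stage <- "structure"
  corr <- sample_correlation(se)
  write_tsv(data.frame(sample_id = rownames(corr), corr,
                       check.names = FALSE),
            file.path(outdir, "sample_correlation.tsv"))
  tree <- cluster_samples(corr)
  pca <- pca_samples(se)
  write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            file.path(outdir, "pca_scores.tsv"))
  res$corr <- corr; res$tree <- tree; res$pca <- pca

  stage <- "inddiff"
  idc <- cfg$inddiff
  have <- unique(fmm_meta(se)$individual_id)
  if (all(c(idc$ind_a, idc$ind_b) %in% have)) {
    ind <- individual_differences(se, idc$ind_a, idc$ind_b,
                                  reference = idc$reference,
                                  n_perm = idc$n_perm,
                                  seed = derive_seed(cfg$seed, "inddiff"))
    write_tsv(ind$correlations, file.path(outdir, "inddiff_cor.tsv"))
    res$inddiff <- ind
  } else log_line("individuals %s/%s absent; stage skipped",
                  idc$ind_a, idc$ind_b)

  stage <- "network"
  nw <- cfg$network
  net <- comethylation_network(se, beta = nw$beta, signed = nw$signed,
                               min_size = nw$min_module_size,
                               cut_height = nw$cut_height,
                               max_features = nw$max_features,
                               pseudocount = nw$pseudocount)
  gs <- net$stats$GS
  write_tsv(data.frame(feature_id = names(net$labels),
                       module = unname(net$labels),
                       MM = unname(net$stats$MM),
                       gs[match(names(net$labels), rownames(gs)), ,
                          drop = FALSE],
                       check.names = FALSE),
            file.path(outdir, "modules.tsv"))
  write_tsv(data.frame(sample_id = rownames(net$ME), net$ME,
                       check.names = FALSE),
            file.path(outdir, "module_eigengenes.tsv"))
  write_tsv(net$stats$module_trait,
            file.path(outdir, "module_trait_cor.tsv"))
  res$network <- net

  stage <- "manifest"
  cfg_plain <- unclass(cfg)
  cfg_path <- file.path(outdir, "params.yaml")
  yaml::write_yaml(cfg_plain, cfg_path)
  ## hash effective parameters only (the run directory is not one)
  hash_cfg <- cfg_plain
  hash_cfg$outdir <- NULL
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hash_cfg, hash_path)
  outs <- sort(setdiff(list.files(outdir, recursive = TRUE),
                       c("manifest.yaml", "failed")))
  sums <- tools::md5sum(file.path(outdir, outs))
  manifest <- list(
    package = "medipnet",
    version = as.character(utils::packageVersion("medipnet")),
    seed = cfg$seed,
    parameter_hash = unname(tools::md5sum(hash_path)),
    outputs = as.list(setNames(unname(sums), outs)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  res$manifest <- manifest

  stage <- "done"
  if (file.exists(file.path(outdir, "failed")))
    unlink(file.path(outdir, "failed"))
  invisible(res)
}

#' Path of the bundled demo configuration
#' @return path to the demo YAML shipped with the package.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "medipnet",
              mustWork = TRUE)
}
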