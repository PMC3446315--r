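## Synthetic methylome generator. Emulates, at desk scale, the structure of
## a multi-tissue MeDIP-seq study: a CpG landscape with island-like
## clusters, gene models, per-tissue/per-individual methylation states with
## planted tissue-specific DMRs concentrated in chosen feature classes, and
## MeDIP-like read counts whose expectation depends jointly on methylation
## and local CpG density (the very confounding the coupling-factor
## normalization corrects).

#' Simulation configuration
#'
#' Collects every knob of the synthetic methylome generator with validated
#' defaults. Defaults define the package's standard study conditions:
#' three tissues (cortex, cerebellum, blood) sampled from the same three
#' individuals, planted tissue-specific DMR shifts of 0.4, and intragenic
#' CGIs enriched two-fold for planted DMRs.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length, bp.
#' @param cgi_per_mb CpG-island density per megabase.
#' @param cgi_len_range CGI length range, bp.
#' @param cgi_class_mix named proportions of CGIs anchored at promoters,
#'   gene bodies, 3' UTRs, or intergenic space.
#' @param cpg_rate_background,cpg_rate_island per-bp CpG probability
#'   outside/inside islands.
#' @param genes_per_chrom,gene_len_range,utr3_len gene-model geometry.
#' @param tissues character vector of tissue names.
#' @param n_individuals individuals per tissue (shared across tissues).
#' @param library_size expected reads per sample.
#' @param dmr_frac named per-class fraction of features receiving a planted
#'   tissue-specific shift; the `default` entry covers unlisted classes.
#' @param delta planted DMR effect size on the methylation scale.
#' @param noise_sd residual per-sample noise SD.
#' @param ind_sd SD of per-individual methylation deviations.
#' @param rho_individual cross-tissue correlation of individual deviations,
#'   in \[0,1\] (shared/private variance construction).
#' @param bg_meth mean methylation level of unannotated genome.
#' @param bg_meth_sd between-bin SD of background methylation (unannotated
#'   genome varies continuously around `bg_meth`, shared across samples).
#' @param half_saturation half-saturation constant K of the capture
#'   efficiency g(CF) = CF/(CF+K).
#' @param medip_background nonspecific pulldown rate added to every bin.
#' @param overdispersion Gamma mixing variance for the count model
#'   (0 = pure Poisson, the default).
#' @param bin_size,bin_step,max_distance binning/CF parameters forwarded to
#'   the normalization stage.
#' @param seed integer global seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 300000L,
                       cgi_per_mb = 40,
                       cgi_len_range = c(500L, 1500L),
                       cgi_class_mix = c(promoter = 0.35, intragenic = 0.25,
                                         utr3 = 0.15, intergenic = 0.25),
                       cpg_rate_background = 0.01,
                       cpg_rate_island = 0.10,
                       genes_per_chrom = 15L,
                       gene_len_range = c(3000L, 8000L),
                       utr3_len = 500L,
                       tissues = c("cortex", "cerebellum", "blood"),
                       n_individuals = 3L,
                       library_size = 2e5,
                       dmr_frac = c(default = 0.05, CGI_INTRAGENIC = 0.10),
                       delta = 0.4,
                       noise_sd = 0.05,
                       ind_sd = 0.1,
                       rho_individual = 0.7,
                       bg_meth = 0.7,
                       bg_meth_sd = 0.1,
                       half_saturation = 10,
                       medip_background = 0.02,
                       overdispersion = 0,
                       bin_size = 500L,
                       bin_step = 250L,
                       max_distance = 500L,
                       seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              cgi_per_mb = cgi_per_mb, cgi_len_range = cgi_len_range,
              cgi_class_mix = cgi_class_mix,
              cpg_rate_background = cpg_rate_background,
              cpg_rate_island = cpg_rate_island,
              genes_per_chrom = as.integer(genes_per_chrom),
              gene_len_range = gene_len_range,
              utr3_len = as.integer(utr3_len),
              tissues = tissues, n_individuals = as.integer(n_individuals),
              library_size = library_size, dmr_frac = dmr_frac,
              delta = delta, noise_sd = noise_sd, ind_sd = ind_sd,
              rho_individual = rho_individual, bg_meth = bg_meth,
              bg_meth_sd = bg_meth_sd,
              half_saturation = half_saturation,
              medip_background = medip_background,
              overdispersion = overdispersion,
              bin_size = as.integer(bin_size),
              bin_step = as.integer(bin_step),
              max_distance = as.integer(max_distance),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cpg_rate_background = cfg$cpg_rate_background,
             cpg_rate_island = cfg$cpg_rate_island,
             bg_meth = cfg$bg_meth)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) stopf("probabilities out of [0,1]: %s",
                         paste(bad, collapse = ", "))
  if (any(cfg$dmr_frac < 0 | cfg$dmr_frac > 1))
    stopf("dmr_frac values must be in [0,1]")
  if (cfg$rho_individual < 0 || cfg$rho_individual > 1)
    stopf("rho_individual must be in [0,1]")
  if (cfg$delta < 0 || cfg$delta > 1) stopf("delta must be in [0,1]")
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1)
    stopf("need at least one chromosome of positive length")
  if (cfg$library_size <= 0) stopf("library_size must be positive")
  if (abs(sum(cfg$cgi_class_mix) - 1) > 1e-8)
    stopf("cgi_class_mix must sum to 1")
  invisible(cfg)
}

## place n non-overlapping intervals of given lengths in [0, L) with a
## minimum gap; returns sorted 0-based starts or errors if they cannot fit
place_nonoverlapping <- function(n, lens, L, min_gap) {
  if (n == 0L) return(integer(0))
  free <- L - sum(lens) - (n - 1L) * min_gap
  if (free < 0)
    stopf("cannot place %d intervals (total %d bp + gaps) on a %d bp chrom",
          n, sum(lens), L)
  cuts <- sort(runif(n, 0, free))
  offsets <- c(0, cumsum(lens[-n] + min_gap))
  as.integer(floor(cuts)) + as.integer(offsets)
}

## CpG positions on one chromosome: two-rate process (island vs background)
draw_cpgs <- function(L, islands0, rate_bg, rate_is) {
  ## islands0: data.frame(start0, end0)
  segs_s <- 0L; segs_e <- integer(0); rates <- numeric(0)
  pos <- integer(0)
  bound <- c(0L)
  if (nrow(islands0)) {
    o <- order(islands0$start0)
    islands0 <- islands0[o, ]
  }
  prev <- 0L
  draw_seg <- function(s, e, rate) {
    len <- e - s
    if (len <= 0 || rate <= 0) return(integer(0))
    k <- rbinom(1L, len, rate)
    if (k == 0L) return(integer(0))
    s + sort(sample.int(len, k)) - 1L
  }
  if (nrow(islands0)) {
    for (i in seq_len(nrow(islands0))) {
      pos <- c(pos, draw_seg(prev, islands0$start0[i], rate_bg))
      pos <- c(pos, draw_seg(islands0$start0[i], islands0$end0[i], rate_is))
      prev <- islands0$end0[i]
    }
  }
  pos <- c(pos, draw_seg(prev, L, rate_bg))
  pos
}

#' Simulate a toy genome with CpG landscape, islands and gene models
#'
#' Genes are placed non-overlapping per chromosome; CGIs are anchored to
#' gene features according to `cgi_class_mix` (at promoters, inside gene
#' bodies, at 3' UTRs, or in intergenic space) so all four CGI location
#' classes arise with usable counts. CpG positions follow a two-rate
#' Bernoulli process along the chromosome: a background rate outside
#' islands and an elevated rate inside. Promoter-anchored genes receive a
#' high `promoter_gc`, others a lower one, so promoter CpG classes span
#' HCP/ICP/LCP.
#'
#' @param config a [sim_config()].
#' @return a `SyntheticGenome`: list with `chrom_lengths`, `cpg`, `cgis`,
#'   `genes` (all `GRanges`).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  if (config$cpg_rate_island <= config$cpg_rate_background)
    warnf("island CpG rate <= background rate: islands not distinguishable")
  set.seed(derive_seed(config$seed, "genome"))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms),
                            sprintf("chr%d", seq_len(config$n_chroms)))
  genes_l <- list(); cgis_l <- list(); cpg_l <- list()
  n_cgi <- max(0L, round(config$cgi_per_mb * config$chrom_length / 1e6))
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    ng <- config$genes_per_chrom
    glens <- as.integer(round(runif(ng, config$gene_len_range[1],
                                    config$gene_len_range[2])))
    gstarts <- place_nonoverlapping(ng, glens, L, min_gap = 6000L)
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    ## CGI anchoring
    n_by <- round(n_cgi * config$cgi_class_mix)
    clens <- as.integer(round(runif(sum(n_by), config$cgi_len_range[1],
                                    config$cgi_len_range[2])))
    anchors <- rep(names(config$cgi_class_mix), n_by)
    cl_i <- 0L
    cgi_s <- integer(0); cgi_e <- integer(0)
    host <- sample(rep_len(seq_len(ng), sum(n_by)))
    for (a in seq_along(anchors)) {
      cl_i <- cl_i + 1L
      len <- clens[cl_i]
      g <- host[a]
      s <- switch(anchors[a],
        promoter = if (gstrand[g] == "+") gstarts[g] - len %/% 2L else
          gstarts[g] + glens[g] - len %/% 2L,
        intragenic = gstarts[g] + glens[g] %/% 2L - len %/% 2L,
        utr3 = if (gstrand[g] == "+")
          gstarts[g] + glens[g] - config$utr3_len %/% 2L - len %/% 2L else
          gstarts[g] + config$utr3_len %/% 2L - len %/% 2L,
        intergenic = {
          gap_mid <- if (g < ng) (gstarts[g] + glens[g] + gstarts[g + 1L]) %/% 2L
                     else min(L - len - 2100L, gstarts[g] + glens[g] + 3000L)
          gap_mid - len %/% 2L
        })
      s <- max(0L, min(as.integer(s), L - len))
      cgi_s <- c(cgi_s, s); cgi_e <- c(cgi_e, s + len)
    }
    ## drop CGIs overlapping a previously placed CGI (keep first)
    if (length(cgi_s)) {
      o <- order(cgi_s)
      cgi_s <- cgi_s[o]; cgi_e <- cgi_e[o]
      anchors <- anchors[o]; hosts_o <- host[seq_along(anchors)][o]
      keep <- rep(TRUE, length(cgi_s))
      last_end <- -1L
      for (i in seq_along(cgi_s)) {
        if (cgi_s[i] < last_end) keep[i] <- FALSE
        else last_end <- cgi_e[i]
      }
      cgi_s <- cgi_s[keep]; cgi_e <- cgi_e[keep]; anchors <- anchors[keep]
      hosts_o <- hosts_o[keep]
    } else hosts_o <- integer(0)
    ## high-GC promoters for promoter-anchored genes
    pg <- runif(ng, 0.35, 0.50)
    pg[unique(hosts_o[anchors == "promoter"])] <- runif(
      length(unique(hosts_o[anchors == "promoter"])), 0.58, 0.68)
    cpg_pos <- draw_cpgs(L, data.frame(start0 = cgi_s, end0 = cgi_e),
                         config$cpg_rate_background, config$cpg_rate_island)
    genes_l[[ch]] <- data.frame(chrom = rep(ch, length(gstarts)),
                                start0 = gstarts, end0 = gstarts + glens,
                                strand = gstrand, promoter_gc = pg)
    cgis_l[[ch]] <- data.frame(chrom = rep(ch, length(cgi_s)),
                               start0 = cgi_s, end0 = cgi_e)
    cpg_l[[ch]] <- data.frame(chrom = rep(ch, length(cpg_pos)),
                              pos0 = cpg_pos)
  }
  gdf <- do.call(rbind, genes_l)
  genes <- gr0(gdf$chrom, gdf$start0, gdf$end0, strand = gdf$strand,
               chrom_lengths = chrom_lengths)
  mcols(genes)$gene_id <- sprintf("g%03d", seq_along(genes))
  mcols(genes)$utr3_len <- config$utr3_len
  mcols(genes)$promoter_gc <- gdf$promoter_gc
  cdf <- do.call(rbind, cgis_l)
  cgis <- if (nrow(cdf)) gr0(cdf$chrom, cdf$start0, cdf$end0,
                             chrom_lengths = chrom_lengths) else GRanges()
  pdf <- do.call(rbind, cpg_l)
  cpg <- if (nrow(pdf)) gr0(pdf$chrom, pdf$pos0, pdf$pos0 + 1L,
                            chrom_lengths = chrom_lengths) else GRanges()
  structure(list(chrom_lengths = chrom_lengths, cpg = cpg,
                 cgis = sort_features(cgis), genes = sort_features(genes)),
            class = "SyntheticGenome")
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat(sprintf("SyntheticGenome: %d chrom(s), %s bp total, %d CpGs, %d CGIs, %d genes\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              length(x$cpg), length(x$cgis), length(x$genes)))
  invisible(x)
}

## baseline methylation by feature class: promoter CGIs / HCPs low, gene
## bodies high, LCPs highest
baseline_methylation <- c(
  CGI_PROMOTER = 0.10, CGI_INTRAGENIC = 0.45, CGI_3UTR = 0.45,
  CGI_INTERGENIC = 0.40, SHORE_PROMOTER = 0.55, SHORE_INTRAGENIC = 0.55,
  SHORE_3UTR = 0.55, SHORE_INTERGENIC = 0.55, CDS = 0.70,
  HCP = 0.15, ICP = 0.55, LCP = 0.80)

#' Simulate true per-feature methylation with planted structure
#'
#' Builds the annotated feature universe of the genome, assigns each class
#' its canonical baseline methylation (promoter CGIs and HCPs
#' hypomethylated, gene bodies and LCPs high), then plants
#' tissue-specific DMRs: a configured per-class fraction of features gets a
#' shift of `delta` in one randomly chosen tissue, directed away from the
#' nearer methylation bound. Individual deviations are drawn per
#' (feature, individual) from a shared + tissue-private construction so
#' their cross-tissue correlation equals `rho_individual` in expectation.
#'
#' @param genome a `SyntheticGenome`.
#' @param config a [sim_config()].
#' @return a `TrueMethylome`: list with array `m` (feature x tissue x
#'   individual, values in \[0,1\]), the `features` GRanges, the
#'   `planted_dmrs` table and the effective `config`.
#' @export
simulate_methylome <- function(genome, config) {
  set.seed(derive_seed(config$seed, "methylome"))
  features <- annotate_features(genome)
  n <- length(features)
  cls <- mcols(features)$class
  tissues <- config$tissues
  inds <- sprintf("ind%d", seq_len(config$n_individuals))
  base <- unname(baseline_methylation[cls])
  base[is.na(base)] <- 0.5
  ## plant tissue-specific DMRs per class
  frac_default <- unname(config$dmr_frac["default"])
  if (is.na(frac_default)) frac_default <- 0
  planted <- data.frame(feature_id = character(0), class = character(0),
                        tissue = character(0), delta = numeric(0))
  shift <- matrix(0, n, length(tissues),
                  dimnames = list(names(features), tissues))
  for (k in unique(cls)) {
    idx <- which(cls == k)
    frac <- config$dmr_frac[k]
    if (is.na(frac)) frac <- frac_default
    n_dmr <- round(frac * length(idx))
    if (n_dmr == 0) next
    chosen <- sample(idx, n_dmr)
    t_pick <- sample(seq_along(tissues), n_dmr, replace = TRUE)
    sgn <- ifelse(base[chosen] < 0.5, 1, -1)
    for (j in seq_len(n_dmr))
      shift[chosen[j], t_pick[j]] <- sgn[j] * config$delta
    planted <- rbind(planted, data.frame(
      feature_id = names(features)[chosen], class = k,
      tissue = tissues[t_pick], delta = sgn * config$delta))
  }
  ## individual effects: shared across tissues with correlation rho
  rho <- config$rho_individual
  shared <- matrix(rnorm(n * length(inds), 0, config$ind_sd), n)
  m <- array(NA_real_, dim = c(n, length(tissues), length(inds)),
             dimnames = list(names(features), tissues, inds))
  n_clip <- 0L
  for (ti in seq_along(tissues)) {
    for (ii in seq_along(inds)) {
      private <- rnorm(n, 0, config$ind_sd)
      ind_eff <- sqrt(rho) * shared[, ii] + sqrt(1 - rho) * private
      v <- base + shift[, ti] + ind_eff + rnorm(n, 0, config$noise_sd)
      n_clip <- n_clip + sum(v < 0 | v > 1)
      m[, ti, ii] <- pmin(1, pmax(0, v))
    }
  }
  if (n_clip > 0)
    message(sprintf("%d methylation value(s) clipped to [0,1]", n_clip))
  structure(list(m = m, features = features, planted_dmrs = planted,
                 baseline = base, config = config),
            class = "TrueMethylome")
}

#' @export
print.TrueMethylome <- function(x, ...) {
  d <- dim(x$m)
  cat(sprintf(
    "TrueMethylome: %d features x %d tissues x %d individuals, %d planted DMRs\n",
    d[1], d[2], d[3], nrow(x$planted_dmrs)))
  invisible(x)
}

#' Simulate a feature-level methylation matrix with planted structure
#'
#' A direct feature-level counterpart of [simulate_methylome()] for
#' statistical validation at a chosen feature count: baseline methylation
#' plus optional per-tissue signatures, planted tissue-specific DMR shifts
#' in randomly chosen features, correlated per-individual deviations
#' (shared/private construction with cross-tissue correlation `rho`), and
#' residual noise. Values are clipped to \[0,1\].
#'
#' @param n_features number of features.
#' @param n_planted number of features receiving a tissue-specific shift.
#' @param delta shift size (applied in one random tissue per planted
#'   feature, directed away from the nearer bound).
#' @param tissues tissue names.
#' @param n_individuals individuals (shared across tissues).
#' @param baseline baseline methylation level.
#' @param tissue_sd SD of random per-(feature, tissue) signatures (default
#'   0: tissue structure comes only from planted shifts).
#' @param ind_sd SD of per-individual deviations.
#' @param rho cross-tissue correlation of individual deviations, \[0,1\].
#' @param noise_sd residual noise SD.
#' @param seed random seed.
#' @return a `RangedSummarizedExperiment` (assay `score`) with dummy
#'   single-bp feature coordinates, sample metadata, and the planted
#'   feature ids in `metadata()$planted`.
#' @export
simulate_feature_matrix <- function(n_features = 2000L, n_planted = 100L,
                                    delta = 0.4,
                                    tissues = c("cortex", "cerebellum",
                                                "blood"),
                                    n_individuals = 3L, baseline = 0.5,
                                    tissue_sd = 0, ind_sd = 0.1,
                                    rho = 0.7, noise_sd = 0.05,
                                    seed = 1L) {
  stopifnot(n_planted <= n_features, rho >= 0, rho <= 1)
  set.seed(seed)
  inds <- sprintf("ind%d", seq_len(n_individuals))
  meta <- expand.grid(individual_id = inds, tissue = tissues,
                      stringsAsFactors = FALSE)[, 2:1]
  meta$tissue_group <- meta$tissue
  meta$sample_id <- paste(meta$tissue, meta$individual_id, sep = "_")
  meta <- meta[, c("sample_id", "individual_id", "tissue", "tissue_group")]
  fid <- sprintf("f%05d", seq_len(n_features))
  base <- rep(baseline, n_features)
  shift <- matrix(0, n_features, length(tissues))
  if (tissue_sd > 0)
    shift <- shift + matrix(rnorm(length(shift), 0, tissue_sd),
                            n_features)
  planted <- sort(sample.int(n_features, n_planted))
  t_pick <- sample(seq_along(tissues), n_planted, replace = TRUE)
  sgn <- ifelse(base[planted] < 0.5, 1, sample(c(-1, 1), n_planted,
                                               replace = TRUE))
  for (j in seq_len(n_planted))
    shift[planted[j], t_pick[j]] <- shift[planted[j], t_pick[j]] +
      sgn[j] * delta
  shared <- matrix(rnorm(n_features * n_individuals, 0, ind_sd),
                   n_features)
  vals <- matrix(NA_real_, n_features, nrow(meta),
                 dimnames = list(fid, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    ti <- match(meta$tissue[s], tissues)
    ii <- match(meta$individual_id[s], inds)
    private <- rnorm(n_features, 0, ind_sd)
    ind_eff <- sqrt(rho) * shared[, ii] + sqrt(1 - rho) * private
    vals[, s] <- pmin(1, pmax(0, base + shift[, ti] + ind_eff +
                                rnorm(n_features, 0, noise_sd)))
  }
  rr <- GRanges("chrS", IRanges(seq_len(n_features), width = 1L))
  names(rr) <- fid
  mcols(rr)$feature_id <- fid
  mcols(rr)$class <- "SYNTH"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = vals), rowRanges = rr,
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
  S4Vectors::metadata(se)$planted <- fid[planted]
  S4Vectors::metadata(se)$planted_tissue <- tissues[t_pick]
  se
}

#' Saturating MeDIP capture efficiency
#'
#' `g(CF) = CF / (CF + K)`: the fraction of the maximal pulldown achieved
#' at coupling factor CF, with half-saturation constant `K`.
#'
#' @param cf coupling factors.
#' @param K half-saturation constant (default 10).
#' @return values in \[0,1).
#' @export
capture_efficiency <- function(cf, K = 10) {
  if (K <= 0) stopf("half-saturation K must be positive")
  cf / (cf + K)
}

#' Simulate MeDIP-like bin counts
#'
#' Counts are generated directly at bin level: for sample s and bin b,
#' `count ~ Poisson(L_s * (m_b * g(CF_b) + background))` where `m_b` is the
#' bin's true methylation (its overlapping feature's level, or the
#' background methylation for unannotated bins), `g` the saturating
#' capture efficiency and `L_s` a per-sample scale chosen so the expected
#' total equals the configured library size. Optional Gamma mixing adds
#' overdispersion.
#'
#' @param methylome a `TrueMethylome`.
#' @param genome the matching `SyntheticGenome`.
#' @param config a [sim_config()].
#' @return a `MedipExperiment`: list with `counts` (bin x sample), `bins`,
#'   `cf`, the sample `metadata`, and the true per-bin methylation matrix
#'   `m_bins` (ground truth for validation).
#' @export
simulate_medip_counts <- function(methylome, genome, config) {
  set.seed(derive_seed(config$seed, "counts"))
  bins <- make_bins(genome$chrom_lengths, config$bin_size, config$bin_step)
  cf <- coupling_factor(bins, genome$cpg, config$max_distance)
  g <- capture_efficiency(cf, config$half_saturation)
  features <- methylome$features
  ## bin -> feature by bin midpoint, class-priority tie break
  prio <- match(mcols(features)$class, FEATURE_CLASSES)
  ord <- order(prio)
  mid0 <- (start0(bins) + end0(bins)) %/% 2L
  mids <- GRanges(seqnames(bins), IRanges(mid0 + 1L, width = 1L))
  hit <- findOverlaps(mids, granges(features)[ord], ignore.strand = TRUE,
                      select = "first")
  feat_of_bin <- ifelse(is.na(hit), NA_integer_, ord[hit])
  tissues <- dimnames(methylome$m)[[2]]
  inds <- dimnames(methylome$m)[[3]]
  meta <- expand.grid(individual_id = inds, tissue = tissues,
                      stringsAsFactors = FALSE)[, 2:1]
  meta$tissue_group <- meta$tissue
  meta$sample_id <- paste(meta$tissue, meta$individual_id, sep = "_")
  meta <- meta[, c("sample_id", "individual_id", "tissue", "tissue_group")]
  n_bin <- length(bins)
  ## unannotated genome varies continuously bin-to-bin (shared across
  ## samples): background methylation is not a single flat level
  bg_bin <- pmin(1, pmax(0, rnorm(n_bin, config$bg_meth,
                                  config$bg_meth_sd %||% 0)))
  counts <- matrix(0L, n_bin, nrow(meta),
                   dimnames = list(region_id(bins), meta$sample_id))
  m_bins <- matrix(NA_real_, n_bin, nrow(meta),
                   dimnames = dimnames(counts))
  for (s in seq_len(nrow(meta))) {
    mv <- methylome$m[, meta$tissue[s], meta$individual_id[s]]
    m_b <- ifelse(is.na(feat_of_bin), bg_bin, mv[feat_of_bin])
    w <- m_b * g + config$medip_background
    if (any(w < 0)) stopf("negative count rate encountered")
    tot <- sum(w)
    lambda <- if (tot > 0) config$library_size * w / tot else rep(0, n_bin)
    if (config$overdispersion > 0) {
      d <- config$overdispersion
      lambda <- lambda * rgamma(n_bin, shape = 1 / d, scale = d)
    }
    counts[, s] <- rpois(n_bin, lambda)
    m_bins[, s] <- m_b
  }
  structure(list(counts = counts, bins = bins, cf = cf, metadata = meta,
                 m_bins = m_bins, config = config),
            class = "MedipExperiment")
}

#' @export
print.MedipExperiment <- function(x, ...) {
  cat(sprintf("MedipExperiment: %d bins x %d samples, median depth %s\n",
              nrow(x$counts), ncol(x$counts),
              format(round(median(colSums(x$counts))), big.mark = ",")))
  invisible(x)
}

#' Simulate a complete synthetic MeDIP-seq study
#'
#' Runs [simulate_genome()], [simulate_methylome()] and
#' [simulate_medip_counts()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `methylome`, `experiment`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  methylome <- simulate_methylome(genome, config)
  experiment <- simulate_medip_counts(methylome, genome, config)
  list(genome = genome, methylome = methylome, experiment = experiment)
}

#' Write the synthetic study to plain-text fixtures
#'
#' Emits CpG/CGI BED files, a gene-model table, the bin x sample count
#' matrix, sample metadata and chromosome lengths; everything round-trips
#' losslessly through [read_fixtures()].
#'
#' @param genome a `SyntheticGenome`.
#' @param experiment a `MedipExperiment` (or `NULL` to skip counts).
#' @param outdir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_fixtures <- function(genome, experiment = NULL, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stopf("cannot create output directory: %s", outdir)
  paths <- c(cpg = file.path(outdir, "cpg.bed"),
             cgis = file.path(outdir, "cgis.bed"),
             genes = file.path(outdir, "genes.tsv"),
             chroms = file.path(outdir, "chrom_lengths.tsv"))
  write_bed(genome$cpg, paths[["cpg"]])
  write_bed(genome$cgis, paths[["cgis"]])
  g <- genome$genes
  gdf <- data.frame(chrom = as.character(seqnames(g)), start = start0(g),
                    end = end0(g), strand = as.character(strand(g)),
                    gene_id = mcols(g)$gene_id,
                    utr3_len = mcols(g)$utr3_len,
                    promoter_gc = mcols(g)$promoter_gc)
  write.table(gdf, paths[["genes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(chrom = names(genome$chrom_lengths),
                         length = unname(genome$chrom_lengths)),
              paths[["chroms"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(experiment)) {
    paths <- c(paths, counts = file.path(outdir, "counts.tsv"),
               metadata = file.path(outdir, "metadata.tsv"))
    cdf <- data.frame(bin = rownames(experiment$counts),
                      experiment$counts, check.names = FALSE)
    write.table(cdf, paths[["counts"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(experiment$metadata, paths[["metadata"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read back fixtures written by [write_fixtures()]
#'
#' @param outdir the fixture directory.
#' @return list with `genome` (`SyntheticGenome`), and when present
#'   `counts` matrix, `bins` and `metadata`.
#' @export
read_fixtures <- function(outdir) {
  chrom_df <- read.delim(file.path(outdir, "chrom_lengths.tsv"))
  chrom_lengths <- setNames(chrom_df$length, chrom_df$chrom)
  gdf <- read.delim(file.path(outdir, "genes.tsv"))
  genes <- if (nrow(gdf)) {
    g <- gr0(gdf$chrom, gdf$start, gdf$end, strand = gdf$strand,
             chrom_lengths = chrom_lengths)
    mcols(g)$gene_id <- gdf$gene_id
    mcols(g)$utr3_len <- gdf$utr3_len
    mcols(g)$promoter_gc <- gdf$promoter_gc
    g
  } else GRanges()
  fix_si <- function(gr) {
    if (length(gr) == 0L) return(gr)
    mcols(gr) <- NULL
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(chrom_lengths)[seqlevels(gr)]
    gr
  }
  genome <- structure(list(
    chrom_lengths = chrom_lengths,
    cpg = fix_si(read_bed(file.path(outdir, "cpg.bed"))),
    cgis = fix_si(read_bed(file.path(outdir, "cgis.bed"))),
    genes = sort_features(genes)), class = "SyntheticGenome")
  out <- list(genome = genome)
  cpath <- file.path(outdir, "counts.tsv")
  if (file.exists(cpath)) {
    cdf <- read.delim(cpath, check.names = FALSE)
    counts <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(counts) <- cdf$bin
    out$counts <- counts
    parts <- do.call(rbind, strsplit(cdf$bin, "[:-]"))
    out$bins <- gr0(parts[, 1], as.integer(parts[, 2]),
                    as.integer(parts[, 3]), chrom_lengths = chrom_lengths)
    out$metadata <- read.delim(file.path(outdir, "metadata.tsv"))
  }
  out
}
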