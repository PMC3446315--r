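## Feature-level quantification, CV-ranked tissue-specific DMR calling,
## class-enrichment testing, sample-structure analysis (correlation,
## clustering, PCA), between-individual differences and genic metaprofiles.

#' Quantify methylation per annotated feature
#'
#' Two quantification modes mirror the two feature-level measures used for
#' MeDIP-seq data: `"rms"` averages the CpG-density-corrected relative
#' methylation score of all bins overlapping the feature; `"rpkm"` sums
#' read counts of bins whose midpoint falls in the feature and normalizes
#' for total read count and feature length
#' (`reads * 1e9 / (total_reads * length_bp)`).
#'
#' @param x a bin x sample matrix (rms values for mode `"rms"`, raw counts
#'   for mode `"rpkm"`).
#' @param bins the matching bin `GRanges`.
#' @param features annotated feature `GRanges` (from
#'   [annotate_features()]).
#' @param metadata sample metadata `data.frame` with columns `sample_id`,
#'   `individual_id`, `tissue`, `tissue_group`; rows match columns of `x`.
#' @param mode `"rms"` or `"rpkm"`.
#' @return a `RangedSummarizedExperiment` with assay `score`, feature
#'   annotation in `rowRanges` and sample metadata in `colData`.
#' @export
quantify_features <- function(x, bins, features, metadata,
                              mode = c("rms", "rpkm")) {
  mode <- match.arg(mode)
  if (length(features) == 0L) stopf("no features to quantify")
  if (any(width(features) == 0L)) stopf("zero-length feature(s) present")
  x <- as.matrix(x)
  if (nrow(x) != length(bins))
    stopf("matrix has %d rows but there are %d bins", nrow(x), length(bins))
  if (mode == "rms") {
    ov <- findOverlaps(granges(features), bins, ignore.strand = TRUE)
    qf <- factor(queryHits(ov), levels = seq_along(features))
    vals <- vapply(seq_len(ncol(x)), function(j)
      as.numeric(tapply(x[subjectHits(ov), j], qf, mean, na.rm = TRUE)),
      numeric(length(features)))
    vals <- matrix(vals, nrow = length(features))
    vals[is.nan(vals)] <- NA_real_
  } else {
    totals <- colSums(x)
    if (any(totals <= 0)) stopf("sample(s) with non-positive total counts")
    mid0 <- (start0(bins) + end0(bins)) %/% 2L
    mids <- GRanges(seqnames(bins), IRanges(mid0 + 1L, width = 1L))
    ov <- findOverlaps(granges(features), mids, ignore.strand = TRUE)
    qf <- factor(queryHits(ov), levels = seq_along(features))
    raw <- vapply(seq_len(ncol(x)), function(j) {
      s <- tapply(x[subjectHits(ov), j], qf, sum)
      s[is.na(s)] <- 0
      as.numeric(s)
    }, numeric(length(features)))
    raw <- matrix(raw, nrow = length(features))
    vals <- sweep(raw, 2, totals, "/") * 1e9 / width(features)
  }
  rownames(vals) <- names(features) %||% mcols(features)$feature_id
  colnames(vals) <- metadata$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(score = vals), rowRanges = features,
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id))
}

fmm_values <- function(se) {
  if (inherits(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "score") else as.matrix(se)
}

fmm_meta <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))
}

#' Rank features by coefficient of variance
#'
#' The tissue-specificity statistic: `CV = SD / (mean + 1)` with sample SD
#' (n-1 denominator). With `group_by = "tissue_group"` the CV is taken
#' over per-group mean profiles (the three-tissue analysis); with
#' `group_by = "sample"` over individual samples (e.g. within-cortex
#' variability). Records are ranked by descending CV, ties broken by
#' feature id.
#'
#' @param se a feature matrix from [quantify_features()].
#' @param group_by `"tissue_group"` or `"sample"`.
#' @return `data.frame` with `feature_id`, `class`, `cv`, `rank` and one
#'   mean column per group.
#' @export
cv_rank <- function(se, group_by = c("tissue_group", "sample")) {
  group_by <- match.arg(group_by)
  vals <- fmm_values(se)
  meta <- fmm_meta(se)
  if (group_by == "tissue_group") {
    groups <- unique(meta$tissue_group)
    if (length(groups) < 2L) stopf("need >= 2 tissue groups, got %d",
                                   length(groups))
    prof <- vapply(groups, function(g)
      rowMeans(vals[, meta$tissue_group == g, drop = FALSE], na.rm = TRUE),
      numeric(nrow(vals)))
    prof <- matrix(prof, nrow = nrow(vals),
                   dimnames = list(rownames(vals), groups))
  } else {
    if (ncol(vals) < 2L) stopf("need >= 2 samples")
    prof <- vals
  }
  mu <- rowMeans(prof, na.rm = TRUE)
  s <- apply(prof, 1, sd, na.rm = TRUE)
  cv <- s / (mu + 1)
  fid <- rownames(vals)
  out <- data.frame(feature_id = fid,
                    class = SummarizedExperiment::rowRanges(se)$class %||%
                      rep(NA_character_, nrow(vals)),
                    cv = cv, stringsAsFactors = FALSE)
  if (group_by == "tissue_group")
    for (g in colnames(prof)) out[[paste0("mean_", g)]] <- prof[, g]
  o <- order(-out$cv, out$feature_id)
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the DMR set from a ranked CV table
#'
#' Either the `top_k` highest-CV features (the "top 50" style tables) or
#' all features with `CV > cv_gt` (the CV > 1 definition of TS-DMRs).
#'
#' @param records ranked table from [cv_rank()].
#' @param top_k integer, or `NULL`.
#' @param cv_gt CV threshold, or `NULL`. Exactly one of `top_k`/`cv_gt`
#'   must be given.
#' @return the selected subset of `records`.
#' @export
select_dmrs <- function(records, top_k = NULL, cv_gt = NULL) {
  if (is.null(top_k) == is.null(cv_gt))
    stopf("give exactly one of top_k or cv_gt")
  if (!is.null(top_k)) {
    if (top_k > nrow(records)) {
      warnf("top_k = %d exceeds %d features; returning all",
            top_k, nrow(records))
      top_k <- nrow(records)
    }
    return(records[order(records$rank)[seq_len(top_k)], ])
  }
  records[records$cv > cv_gt, ]
}

#' Observed/expected class enrichment of a DMR set
#'
#' For each feature class, the expected DMR count is the DMR-set size
#' times the class's genome-wide proportion; the o/e ratio is
#' observed/expected and the departure from proportionality is tested with
#' a Pearson chi-square goodness of fit (df = K - 1). Classes with
#' expected count below 1 are pooled into `"other"`.
#'
#' @param dmr_set selected records (needs a `class` column).
#' @param all_features the full record table (or any data.frame with a
#'   `class` column) defining genome-wide proportions.
#' @return an `EnrichmentResult`: list with the per-class `table`
#'   (observed, expected, oe), `statistic`, `df`, `p.value`.
#' @export
enrichment_oe <- function(dmr_set, all_features) {
  cls_all <- all_features$class
  cls_dmr <- dmr_set$class
  if (length(unique(cls_all)) < 2L) stopf("need >= 2 feature classes")
  n_all <- table(cls_all)
  props <- n_all / sum(n_all)
  obs <- table(factor(cls_dmr, levels = names(n_all)))
  expd <- as.numeric(props) * length(cls_dmr)
  tab <- data.frame(class = names(n_all), observed = as.integer(obs),
                    expected = expd,
                    oe = ifelse(expd > 0, as.integer(obs) / expd, NA_real_),
                    stringsAsFactors = FALSE)
  pool <- tab$expected < 1
  if (any(pool)) {
    message(sprintf("pooling %d class(es) with expected < 1 into 'other'",
                    sum(pool)))
    other <- data.frame(class = "other",
                        observed = sum(tab$observed[pool]),
                        expected = sum(tab$expected[pool]), oe = NA_real_)
    other$oe <- ifelse(other$expected > 0,
                       other$observed / other$expected, NA_real_)
    keep <- tab[!pool, ]
    tab_test <- rbind(keep, other)
  } else tab_test <- tab
  test <- suppressWarnings(chisq.test(
    x = tab_test$observed, p = tab_test$expected / sum(tab_test$expected)))
  structure(list(table = tab, pooled_table = tab_test,
                 statistic = unname(test$statistic),
                 df = unname(test$parameter),
                 p.value = unname(test$p.value)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Class enrichment: chi-square = %.3g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between samples
#'
#' @param se feature matrix or `SummarizedExperiment`.
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(se) {
  vals <- fmm_values(se)
  if (ncol(vals) < 2L) stopf("need >= 2 samples")
  v <- apply(vals, 2, var, na.rm = TRUE)
  if (any(v == 0 | is.na(v)))
    stopf("zero-variance sample(s): %s",
          paste(colnames(vals)[v == 0 | is.na(v)], collapse = ", "))
  cor(vals, use = "pairwise.complete.obs")
}

#' Cluster samples on correlation dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - r`.
#'
#' @param corr correlation matrix from [sample_correlation()].
#' @return an `hclust` tree.
#' @export
cluster_samples <- function(corr) {
  if (any(!is.finite(corr))) stopf("correlation matrix contains NaN/NA")
  hclust(as.dist(1 - corr), method = "average")
}

#' Purity of a k-group cut against known labels
#'
#' Cuts the sample tree into `k` clusters and reports the fraction of
#' samples whose cluster's majority label matches their own.
#'
#' @param tree an `hclust` from [cluster_samples()].
#' @param labels true per-sample labels (e.g. tissue).
#' @param k number of clusters (default: number of distinct labels).
#' @return purity in \[0,1\].
#' @export
cluster_purity <- function(tree, labels, k = length(unique(labels))) {
  cl <- cutree(tree, k = k)
  agree <- vapply(split(labels, cl), function(l) max(table(l)), 0)
  sum(agree) / length(labels)
}

#' PCA of samples over features
#'
#' Principal components of the feature-centered matrix, samples as
#' observations.
#'
#' @param se feature matrix or `SummarizedExperiment`.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `variance`
#'   (component variances, non-increasing) and `prop_variance`.
#' @export
pca_samples <- function(se, n_components = 3L) {
  vals <- fmm_values(se)
  vals <- vals[complete.cases(vals), , drop = FALSE]
  if (ncol(vals) < n_components)
    stopf("need >= %d samples, got %d", n_components, ncol(vals))
  if (all(apply(vals, 1, var) == 0)) stopf("constant matrix: PCA undefined")
  p <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance = p$sdev[seq_len(k)]^2,
       prop_variance = p$sdev[seq_len(k)]^2 / sum(p$sdev^2))
}

#' Between-individual methylation differences across tissues
#'
#' For each tissue group, computes the per-feature difference in
#' normalized methylation between two named individuals (averaging over a
#' group's samples, e.g. cortical regions), then correlates the
#' blood-detected differences with those seen in each brain tissue.
#' Significance comes from feature-label permutation.
#'
#' @param se feature matrix `SummarizedExperiment`.
#' @param ind_a,ind_b individual ids to contrast.
#' @param reference tissue group whose differences are correlated against
#'   the others (default `"blood"`).
#' @param n_perm permutations for the p-value (default 1000).
#' @param seed permutation seed.
#' @return an `IndividualDiff`: list with the per-feature `differences`
#'   matrix (features x tissue groups, antisymmetric under swapping
#'   individuals) and a `correlations` table (tissue, r, p_perm).
#' @export
individual_differences <- function(se, ind_a, ind_b, reference = "blood",
                                   n_perm = 1000L, seed = 1L) {
  vals <- fmm_values(se)
  meta <- fmm_meta(se)
  groups <- unique(meta$tissue_group)
  diffs <- vapply(groups, function(g) {
    a <- meta$tissue_group == g & meta$individual_id == ind_a
    b <- meta$tissue_group == g & meta$individual_id == ind_b
    if (!any(a) || !any(b))
      stopf("individual %s missing in tissue group %s",
            if (!any(a)) ind_a else ind_b, g)
    rowMeans(vals[, a, drop = FALSE], na.rm = TRUE) -
      rowMeans(vals[, b, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(vals)))
  rownames(diffs) <- rownames(vals)
  if (!reference %in% groups)
    stopf("reference group '%s' not present", reference)
  others <- setdiff(groups, reference)
  set.seed(seed)
  cor_tab <- do.call(rbind, lapply(others, function(g) {
    ok <- is.finite(diffs[, reference]) & is.finite(diffs[, g])
    x <- diffs[ok, reference]; y <- diffs[ok, g]
    if (sd(x) == 0 || sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      r <- cor(x, y)
      perm <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)), 0)
      p <- (1 + sum(abs(perm) >= abs(r))) / (n_perm + 1)
    }
    data.frame(tissue = g, reference = reference, r = r, p_perm = p,
               n_features = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(list(differences = diffs, correlations = cor_tab,
                 ind_a = ind_a, ind_b = ind_b),
            class = "IndividualDiff")
}

#' @export
print.IndividualDiff <- function(x, ...) {
  cat(sprintf("Between-individual differences (%s - %s):\n",
              x$ind_a, x$ind_b))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Average genic methylation metaprofile
#'
#' Scales every gene body to `n_body_bins` positions, adds fixed-width
#' flank windows of `flank` bp split into `n_flank_bins` positions each,
#' orients minus-strand genes 5'->3', samples the bin-level score at each
#' position and averages over genes. Genes shorter than `n_body_bins` bp
#' are skipped.
#'
#' @param scores per-bin score vector (e.g. rms).
#' @param bins the bin `GRanges`.
#' @param genes stranded gene `GRanges`.
#' @param n_body_bins positions across the gene body (default 40).
#' @param flank flank span bp (default 2000).
#' @param n_flank_bins positions per flank (default 10).
#' @return list with `profile` (mean per position), `positions` (labels),
#'   `n_genes` used and `n_skipped`.
#' @export
metagene_profile <- function(scores, bins, genes, n_body_bins = 40L,
                             flank = 2000L, n_flank_bins = 10L) {
  genes <- check_genes(genes)
  stopifnot(length(scores) == length(bins), flank >= 0)
  ## per-step-window lookup: position -> score via the step grid
  d <- diff(BiocGenerics::start(bins)); d <- d[d > 0]
  step <- if (length(d)) min(d) else width(bins)[1]
  sl <- seqlengths(bins)
  lookup <- function(chrom, pos0) {
    ## mean score of bins containing each position
    g <- GRanges(chrom, IRanges(pos0 + 1L, width = 1L))
    ov <- findOverlaps(g, bins)
    qf <- factor(queryHits(ov), levels = seq_along(g))
    as.numeric(tapply(scores[subjectHits(ov)], qf, mean, na.rm = TRUE))
  }
  n_pos <- n_body_bins + 2L * n_flank_bins
  n_skipped <- 0L
  rows <- lapply(seq_along(genes), function(i) {
    s <- start0(genes)[i]; e <- end0(genes)[i]
    if (e - s < n_body_bins) { n_skipped <<- n_skipped + 1L; return(NULL) }
    ch <- as.character(seqnames(genes))[i]
    up <- s - flank + (seq_len(n_flank_bins) - 0.5) * (flank / n_flank_bins)
    body <- s + (seq_len(n_body_bins) - 0.5) * ((e - s) / n_body_bins)
    down <- e + (seq_len(n_flank_bins) - 0.5) * (flank / n_flank_bins)
    pos <- floor(c(up, body, down))
    ok <- pos >= 0 & pos < sl[ch]
    v <- rep(NA_real_, n_pos)
    v[ok] <- lookup(ch, pos[ok])
    if (as.character(strand(genes))[i] == "-") v <- rev(v)
    v
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stopf("no genes long enough for the profile")
  mat <- do.call(rbind, rows)
  prof <- colMeans(mat, na.rm = TRUE)
  labels <- c(sprintf("up_%d", seq_len(n_flank_bins)),
              sprintf("body_%d", seq_len(n_body_bins)),
              sprintf("down_%d", seq_len(n_flank_bins)))
  list(profile = setNames(prof, labels), positions = labels,
       n_genes = length(rows), n_skipped = n_skipped)
}
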