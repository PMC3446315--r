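## Signed weighted co-methylation networks: soft-thresholded adjacency,
## topological overlap, average-linkage module detection with a static
## tree cut, module eigengenes and module-trait statistics.

#' Log-transform a non-negative methylation score matrix
#'
#' `x -> log2(x + pseudocount)`; monotone, so within-feature sample
#' rankings are preserved.
#'
#' @param x non-negative matrix.
#' @param pseudocount additive offset (default 1).
#' @return transformed matrix.
#' @export
log_transform <- function(x, pseudocount = 1) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) stopf("log_transform requires values >= 0")
  log2(x + pseudocount)
}

#' Signed (or unsigned) weighted adjacency
#'
#' Features are nodes; profiles across samples are correlated and
#' soft-thresholded: signed `A_ij = ((1 + cor)/2)^beta` (anti-correlated
#' features get adjacency near 0), unsigned `|cor|^beta`. Zero-variance
#' features are dropped with a warning.
#'
#' @param mat feature x sample matrix.
#' @param beta soft-thresholding power (positive integer).
#' @param signed signed network flag (default `TRUE`).
#' @return adjacency matrix in \[0,1\] with unit diagonal.
#' @export
adjacency_matrix <- function(mat, beta = 6L, signed = TRUE) {
  mat <- as.matrix(mat)
  if (beta < 1) stopf("beta must be >= 1")
  if (ncol(mat) < 3L) stopf("need >= 3 samples to correlate profiles")
  v <- apply(mat, 1, var, na.rm = TRUE)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    warnf("dropping %d zero-variance feature(s) from the network",
          sum(drop))
    mat <- mat[!drop, , drop = FALSE]
  }
  r <- cor(t(mat), use = "pairwise.complete.obs")
  A <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 -
#' A_ij)` with connectivity `k_i = sum_{u != i} A_iu`; diagonal 1. Two
#' features overlap strongly when they are directly connected and share
#' neighbors.
#'
#' @param A adjacency matrix (symmetric, \[0,1\], unit diagonal).
#' @return the TOM, symmetric in \[0,1\].
#' @export
tom_similarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stopf("A must be symmetric")
  if (any(A < -1e-12 | A > 1 + 1e-12)) stopf("A entries must lie in [0,1]")
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  AA <- A %*% A
  ## (A%*%A)_ij counts the u = i and u = j terms (A_ii A_ij + A_ij A_jj);
  ## remove them, then add back the direct link
  num <- AA - A * outer(diag(A), rep(1, n)) -
    A * outer(rep(1, n), diag(A)) + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  TOM <- (TOM + t(TOM)) / 2
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes node
#' connectivities, bins them, and regresses `log10 p(k)` on `log10 k`; the
#' scale-free fit index is the regression R-squared signed by the negative
#' slope. Returns the smallest power reaching `rsq_cut` (default 0.8), or
#' the power with maximal fit if none does.
#'
#' @param mat feature x sample matrix.
#' @param powers candidate powers (default 1:20).
#' @param signed signed network flag.
#' @param rsq_cut fit threshold.
#' @param n_bins connectivity histogram bins (default 10, needs >= 8
#'   populated).
#' @return list with `beta`, the per-power `fit_table` (power,
#'   signed_rsq, slope, mean_k) and `degenerate` flag.
#' @export
pick_soft_power <- function(mat, powers = 1:20, signed = TRUE,
                            rsq_cut = 0.8, n_bins = 10L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 4L) stopf("need >= 4 samples")
  if (nrow(mat) < 3L * n_bins)
    stopf("too few features (%d) to bin connectivities", nrow(mat))
  rows <- lapply(powers, function(b) {
    A <- suppressWarnings(adjacency_matrix(mat, beta = b, signed = signed))
    k <- rowSums(A) - 1
    if (max(k) - min(k) < 1e-10)
      return(data.frame(power = b, signed_rsq = NA_real_,
                        slope = NA_real_, mean_k = mean(k)))
    br <- seq(min(k), max(k), length.out = n_bins + 1L)
    cut_k <- cut(k, breaks = br, include.lowest = TRUE)
    p_k <- as.numeric(table(cut_k)) / length(k)
    mid <- (br[-1] + br[-length(br)]) / 2
    ok <- p_k > 0 & mid > 0
    if (sum(ok) < 8L)
      return(data.frame(power = b, signed_rsq = NA_real_,
                        slope = NA_real_, mean_k = mean(k)))
    fit <- lm(y ~ x, data = data.frame(x = log10(mid[ok]),
                                       y = log10(p_k[ok])))
    r2 <- summary(fit)$r.squared
    sl <- unname(coef(fit)[2])
    data.frame(power = b, signed_rsq = -sign(sl) * r2, slope = sl,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  degenerate <- all(is.na(tab$signed_rsq))
  if (degenerate) {
    warnf("connectivity distribution degenerate; scale-free fit undefined")
    return(list(beta = powers[1], fit_table = tab, degenerate = TRUE))
  }
  hit <- which(!is.na(tab$signed_rsq) & tab$signed_rsq >= rsq_cut)
  beta <- if (length(hit)) tab$power[hit[1]] else
    tab$power[which.max(tab$signed_rsq)]
  list(beta = beta, fit_table = tab, degenerate = FALSE)
}

## standard module color palette, assigned by decreasing module size
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-methylation modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static cut at `cut_height` times the maximal merge height.
#' Clusters smaller than `min_size` become `"grey"` (unassigned); the rest
#' are named by decreasing size along the standard color palette.
#'
#' @param TOM topological overlap matrix.
#' @param min_size minimum module size (default 30).
#' @param cut_height cut height as a fraction of the tree height
#'   (default 0.95).
#' @return list with `labels` (per-feature module color), the `tree`
#'   (`hclust`), and `sizes`.
#' @export
detect_modules <- function(TOM, min_size = 30L, cut_height = 0.95) {
  if (cut_height <= 0 || cut_height > 1)
    stopf("cut_height must be in (0, 1]")
  dissTOM <- 1 - TOM
  diag(dissTOM) <- 0
  tree <- hclust(as.dist(dissTOM), method = "average")
  h <- cut_height * max(tree$height)
  cl <- cutree(tree, h = h)
  sizes <- table(cl)
  if (length(sizes) == 1L)
    warnf("all features fall in a single cluster at the chosen cut")
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big], as.integer(big))]
  if (length(big) > length(MODULE_COLORS))
    big <- big[seq_along(MODULE_COLORS)]
  color_of <- setNames(MODULE_COLORS[seq_along(big)], big)
  labels <- unname(ifelse(as.character(cl) %in% big,
                          color_of[as.character(cl)], "grey"))
  names(labels) <- rownames(TOM)
  list(labels = labels, tree = tree,
       sizes = sort(table(labels), decreasing = TRUE))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component, across
#' samples, of the module's standardized feature profiles; its sign is
#' aligned with the module mean profile and it is scaled to unit variance.
#'
#' @param mat feature x sample matrix.
#' @param labels per-feature module labels (`"grey"` skipped).
#' @return matrix samples x modules of eigengene values.
#' @export
module_eigengenes <- function(mat, labels) {
  mat <- as.matrix(mat)
  stopifnot(length(labels) == nrow(mat))
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) stopf("no assigned modules")
  ME <- vapply(mods, function(m) {
    X <- mat[labels == m, , drop = FALSE]
    if (nrow(X) < 2L) stopf("module '%s' has < 2 features", m)
    sds <- apply(X, 1, sd)
    if (any(sds == 0)) stopf("module '%s' contains constant profiles", m)
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    me <- sv$v[, 1]
    if (cor(me, colMeans(Xs)) < 0) me <- -me
    me / sd(me)
  }, numeric(ncol(mat)))
  rownames(ME) <- colnames(mat)
  ME
}

#' One-hot trait indicators from sample metadata
#'
#' @param meta sample metadata with a `tissue_group` column.
#' @return samples x traits 0/1 matrix.
#' @export
trait_indicators <- function(meta) {
  groups <- unique(meta$tissue_group)
  out <- vapply(groups, function(g) as.numeric(meta$tissue_group == g),
                numeric(nrow(meta)))
  rownames(out) <- meta$sample_id
  out
}

## Pearson correlation with Student-t p-value (n-2 df)
cor_with_p <- function(x, y) {
  r <- cor(x, y)
  n <- length(x)
  t <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(t), df = n - 2)
  c(r = r, p = p)
}

#' Module-trait correlations, module membership and trait significance
#'
#' Correlates each module eigengene with each trait indicator (Pearson,
#' Student-t p-value on n-2 df); computes per-feature module membership
#' `MM = |cor(profile, ME of its module)|` and trait significance
#' `GS = |cor(profile, trait)|`.
#'
#' @param ME eigengene matrix from [module_eigengenes()].
#' @param traits samples x traits indicator matrix.
#' @param mat feature x sample matrix.
#' @param labels per-feature module labels.
#' @return list with `module_trait` (long table: module, trait, r, p),
#'   `MM` (named per-feature vector, `NA` for grey), `GS` (features x
#'   traits matrix).
#' @export
module_trait_stats <- function(ME, traits, mat, labels) {
  traits <- as.matrix(traits)
  if (any(apply(traits, 2, var) == 0))
    stopf("constant trait column(s): %s",
          paste(colnames(traits)[apply(traits, 2, var) == 0],
                collapse = ", "))
  mt <- do.call(rbind, lapply(colnames(ME), function(m)
    do.call(rbind, lapply(colnames(traits), function(tr) {
      rp <- cor_with_p(ME[, m], traits[, tr])
      data.frame(module = m, trait = tr, r = rp[["r"]], p = rp[["p"]],
                 stringsAsFactors = FALSE)
    }))))
  mat <- as.matrix(mat)
  MM <- rep(NA_real_, nrow(mat))
  names(MM) <- rownames(mat)
  for (m in colnames(ME)) {
    idx <- which(labels == m)
    if (length(idx))
      MM[idx] <- abs(cor(t(mat[idx, , drop = FALSE]), ME[, m]))
  }
  GS <- abs(cor(t(mat), traits))
  rownames(GS) <- rownames(mat)
  list(module_trait = mt, MM = MM, GS = GS)
}

#' Build a co-methylation network end to end
#'
#' Log-transforms the feature matrix, optionally restricts to the most
#' variable features, picks (or accepts) the soft power, builds the signed
#' adjacency and TOM, detects modules, computes eigengenes and
#' module-trait statistics.
#'
#' @param se feature matrix `SummarizedExperiment` (or matrix + `meta`).
#' @param meta sample metadata (taken from `se` when omitted).
#' @param beta soft power; `NULL` to select by scale-free fit.
#' @param signed signed network flag.
#' @param min_size,cut_height module detection parameters.
#' @param max_features variance-ranked feature cap to keep TOM memory
#'   desk-scale (default 2000; `Inf` for all).
#' @param pseudocount log-transform offset.
#' @return a `ComethylationNetwork`: list with `labels`, `tree`, `ME`,
#'   `stats`, `beta`, `power_fit`, `features_used`.
#' @export
comethylation_network <- function(se, meta = NULL, beta = NULL,
                                  signed = TRUE, min_size = 30L,
                                  cut_height = 0.95, max_features = 2000L,
                                  pseudocount = 1) {
  vals <- fmm_values(se)
  if (is.null(meta)) meta <- fmm_meta(se)
  x <- log_transform(vals, pseudocount)
  x <- x[complete.cases(x), , drop = FALSE]
  v <- apply(x, 1, var)
  x <- x[v > 0, , drop = FALSE]
  if (nrow(x) > max_features) {
    keep <- order(apply(x, 1, var), decreasing = TRUE)[seq_len(max_features)]
    x <- x[sort(keep), , drop = FALSE]
  }
  power_fit <- NULL
  if (is.null(beta)) {
    power_fit <- pick_soft_power(x, signed = signed)
    beta <- power_fit$beta
  }
  A <- adjacency_matrix(x, beta = beta, signed = signed)
  ## adjacency may have dropped features
  x <- x[rownames(A), , drop = FALSE]
  TOM <- tom_similarity(A)
  mods <- detect_modules(TOM, min_size = min_size, cut_height = cut_height)
  ME <- module_eigengenes(x, mods$labels)
  traits <- trait_indicators(meta)
  stats <- module_trait_stats(ME, traits, x, mods$labels)
  structure(list(labels = mods$labels, tree = mods$tree, sizes = mods$sizes,
                 ME = ME, stats = stats, beta = beta, power_fit = power_fit,
                 features_used = rownames(x)),
            class = "ComethylationNetwork")
}

#' @export
print.ComethylationNetwork <- function(x, ...) {
  cat(sprintf("ComethylationNetwork: beta = %d, %d features, modules:\n",
              x$beta, length(x$labels)))
  print(x$sizes)
  invisible(x)
}
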