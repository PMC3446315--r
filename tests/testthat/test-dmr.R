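test_that("feature quantification matches RPKM-style arithmetic", {
  ## 10 reads on a 1,000 bp feature with 1e6 total reads -> score 10
  bins <- make_bins(c(chr1 = 100000), 500, 500)
  counts <- matrix(0L, length(bins), 1)
  counts[3:4, 1] <- 5L              # bins [1000,1500),[1500,2000)
  counts[10, 1] <- 1e6L - 10L       # rest of the library elsewhere
  feat <- t_gr0("chr1", 1000L, 2000L)
  mcols(feat)$feature_id <- "f1"; mcols(feat)$class <- "CDS"
  names(feat) <- "f1"
  meta <- data.frame(sample_id = "s1", individual_id = "i1",
                     tissue = "t1", tissue_group = "t1")
  se <- quantify_features(counts, bins, feat, meta, mode = "rpkm")
  expect_equal(unname(assay(se)["f1", "s1"]), 10)
  ## doubling everything leaves the score unchanged
  se2 <- quantify_features(counts * 2L, bins, feat, meta, mode = "rpkm")
  expect_equal(assay(se), assay(se2))
  ## zero reads -> zero score
  c0 <- matrix(0L, length(bins), 1)
  c0[10, 1] <- 100L
  se0 <- quantify_features(c0, bins, feat, meta, mode = "rpkm")
  expect_equal(unname(assay(se0)["f1", "s1"]), 0)
  expect_error(quantify_features(counts, bins, GRanges(), meta), "features")
})

test_that("rms-mode quantification averages overlapping bins", {
  bins <- make_bins(c(chr1 = 2000), 500, 250)
  rms <- matrix(c(0.1, 0.3, 0.5, 0.7, 0.9, NA, 0.2, 0.4), ncol = 1)
  feat <- t_gr0("chr1", 0L, 750L)   # overlaps bins 1..3
  mcols(feat)$feature_id <- "f1"; mcols(feat)$class <- "CDS"
  names(feat) <- "f1"
  meta <- data.frame(sample_id = "s1", individual_id = "i1",
                     tissue = "t1", tissue_group = "t1")
  se <- quantify_features(rms, bins, feat, meta, mode = "rms")
  expect_equal(unname(assay(se)[1, 1]), mean(c(0.1, 0.3, 0.5)))
})

test_that("CV statistic equals SD/(mean+1) with n-1 denominator", {
  meta <- t_meta(c("a", "b", "c"), 1L)
  ## group means {0, 2, 4}: mean 2, SD 2 -> CV = 2/3
  vals <- matrix(rep(c(0, 2, 4), each = 2), nrow = 2, byrow = FALSE)
  se <- t_se(vals, meta)
  rec <- cv_rank(se)
  expect_equal(rec$cv, c(2 / 3, 2 / 3))
  ## identical profiles across groups -> CV 0
  se0 <- t_se(matrix(5, 3, 3), meta)
  expect_equal(cv_rank(se0)$cv, rep(0, 3))
  ## adding a constant strictly decreases CV (mean grows, SD fixed)
  for (c0 in c(1, 5, 10)) {
    rec_c <- cv_rank(t_se(vals + c0, meta))
    expect_lt(rec_c$cv[1], rec$cv[1])
  }
  expect_error(cv_rank(t_se(matrix(1, 2, 1),
                            t_meta("a", 1L))), "groups")
})

test_that("CV ranking is descending with deterministic tie-break", {
  meta <- t_meta(c("a", "b", "c"), 1L)
  set.seed(1)
  vals <- matrix(runif(30), 10, 3,
                 dimnames = list(sprintf("f%02d", 1:10), meta$sample_id))
  rec <- cv_rank(t_se(vals, meta))
  expect_equal(rec$rank, seq_len(10))
  expect_true(all(diff(rec$cv) <= 0))
  mu <- rowMeans(vals); s <- apply(vals, 1, sd)
  expect_equal(sort(rec$cv, decreasing = TRUE),
               unname(sort(s / (mu + 1), decreasing = TRUE)))
})

test_that("DMR selection by top-k and CV threshold", {
  rec <- data.frame(feature_id = c("a", "b", "c", "d"),
                    class = "X", cv = c(0.9, 1.2, 0.1, 2.0))
  rec <- rec[order(-rec$cv), ]; rec$rank <- 1:4
  top <- select_dmrs(rec, top_k = 3)
  expect_equal(top$cv, c(2.0, 1.2, 0.9))
  expect_equal(nrow(select_dmrs(rec, cv_gt = 1.0)), 2L)
  expect_equal(nrow(select_dmrs(rec, cv_gt = 99)), 0L)
  expect_warning(all4 <- select_dmrs(rec, top_k = 10), "exceeds")
  expect_equal(nrow(all4), 4L)
  expect_equal(nrow(select_dmrs(rec, top_k = 4)), 4L)
  expect_error(select_dmrs(rec), "exactly one")
})

test_that("o/e enrichment reproduces the hand-computed chi-square", {
  all_f <- data.frame(class = rep(c("A", "B"), each = 500))
  dmr <- data.frame(class = rep(c("A", "B"), c(30, 10)))
  enr <- enrichment_oe(dmr, all_f)
  expect_equal(enr$table$expected, c(20, 20))
  expect_equal(enr$table$oe, c(1.5, 0.5))
  expect_equal(enr$statistic, 10)
  expect_equal(enr$df, 1)
  expect_equal(enr$p.value, pchisq(10, 1, lower.tail = FALSE))
  ## proportional draw: o/e all 1, chi-square 0
  prop <- data.frame(class = rep(c("A", "B"), each = 25))
  enr0 <- enrichment_oe(prop, all_f)
  expect_equal(enr0$table$oe, c(1, 1))
  expect_equal(enr0$statistic, 0)
})

test_that("chi-square matches the sum((O-E)^2/E) formula on random tables", {
  set.seed(7)
  for (i in 1:20) {
    K <- sample(3:6, 1)
    sizes <- sample(50:200, K)
    all_f <- data.frame(class = rep(LETTERS[1:K], sizes))
    dmr <- data.frame(class = sample(rep(LETTERS[1:K],
                                         sample(5:30, K, replace = TRUE))))
    enr <- enrichment_oe(dmr, all_f)
    O <- enr$pooled_table$observed; E <- enr$pooled_table$expected
    expect_equal(enr$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
    expect_equal(sum(enr$table$observed), nrow(dmr))
    expect_equal(sum(enr$table$expected), nrow(dmr), tolerance = 1e-9)
  }
})

test_that("planted two-fold enrichment is recovered within binomial CI", {
  set.seed(42)
  ## class A holds 20% of features but DMRs hit it at twice the rate:
  ## P(DMR in A) = 2*0.2 / (2*0.2 + 0.8) = 1/3, so true o/e = 5/3
  prop_a <- 0.2
  p_dmr_a <- 2 * prop_a / (2 * prop_a + (1 - prop_a))
  all_f <- data.frame(class = rep(c("A", "B"), c(400, 1600)))
  true_oe <- p_dmr_a / prop_a
  for (n_dmr in c(50, 200, 1000)) {
    oe_reps <- vapply(1:100, function(i) {
      obs_a <- rbinom(1, n_dmr, p_dmr_a)
      dmr <- data.frame(class = rep(c("A", "B"), c(obs_a, n_dmr - obs_a)))
      enr <- enrichment_oe(dmr, all_f)
      oe <- enr$table$oe[enr$table$class == "A"]
      ## arithmetic contract: o/e is observed over proportional expectation
      expect_equal(oe, obs_a / (prop_a * n_dmr), tolerance = 1e-12)
      oe
    }, 0)
    ## estimator is unbiased: replicate mean sits inside the CLT band
    se_mean <- sqrt(p_dmr_a * (1 - p_dmr_a) / n_dmr) / prop_a / 10
    expect_lt(abs(mean(oe_reps) - true_oe), 4 * se_mean)
    ## and individual estimates concentrate as the DMR count grows
    expect_gt(mean(abs(oe_reps - true_oe) <=
                     (qbinom(0.975, n_dmr, p_dmr_a) -
                        qbinom(0.025, n_dmr, p_dmr_a)) /
                     (2 * prop_a * n_dmr) * 1.05), 0.9)
  }
})

test_that("sample correlation matches the covariance-formula oracle", {
  set.seed(13)
  meta <- t_meta(c("a", "b", "c", "d", "e"), 1L)
  vals <- matrix(rnorm(100), 20, 5)
  corr <- sample_correlation(t_se(vals, meta))
  expect_equal(diag(corr), setNames(rep(1, 5), meta$sample_id))
  expect_true(isSymmetric(corr))
  for (i in 1:5) for (j in 1:5) {
    x <- vals[, i]; y <- vals[, j]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(corr[i, j]), oracle, tolerance = 1e-12)
  }
  ## affine relation gives r = 1
  v2 <- cbind(c(1, 2, 3), c(2, 4, 6))
  corr2 <- sample_correlation(t_se(v2, t_meta(c("a", "b"), 1L)))
  expect_equal(unname(corr2[1, 2]), 1)
  vz <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_error(sample_correlation(t_se(vz, t_meta(c("a", "b"), 1L))),
               "zero-variance")
})

test_that("average-linkage clustering joins correlated samples first", {
  ## two perfectly correlated samples and one anti-correlated
  vals <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  meta <- t_meta(c("a", "b", "c"), 1L)
  corr <- sample_correlation(t_se(vals, meta))
  tree <- cluster_samples(corr)
  ## first merge joins the correlated pair at height 0
  expect_equal(sort(abs(tree$merge[1, ])), c(1, 2))
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  bad <- corr; bad[1, 2] <- NaN
  expect_error(cluster_samples(bad), "NaN")
})

test_that("tissue-dominant variance yields a pure 3-cluster cut", {
  se <- simulate_feature_matrix(500, 0, tissue_sd = 0.2, ind_sd = 0.02,
                                noise_sd = 0.02, rho = 0, seed = 9L)
  tree <- cluster_samples(sample_correlation(se))
  expect_equal(cluster_purity(tree, colData(se)$tissue_group), 1)
})

test_that("sample PCA returns ordered components and honors duplicates", {
  set.seed(2)
  meta <- t_meta(letters[1:5], 2L)
  vals <- matrix(rnorm(1000), 100, 10)
  vals[, 2] <- vals[, 1]            # duplicated sample
  p <- pca_samples(t_se(vals, meta), n_components = 3)
  expect_true(all(diff(p$variance) <= 1e-12))
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-9)
  ## reconstruction error decreases monotonically with k
  recon_err <- 1 - cumsum(p$prop_variance)
  expect_true(all(diff(recon_err) <= 1e-12))
  expect_error(pca_samples(t_se(matrix(1, 10, 10), meta)), "constant")
})

test_that("individual differences are antisymmetric with stable correlations", {
  se <- simulate_feature_matrix(300, 0, ind_sd = 0.15, noise_sd = 0.02,
                                rho = 0.7, seed = 44L)
  d12 <- individual_differences(se, "ind1", "ind2", n_perm = 200, seed = 1)
  d21 <- individual_differences(se, "ind2", "ind1", n_perm = 200, seed = 1)
  expect_equal(d12$differences, -d21$differences)
  expect_equal(d12$correlations$r, d21$correlations$r, tolerance = 1e-12)
  ## same individual: all differences zero, correlation undefined
  dd <- individual_differences(se, "ind1", "ind1", n_perm = 10, seed = 1)
  expect_true(all(dd$differences == 0))
  expect_true(all(is.na(dd$correlations$r)))
  expect_error(individual_differences(se, "ind1", "nope"), "missing")
})

test_that("metagene profiles scale gene bodies and mirror minus-strand genes", {
  bins <- make_bins(c(chr1 = 20000), 500, 250)
  gplus <- GRanges("chr1", IRanges(5001, 15000), strand = "+")
  mcols(gplus)$gene_id <- "g1"; mcols(gplus)$utr3_len <- 500L
  ## constant signal -> flat profile
  prof <- metagene_profile(rep(0.5, length(bins)), bins, gplus,
                           n_body_bins = 20, flank = 2000, n_flank_bins = 5)
  expect_true(all(abs(prof$profile - 0.5) < 1e-12))
  ## step signal: low before midpoint, high after
  scores <- ifelse(end(bins) <= 10000, 0, 1)
  pf <- metagene_profile(scores, bins, gplus, n_body_bins = 20,
                         flank = 2000, n_flank_bins = 5)
  body <- pf$profile[6:25]
  expect_true(mean(body[1:8]) < 0.2 && mean(body[13:20]) > 0.8)
  ## minus-strand gene mirrors the profile of the same signal
  gminus <- gplus; strand(gminus) <- "-"
  pm <- metagene_profile(scores, bins, gminus, n_body_bins = 20,
                         flank = 2000, n_flank_bins = 5)
  expect_equal(unname(pm$profile), unname(rev(pf$profile)))
  ## short genes are skipped and counted
  gshort <- GRanges("chr1", IRanges(1, 10), strand = "+")
  mcols(gshort)$gene_id <- "gs"; mcols(gshort)$utr3_len <- 0L
  expect_error(metagene_profile(scores, bins, gshort, n_body_bins = 20),
               "no genes")
  ps <- metagene_profile(scores, bins, c(gplus, gshort), n_body_bins = 20)
  expect_equal(ps$n_skipped, 1L)
  expect_equal(ps$n_genes, 1L)
})
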