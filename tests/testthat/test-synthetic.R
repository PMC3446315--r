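test_that("CpG landscape follows the two-rate island/background process", {
  ## no CpGs anywhere when both rates are zero
  cfg0 <- sim_config(cpg_rate_background = 0, cpg_rate_island = 0)
  expect_warning(g0 <- simulate_genome(cfg0), "not distinguishable")
  expect_equal(length(g0$cpg), 0L)
  ## background-only 1 Mb chromosome: count within 3 binomial SD of L*p
  cfg1 <- sim_config(n_chroms = 1L, chrom_length = 1000000L, cgi_per_mb = 0,
                     cpg_rate_background = 0.01, seed = 2L)
  g1 <- simulate_genome(cfg1)
  mu <- 1e6 * 0.01
  s3 <- 3 * sqrt(1e6 * 0.01 * 0.99)
  expect_gt(length(g1$cpg), mu - s3)
  expect_lt(length(g1$cpg), mu + s3)
  ## CpG positions strictly increasing within each chromosome
  pos <- split(start(g1$cpg), as.character(seqnames(g1$cpg)))
  expect_true(all(vapply(pos, function(p) all(diff(p) > 0), TRUE)))
  ## island CpG density well above background
  cfg2 <- sim_config(seed = 2L)
  g2 <- simulate_genome(cfg2)
  in_isl <- countOverlaps(g2$cgis, g2$cpg)
  expect_gt(sum(in_isl) / sum(width(g2$cgis)),
            3 * length(g2$cpg) / sum(g2$chrom_lengths))
})

test_that("genome simulation is deterministic and respects packing limits", {
  cfg <- sim_config(seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(simulate_genome(cfg), NULL, d1)
  write_fixtures(simulate_genome(cfg), NULL, d2)
  for (f in c("cpg.bed", "cgis.bed", "genes.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## genes never overlap within a chromosome
  g <- simulate_genome(cfg)$genes
  expect_equal(sum(countOverlaps(g, g, ignore.strand = TRUE) > 1), 0L)
  ## impossible packing is an error
  expect_error(simulate_genome(sim_config(chrom_length = 20000L)),
               "cannot place")
})

test_that("methylome baselines order classes and DMR planting is exact", {
  cfg <- sim_config(noise_sd = 0, ind_sd = 0, seed = 12L)
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  cls <- mcols(meth$features)$class
  m_mean <- apply(meth$m, 1, mean)
  ## promoter CGIs hypomethylated vs intragenic CGIs vs LCPs (highest)
  expect_lt(mean(m_mean[cls == "CGI_PROMOTER"]),
            mean(m_mean[cls == "CGI_INTRAGENIC"]))
  expect_lt(mean(m_mean[cls == "CGI_INTRAGENIC"]),
            mean(m_mean[cls == "LCP"]))
  expect_true(all(meth$m >= 0 & meth$m <= 1))
  ## with zero noise, a planted shift is recovered exactly as delta
  pd <- meth$planted_dmrs
  expect_gt(nrow(pd), 0)
  other <- setdiff(cfg$tissues, pd$tissue[1])[1]
  f1 <- pd$feature_id[1]
  expect_equal(mean(meth$m[f1, pd$tissue[1], ]) -
                 mean(meth$m[f1, other, ]),
               pd$delta[1], tolerance = 1e-12)
})

test_that("zero dmr fraction leaves tissues identical up to individual effects", {
  cfg <- sim_config(dmr_frac = c(default = 0), noise_sd = 0, ind_sd = 0,
                    seed = 4L)
  meth <- simulate_methylome(simulate_genome(cfg), cfg)
  expect_equal(nrow(meth$planted_dmrs), 0L)
  for (t2 in cfg$tissues[-1])
    expect_equal(meth$m[, 1, ], meth$m[, t2, ])
})

test_that("uncorrelated individual deviations stay uncorrelated across tissues", {
  se <- simulate_feature_matrix(2000, 0, rho = 0, ind_sd = 0.15,
                                noise_sd = 0, seed = 19L)
  v <- assay(se, "score")
  meta <- as.data.frame(colData(se))
  d <- function(t) v[, meta$tissue == t & meta$individual_id == "ind1"] -
    v[, meta$tissue == t & meta$individual_id == "ind2"]
  expect_lt(abs(cor(d("blood"), d("cortex"))), 0.1)
  expect_lt(abs(cor(d("blood"), d("cerebellum"))), 0.1)
})

test_that("MeDIP counts follow the saturating Poisson rate model", {
  cfg <- sim_config(seed = 3L)
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  ## zero methylation and zero background gives zero counts
  cfg0 <- sim_config(seed = 3L, medip_background = 0, bg_meth = 0,
                     bg_meth_sd = 0)
  m0 <- meth; m0$m[] <- 0
  e0 <- simulate_medip_counts(m0, genome, cfg0)
  expect_true(all(e0$counts == 0))
  ## counts increase with CF at fixed methylation, matching g analytically
  m1 <- meth; m1$m[] <- 1
  cfg1 <- sim_config(seed = 3L, medip_background = 0, bg_meth = 1,
                     bg_meth_sd = 0)
  e1 <- simulate_medip_counts(m1, genome, cfg1)
  g <- capture_efficiency(e1$cf, cfg1$half_saturation)
  lo <- e1$cf >= 4 & e1$cf <= 6
  hi <- e1$cf >= 45 & e1$cf <= 55
  expect_gt(mean(e1$counts[hi, 1]), mean(e1$counts[lo, 1]))
  ## ratio of mean counts matches the ratio of g at those CF levels
  expect_equal(mean(e1$counts[hi, 1]) / mean(e1$counts[lo, 1]),
               mean(g[hi]) / mean(g[lo]), tolerance = 0.15)
})

test_that("expected counts scale linearly with library size", {
  cfg_a <- sim_config(seed = 6L, library_size = 1e5)
  cfg_b <- sim_config(seed = 6L, library_size = 2e5)
  genome <- simulate_genome(cfg_a)
  meth <- simulate_methylome(genome, cfg_a)
  ea <- simulate_medip_counts(meth, genome, cfg_a)
  eb <- simulate_medip_counts(meth, genome, cfg_b)
  expect_equal(mean(eb$counts) / mean(ea$counts), 2, tolerance = 0.05)
})

test_that("count marginals match their Poisson rates within 3 SE", {
  ## replicate one sample's counts by reseeding only the count stage;
  ## flat background SD so the rate vector is identical across replicates
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L,
                    genes_per_chrom = 8L, tissues = "t",
                    n_individuals = 1L, bg_meth_sd = 0,
                    library_size = 5e4, seed = 10L)
  genome <- simulate_genome(cfg)
  meth <- simulate_methylome(genome, cfg)
  e1 <- simulate_medip_counts(meth, genome, cfg)
  g <- capture_efficiency(e1$cf, cfg$half_saturation)
  w <- e1$m_bins[, 1] * g + cfg$medip_background
  lambda <- cfg$library_size * w / sum(w)
  n_rep <- 1000L
  reps <- vapply(seq_len(n_rep), function(i) {
    cfg_i <- cfg; cfg_i$seed <- i
    simulate_medip_counts(meth, genome, cfg_i)$counts[, 1]
  }, numeric(nrow(e1$counts)))
  mu_hat <- rowMeans(reps)
  var_hat <- apply(reps, 1, var)
  idx <- which(lambda > 5)[seq_len(50)]
  ## mean within 3 SE of lambda; variance within 3 SE of lambda (Poisson)
  se_mean <- sqrt(lambda[idx] / n_rep)
  se_var <- sqrt((lambda[idx] + 2 * lambda[idx]^2) / n_rep)
  expect_true(all(abs(mu_hat[idx] - lambda[idx]) < 3 * se_mean))
  expect_true(mean(abs(var_hat[idx] - lambda[idx]) < 3 * se_var) > 0.9)
})

test_that("fixtures round-trip losslessly through the package readers", {
  cfg <- sim_config(seed = 15L)
  study <- simulate_study(cfg)
  d <- withr::local_tempdir()
  write_fixtures(study$genome, study$experiment, d)
  back <- read_fixtures(d)
  expect_equal(back$genome$chrom_lengths, study$genome$chrom_lengths)
  expect_equal(granges(back$genome$cpg), granges(study$genome$cpg))
  expect_equal(granges(back$genome$cgis), granges(study$genome$cgis))
  expect_equal(start(back$genome$genes), start(study$genome$genes))
  expect_equal(mcols(back$genome$genes)$gene_id,
               mcols(study$genome$genes)$gene_id)
  expect_equal(back$counts, study$experiment$counts)
  expect_equal(back$metadata, study$experiment$metadata)
  expect_equal(granges(back$bins), granges(study$experiment$bins))
  ## empty genome still writes valid (empty) files
  empty <- structure(list(chrom_lengths = c(chr1 = 1000),
                          cpg = GRanges(), cgis = GRanges(),
                          genes = GRanges()), class = "SyntheticGenome")
  d2 <- withr::local_tempdir()
  write_fixtures(empty, NULL, d2)
  back2 <- read_fixtures(d2)
  expect_equal(length(back2$genome$cpg), 0L)
})

test_that("planted DMR fractions match configuration within binomial CI", {
  cfg <- sim_config(n_chroms = 4L, seed = 23L,
                    dmr_frac = c(default = 0.1, CGI_INTRAGENIC = 0.2))
  meth <- simulate_methylome(simulate_genome(cfg), cfg)
  cls <- mcols(meth$features)$class
  n_intra <- sum(cls == "CGI_INTRAGENIC")
  obs <- sum(meth$planted_dmrs$class == "CGI_INTRAGENIC")
  ## deterministic rounding of the per-class fraction
  expect_equal(obs, round(0.2 * n_intra))
  expect_equal(nrow(meth$planted_dmrs),
               sum(vapply(unique(cls), function(k) {
                 f <- if (k == "CGI_INTRAGENIC") 0.2 else 0.1
                 round(f * sum(cls == k))
               }, 0)))
})
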