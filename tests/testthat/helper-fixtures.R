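## Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## GRanges from 0-based half-open coordinates (test-side mirror)
t_gr0 <- function(chrom, start0, end0, strand = "*") {
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
}

## a hand-built 3-gene fixture on one 1 Mb chromosome
three_gene_fixture <- function() {
  chrom_lengths <- c(chr1 = 1e6)
  genes <- t_gr0("chr1",
                 start0 = c(100000L, 300000L, 600000L),
                 end0   = c(110000L, 310000L, 610000L),
                 strand = c("+", "-", "+"))
  mcols(genes)$gene_id <- c("gA", "gB", "gC")
  mcols(genes)$utr3_len <- 500L
  list(chrom_lengths = chrom_lengths, genes = genes)
}

## tiny sample-metadata table: tissues x individuals
t_meta <- function(tissues = c("cortex", "cerebellum", "blood"),
                   n_ind = 3L) {
  inds <- sprintf("ind%d", seq_len(n_ind))
  m <- expand.grid(individual_id = inds, tissue = tissues,
                   stringsAsFactors = FALSE)[, 2:1]
  m$tissue_group <- m$tissue
  m$sample_id <- paste(m$tissue, m$individual_id, sep = "_")
  m[, c("sample_id", "individual_id", "tissue", "tissue_group")]
}

## SummarizedExperiment from a plain matrix + metadata
t_se <- function(vals, meta, class = "SYNTH") {
  fid <- rownames(vals) %||% sprintf("f%04d", seq_len(nrow(vals)))
  rownames(vals) <- fid
  colnames(vals) <- meta$sample_id
  rr <- GRanges("chrT", IRanges(seq_len(nrow(vals)), width = 1L))
  names(rr) <- fid
  mcols(rr)$feature_id <- fid
  mcols(rr)$class <- rep_len(class, nrow(vals))
  SummarizedExperiment(assays = list(score = vals), rowRanges = rr,
                       colData = S4Vectors::DataFrame(
                         meta, row.names = meta$sample_id))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## --- independent oracles ---------------------------------------------

## brute-force CpG window count for one bin (0-based half-open bin)
oracle_cf <- function(bin_start0, bin_end0, cpg_pos0, max_distance) {
  sum(cpg_pos0 >= bin_start0 - max_distance &
        cpg_pos0 < bin_end0 + max_distance)
}

## triple-loop topological overlap
oracle_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    TOM[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

## adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(v) sum(choose(v, 2))
  si <- sc(tab); sa <- sc(rowSums(tab)); sb <- sc(colSums(tab))
  tot <- choose(n, 2)
  (si - sa * sb / tot) / ((sa + sb) / 2 - sa * sb / tot)
}

## three orthogonal co-methylation blocks: within-block correlation rho_w,
## between-block exactly 0 (orthonormalized factors)
block_matrix <- function(n_per = 200L, n_samples = 9L, rho_w = 0.8,
                         seed = 21L) {
  set.seed(seed)
  blocks <- rep(1:3, each = n_per)
  z <- qr.Q(qr(matrix(rnorm(n_samples * 3), n_samples)))
  z <- t(z) * sqrt(n_samples)
  x <- t(sapply(seq_along(blocks), function(f)
    sqrt(rho_w) * z[blocks[f], ] + sqrt(1 - rho_w) * rnorm(n_samples)))
  rownames(x) <- sprintf("f%03d", seq_along(blocks))
  colnames(x) <- sprintf("s%d", seq_len(n_samples))
  list(x = x, blocks = blocks)
}
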