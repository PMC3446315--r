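#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqinfo Seqinfo
#' @importFrom stats lm coef prcomp pchisq pt rbinom rpois
#'   rnorm runif rgamma hclust as.dist cutree chisq.test setNames
#' @importFrom stats aggregate complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage-specific random seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that each stage is
#' individually reproducible. The derivation is a small deterministic hash of
#' the stage name folded into the global seed, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

## chrom lengths: named numeric vector -> Seqinfo
as_seqinfo <- function(chrom_lengths) {
  Seqinfo(seqnames = names(chrom_lengths),
          seqlengths = as.integer(chrom_lengths))
}

## build a GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, strand = "*", chrom_lengths = NULL) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0),
                strand = strand)
  if (!is.null(chrom_lengths))
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(chrom_lengths)[seqlevels(gr)]
  gr
}

## 0-based start / half-open end of a GRanges
start0 <- function(gr) BiocGenerics::start(gr) - 1L
end0 <- function(gr) BiocGenerics::end(gr)

## feature id as chrom:start-end (0-based half-open), the bin naming scheme
region_id <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start0(gr), end0(gr))
}
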