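## Feature-universe construction: CpG islands sub-typed by genomic
## location, 2-kb CGI shores, coding sequences, and promoters classified
## by CpG content (HCP / ICP / LCP).

#' Feature class labels used across the package
#' @export
FEATURE_CLASSES <- c("CGI_PROMOTER", "CGI_INTRAGENIC", "CGI_3UTR",
                     "CGI_INTERGENIC", "SHORE_PROMOTER", "SHORE_INTRAGENIC",
                     "SHORE_3UTR", "SHORE_INTERGENIC", "CDS",
                     "HCP", "ICP", "LCP")

## gene-model accessors -----------------------------------------------------
## genes: GRanges with strand and mcols gene_id, utr3_len (bp of terminal
## 3'UTR). TSS = 5' end by strand; CDS = gene body minus the 3'UTR.

check_genes <- function(genes) {
  unstranded <- as.character(strand(genes)) == "*"
  if (any(unstranded)) {
    ids <- mcols(genes)$gene_id %||% as.character(which(unstranded))
    stopf("gene(s) without strand: %s",
          paste(utils::head(ids[unstranded], 3), collapse = ", "))
  }
  if (is.null(mcols(genes)$gene_id))
    mcols(genes)$gene_id <- sprintf("gene_%d", seq_along(genes))
  genes
}

#' Transcription start sites of a set of gene models
#' @param genes stranded gene `GRanges`.
#' @return width-1 `GRanges` at each gene's 5' end.
#' @export
tss_sites <- function(genes) {
  genes <- check_genes(genes)
  suppressWarnings(resize(granges(genes), width = 1L, fix = "start"))
}

#' 3' UTR spans of gene models
#' @param genes gene `GRanges` with an `utr3_len` metadata column.
#' @return `GRanges` of the terminal `utr3_len` bp of each gene.
#' @export
utr3_ranges <- function(genes) {
  genes <- check_genes(genes)
  len <- pmin(mcols(genes)$utr3_len %||% 0L, width(genes))
  out <- suppressWarnings(resize(granges(genes), width = len, fix = "end"))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  out
}

#' Coding-sequence spans (gene body minus the 3' UTR)
#' @param genes gene `GRanges` with an `utr3_len` metadata column.
#' @return `GRanges` of CDS intervals.
#' @export
cds_ranges <- function(genes) {
  genes <- check_genes(genes)
  len <- pmax(width(genes) - (mcols(genes)$utr3_len %||% 0L), 1L)
  out <- suppressWarnings(resize(granges(genes), width = len, fix = "start"))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  out
}

## strand-aware promoter window [TSS - up, TSS + down), clipped; built as
## a plain GRanges (no seqinfo) so near-boundary windows never trip
## out-of-bounds validity before clipping
promoter_windows <- function(genes, up = 1000L, down = 500L,
                             chrom_lengths = NULL) {
  genes <- check_genes(genes)
  str <- as.character(strand(genes))
  gs0 <- start0(genes); ge0 <- end0(genes)
  s0 <- ifelse(str == "+", gs0 - up, ge0 - down)
  e0 <- ifelse(str == "+", gs0 + down, ge0 + up)
  s0 <- pmax(0, s0)
  if (!is.null(chrom_lengths))
    e0 <- pmin(e0, as.numeric(chrom_lengths[as.character(seqnames(genes))]))
  w <- GRanges(seqnames(genes), IRanges(s0 + 1L, e0), strand = str)
  mcols(w)$gene_id <- mcols(genes)$gene_id
  w
}

#' Sub-type CpG islands by genomic location
#'
#' Each CGI is assigned exactly one location class with precedence
#' promoter > 3'UTR > intragenic > intergenic: promoter status dominates
#' when a CGI spans multiple contexts. A CGI overlapping the promoter
#' windows of several genes is linked to the gene with the nearest TSS.
#'
#' @param cgis CGI `GRanges` (non-overlapping).
#' @param genes stranded gene `GRanges` with `gene_id` and `utr3_len`.
#' @param promoter_up,promoter_down promoter window around the TSS in bp
#'   (default \[TSS-1000, TSS+500) in the direction of transcription).
#' @return the CGIs with metadata columns `class` (one of `CGI_PROMOTER`,
#'   `CGI_3UTR`, `CGI_INTRAGENIC`, `CGI_INTERGENIC`) and `gene_id`.
#' @export
classify_cgi_location <- function(cgis, genes, promoter_up = 1000L,
                                  promoter_down = 500L) {
  genes <- check_genes(genes)
  cls <- rep("CGI_INTERGENIC", length(cgis))
  gid <- rep(NA_character_, length(cgis))
  if (length(genes)) {
    body_hit <- overlapsAny(cgis, granges(genes), ignore.strand = TRUE)
    utr <- utr3_ranges(genes)
    utr_hit <- overlapsAny(cgis, utr, ignore.strand = TRUE)
    prom <- promoter_windows(genes, promoter_up, promoter_down)
    ovp <- findOverlaps(cgis, prom, ignore.strand = TRUE)
    cls[body_hit] <- "CGI_INTRAGENIC"
    ## gene_id for intragenic/3'UTR: first overlapping gene
    ovb <- findOverlaps(cgis, granges(genes), ignore.strand = TRUE,
                        select = "first")
    gid[!is.na(ovb)] <- mcols(genes)$gene_id[ovb[!is.na(ovb)]]
    cls[utr_hit] <- "CGI_3UTR"
    ou <- findOverlaps(cgis, utr, ignore.strand = TRUE, select = "first")
    gid[utr_hit] <- mcols(utr)$gene_id[ou[utr_hit]]
    if (length(ovp)) {
      qh <- queryHits(ovp); sh <- subjectHits(ovp)
      if (anyDuplicated(qh)) {
        ## nearest-TSS tie-break among overlapping promoter windows
        tss <- BiocGenerics::start(tss_sites(genes))
        mid <- (BiocGenerics::start(cgis) + BiocGenerics::end(cgis)) / 2
        d <- abs(mid[qh] - tss[sh])
        o <- order(qh, d)
        qh <- qh[o]; sh <- sh[o]
        keep <- !duplicated(qh)
        qh <- qh[keep]; sh <- sh[keep]
        message(sprintf(
          "%d CGI(s) overlap multiple promoters; assigned to nearest TSS",
          sum(duplicated(queryHits(ovp)))))
      }
      cls[qh] <- "CGI_PROMOTER"
      gid[qh] <- mcols(genes)$gene_id[sh]
    }
  }
  out <- granges(cgis)
  mcols(out)$class <- cls
  mcols(out)$gene_id <- gid
  out
}

#' Build CGI shores
#'
#' Two shores per CGI, spanning `shore_width` bp (default 2,000) up- and
#' downstream, clipped at chromosome ends, with any bases falling inside
#' another CGI subtracted so shores never overlap island bases. When the
#' input CGIs carry a location `class` (`CGI_*`), shores inherit it as
#' `SHORE_*`.
#'
#' @param cgis CGI `GRanges`, sorted and non-overlapping per chromosome.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param shore_width shore span in bp (default 2000).
#' @return shore `GRanges` with `class`, `cgi_id` (parent index) and `side`.
#' @export
make_shores <- function(cgis, chrom_lengths, shore_width = 2000L) {
  if (length(cgis) == 0L) return(GRanges())
  w <- as.integer(shore_width)
  L <- as.integer(chrom_lengths[as.character(seqnames(cgis))])
  left <- GRanges(seqnames(cgis),
                  IRanges(start = pmax(1L, BiocGenerics::start(cgis) - w),
                          end = BiocGenerics::start(cgis) - 1L))
  right <- GRanges(seqnames(cgis),
                   IRanges(start = BiocGenerics::end(cgis) + 1L,
                           end = pmin(L, BiocGenerics::end(cgis) + w)))
  parent_class <- mcols(cgis)$class
  shore_class <- if (is.null(parent_class)) rep("SHORE", length(cgis)) else
    sub("^CGI_", "SHORE_", parent_class)
  shores <- c(left, right)
  mcols(shores)$cgi_id <- rep(seq_along(cgis), 2L)
  mcols(shores)$side <- rep(c("left", "right"), each = length(cgis))
  mcols(shores)$class <- rep(shore_class, 2L)
  shores <- shores[width(shores) > 0L]
  ## punch out any bases that fall inside a CGI
  cgi_plain <- granges(cgis)
  hit <- overlapsAny(shores, cgi_plain, ignore.strand = TRUE)
  if (any(hit)) {
    pieces <- lapply(which(hit), function(i) {
      p <- GenomicRanges::setdiff(granges(shores[i]), cgi_plain,
                                  ignore.strand = TRUE)
      if (length(p)) {
        md <- mcols(shores)[rep(i, length(p)), , drop = FALSE]
        mcols(p) <- md
      }
      p
    })
    shores <- c(shores[!hit], do.call(c, pieces))
  }
  sort_features(shores)
}

#' Classify one promoter from per-sub-window statistics
#'
#' The CpG-content rule: HCP if any sub-window has GC fraction >=
#' `gc_hcp` and CpG observed/expected ratio >= `ratio_hcp`; LCP if no
#' sub-window reaches `ratio_lcp`; ICP otherwise.
#'
#' @param gc numeric vector of GC fractions, one per sub-window.
#' @param ratio numeric vector of CpG o/e ratios, same length.
#' @param gc_hcp,ratio_hcp,ratio_lcp classification thresholds.
#' @return one of `"HCP"`, `"ICP"`, `"LCP"`.
#' @export
promoter_class_from_stats <- function(gc, ratio, gc_hcp = 0.55,
                                      ratio_hcp = 0.75, ratio_lcp = 0.48) {
  stopifnot(length(gc) == length(ratio), length(gc) > 0)
  if (any(gc >= gc_hcp & ratio >= ratio_hcp)) return("HCP")
  if (all(ratio < ratio_lcp)) return("LCP")
  "ICP"
}

#' Classify promoters by CpG content (HCP / ICP / LCP)
#'
#' Each gene's promoter window (\[TSS-700, TSS+200) by default) is scanned
#' with sliding sub-windows; per sub-window the GC fraction and the CpG
#' observed/expected ratio `#CpG * len / (#C * #G)` are computed. Since the
#' synthetic genome carries no literal sequence, `#C` and `#G` derive from
#' a configured GC fraction (a `promoter_gc` metadata column on the genes,
#' or the scalar `gc` fallback), while `#CpG` is counted from the CpG
#' position track.
#'
#' @param genes stranded gene `GRanges`.
#' @param cpg CpG position `GRanges`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param gc fallback GC fraction when genes carry no `promoter_gc` column.
#' @param up,down promoter window around the TSS, bp.
#' @param subwindow sliding sub-window width, bp (default 500).
#' @param slide sub-window offset, bp (default 5).
#' @param gc_hcp,ratio_hcp,ratio_lcp thresholds passed to
#'   [promoter_class_from_stats()].
#' @return promoter-window `GRanges` with `class` and `gene_id`.
#' @export
classify_promoters <- function(genes, cpg, chrom_lengths, gc = 0.5,
                               up = 700L, down = 200L, subwindow = 500L,
                               slide = 5L, gc_hcp = 0.55, ratio_hcp = 0.75,
                               ratio_lcp = 0.48) {
  genes <- check_genes(genes)
  win <- promoter_windows(genes, up, down, chrom_lengths)
  gc_gene <- mcols(genes)$promoter_gc %||% rep(gc, length(genes))
  cpg_by_chrom <- lapply(split(BiocGenerics::start(cpg),
                               as.character(seqnames(cpg))), sort)
  n_short <- 0L
  cls <- vapply(seq_along(win), function(i) {
    s <- BiocGenerics::start(win)[i]; e <- BiocGenerics::end(win)[i]
    ch <- as.character(seqnames(win))[i]
    if (e - s + 1L < subwindow) {
      n_short <<- n_short + 1L
      starts <- s; ends <- e
    } else {
      starts <- seq.int(s, e - subwindow + 1L, by = as.integer(slide))
      ends <- starts + subwindow - 1L
    }
    pos <- cpg_by_chrom[[ch]] %||% numeric(0)
    n_cpg <- findInterval(ends, pos) - findInterval(starts - 1L, pos)
    len <- ends - starts + 1
    g <- gc_gene[i]
    ## o/e ratio with #C = #G = gc*len/2
    denom <- (g * len / 2)^2
    ratio <- ifelse(denom > 0, n_cpg * len / denom, 0)
    promoter_class_from_stats(rep(g, length(starts)), ratio,
                              gc_hcp, ratio_hcp, ratio_lcp)
  }, "")
  if (n_short > 0)
    message(sprintf(
      "%d promoter window(s) shorter than %d bp classified on full window",
      n_short, subwindow))
  mcols(win)$class <- cls
  win
}

#' Build the full annotated feature universe of a genome
#'
#' Combines location-sub-typed CGIs, their shores (inheriting the parent
#' subtype), CDS spans and CpG-content promoter classes into one `GRanges`
#' with stable feature ids.
#'
#' @param genome a `SyntheticGenome` (or any list with `chrom_lengths`,
#'   `cpg`, `cgis`, `genes`).
#' @param shore_width shore span bp.
#' @param promoter_up,promoter_down CGI-subtyping promoter window bp.
#' @param ... passed to [classify_promoters()].
#' @return `GRanges` with metadata `feature_id`, `class`, `gene_id`.
#' @export
annotate_features <- function(genome, shore_width = 2000L,
                              promoter_up = 1000L, promoter_down = 500L,
                              ...) {
  cgis <- classify_cgi_location(genome$cgis, genome$genes,
                                promoter_up, promoter_down)
  mcols(cgis)$feature_id <- sprintf("cgi_%04d", seq_along(cgis))
  shores <- make_shores(cgis, genome$chrom_lengths, shore_width)
  if (length(shores)) {
    mcols(shores)$feature_id <- sprintf("shore_%04d_%s",
                                        mcols(shores)$cgi_id,
                                        mcols(shores)$side)
    mcols(shores)$gene_id <- NA_character_
  }
  cds <- cds_ranges(genome$genes)
  mcols(cds)$class <- "CDS"
  mcols(cds)$feature_id <- sprintf("cds_%s", mcols(cds)$gene_id)
  prom <- classify_promoters(genome$genes, genome$cpg,
                             genome$chrom_lengths, ...)
  mcols(prom)$feature_id <- sprintf("prom_%s", mcols(prom)$gene_id)
  keep_cols <- c("feature_id", "class", "gene_id")
  pick <- function(gr) {
    md <- mcols(gr)
    for (k in setdiff(keep_cols, colnames(md))) md[[k]] <- NA_character_
    mcols(gr) <- md[, keep_cols]
    gr
  }
  feats <- suppressWarnings(c(pick(cgis), pick(shores), pick(cds),
                              pick(prom)))
  feats <- feats[width(feats) > 0L]
  names(feats) <- mcols(feats)$feature_id
  feats
}
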