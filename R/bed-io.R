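#' Read a BED3/BED6 file into a GRanges
#'
#' Coordinates on disk are 0-based half-open (BED convention); the returned
#' `GRanges` uses the usual 1-based closed representation. Lines are
#' validated before parsing so that malformed input is reported with its
#' line number.
#'
#' @param path path to a BED file.
#' @return a `GRanges`; the BED name column, when present, is carried in
#'   `mcols()$name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  body <- lines[keep]
  if (length(body) == 0L) return(GRanges())
  ln <- which(keep)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("%s: line %d has %d fields (need >= 3)",
          path, ln[which(nf < 3L)[1]], nf[which(nf < 3L)[1]])
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(st) | is.na(en))
  if (length(bad))
    stopf("%s: line %d has non-numeric coordinates", path, ln[bad[1]])
  bad <- which(st >= en)
  if (length(bad))
    stopf("%s: line %d has start >= end (%g >= %g)",
          path, ln[bad[1]], st[bad[1]], en[bad[1]])
  gr <- rtracklayer::import(path, format = "BED")
  sort_features(gr)
}

#' Write a GRanges as BED6
#'
#' The inverse of [read_bed()]: intervals are written 0-based half-open and
#' sorted by (chrom, start, end). A `name` or `class` metadata column is
#' written to the BED name field.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- sort_features(gr)
  nm <- mcols(gr)$name %||% mcols(gr)$class %||% mcols(gr)$feature_id
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start0(gr),
    end = end0(gr),
    name = if (is.null(nm)) "." else as.character(nm),
    score = 0L,
    strand = ifelse(as.character(strand(gr)) == "*", ".",
                    as.character(strand(gr))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## stable (chrom, start, end) ordering, independent of seqlevel order
sort_features <- function(gr) {
  gr[order(as.character(seqnames(gr)), BiocGenerics::start(gr),
           BiocGenerics::end(gr))]
}
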