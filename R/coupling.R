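## Genome binning, CpG coupling factors, calibration and relative
## methylation scores. The normalization follows the MEDIPS-style logic:
## MeDIP enrichment at a bin is confounded by how many CpGs the antibody
## could have captured there, so raw signal is divided by the signal
## expected at that bin's CpG coupling factor, read off a calibration line
## fitted over the ascending part of the mean-signal-vs-CF curve.

#' Tile chromosomes with overlapping bins
#'
#' Bins of `bin_size` bp are laid at every multiple of `step` (default
#' 500 bp bins every 250 bp, i.e. two-fold overlapping). The final bins on
#' each chromosome are clipped at the chromosome end; a chromosome shorter
#' than `bin_size` gets a single full-length bin.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param step offset between consecutive bin starts, `0 < step <= bin_size`.
#' @return a `GRanges` of bins carrying `seqinfo`.
#' @export
make_bins <- function(chrom_lengths, bin_size = 500L, step = 250L) {
  if (bin_size <= 0) stopf("bin_size must be positive")
  if (step <= 0 || step > bin_size)
    stopf("step must satisfy 0 < step <= bin_size (got step=%d, bin_size=%d)",
          step, bin_size)
  if (is.null(names(chrom_lengths))) stopf("chrom_lengths must be named")
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    if (L <= bin_size) {
      starts <- 0L
    } else {
      starts <- seq.int(0L, L - 1L, by = as.integer(step))
    }
    gr0(ch, starts, pmin(starts + as.integer(bin_size), L),
        chrom_lengths = NULL)
  })
  bins <- suppressWarnings(do.call(c, per_chrom))
  GenomeInfoDb::seqinfo(bins) <- as_seqinfo(chrom_lengths)[seqlevels(bins)]
  bins
}

#' Count reads in overlapping bins by the midpoint rule
#'
#' Each read (or fragment interval) is assigned to every bin containing its
#' midpoint, so on a two-fold overlapping grid a read contributes to at
#' most two bins and is never double counted within one step window.
#'
#' @param reads `GRanges` of read/fragment intervals.
#' @param bins bin `GRanges` from [make_bins()].
#' @return integer vector of counts, one per bin.
#' @export
count_reads_in_bins <- function(reads, bins) {
  if (length(reads) == 0L) return(integer(length(bins)))
  on_chrom <- as.character(seqnames(reads)) %in% seqlevels(bins)
  sl <- seqlengths(bins)
  mid0 <- (start0(reads) + end0(reads)) %/% 2L
  in_range <- on_chrom
  idx <- which(on_chrom)
  if (length(idx)) {
    lens <- sl[as.character(seqnames(reads))[idx]]
    in_range[idx] <- mid0[idx] >= 0L & mid0[idx] < lens
  }
  n_skip <- sum(!in_range)
  if (n_skip > 0)
    warnf("%d read(s) fall outside the binned chromosomes and were skipped",
          n_skip)
  reads <- reads[in_range]
  if (length(reads) == 0L) return(integer(length(bins)))
  mids <- GRanges(seqnames(reads),
                  IRanges(start = mid0[in_range] + 1L, width = 1L))
  countOverlaps(bins, mids)
}

#' CpG coupling factor per bin
#'
#' The coupling factor CF of a bin is the number of CpG positions within
#' `max_distance` bp around it: all CpGs `p` with
#' `bin_start - max_distance <= p < bin_end + max_distance` (0-based
#' coordinates). CF is the proxy for the maximal possible MeDIP signal at
#' the bin.
#'
#' @param bins bin `GRanges`.
#' @param cpg `GRanges` of single-bp CpG positions.
#' @param max_distance window extension in bp (default 500, fragment scale).
#' @return numeric vector of CF values, one per bin.
#' @export
coupling_factor <- function(bins, cpg, max_distance = 500L) {
  if (max_distance < 0) stopf("max_distance must be >= 0")
  if (length(cpg) == 0L) return(numeric(length(bins)))
  win <- GRanges(seqnames(bins),
                 IRanges(start = pmax(1L, BiocGenerics::start(bins) -
                                        as.integer(max_distance)),
                         end = BiocGenerics::end(bins) +
                           as.integer(max_distance)))
  cpg_plain <- GRanges(seqnames(cpg), ranges(cpg))
  as.numeric(countOverlaps(win, cpg_plain))
}

#' Fit the MeDIP calibration curve
#'
#' Bins are grouped by their (integer-rounded) coupling factor; sparse
#' levels (fewer than `min_bins` bins) are pooled with the next level up.
#' Mean reads-per-million is computed per level and a least-squares line is
#' fitted over the ascending portion of the curve: levels from CF = 1 up to
#' the level with maximal mean signal. Beyond that level the antibody
#' saturates and the linear dependence no longer holds.
#'
#' @param rpm reads-per-million per bin.
#' @param cf coupling factor per bin.
#' @param min_bins minimum bins per CF level before pooling (default 10).
#' @return a `CalibrationCurve` object: list with the pooled `levels`, their
#'   `mean_rpm` and `n_bins`, the fitted `intercept` and `slope`, and the
#'   fit range `cf_lo`, `cf_hi`.
#' @export
calibration_curve <- function(rpm, cf, min_bins = 10L) {
  stopifnot(length(rpm) == length(cf))
  lev <- round(cf)
  ok <- is.finite(rpm) & is.finite(lev)
  lev <- lev[ok]; r <- rpm[ok]
  ulev <- sort(unique(lev))
  ## pool sparse levels upward
  groups <- list(); cur_idx <- integer(0)
  for (u in ulev) {
    cur_idx <- c(cur_idx, which(lev == u))
    if (length(cur_idx) >= min_bins) {
      groups[[length(groups) + 1L]] <- cur_idx
      cur_idx <- integer(0)
    }
  }
  if (length(cur_idx)) {
    if (length(groups)) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur_idx)
    } else groups[[1L]] <- cur_idx
  }
  lev_mean <- vapply(groups, function(i) mean(lev[i]), 0)
  rpm_mean <- vapply(groups, function(i) mean(r[i]), 0)
  n_bins <- vapply(groups, length, 0L)
  use <- lev_mean >= 1
  if (sum(use) < 2L)
    stopf("calibration needs >= 2 CF levels with CF >= 1 (got %d)", sum(use))
  i_max <- which(use)[which.max(rpm_mean[use])]
  cf_hi <- lev_mean[i_max]
  asc <- use & lev_mean <= cf_hi
  if (sum(asc) < 2L)
    stopf(paste("no ascending CpG-density dependence (flat or immediately",
                "decreasing calibration curve): normalization is not",
                "meaningful"))
  ## weighted by bins per level: levels estimated from more bins carry
  ## more information, and the line then fits best where the genome's
  ## CF mass actually lies
  fit <- lm(y ~ x, data = data.frame(x = lev_mean[asc], y = rpm_mean[asc]),
            weights = n_bins[asc])
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    stopf(paste("calibration slope is not positive (%.3g): no CpG-density",
                "dependence detected, normalization is not meaningful"), b)
  structure(list(levels = lev_mean, mean_rpm = rpm_mean, n_bins = n_bins,
                 intercept = a, slope = b,
                 cf_lo = min(lev_mean[asc]), cf_hi = cf_hi),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf(
    "CalibrationCurve: %d CF levels, fit rpm = %.4g + %.4g * CF on [%g, %g]\n",
    length(x$levels), x$intercept, x$slope, x$cf_lo, x$cf_hi))
  invisible(x)
}

#' Expected signal at a coupling factor under a calibration curve
#'
#' Linear interpolation of the pooled per-level mean signal over the
#' ascending calibration range, with CF capped at the saturation level
#' `cf_hi` and constant extension below the lowest level. Tracking the
#' empirical curve (rather than the fitted straight line) keeps the
#' corrected scores free of residual CpG-density dependence when antibody
#' capture saturates; the fitted line remains the validity check and
#' summary of the dependence.
#'
#' @param calib a `CalibrationCurve`.
#' @param cf coupling factor(s).
#' @return expected mean rpm at each `cf`.
#' @export
expected_signal <- function(calib, cf) {
  asc <- calib$levels >= calib$cf_lo & calib$levels <= calib$cf_hi
  x <- calib$levels[asc]; y <- calib$mean_rpm[asc]
  stats::approx(x, y, xout = pmin(cf, calib$cf_hi), rule = 2)$y
}

#' CpG-density-corrected relative methylation score
#'
#' Divides each bin's reads-per-million by the signal expected at its
#' coupling factor under the calibration curve (see [expected_signal()];
#' CF capped at the saturation level `cf_hi`), then scales the ratio into
#' \[0, 1\] by its 99th percentile over CpG-containing bins. Bins with
#' CF = 0 carry no possible MeDIP signal and get `NA`.
#'
#' @param rpm reads-per-million per bin.
#' @param cf coupling factor per bin.
#' @param calib a `CalibrationCurve`.
#' @param eps lower guard on the expected signal (default 1e-6).
#' @param scale_quantile quantile used to map raw ratios into \[0,1\]
#'   (default 0.99; more robust than the maximum).
#' @return numeric vector of rms values in \[0,1\] (`NA` where CF = 0).
#' @export
rms_normalize <- function(rpm, cf, calib, eps = 1e-6, scale_quantile = 0.99) {
  stopifnot(inherits(calib, "CalibrationCurve"), length(rpm) == length(cf))
  expected <- expected_signal(calib, cf)
  raw <- rpm / pmax(eps, expected)
  pos <- cf > 0
  q <- if (any(pos)) quantile(raw[pos], scale_quantile, na.rm = TRUE,
                              names = FALSE) else 0
  rms <- if (q > 0) pmin(raw / q, 1) else rep(0, length(raw))
  rms[!pos] <- NA_real_
  rms
}

#' Normalize a bin-by-sample count matrix to relative methylation scores
#'
#' Convenience wrapper running, per sample: reads-per-million scaling,
#' calibration-curve fitting ([calibration_curve()]) and rms computation
#' ([rms_normalize()]) against a shared coupling-factor track.
#'
#' @param counts integer matrix, bins x samples.
#' @param bins bin `GRanges` matching the rows.
#' @param cpg CpG position `GRanges`.
#' @param max_distance CF window extension bp.
#' @param min_bins minimum bins per calibration level.
#' @param ... passed to [rms_normalize()].
#' @return list with `rms` and `rpm` matrices (bins x samples), the `cf`
#'   vector, the `bins` and per-sample `calibrations`.
#' @export
medip_normalize <- function(counts, bins, cpg, max_distance = 500L,
                            min_bins = 10L, ...) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(bins))
    stopf("counts has %d rows but there are %d bins",
          nrow(counts), length(bins))
  cf <- coupling_factor(bins, cpg, max_distance)
  totals <- colSums(counts)
  if (any(totals == 0)) stopf("sample(s) with zero total reads: %s",
                              paste(colnames(counts)[totals == 0],
                                    collapse = ", "))
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  calibs <- lapply(seq_len(ncol(rpm)), function(j)
    calibration_curve(rpm[, j], cf, min_bins = min_bins))
  rms <- vapply(seq_len(ncol(rpm)), function(j)
    rms_normalize(rpm[, j], cf, calibs[[j]], ...), numeric(nrow(rpm)))
  dimnames(rms) <- dimnames(rpm) <- dimnames(counts)
  names(calibs) <- colnames(counts)
  list(rms = rms, rpm = rpm, cf = cf, bins = bins, calibrations = calibs)
}

#' Write bin scores as a bedGraph track
#'
#' The overlapping bin grid is collapsed to non-overlapping step windows;
#' each step window's value is the mean score of the bins overlapping it.
#' Windows whose every overlapping bin is `NA`-flagged are omitted.
#'
#' @param scores numeric vector, one score per bin.
#' @param bins bin `GRanges` from [make_bins()].
#' @param path output path.
#' @param step step window size in bp; by default inferred as the smallest
#'   distance between consecutive bin starts.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(scores, bins, path, step = NULL) {
  stopifnot(length(scores) == length(bins))
  if (is.null(step)) {
    d <- diff(BiocGenerics::start(bins))
    d <- d[d > 0]
    step <- if (length(d)) min(d) else width(bins)[1]
  }
  sl <- seqlengths(bins)
  wins <- make_bins(sl[!is.na(sl)], bin_size = step, step = step)
  ov <- findOverlaps(wins, bins, minoverlap = 1L)
  qf <- factor(queryHits(ov), levels = seq_along(wins))
  val <- as.numeric(tapply(scores[subjectHits(ov)], qf, mean, na.rm = TRUE))
  keep <- is.finite(val)
  out <- wins[keep]
  mcols(out)$score <- val[keep]
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stopf("output directory does not exist: %s", dirname(path))
  rtracklayer::export(out, path, format = "bedGraph")
  invisible(path)
}
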