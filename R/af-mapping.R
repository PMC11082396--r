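#' Per-variant mutant allele frequency
#'
#' `AF = ad_alt / (ad_ref + ad_alt)`. Sites with zero total depth have no
#' defined frequency and are a hard error; filter them out first (as
#' [sliding_median()] does).
#'
#' @param variants A [variant_table()].
#' @return Numeric vector of allele frequencies in `[0, 1]`.
#' @export
allele_frequency <- function(variants) {
  total <- variants$ad_ref + variants$ad_alt
  if (any(total == 0))
    stop("allele frequency undefined at zero total depth (",
         sum(total == 0), " site(s)); filter by depth first")
  variants$ad_alt / total
}

#' Sliding-window median allele frequency track
#'
#' The mapping signal of a pooled-F2 scan: per chromosome, variants passing
#' the total-depth filter are windowed in runs of `window_size` consecutive
#' variants (step 1) and the median allele frequency of each window is
#' reported. Chromosomes with fewer retained variants than `window_size`
#' contribute no windows; the median of an even-sized window is the mean of
#' the two central order statistics.
#'
#' @param variants A [variant_table()] (any order; sorted internally).
#' @param window_size Number of variants per window (default 100).
#' @param min_total_depth Minimum `ad_ref + ad_alt` for a variant to enter any
#'   window (default 15).
#' @return A `data.frame` (class `window_track`) with columns `chrom`,
#'   `start`, `end` (positions of the first/last member variant), `median_af`,
#'   `n` (member count, always `window_size`).
#' @export
sliding_median <- function(variants, window_size = 100, min_total_depth = 15) {
  if (window_size < 1) stop("window_size must be >= 1")
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  v <- v[v$ad_ref + v$ad_alt >= min_total_depth, , drop = FALSE]
  out <- list()
  for (ch in unique(v$chrom)) {
    vc <- v[v$chrom == ch, , drop = FALSE]
    n <- nrow(vc)
    if (n < window_size) next
    af <- allele_frequency(vc)
    k <- n - window_size + 1L
    med <- vapply(seq_len(k), function(i)
      median(af[i:(i + window_size - 1L)]), numeric(1))
    out[[ch]] <- data.frame(
      chrom = ch,
      start = vc$pos[seq_len(k)],
      end = vc$pos[seq_len(k) + window_size - 1L],
      median_af = med, n = window_size, stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, c(out, list(data.frame(
    chrom = character(), start = integer(), end = integer(),
    median_af = numeric(), n = integer(), stringsAsFactors = FALSE))))
  rownames(track) <- NULL
  class(track) <- c("window_track", "data.frame")
  track
}

#' Call enriched (conserved) regions from a window track
#'
#' Maximal runs of at least `min_windows` consecutive windows whose median
#' allele frequency is at least `af_min`, merged per chromosome. A region
#' spans from the start of its first window to the end of its last.
#'
#' @param track A window track from [sliding_median()].
#' @param af_min Median-AF threshold for a window to be enriched (default 0.9).
#' @param min_windows Minimum run length (default 5).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `mean_af`
#'   (mean of member window medians), `n_windows`.
#' @export
call_regions <- function(track, af_min = 0.9, min_windows = 5) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tc <- track[track$chrom == ch, , drop = FALSE]
    hot <- tc$median_af >= af_min
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_windows)) {
      i1 <- starts[j]; i2 <- ends[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = tc$start[i1], end = tc$end[i2],
        mean_af = mean(tc$median_af[i1:i2]), n_windows = i2 - i1 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, c(out, list(data.frame(
    chrom = character(), start = integer(), end = integer(),
    mean_af = numeric(), n_windows = integer(), stringsAsFactors = FALSE))))
  rownames(regions) <- NULL
  regions
}
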