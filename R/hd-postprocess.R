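# High-density aggregation: pool the offset instances, threshold at the
# rank-5000 score, explode kept windows into 10-bp bins, sum bin scores,
# call peaks on the summed track, and apply the amplitude-then-score
# two-stage elbow cutoff.

#' Bundle per-offset scan instances
#'
#' @param instances Named list mapping offset (as character or via
#'   `offsets`) to a `GRanges` of scored windows (as from [scan_genome()]).
#' @param window,shift Window width and shift shared by all instances.
#' @param bin Bin width for postprocessing (default 10); all offsets must be
#'   multiples of it.
#' @return An object of class `hd_bundle`.
#' @export
hd_bundle <- function(instances, window = 500L, shift = 250L, bin = 10L) {
  if (!is.list(instances) || length(instances) == 0L)
    stop("`instances` must be a non-empty list of scored-window GRanges", call. = FALSE)
  offs <- suppressWarnings(as.integer(names(instances)))
  if (anyNA(offs))
    stop("`instances` must be named by integer offsets", call. = FALSE)
  if (any(offs %% bin != 0L))
    stop("all offsets must be multiples of the bin width", call. = FALSE)
  for (g in instances) {
    g <- .as_granges(g)
    if (!"score" %in% names(mcols(g)))
      stop("every instance must carry a `score` metadata column", call. = FALSE)
  }
  structure(list(instances = instances, offsets = offs,
                 window = as.integer(window), shift = as.integer(shift),
                 bin = as.integer(bin)), class = "hd_bundle")
}

#' @export
print.hd_bundle <- function(x, ...) {
  cat(sprintf("hd_bundle: %d instance(s) (offsets %s), window %d, shift %d, bin %d; %d windows total\n",
              length(x$instances),
              paste(range(x$offsets), collapse = ".."),
              x$window, x$shift, x$bin,
              sum(vapply(x$instances, length, 1L))))
  invisible(x)
}

#' Pool instances and threshold at the top-N score
#'
#' Concatenates the windows of every instance, ranks the pooled list and
#' computes `theta`, the score of the `rank_cutoff`-th pooled window (the
#' smallest score when fewer windows exist). Windows scoring below `theta`
#' are discarded (equivalently, reset to zero); ties at `theta` are kept.
#'
#' @param bundle An [hd_bundle()].
#' @param rank_cutoff Pooled rank defining the threshold (default 5000).
#' @return A list with `kept` (ranked `GRanges` of retained windows) and
#'   `theta` (the threshold score).
#' @export
concat_and_threshold <- function(bundle, rank_cutoff = 5000L) {
  stopifnot(inherits(bundle, "hd_bundle"))
  .assert_scalar_number(rank_cutoff, "rank_cutoff", lower = 1)
  pooled <- suppressWarnings(do.call(c, unname(bundle$instances)))
  if (length(pooled) == 0L)
    stop("the pooled window list is empty; nothing to threshold", call. = FALSE)
  ranked <- take_top(pooled, top_n = length(pooled))
  theta <- mcols(ranked)$score[min(length(ranked), as.integer(rank_cutoff))]
  kept <- ranked[mcols(ranked)$score >= theta]
  list(kept = kept, theta = theta)
}

#' Explode scored windows into fixed-width bins
#'
#' Splits each window into `window_width / bin` consecutive segments, each
#' retaining the score of its parent window. Window starts (0-based) and
#' widths must be multiples of `bin`, which the canonical protocol
#' guarantees by using offsets and a shift that are multiples of 10.
#'
#' @param kept A `GRanges` of scored windows, all the same width.
#' @param bin Bin width in bp (default 10).
#' @return A `GRanges` of width-`bin` segments with a `score` column.
#' @export
explode_bins <- function(kept, bin = 10L) {
  kept <- .as_granges(kept)
  bin <- as.integer(bin)
  if (length(kept) == 0L) {
    gr <- GRanges(); mcols(gr)$score <- numeric(0); return(gr)
  }
  if (!"score" %in% names(mcols(kept)))
    stop("windows must carry a `score` metadata column", call. = FALSE)
  start0 <- start(kept) - 1L
  if (any(start0 %% bin != 0L))
    stop(sprintf("window start %d is not on the %d-bp bin grid",
                 start0[which(start0 %% bin != 0L)[1L]], bin), call. = FALSE)
  if (any(width(kept) %% bin != 0L))
    stop("window width must be a multiple of the bin width", call. = FALSE)
  per <- width(kept) %/% bin
  i <- rep(seq_along(kept), per)
  off <- unlist(lapply(per, function(m) seq_len(m) - 1L)) * bin
  gr <- GRanges(as.character(seqnames(kept))[i],
                IRanges(start(kept)[i] + off, width = bin))
  mcols(gr)$score <- mcols(kept)$score[i]
  gr
}

#' Sum bin scores into a genome-wide track
#'
#' Segments sharing the same coordinates are merged and their scores summed.
#' Bins never touched by a segment are absent (implicitly zero).
#'
#' @param segments A `GRanges` of equal-width bin segments with `score`.
#' @param bin Bin width (recorded on the result).
#' @return A `GRanges` "bin track" in coordinate order with a `value`
#'   metadata column; the bin width is stored in `metadata(track)$bin_width`.
#' @export
sum_bins <- function(segments, bin = 10L) {
  segments <- .as_granges(segments)
  if (length(segments) == 0L) {
    gr <- GRanges(); mcols(gr)$value <- numeric(0)
    S4Vectors::metadata(gr)$bin_width <- as.integer(bin)
    return(gr)
  }
  chrom <- as.character(seqnames(segments))
  st <- start(segments)
  key <- paste0(chrom, "\r", st)
  first <- !duplicated(key)
  value <- base::rowsum(mcols(segments)$score, key, reorder = FALSE)[, 1L]
  o <- order(chrom[first], st[first])
  gr <- GRanges(chrom[first][o], IRanges(st[first][o], width = as.integer(bin)))
  mcols(gr)$value <- unname(value[o])
  S4Vectors::metadata(gr)$bin_width <- as.integer(bin)
  gr
}

#' Call peaks on a summed bin track
#'
#' A peak is a maximal run of bins with value strictly greater than
#' `cutoff`; runs on the same chromosome separated by at most `max_gap` bp
#' of sub-cutoff signal are merged, and merged runs shorter than
#' `min_length` bp are discarded. Defaults (min length 200 bp, max gap
#' 30 bp) follow the bedGraph peak caller the protocol uses downstream of
#' the summed track. The amplitude of a peak is the maximum bin value inside
#' it.
#'
#' @param track A bin track from [sum_bins()].
#' @param cutoff Score threshold (for the high-density protocol, `theta`
#'   from [concat_and_threshold()]). May be negative, since
#'   log-likelihood-ratio scores are signed; only bins actually present in
#'   the track can form peaks.
#' @param min_length Minimum peak length in bp after gap merging.
#' @param max_gap Maximum below-cutoff gap (bp) bridged when merging runs.
#' @return A `GRanges` of peaks with an `amplitude` metadata column.
#' @export
call_peaks <- function(track, cutoff, min_length = 200L, max_gap = 30L) {
  track <- .as_granges(track)
  .assert_scalar_number(cutoff, "cutoff")
  .assert_scalar_number(min_length, "min_length", lower = 0)
  .assert_scalar_number(max_gap, "max_gap", lower = 0)
  above <- track[mcols(track)$value > cutoff]
  if (length(above) == 0L) {
    gr <- GRanges(); mcols(gr)$amplitude <- numeric(0); return(gr)
  }
  peaks <- GenomicRanges::reduce(GRanges(seqnames(above), ranges(above)),
                                 min.gapwidth = as.integer(max_gap) + 1L)
  peaks <- peaks[width(peaks) >= min_length]
  if (length(peaks) == 0L) {
    mcols(peaks)$amplitude <- numeric(0); return(peaks)
  }
  hits <- GenomicRanges::findOverlaps(peaks, above)
  amp <- tapply(mcols(above)$value[subjectHits(hits)], queryHits(hits), max)
  mcols(peaks)$amplitude <- as.numeric(amp[as.character(seq_along(peaks))])
  peaks[order(as.character(seqnames(peaks)), start(peaks))]
}

#' High-density top predictions
#'
#' The full postprocess: pool and threshold the instances
#' ([concat_and_threshold()]), explode kept windows to bins, sum bin scores,
#' call peaks at `cutoff = theta`, then apply the two-criterion cutoff. Every
#' called peak is annotated with its amplitude (maximum summed bin value)
#' and its maximum single window score (over kept windows overlapping it by
#' at least 1 bp). Two elbow cutoffs are computed on the full peak set — one
#' on the descending amplitude curve, one on the descending
#' maximum-window-score curve — and the top predictions are the peaks at or
#' above both cutoffs: a peak passing amplitude but not score (or the
#' reverse) is excluded. With fewer than 3 peaks the elbows are undefined
#' and all peaks are kept, with a warning.
#'
#' @param bundle An [hd_bundle()].
#' @param rank_cutoff Pooled rank defining the score threshold (default
#'   5000). This is a genome-size-dependent choice: it should exceed the
#'   expected number of genuinely signal-bearing windows so the kept set
#'   retains a tail of near-threshold background windows, which is what
#'   gives the amplitude curve the knee the elbow cutoff detects.
#' @param min_length,max_gap Peak-calling parameters, see [call_peaks()].
#' @return A list with `peaks` (coordinate-sorted `GRanges` with `amplitude`
#'   and `max_window_score`), `theta`, `track` (the summed bin track),
#'   `kept` (the thresholded windows) and `all_peaks` (the called peaks
#'   before the elbow cutoffs).
#' @export
hd_top_predictions <- function(bundle, rank_cutoff = 5000L,
                               min_length = 200L, max_gap = 30L) {
  stopifnot(inherits(bundle, "hd_bundle"))
  ct <- concat_and_threshold(bundle, rank_cutoff)
  segs <- explode_bins(ct$kept, bin = bundle$bin)
  track <- sum_bins(segs, bin = bundle$bin)
  peaks <- call_peaks(track, cutoff = ct$theta,
                      min_length = min_length, max_gap = max_gap)
  if (length(peaks)) {
    hits <- GenomicRanges::findOverlaps(peaks, ct$kept)
    mws <- rep(NA_real_, length(peaks))
    if (length(hits)) {
      mx <- tapply(mcols(ct$kept)$score[subjectHits(hits)], queryHits(hits), max)
      mws[as.integer(names(mx))] <- as.numeric(mx)
    }
    mcols(peaks)$max_window_score <- mws
    all_peaks <- peaks
    if (length(peaks) >= 3L) {
      amp <- sort(mcols(peaks)$amplitude, decreasing = TRUE)
      a_cut <- amp[elbow_index(amp)]
      sc <- sort(mws, decreasing = TRUE)
      s_cut <- sc[elbow_index(sc)]
      peaks <- peaks[mcols(peaks)$amplitude >= a_cut &
                       !is.na(mws) & mws >= s_cut]
    } else {
      warning("fewer than 3 peaks: elbow cutoffs undefined, keeping all")
    }
  } else {
    mcols(peaks)$max_window_score <- numeric(0)
    all_peaks <- peaks
  }
  peaks <- peaks[order(as.character(seqnames(peaks)), start(peaks))]
  list(peaks = peaks, theta = ct$theta, track = track, kept = ct$kept,
       all_peaks = all_peaks)
}
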