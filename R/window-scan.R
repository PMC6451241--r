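# Genome scanning: fixed-width windows scored by the Markov
# log-likelihood-ratio model, with a per-instance start offset, top-N
# ranking, and the elbow-point cutoff used by the default protocol.
#
# Window placement is scaffold-anchored: an instance with offset o and shift
# s considers window starts at the 0-based scaffold positions o, o+s, o+2s,
# ... and keeps those windows lying entirely inside a non-exonic segment.
# The offset thus plays the role of "ignore the first o bases of each
# chromosome/scaffold", and windows never straddle a masked exon.

#' Scan configuration
#'
#' @param window Window width in bp (default 500).
#' @param shift Distance between successive window starts within one
#'   instance, in bp (default 250, i.e. half-overlapping windows).
#' @param offset 0-based number of leading scaffold bases ignored before the
#'   first window (the per-instance offset of the high-density protocol).
#' @param top_n Number of top-ranked windows retained by [take_top()]
#'   (default 5000).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 500L, shift = 250L, offset = 0L,
                        top_n = 5000L) {
  .assert_scalar_number(window, "window", lower = 1)
  .assert_scalar_number(shift, "shift", lower = 1)
  .assert_scalar_number(offset, "offset", lower = 0)
  .assert_scalar_number(top_n, "top_n", lower = 1)
  if (shift > window) stop("`shift` must be <= `window`", call. = FALSE)
  structure(list(window = as.integer(window), shift = as.integer(shift),
                 offset = as.integer(offset), top_n = as.integer(top_n)),
            class = "scan_config")
}

#' Extract non-exonic segments and their sequences
#'
#' Returns the maximal intervals of each chromosome not covered by `exons`,
#' in genomic coordinates, with the corresponding sequences attached.
#'
#' @param genome A named `DNAStringSet`.
#' @param exons A `GRanges` of regions to exclude (merged internally).
#' @return A `GRanges` with a `seq` metadata column (`DNAStringSet`).
#' @export
extract_noncoding <- function(genome, exons = GRanges()) {
  if (!methods::is(genome, "DNAStringSet"))
    stop("`genome` must be a DNAStringSet", call. = FALSE)
  space <- genome_space(genome, exons)
  segs <- .allowed_gaps(space)
  if (length(segs)) {
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(segs), function(i) {
      as.character(Biostrings::subseq(genome[[as.character(seqnames(segs)[i])]],
                                      start(segs)[i], end(segs)[i]))
    }, ""))
    mcols(segs)$seq <- seqs
  } else {
    mcols(segs)$seq <- Biostrings::DNAStringSet()
  }
  segs
}

# Precompute, per non-exonic segment, the cumulative per-base score arrays
# from which any window score at any offset can be read in O(1). Positions
# are scored with the (order+1)-mer ending at them; the first `order` bases
# of each window are never scored, so a window's score depends only on its
# own sequence and equals score_window() on it.
.prepare_scan <- function(genome, exons, crm_model, bg_model) {
  llr <- .llr_table(crm_model, bg_model)
  k <- crm_model$order
  segs <- extract_noncoding(genome, exons)
  dat <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    codes <- .encode_dna(as.character(mcols(segs)$seq[[i]]))
    L <- length(codes)
    v <- rep(NA_real_, L)
    if (L >= k + 1L) v[(k + 1L):L] <- llr[.kmer_index(codes, k) + 1]
    # Leading zero so range sums over local positions [a, b] read as
    # c[b + 1] - c[a].
    dat[[i]] <- list(
      chrom = as.character(seqnames(segs)[i]),
      start0 = start(segs)[i] - 1L,  # 0-based segment start
      len = L,
      csum = c(0, cumsum(ifelse(is.na(v), 0, v))),
      cval = c(0L, cumsum(!is.na(v))),
      cN = c(0L, cumsum(is.na(codes))))
  }
  list(segments = dat, order = k)
}

# Enumerate and score the windows of one instance (one offset) from
# precomputed segment arrays.
.scan_instance <- function(prep, window, shift, offset, max_n_frac = 0.10) {
  k <- prep$order
  if (window <= k)
    stop("window width must exceed the model order", call. = FALSE)
  out <- lapply(prep$segments, function(sg) {
    lo0 <- sg$start0               # segment [lo0, hi0) in 0-based coords
    hi0 <- sg$start0 + sg$len
    i_min <- ceiling((lo0 - offset) / shift)
    i_max <- floor((hi0 - window - offset) / shift)
    i_min <- max(i_min, 0)
    if (i_max < i_min) return(NULL)
    g0 <- offset + shift * (i_min:i_max)   # 0-based window starts
    s <- g0 - lo0 + 1L                     # 1-based local starts
    e <- s + window - 1L
    nN <- sg$cN[e + 1L] - sg$cN[s]
    nval <- sg$cval[e + 1L] - sg$cval[s + k]
    ssum <- sg$csum[e + 1L] - sg$csum[s + k]
    keep <- (nN <= max_n_frac * window) & (nval > 0L)
    if (!any(keep)) return(NULL)
    data.frame(chrom = sg$chrom, start = g0[keep] + 1L,
               score = ssum[keep] / nval[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    gr <- GRanges()
    mcols(gr)$score <- numeric(0)
    mcols(gr)$offset <- integer(0)
    return(gr)
  }
  gr <- GRanges(out$chrom, IRanges(out$start, width = window))
  mcols(gr)$score <- out$score
  mcols(gr)$offset <- as.integer(offset)
  gr
}

#' Score sliding windows across a genome
#'
#' Runs one scan instance: fixed-width windows whose 0-based starts are
#' congruent to `cfg$offset` modulo `cfg$shift` within each scaffold, kept
#' only when they lie entirely inside a non-exonic segment, each scored with
#' [score_window()] semantics. Windows with more than 10% `N` (or with no
#' scorable position) are dropped.
#'
#' @param genome A named `DNAStringSet`.
#' @param exons `GRanges` of excluded (exonic) regions.
#' @param crm_model,bg_model [train_markov()] models of equal order.
#' @param cfg A [scan_config()].
#' @return A `GRanges` of scored windows in genomic order, with `score` and
#'   `offset` metadata columns.
#' @export
scan_genome <- function(genome, exons, crm_model, bg_model,
                        cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  prep <- .prepare_scan(genome, exons, crm_model, bg_model)
  .scan_instance(prep, cfg$window, cfg$shift, cfg$offset)
}

#' Run the 25-instance high-density scan
#'
#' Scores one instance per offset (canonically 0, 10, ..., 240 bp with the
#' default 500/250 window/shift) reusing a single per-base score
#' precomputation, and bundles the per-instance window lists for
#' [hd_top_predictions()].
#'
#' @inheritParams scan_genome
#' @param offsets Integer vector of instance offsets.
#' @param window,shift Window width and shift in bp.
#' @param bin Bin width in bp for downstream postprocessing (offsets must be
#'   multiples of it).
#' @return An `hd_bundle`.
#' @export
scan_hd <- function(genome, exons, crm_model, bg_model,
                    offsets = seq(0L, 240L, by = 10L),
                    window = 500L, shift = 250L, bin = 10L) {
  prep <- .prepare_scan(genome, exons, crm_model, bg_model)
  instances <- lapply(offsets, function(o)
    .scan_instance(prep, window, shift, o))
  names(instances) <- as.character(offsets)
  hd_bundle(instances, window = window, shift = shift, bin = bin)
}

#' Rank scored windows and keep the top N
#'
#' Descending-score order with ties broken by (chromosome, start) ascending,
#' so the retained set is deterministic across runs and platforms.
#'
#' @param windows A `GRanges` with a `score` metadata column.
#' @param top_n Maximum number of windows to keep (default 5000).
#' @return The ranked, truncated `GRanges`.
#' @export
take_top <- function(windows, top_n = 5000L) {
  windows <- .as_granges(windows)
  if (!"score" %in% names(mcols(windows)))
    stop("windows must carry a `score` metadata column", call. = FALSE)
  .assert_scalar_number(top_n, "top_n", lower = 1)
  o <- .rank_order(windows, mcols(windows)$score)
  windows[o][seq_len(min(length(windows), top_n))]
}

#' Elbow point of a descending curve
#'
#' Both axes are min-max normalised to `[0, 1]`; the elbow is the point with
#' the greatest perpendicular distance to the chord joining the first and
#' last points. Ties resolve to the smallest index; a flat (all-equal) curve
#' returns index 1.
#'
#' @param values Numeric vector of at least 3 values, sorted non-increasing.
#' @return The 1-based index of the elbow point.
#' @export
#' @examples
#' elbow_index(c(10, 9, 8, 1, 0.9, 0.8))  # 4: the corner of the curve
elbow_index <- function(values) {
  if (!is.numeric(values) || length(values) < 3L)
    stop("`values` must be a numeric vector with at least 3 elements", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (is.unsorted(rev(values)))
    stop("`values` must be sorted in descending order", call. = FALSE)
  n <- length(values)
  if (values[1L] == values[n]) return(1L)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - values[n]) / (values[1L] - values[n])
  # Chord runs from (0, 1) to (1, 0): distance is |x + y - 1| / sqrt(2).
  d <- abs(x + y - 1) / sqrt(2)
  which.max(d)
}

#' Default-protocol top predictions
#'
#' Ranks windows, finds the elbow of the score curve and keeps every window
#' whose score is greater than or equal to the score at the elbow point. The
#' result is a prefix of the ranked list.
#'
#' @param windows A `GRanges` of scored windows (any order).
#' @return The kept windows, ranked.
#' @export
default_top_predictions <- function(windows) {
  ranked <- take_top(windows, top_n = length(windows))
  if (length(ranked) < 3L)
    stop("need at least 3 scored windows to locate an elbow point", call. = FALSE)
  cut <- mcols(ranked)$score[elbow_index(mcols(ranked)$score)]
  ranked[mcols(ranked)$score >= cut]
}
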