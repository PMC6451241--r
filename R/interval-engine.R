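# Interval arithmetic with the exact semantics the evaluation pipeline
# needs: sort/merge, fractional-overlap intersection (fraction computed on
# the query interval), and exclusion-aware placement randomisation.
# Set operations stand on GenomicRanges/IRanges.

#' Describe a genome as a space for interval placement
#'
#' A genome space is the pair (chromosome sizes, excluded regions). Excluded
#' regions (typically exons, since predictions are made on non-exonic
#' sequence only) are merged on construction.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths in bp, or a
#'   `DNAStringSet` whose widths are used.
#' @param excluded Optional `GRanges` of regions that shuffled intervals must
#'   not overlap.
#' @return An object of class `genome_space`.
#' @export
#' @examples
#' gs <- genome_space(c(chr1 = 10000), GRanges("chr1", IRanges(2001, 7000)))
genome_space <- function(chrom_sizes, excluded = GRanges()) {
  if (methods::is(chrom_sizes, "DNAStringSet"))
    chrom_sizes <- setNames(Biostrings::width(chrom_sizes), names(chrom_sizes))
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stop("chrom_sizes must be a uniquely named vector of lengths", call. = FALSE)
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (any(chrom_sizes <= 0L)) stop("chromosome lengths must be positive", call. = FALSE)
  excluded <- GenomicRanges::reduce(sort(.as_granges(excluded)))
  unknown <- setdiff(unique(as.character(seqnames(excluded))), names(chrom_sizes))
  if (length(unknown))
    stop("excluded intervals on unknown chromosome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(excluded)) {
    lim <- chrom_sizes[as.character(seqnames(excluded))]
    if (any(end(excluded) > lim) || any(start(excluded) < 1L))
      stop("excluded interval outside its chromosome", call. = FALSE)
  }
  gs <- structure(list(chrom_sizes = chrom_sizes, excluded = excluded),
                  class = "genome_space")
  # Cache the allowed gaps: placement randomisation is called hundreds of
  # times per permutation test.
  genome_gr <- GRanges(names(chrom_sizes), IRanges(1L, unname(chrom_sizes)))
  gaps <- GenomicRanges::setdiff(genome_gr, excluded, ignore.strand = TRUE)
  gs$gaps <- list(chrom = as.character(seqnames(gaps)), start = start(gaps),
                  width = width(gaps))
  gs
}

#' @export
print.genome_space <- function(x, ...) {
  cat(sprintf("genome_space: %d chromosome(s), %s bp total, %d excluded region(s) (%s bp)\n",
              length(x$chrom_sizes), format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
              length(x$excluded), format(sum(as.numeric(width(x$excluded))), big.mark = ",")))
  invisible(x)
}

# Maximal allowed (non-excluded) intervals of a genome space, as GRanges.
.allowed_gaps <- function(space) {
  genome_gr <- GRanges(names(space$chrom_sizes),
                       IRanges(1L, unname(space$chrom_sizes)))
  GenomicRanges::setdiff(genome_gr, space$excluded, ignore.strand = TRUE)
}

#' Sort and merge intervals
#'
#' Sorts by (chromosome, start) and merges overlapping or book-ended
#' (end == next start in half-open coordinates) intervals. Total covered bp
#' is preserved. Idempotent.
#'
#' @param gr A `GRanges`.
#' @return A sorted, disjoint `GRanges` (metadata columns dropped).
#' @export
sort_merge <- function(gr) {
  gr <- .as_granges(gr)
  out <- GenomicRanges::reduce(GRanges(seqnames(gr), ranges(gr)))
  out[order(as.character(seqnames(out)), start(out))]
}

#' Fractional-overlap intersection
#'
#' Index `i` of `a` is a hit iff some interval of `b` overlaps it by at least
#' `min_frac` of the length of `a[i]` (inclusive comparison). The fraction is
#' always computed on the A (query) side, mirroring a one-sided minimum
#' overlap requirement: e.g. at `min_frac = 0.10` a 500-bp query needs at
#' least 50 bp of overlap, a 1000-bp query at least 100 bp.
#'
#' @param a Query `GRanges` (for evaluation calls: the predictions).
#' @param b Subject `GRanges`.
#' @param min_frac Minimum overlap as a fraction of the query length, in
#'   `(0, 1]`.
#' @return A list of class `overlap_result` with `a_hit` and `b_hit` (sorted
#'   indices of qualifying intervals in `a` and `b`), `pairs` (a two-column
#'   matrix of qualifying index pairs) and `pair_count`.
#' @export
#' @examples
#' a <- GRanges("c1", IRanges(1, 500))
#' b <- GRanges("c1", IRanges(451, 1000))
#' intersect_fraction(a, b, 0.10)$a_hit  # 50 bp overlap qualifies
intersect_fraction <- function(a, b, min_frac) {
  a <- .as_granges(a); b <- .as_granges(b)
  .assert_scalar_number(min_frac, "min_frac")
  if (min_frac <= 0 || min_frac > 1)
    stop("`min_frac` must be in (0, 1]", call. = FALSE)
  # suppress the chatty Seqinfo message when a and b share no chromosome
  # (a legitimate comparison that simply has no hits)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE))
  qh <- queryHits(hits); sh <- subjectHits(hits)
  if (length(qh)) {
    ov <- pmin(end(a)[qh], end(b)[sh]) - pmax(start(a)[qh], start(b)[sh]) + 1L
    # Ratio (not f * length) so worked fractions like 50/500 == 0.10 compare
    # exactly under IEEE arithmetic.
    keep <- (ov / width(a)[qh]) >= min_frac
    qh <- qh[keep]; sh <- sh[keep]
  }
  structure(list(a_hit = sort(unique(qh)), b_hit = sort(unique(sh)),
                 pairs = cbind(a = qh, b = sh), pair_count = length(qh)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d qualifying pair(s); %d A hit(s), %d B hit(s)\n",
              x$pair_count, length(x$a_hit), length(x$b_hit)))
  invisible(x)
}

#' Randomise interval placement within a genome space
#'
#' Each input interval is re-placed, with its length preserved, uniformly at
#' random over every position (across all chromosomes, proportionally to the
#' space available on each) where it fits entirely inside a non-excluded
#' region. Outputs may overlap one another. Deterministic given `seed`.
#'
#' @param gr A `GRanges` of intervals to shuffle.
#' @param space A [genome_space()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A `GRanges` of the same length and widths as `gr`.
#' @export
shuffle_intervals <- function(gr, space, seed = NULL) {
  gr <- .as_granges(gr)
  stopifnot(inherits(space, "genome_space"))
  if (length(gr) == 0L) return(gr[0])
  gap_chrom <- space$gaps$chrom
  gap_start <- space$gaps$start
  gap_width <- space$gaps$width
  n_gaps <- length(gap_chrom)
  local_seed(seed, {
    w <- width(gr)
    out_chrom <- character(length(gr))
    out_start <- integer(length(gr))
    # Group by width: intervals of equal length share the same slot counts.
    for (wu in unique(w)) {
      idx <- which(w == wu)
      slots <- pmax(0L, gap_width - wu + 1L)
      total <- sum(as.numeric(slots))
      if (total <= 0)
        stop(sprintf("interval %s (length %d) cannot be placed anywhere in the genome space",
                     .gr_label(gr, idx[1L]), wu), call. = FALSE)
      g <- sample.int(n_gaps, length(idx), replace = TRUE,
                      prob = slots / total)
      off <- vapply(g, function(j) sample.int(slots[j], 1L), 1L)
      out_chrom[idx] <- gap_chrom[g]
      out_start[idx] <- gap_start[g] + off - 1L
    }
    GRanges(out_chrom, IRanges(out_start, width = w))
  })
}
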