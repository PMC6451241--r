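# Assembly-quality simulation: fragment a reference genome to match an
# empirical scaffold-length distribution, lift annotations forward and
# predictions back, and quantify how prediction output degrades.

#' Build a scaffold-length model
#'
#' Records an empirical scaffold-length sample and its quartile boundaries
#' (25th/50th/75th percentiles, linear interpolation). [plan_fragments()]
#' mimics the distribution by repeatedly picking a quartile uniformly at
#' random and drawing a length uniformly from the sample values in it.
#'
#' @param scaffold_lengths Numeric vector of at least 4 scaffold lengths (bp).
#' @return An object of class `length_model` with `sample_lengths` (sorted)
#'   and `quartile_bounds`.
#' @export
#' @examples
#' build_length_model(1:8)$quartile_bounds  # 2.75 4.50 6.25
build_length_model <- function(scaffold_lengths) {
  if (!is.numeric(scaffold_lengths) || length(scaffold_lengths) < 4L)
    stop("need at least 4 scaffold lengths", call. = FALSE)
  if (any(!is.finite(scaffold_lengths)) || any(scaffold_lengths <= 0))
    stop("scaffold lengths must be positive and finite", call. = FALSE)
  s <- sort(as.numeric(scaffold_lengths))
  structure(list(sample_lengths = s,
                 quartile_bounds = unname(stats::quantile(s, c(.25, .5, .75),
                                                          type = 7))),
            class = "length_model")
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("length_model: n = %d, quartile bounds %s bp\n",
              length(x$sample_lengths),
              paste(format(round(x$quartile_bounds), big.mark = ","), collapse = " / ")))
  invisible(x)
}

#' Packaged assembly-quality presets
#'
#' Scaffold N50 values for ten assembly-quality categories, from excellent
#' (A: chromosome arms simply halved) to poor (J: N50 ~24 kb), used to
#' parameterise realistic length models.
#'
#' @return A data.frame with columns `id`, `species`, `scaffold_n50`,
#'   `category`.
#' @export
assembly_presets <- function() {
  read.delim(system.file("extdata", "assembly_presets.tsv",
                         package = "crmbench"),
             stringsAsFactors = FALSE)
}

#' Synthetic length model for an assembly preset
#'
#' Real per-scaffold length samples for the preset species are not shipped;
#' instead a synthetic lognormal scaffold-length sample is generated and
#' rescaled so its N50 matches the preset's. Preset "A" has no N50 (it is
#' the halves mode) and is rejected here.
#'
#' @param id Preset id, `"B"` through `"J"`.
#' @param n Sample size (default 200).
#' @param sdlog Lognormal shape (default 1).
#' @param seed Integer seed for the sample (default 1; the model is a fixed
#'   parameterisation, not a per-run random quantity).
#' @return A [build_length_model()] object.
#' @export
preset_length_model <- function(id, n = 200L, sdlog = 1, seed = 1L) {
  presets <- assembly_presets()
  row <- presets[presets$id == id, ]
  if (nrow(row) != 1L) stop("unknown preset id: ", id, call. = FALSE)
  if (is.na(row$scaffold_n50))
    stop("preset ", id, " is the halves mode; use plan_fragments(mode = \"halves\")",
         call. = FALSE)
  lens <- local_seed(seed, stats::rlnorm(n, meanlog = log(row$scaffold_n50), sdlog = sdlog))
  # Rescale so the sample's N50 equals the preset N50.
  n50 <- function(x) {
    s <- sort(x, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1L]]
  }
  lens <- lens * row$scaffold_n50 / n50(lens)
  build_length_model(pmax(1, round(lens)))
}

#' Plan a fragmentation of a genome
#'
#' Cuts every chromosome into consecutive fragments. In `"quartile"` mode
#' each fragment length is drawn by first picking one of the four quartiles
#' of the length model uniformly at random, then drawing uniformly from the
#' model's sample lengths within that quartile, proceeding from the start of
#' the chromosome until its end (the final fragment is truncated there). In
#' `"halves"` mode each chromosome is split into two equal (+/- 1 bp)
#' fragments. Deterministic given `seed`.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp), or a
#'   `DNAStringSet`.
#' @param model A [build_length_model()]; required for `"quartile"` mode.
#' @param seed Optional integer seed.
#' @param mode `"quartile"` or `"halves"`.
#' @return A `fragment_plan`: a `GRanges` in native coordinates tiling every
#'   chromosome exactly, with a `scaffold` metadata column naming the new
#'   scaffold of each fragment; the seed and mode are kept in
#'   `metadata()`.
#' @export
plan_fragments <- function(chrom_sizes, model = NULL, seed = NULL,
                           mode = c("quartile", "halves")) {
  mode <- match.arg(mode)
  if (methods::is(chrom_sizes, "DNAStringSet"))
    chrom_sizes <- setNames(Biostrings::width(chrom_sizes), names(chrom_sizes))
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named", call. = FALSE)
  pieces <- local_seed(seed, {
    lapply(names(chrom_sizes), function(ch) {
      len <- as.integer(chrom_sizes[[ch]])
      if (mode == "halves") {
        h <- len %/% 2L
        if (h == 0L) return(data.frame(chrom = ch, start = 1L, end = len))
        return(data.frame(chrom = ch, start = c(1L, h + 1L), end = c(h, len)))
      }
      if (is.null(model) || !inherits(model, "length_model"))
        stop("quartile mode requires a length_model", call. = FALSE)
      qb <- model$quartile_bounds
      s <- model$sample_lengths
      quart <- findInterval(s, qb) + 1L  # 1..4, bounds assigned upward
      starts <- integer(0); ends <- integer(0); pos <- 1L
      while (pos <= len) {
        q <- sample.int(4L, 1L)
        cand <- s[quart == q]
        if (length(cand) == 0L) cand <- s
        l <- as.integer(cand[sample.int(length(cand), 1L)])
        e <- min(pos + max(l, 1L) - 1L, len)
        starts <- c(starts, pos); ends <- c(ends, e)
        pos <- e + 1L
      }
      data.frame(chrom = ch, start = starts, end = ends)
    })
  })
  df <- do.call(rbind, pieces)
  plan <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(plan)$scaffold <- sprintf("scaffold_%05d", seq_along(plan))
  S4Vectors::metadata(plan)$seed <- seed
  S4Vectors::metadata(plan)$mode <- mode
  S4Vectors::metadata(plan)$chrom_sizes <- setNames(as.integer(chrom_sizes),
                                                    names(chrom_sizes))
  plan
}

# Validate that a plan tiles the given chromosome sizes exactly.
.check_plan <- function(plan, chrom_sizes) {
  plan <- .as_granges(plan)
  if (!"scaffold" %in% names(mcols(plan)))
    stop("fragment plan must carry a `scaffold` metadata column", call. = FALSE)
  if (anyDuplicated(mcols(plan)$scaffold))
    stop("scaffold ids in the plan must be unique", call. = FALSE)
  for (ch in names(chrom_sizes)) {
    p <- plan[as.character(seqnames(plan)) == ch]
    p <- p[order(start(p))]
    if (length(p) == 0L || start(p)[1L] != 1L ||
        end(p)[length(p)] != chrom_sizes[[ch]] ||
        (length(p) > 1L && any(start(p)[-1L] != end(p)[-length(p)] + 1L)))
      stop("plan does not tile chromosome ", ch, " exactly", call. = FALSE)
  }
  invisible(plan)
}

#' Apply a fragmentation plan to a genome and its annotations
#'
#' Each fragment becomes a scaffold whose sequence is copied verbatim from
#' the native genome. Annotation features intersecting a fragment are
#' clipped to it and re-based to fragment-local coordinates; a feature
#' spanning a breakpoint is split into one piece per fragment, so no
#' annotated mass is lost.
#'
#' @param genome Named `DNAStringSet` (the native genome).
#' @param annotations `GRanges` of features (e.g. exons) in native
#'   coordinates.
#' @param plan A plan from [plan_fragments()].
#' @return A list with `genome` (scaffold `DNAStringSet`) and `annotations`
#'   (`GRanges` in scaffold coordinates).
#' @export
apply_fragmentation <- function(genome, annotations, plan) {
  if (!methods::is(genome, "DNAStringSet"))
    stop("`genome` must be a DNAStringSet", call. = FALSE)
  sizes <- setNames(Biostrings::width(genome), names(genome))
  .check_plan(plan, sizes)
  scaffold <- mcols(plan)$scaffold
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(plan), function(i) {
    as.character(Biostrings::subseq(genome[[as.character(seqnames(plan)[i])]],
                                    start(plan)[i], end(plan)[i]))
  }, ""))
  names(seqs) <- scaffold
  ann_out <- GRanges()
  if (!is.null(annotations) && length(annotations)) {
    annotations <- .as_granges(annotations)
    hits <- GenomicRanges::findOverlaps(annotations, plan, ignore.strand = TRUE)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    piece_start <- pmax(start(annotations)[qh], start(plan)[sh])
    piece_end <- pmin(end(annotations)[qh], end(plan)[sh])
    ann_out <- GRanges(scaffold[sh],
                       IRanges(piece_start - start(plan)[sh] + 1L,
                               piece_end - start(plan)[sh] + 1L))
    mcols(ann_out) <- mcols(annotations)[qh, , drop = FALSE]
  }
  list(genome = seqs, annotations = ann_out)
}

#' Lift scaffold intervals back to native coordinates
#'
#' Exact inverse of the re-basing performed by [apply_fragmentation()]:
#' an interval on a scaffold maps to `fragment_start + local - 1` on the
#' native chromosome. Intervals on unknown scaffolds, or extending past a
#' scaffold end, are errors.
#'
#' @param gr `GRanges` in scaffold coordinates.
#' @param plan The plan used to create the scaffolds.
#' @return `GRanges` in native coordinates (metadata preserved).
#' @export
liftover_back <- function(gr, plan) {
  gr <- .as_granges(gr)
  plan <- .as_granges(plan)
  idx <- match(as.character(seqnames(gr)), mcols(plan)$scaffold)
  if (anyNA(idx))
    stop("unknown scaffold id: ",
         as.character(seqnames(gr))[which(is.na(idx))[1L]], call. = FALSE)
  if (any(end(gr) > width(plan)[idx]))
    stop("interval extends past its scaffold end", call. = FALSE)
  out <- GRanges(as.character(seqnames(plan))[idx],
                 IRanges(start(plan)[idx] + start(gr) - 1L,
                         start(plan)[idx] + end(gr) - 1L))
  mcols(out) <- mcols(gr)
  out
}

#' Robustness of predictions to genome fragmentation
#'
#' Native top predictions are taken as the true positives; everything below
#' the native cutoff is a true negative. A lifted simulated prediction is a
#' true positive when it hits a native top prediction at `min_frac` of its
#' own length, and a false positive when it overlaps scored native territory
#' without hitting any top prediction. Optionally, scores of corresponding
#' windows (exact lifted-coordinate equality) are correlated.
#'
#' @param native_top `GRanges`: top predictions on the native genome.
#' @param native_all_scored `GRanges` of all scored native windows (with a
#'   `score` column when window correlation is wanted).
#' @param sim_top_lifted `GRanges`: top predictions from the fragmented
#'   genome, lifted back to native coordinates.
#' @param min_frac Minimum overlap fraction of the simulated prediction
#'   (default 0.50).
#' @param sim_scored_lifted Optional `GRanges` of all scored windows from the
#'   fragmented run, lifted back, with a `score` column.
#' @return A one-row data.frame: `tp_percent`, `fp_percent`, `pearson_r`
#'   (`NA` without matched windows), `n_common_windows`, `n_sim_top`,
#'   `n_matched_top`.
#' @export
assess_robustness <- function(native_top, native_all_scored, sim_top_lifted,
                              min_frac = 0.50, sim_scored_lifted = NULL) {
  native_top <- .as_granges(native_top)
  sim_top_lifted <- .as_granges(sim_top_lifted)
  native_all_scored <- .as_granges(native_all_scored)
  n_sim <- length(sim_top_lifted)
  tp_idx <- integer(0); fp_idx <- integer(0)
  if (n_sim) {
    tp_idx <- intersect_fraction(sim_top_lifted, native_top, min_frac)$a_hit
    scored_region <- sort_merge(native_all_scored)
    touch <- unique(queryHits(GenomicRanges::findOverlaps(sim_top_lifted,
                                                          scored_region)))
    fp_idx <- setdiff(touch, tp_idx)
  }
  r <- NA_real_; n_common <- 0L
  if (!is.null(sim_scored_lifted) && length(sim_scored_lifted) &&
      "score" %in% names(mcols(native_all_scored)) &&
      "score" %in% names(mcols(sim_scored_lifted))) {
    key <- function(g) paste0(as.character(seqnames(g)), ":", start(g), "-", end(g))
    kn <- key(native_all_scored); ks <- key(sim_scored_lifted)
    # A window can appear once per offset instance; collapse to unique keys
    # (scores at identical coordinates are identical within one run).
    dn <- !duplicated(kn); ds <- !duplicated(ks)
    m <- match(ks[ds], kn[dn])
    sel <- !is.na(m)
    n_common <- sum(sel)
    if (n_common >= 2L)
      r <- stats::cor(mcols(native_all_scored)$score[dn][m[sel]],
                      mcols(sim_scored_lifted)$score[ds][sel])
  }
  data.frame(tp_percent = if (n_sim) 100 * length(tp_idx) / n_sim else NA_real_,
             fp_percent = if (n_sim) 100 * length(fp_idx) / n_sim else NA_real_,
             pearson_r = r, n_common_windows = n_common,
             n_sim_top = n_sim, n_matched_top = length(tp_idx))
}
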