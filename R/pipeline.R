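# End-to-end orchestration: model training from interval sets, the
# high-density protocol, and the window-start-offset experiment.

#' Extract the sequences of a set of intervals
#'
#' @param genome Named `DNAStringSet`.
#' @param gr `GRanges` within the genome.
#' @return A `DNAStringSet`, one entry per interval.
#' @export
interval_sequences <- function(genome, gr) {
  gr <- .as_granges(gr)
  if (length(gr) == 0L) return(Biostrings::DNAStringSet())
  sizes <- setNames(Biostrings::width(genome), names(genome))
  ch <- as.character(seqnames(gr))
  if (any(!ch %in% names(sizes)) || any(end(gr) > sizes[ch]) || any(start(gr) < 1L))
    stop("interval outside the genome", call. = FALSE)
  Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[ch[i]]], start(gr)[i], end(gr)[i]))
  }, ""))
}

#' Train the CRM and background models for a genome scan
#'
#' The background model is trained on the genome's non-exonic sequence; the
#' CRM model on the training-interval sequences, smoothed toward the
#' background model (see `prior_model` in [train_markov()]) so that sequence
#' the small training set carries no information about scores near zero
#' rather than systematically negative.
#'
#' @param genome Named `DNAStringSet`.
#' @param exons `GRanges` of exons.
#' @param training_crms `GRanges` of training CRMs.
#' @param order Markov order (default 5).
#' @param pseudocount Smoothing weight for the CRM model: virtual
#'   background-distributed observations per context (default 16).
#' @return A list with `crm_model` and `bg_model`.
#' @export
train_scan_models <- function(genome, exons, training_crms, order = 5L,
                              pseudocount = 16.0) {
  crm_seqs <- interval_sequences(genome, training_crms)
  bg_seqs <- mcols(extract_noncoding(genome, exons))$seq
  bg_model <- train_markov(bg_seqs, order = order, pseudocount = 1.0)
  crm_model <- train_markov(crm_seqs, order = order, pseudocount = pseudocount,
                            prior_model = bg_model)
  list(crm_model = crm_model, bg_model = bg_model)
}

#' Rank high-density peaks as a prediction list
#'
#' Orders peaks by decreasing maximum window score (coordinate ties
#' deterministic), the ranking used when peaks are fed to the evaluator.
#'
#' @param peaks Peak `GRanges` from [hd_top_predictions()].
#' @return The ranked `GRanges`.
#' @export
rank_peaks <- function(peaks) {
  peaks <- .as_granges(peaks)
  if (length(peaks) == 0L) return(peaks)
  key <- if ("max_window_score" %in% names(mcols(peaks)))
    mcols(peaks)$max_window_score else mcols(peaks)$amplitude
  peaks[.rank_order(peaks, key)]
}

#' Run the full high-density protocol
#'
#' Trains the models, runs one scan instance per offset (canonically 25:
#' offsets 0-240 bp, step 10), and applies the high-density postprocess. The
#' result is deterministic: instances may be computed in any order without
#' changing the peak set.
#'
#' @param genome Named `DNAStringSet`.
#' @param exons `GRanges` of exons (excluded from scanning).
#' @param training_crms `GRanges` of training CRMs.
#' @param offsets Instance offsets (default `seq(0, 240, 10)`).
#' @param window,shift,bin Scan geometry (defaults 500/250/10).
#' @param rank_cutoff Pooled rank defining the score threshold (default 5000).
#' @param min_length,max_gap Peak-calling parameters.
#' @param order,pseudocount Model parameters.
#' @param models Optional pre-trained list with `crm_model`/`bg_model`
#'   (skips training).
#' @return A list with `peaks` (ranked), `theta`, `track`, `kept`, `bundle`,
#'   `models`, and `manifest` (per-instance window counts).
#' @export
run_hd_protocol <- function(genome, exons, training_crms,
                            offsets = seq(0L, 240L, by = 10L),
                            window = 500L, shift = 250L, bin = 10L,
                            rank_cutoff = 5000L, min_length = 200L,
                            max_gap = 30L, order = 5L, pseudocount = 16.0,
                            models = NULL) {
  if (is.null(models))
    models <- train_scan_models(genome, exons, training_crms, order, pseudocount)
  bundle <- scan_hd(genome, exons, models$crm_model, models$bg_model,
                    offsets = offsets, window = window, shift = shift,
                    bin = bin)
  hd <- hd_top_predictions(bundle, rank_cutoff = rank_cutoff,
                           min_length = min_length, max_gap = max_gap)
  manifest <- data.frame(offset = bundle$offsets,
                         n_windows = vapply(bundle$instances, length, 1L),
                         theta = hd$theta)
  list(peaks = rank_peaks(hd$peaks), theta = hd$theta, track = hd$track,
       kept = hd$kept, bundle = bundle, models = models, manifest = manifest)
}

#' Run the default (single-instance) protocol
#'
#' One scan at a fixed offset, top-N ranking and the elbow-point score
#' cutoff — the baseline against which the high-density protocol is
#' compared.
#'
#' @inheritParams run_hd_protocol
#' @param offset Single instance offset (default 0).
#' @param top_n Windows retained before the elbow cutoff (default 5000).
#' @return A list with `predictions` (ranked `GRanges`), `windows` (all
#'   scored windows) and `models`.
#' @export
run_default_protocol <- function(genome, exons, training_crms, offset = 0L,
                                 window = 500L, shift = 250L, top_n = 5000L,
                                 order = 5L, pseudocount = 16.0,
                                 models = NULL) {
  if (is.null(models))
    models <- train_scan_models(genome, exons, training_crms, order, pseudocount)
  windows <- scan_genome(genome, exons, models$crm_model, models$bg_model,
                         scan_config(window = window, shift = shift,
                                     offset = offset, top_n = top_n))
  ranked <- take_top(windows, top_n = top_n)
  list(predictions = default_top_predictions(ranked), windows = windows,
       models = models)
}

# Trim the first `trim` bases off every chromosome, shifting annotations.
.trim_genome <- function(genome, exons, trim) {
  if (trim == 0L) return(list(genome = genome, exons = exons))
  keep <- Biostrings::width(genome) > trim
  g2 <- Biostrings::DNAStringSet(lapply(genome[keep], function(s)
    Biostrings::subseq(s, trim + 1L)))
  names(g2) <- names(genome)[keep]
  e2 <- exons[as.character(seqnames(exons)) %in% names(g2)]
  ns <- pmax(1L, start(e2) - trim)
  ne <- end(e2) - trim
  ok <- ne >= 1L
  e2 <- GRanges(as.character(seqnames(e2))[ok], IRanges(ns[ok], ne[ok]))
  list(genome = g2, exons = e2)
}

#' Window-start offset experiment
#'
#' Measures the sensitivity of the default protocol to the position of the
#' first analysis window: for each trim value the first `trim` bases of
#' every chromosome are deleted, the default protocol re-run on the trimmed
#' genome, predictions lifted back (+trim) and evaluated. The CRM model is
#' trained once on the native training sequences; the background model is
#' retrained per trim.
#'
#' @param genome,exons,training_crms As in [run_hd_protocol()].
#' @param reference_crms Database CRMs for evaluation.
#' @param target_term Optional expression term.
#' @param trims Leading-base deletions to test (default
#'   `c(0, 5, 15, 40, 80, 125)`).
#' @param min_frac Evaluation overlap fraction (default 0.10).
#' @param window,shift,top_n,order,pseudocount As in
#'   [run_default_protocol()].
#' @return A data.frame with one row per trim: the trim, the number of top
#'   predictions and the five measures.
#' @export
run_offset_experiment <- function(genome, exons, training_crms,
                                  reference_crms, target_term = NULL,
                                  trims = c(0L, 5L, 15L, 40L, 80L, 125L),
                                  min_frac = 0.10, window = 500L,
                                  shift = 250L, top_n = 5000L, order = 5L,
                                  pseudocount = 16.0) {
  # Models are trained once on the native genome: trimming changes which
  # windows are scored, not the sequence statistics.
  models <- train_scan_models(genome, exons, training_crms, order = order,
                              pseudocount = pseudocount)
  rows <- lapply(trims, function(tr) {
    tg <- .trim_genome(genome, exons, as.integer(tr))
    run <- run_default_protocol(tg$genome, tg$exons, training_crms,
                                window = window, shift = shift, top_n = top_n,
                                models = models)
    preds <- GenomicRanges::shift(run$predictions, as.integer(tr))
    cbind(trim = as.integer(tr),
          evaluate_fixed(preds, reference_crms, training_crms, target_term,
                         min_frac = min_frac))
  })
  do.call(rbind, rows)
}
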