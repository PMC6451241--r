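# The evaluation engine: five interval-overlap performance measures against
# a database of validated CRMs, fixed-cutoff and semi-continuous evaluation,
# and the permutation-based random expectation.
#
# Conventions (documented design choices):
# * the overlap fraction is always computed on the prediction's length;
# * numerators count DISTINCT items (predictions for recovery/precision,
#   reference/training CRMs for the recall-type measures), so every measure
#   is a percentage in [0, 100];
# * NA is returned exactly when a measure's denominator is empty.

.has_terms <- function(crms) {
  if (!"terms" %in% names(mcols(crms)))
    stop("expression-annotated CRMs must carry a `terms` metadata column (see read_expression_table)",
         call. = FALSE)
  lengths(mcols(crms)$terms) > 0L
}

.term_match <- function(crms, target_term) {
  vapply(as.list(mcols(crms)$terms), function(t) target_term %in% t, NA)
}

#' Prepare the reference CRM database for evaluation
#'
#' Applies the database conventions: reference CRMs of length >=
#' `max_len` bp are dropped (the database export used for evaluation is
#' restricted to CRMs shorter than 2 kb); any reference CRM sharing at least
#' half of its own length with a training CRM is removed, so the training
#' data cannot be credited as discoveries. The survivors are returned twice:
#' sorted and merged (coordinates only) for the recovery/recall track, and
#' unmerged with their expression terms for the expression-pattern track.
#'
#' @param reference_crms `GRanges` of database CRMs, optionally with a
#'   `terms` metadata column ([read_expression_table()]).
#' @param training_crms Optional `GRanges` of training CRMs to filter out.
#' @param max_len Length filter in bp (strictly-less-than; default 2000).
#' @return A list with `merged_ref` (sorted, merged `GRanges`) and
#'   `expr_ref` (filtered `GRanges` with metadata intact).
#' @export
prepare_reference <- function(reference_crms, training_crms = NULL,
                              max_len = 2000L) {
  ref <- .as_granges(reference_crms)
  ref <- ref[width(ref) < max_len]
  if (!is.null(training_crms) && length(training_crms)) {
    hit <- intersect_fraction(ref, .as_granges(training_crms), 0.5)$a_hit
    if (length(hit)) ref <- ref[-hit]
  }
  list(merged_ref = sort_merge(ref), expr_ref = ref)
}

#' Database recovery: fraction of predictions overlapping known CRMs
#'
#' `100 * |predictions hitting the merged reference at >= min_frac of the
#' prediction's length| / |predictions|`. This partitions the predictions
#' into "known" and "novel"; a lower value suggests more false positives
#' (or more undiscovered CRMs).
#'
#' @param predictions `GRanges` of predicted CRMs.
#' @param merged_ref Merged reference CRMs from [prepare_reference()].
#' @param min_frac Minimum overlap fraction of the prediction (default 0.10).
#' @return A percentage in `[0, 100]`, or `NA` (with a warning) for an empty
#'   prediction set.
#' @export
redfly_recovery <- function(predictions, merged_ref, min_frac = 0.10) {
  predictions <- .as_granges(predictions)
  if (length(predictions) == 0L) {
    warning("no predictions: recovery is undefined")
    return(NA_real_)
  }
  hit <- intersect_fraction(predictions, .as_granges(merged_ref), min_frac)$a_hit
  100 * length(hit) / length(predictions)
}

#' Database recall: fraction of known CRMs recovered
#'
#' `100 * |distinct merged reference CRMs hit| / |merged reference CRMs|`;
#' the overlap fraction is still computed on the prediction's length.
#'
#' @inheritParams redfly_recovery
#' @return A percentage, or `NA` for an empty reference.
#' @export
redfly_recall <- function(predictions, merged_ref, min_frac = 0.10) {
  merged_ref <- .as_granges(merged_ref)
  if (length(merged_ref) == 0L) {
    warning("empty reference: recall is undefined")
    return(NA_real_)
  }
  hit <- intersect_fraction(.as_granges(predictions), merged_ref, min_frac)$b_hit
  100 * length(hit) / length(merged_ref)
}

#' Training-set sensitivity
#'
#' `100 * |distinct training CRMs hit by at least one qualifying prediction|
#' / |training CRMs|`. Counting distinct training CRMs (rather than
#' qualifying predictions) caps the measure at 100% when several predictions
#' tile one training CRM.
#'
#' @param predictions `GRanges` of predicted CRMs.
#' @param training_crms `GRanges` of the training CRMs.
#' @param min_frac Minimum overlap fraction of the prediction (default 0.10).
#' @return A percentage, or `NA` for an empty training set.
#' @export
training_set_sensitivity <- function(predictions, training_crms,
                                     min_frac = 0.10) {
  training_crms <- .as_granges(training_crms)
  if (length(training_crms) == 0L) {
    warning("empty training set: sensitivity is undefined")
    return(NA_real_)
  }
  hit <- intersect_fraction(.as_granges(predictions), training_crms, min_frac)$b_hit
  100 * length(hit) / length(training_crms)
}

#' Expression-pattern precision
#'
#' Among predictions that hit at least one expression-annotated reference
#' CRM, the fraction whose hit set includes at least one CRM annotated with
#' `target_term`. A prediction with several annotated hits counts once and
#' is correct if any hit carries the term.
#'
#' @param predictions `GRanges` of predicted CRMs.
#' @param expr_ref Expression-annotated reference CRMs (unmerged, with a
#'   `terms` column), as from [prepare_reference()].
#' @param target_term The expected expression term (non-empty string).
#' @param min_frac Minimum overlap fraction of the prediction (default 0.10).
#' @return A percentage, or `NA` when no prediction hits any annotated CRM.
#' @export
expression_pattern_precision <- function(predictions, expr_ref, target_term,
                                         min_frac = 0.10) {
  predictions <- .as_granges(predictions)
  expr_ref <- .as_granges(expr_ref)
  if (!is.character(target_term) || length(target_term) != 1L || !nzchar(target_term))
    stop("`target_term` must be a non-empty string", call. = FALSE)
  annotated <- expr_ref[.has_terms(expr_ref)]
  if (length(predictions) == 0L || length(annotated) == 0L) return(NA_real_)
  ov <- intersect_fraction(predictions, annotated, min_frac)
  if (length(ov$a_hit) == 0L) return(NA_real_)
  match_b <- .term_match(annotated, target_term)
  correct <- unique(ov$pairs[match_b[ov$pairs[, "b"]], "a"])
  100 * length(correct) / length(ov$a_hit)
}

#' Expression-pattern recall
#'
#' `100 * |distinct reference CRMs annotated with target_term that are hit| /
#' |reference CRMs annotated with target_term|`.
#'
#' @inheritParams expression_pattern_precision
#' @return A percentage, or `NA` when no reference CRM carries the term.
#' @export
expression_pattern_recall <- function(predictions, expr_ref, target_term,
                                      min_frac = 0.10) {
  expr_ref <- .as_granges(expr_ref)
  if (!is.character(target_term) || length(target_term) != 1L || !nzchar(target_term))
    stop("`target_term` must be a non-empty string", call. = FALSE)
  carriers <- expr_ref[.has_terms(expr_ref) & .term_match(expr_ref, target_term) %in% TRUE]
  if (length(carriers) == 0L) {
    warning("no reference CRM carries the target term: recall is undefined")
    return(NA_real_)
  }
  hit <- intersect_fraction(.as_granges(predictions), carriers, min_frac)$b_hit
  100 * length(hit) / length(carriers)
}

#' Evaluate a prediction set at a fixed cutoff
#'
#' Computes all five measures on the prediction list as given. Reference
#' preparation (length filter, training-CRM removal, merging) is applied
#' here via [prepare_reference()].
#'
#' @param predictions Ranked `GRanges` of predicted CRMs (rank 1 = best).
#' @param reference_crms Database CRMs (`GRanges`, optionally with `terms`).
#' @param training_crms Optional training CRMs; `NULL` leaves
#'   `training_set_sensitivity` as `NA`.
#' @param target_term Optional expression term; `NULL` leaves the
#'   expression-pattern measures `NA`.
#' @param min_frac Minimum overlap fraction of the prediction (default 0.10).
#' @param max_len Reference length filter in bp (default 2000).
#' @return A one-row data.frame: `n_predictions`, `redfly_recovery`,
#'   `redfly_recall`, `training_set_sensitivity`,
#'   `expression_pattern_precision`, `expression_pattern_recall`.
#' @export
evaluate_fixed <- function(predictions, reference_crms, training_crms = NULL,
                           target_term = NULL, min_frac = 0.10,
                           max_len = 2000L) {
  predictions <- .as_granges(predictions)
  prep <- prepare_reference(reference_crms, training_crms, max_len = max_len)
  has_terms_col <- "terms" %in% names(mcols(prep$expr_ref))
  res <- data.frame(
    n_predictions = length(predictions),
    redfly_recovery = suppressWarnings(
      redfly_recovery(predictions, prep$merged_ref, min_frac)),
    redfly_recall = suppressWarnings(
      redfly_recall(predictions, prep$merged_ref, min_frac)),
    training_set_sensitivity = if (is.null(training_crms)) NA_real_ else
      suppressWarnings(training_set_sensitivity(predictions, training_crms, min_frac)),
    expression_pattern_precision = if (is.null(target_term) || !has_terms_col)
      NA_real_ else suppressWarnings(
        expression_pattern_precision(predictions, prep$expr_ref, target_term, min_frac)),
    expression_pattern_recall = if (is.null(target_term) || !has_terms_col)
      NA_real_ else suppressWarnings(
        expression_pattern_recall(predictions, prep$expr_ref, target_term, min_frac)))
  res
}

#' Evaluate a ranked prediction list semi-continuously
#'
#' Recomputes [evaluate_fixed()] on the top `n` predictions for `n = step,
#' 2*step, ...` up to `max_n` (or the full list, whichever is smaller), with
#' a final partial bucket when the list does not end on a multiple of
#' `step`.
#'
#' @inheritParams evaluate_fixed
#' @param step Evaluation stride in predictions (default 250).
#' @param max_n Largest cutoff evaluated (default 7000).
#' @return A data.frame with one row per cutoff, the cutoff in column `n`.
#' @export
evaluate_continuous <- function(predictions, reference_crms,
                                training_crms = NULL, target_term = NULL,
                                min_frac = 0.10, step = 250L, max_n = 7000L,
                                max_len = 2000L) {
  predictions <- .as_granges(predictions)
  .assert_scalar_number(step, "step")
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  top <- min(max_n, length(predictions))
  if (top == 0L) stop("no predictions to evaluate", call. = FALSE)
  ns <- unique(c(seq(step, top, by = step), top))
  rows <- lapply(ns, function(n) {
    cbind(n = n, evaluate_fixed(head(predictions, n), reference_crms,
                                training_crms, target_term, min_frac, max_len))
  })
  do.call(rbind, rows)
}

#' Permutation-based random expectation of a measure
#'
#' Re-places the predictions uniformly at random in the non-excluded genome
#' ([shuffle_intervals()]) and recomputes the chosen measure, `n_perm`
#' times, giving an empirical null distribution. Significance of the
#' observed value is summarised as `z = (observed - null mean) / null sd`
#' with the population (divisor n) standard deviation.
#'
#' @param predictions `GRanges` of predicted CRMs.
#' @param space A [genome_space()] (exclusions are typically the exons, as
#'   predictions are made on non-exonic sequence only).
#' @param measure One of `"redfly_recovery"`, `"redfly_recall"`,
#'   `"training_set_sensitivity"`, `"expression_pattern_precision"`,
#'   `"expression_pattern_recall"`.
#' @param reference_crms,training_crms,target_term,min_frac,max_len As in
#'   [evaluate_fixed()]; only the arguments the chosen measure needs are
#'   required.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed; the whole summary is deterministic
#'   given it.
#' @return An object of class `null_summary`: `measure`, `observed`,
#'   `null_mean`, `null_sd`, `z` (`NA` iff `null_sd == 0`), `sd_zero`,
#'   `n_permutations`, `seed`, and the vector of `null_values`.
#' @export
permutation_null <- function(predictions, space, measure,
                             reference_crms = NULL, training_crms = NULL,
                             target_term = NULL, min_frac = 0.10,
                             n_perm = 100L, seed = NULL, max_len = 2000L) {
  predictions <- .as_granges(predictions)
  measure <- match.arg(measure, c("redfly_recovery", "redfly_recall",
                                  "training_set_sensitivity",
                                  "expression_pattern_precision",
                                  "expression_pattern_recall"))
  .assert_scalar_number(n_perm, "n_perm", lower = 1)
  prep <- if (!is.null(reference_crms))
    prepare_reference(reference_crms, training_crms, max_len = max_len)
  compute <- switch(measure,
    redfly_recovery = function(p) redfly_recovery(p, prep$merged_ref, min_frac),
    redfly_recall = function(p) redfly_recall(p, prep$merged_ref, min_frac),
    training_set_sensitivity = function(p)
      training_set_sensitivity(p, training_crms, min_frac),
    expression_pattern_precision = function(p)
      expression_pattern_precision(p, prep$expr_ref, target_term, min_frac),
    expression_pattern_recall = function(p)
      expression_pattern_recall(p, prep$expr_ref, target_term, min_frac))
  observed <- suppressWarnings(compute(predictions))
  null_values <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      suppressWarnings(compute(shuffle_intervals(predictions, space)))
    }, 1.0)
  })
  # An NA permutation value means the measure's denominator was empty for
  # that placement (e.g. no shuffled prediction hit any annotated CRM); it
  # contributes no signal and is scored as 0 for the null.
  null_values[is.na(null_values)] <- 0
  m <- mean(null_values)
  s <- .pop_sd(null_values)
  structure(list(measure = measure, observed = observed, null_mean = m,
                 null_sd = s, z = if (s == 0) NA_real_ else (observed - m) / s,
                 sd_zero = s == 0, n_permutations = as.integer(n_perm),
                 seed = seed, null_values = null_values),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("null_summary [%s]: observed %.4g, null %.4g +/- %.4g (%d perms), z = %s\n",
              x$measure, x$observed, x$null_mean, x$null_sd, x$n_permutations,
              if (is.na(x$z)) "NA (zero null sd)" else sprintf("%.3g", x$z)))
  invisible(x)
}

#' Write an evaluation summary table
#'
#' Writes a tab-delimited table (one row per training set and cutoff, or
#' whatever rows the caller assembled) with `NA` rendered literally and
#' numerics at full precision, so a read-back recovers the values
#' bit-exactly.
#'
#' @param rows A data.frame of evaluation rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame", call. = FALSE)
  .write_tsv_exact(rows, path)
}
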