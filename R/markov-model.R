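# Fixed-order Markov sequence model and the window log-likelihood-ratio
# score. This is the supervised scorer behind genome scanning: a CRM model
# trained on known-CRM sequences and a background model trained on
# non-exonic genome sequence; a window's score is the mean per-base
# log-likelihood ratio between the two.

.BASES <- c("A", "C", "G", "T")

# All k-mers over ACGT in lexicographic (base-4) order, matching both the
# column order of Biostrings::oligonucleotideFrequency and the encoding of
# .kmer_index (first base most significant).
.all_kmers <- function(k) {
  if (k == 0L) return("")
  g <- expand.grid(rep(list(.BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(unname(as.list(g))))
}

#' Train a fixed-order Markov model
#'
#' Estimates conditional probabilities `P(base | preceding k bases)` from
#' (k+1)-mer counts with add-pseudocount smoothing. Windows containing `N`
#' (or any non-ACGT letter) are excluded from counting. With no training
#' data, every conditional is the pure pseudocount value 1/4.
#'
#' @param sequences A `DNAStringSet` or character vector of training
#'   sequences.
#' @param order Markov order `k >= 0`; the default 5 conditions each base on
#'   the preceding 5, i.e. models hexamer statistics.
#' @param pseudocount Positive smoothing constant added to every (k+1)-mer
#'   count.
#' @param both_strands If `TRUE`, reverse complements are added to the
#'   training data before counting. Default `FALSE` (count the given strand
#'   only).
#' @param prior_model Optional `markov_model` of the same order used as the
#'   smoothing prior: each context receives `4 * pseudocount` virtual
#'   observations distributed according to the prior's conditionals, instead
#'   of uniformly. Shrinking a CRM model toward the background model this
#'   way (back-off smoothing, in the spirit of interpolated Markov models)
#'   removes the negative score bias that uniform smoothing gives every
#'   sequence the small training set cannot explain.
#' @return An object of class `markov_model` with elements `order`,
#'   `log_cond` (a `4^k x 4` matrix of log conditional probabilities, rows =
#'   contexts in lexicographic order) and `pseudocount`.
#' @export
#' @examples
#' m <- train_markov("AAAA", order = 0, pseudocount = 1)
#' exp(m$log_cond[1, "A"])  # (4 + 1) / (4 + 4) = 5/8
train_markov <- function(sequences, order = 5L, pseudocount = 1.0,
                         both_strands = FALSE, prior_model = NULL) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != floor(order))
    stop("`order` must be a non-negative integer", call. = FALSE)
  order <- as.integer(order)
  .assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (!methods::is(sequences, "DNAStringSet"))
    stop("`sequences` must be a DNAStringSet or character vector", call. = FALSE)
  if (both_strands && length(sequences))
    sequences <- c(sequences, Biostrings::reverseComplement(sequences))
  w <- order + 1L
  n_ctx <- 4L^order
  total_len <- sum(as.numeric(Biostrings::width(sequences)))
  if (total_len < 4^w)
    warning(sprintf("training data (%d bp) shorter than 4^(order+1) = %d; estimates rely heavily on the pseudocount",
                    as.integer(total_len), 4L^w))
  counts <- numeric(4L^w)
  long_enough <- Biostrings::width(sequences) >= w
  if (any(long_enough)) {
    cm <- Biostrings::oligonucleotideFrequency(sequences[long_enough], width = w)
    counts <- if (is.matrix(cm)) colSums(cm) else cm
  }
  cmat <- matrix(counts, nrow = n_ctx, ncol = 4L, byrow = TRUE,
                 dimnames = list(.all_kmers(order), .BASES))
  if (is.null(prior_model)) {
    cmat <- cmat + pseudocount
  } else {
    if (!inherits(prior_model, "markov_model") || prior_model$order != order)
      stop("`prior_model` must be a markov_model of the same order", call. = FALSE)
    cmat <- cmat + 4 * pseudocount * exp(prior_model$log_cond)
  }
  log_cond <- log(cmat / rowSums(cmat))
  structure(list(order = order, log_cond = log_cond,
                 pseudocount = pseudocount), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: order %d (%d contexts), pseudocount %g\n",
              x$order, nrow(x$log_cond), x$pseudocount))
  invisible(x)
}

# Encode a DNA character string as integer codes 0..3 (NA for N/other).
.encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, .BASES) - 1L
}

# Flattened (k+1)-mer log-likelihood-ratio lookup table between two models
# of equal order: llr[idx + 1] for idx = base-4 encoding of context+base.
.llr_table <- function(crm_model, bg_model) {
  if (!inherits(crm_model, "markov_model") || !inherits(bg_model, "markov_model"))
    stop("models must be markov_model objects", call. = FALSE)
  if (crm_model$order != bg_model$order)
    stop("CRM and background models must have the same order", call. = FALSE)
  as.vector(t(crm_model$log_cond - bg_model$log_cond))
}

# Per-position (k+1)-mer index along an integer-coded sequence: idx[i] (for
# i in (k+1)..n, stored at output position i-k) encodes bases i-k..i in
# base 4. NA wherever any base in the word is ambiguous.
.kmer_index <- function(codes, k) {
  n <- length(codes)
  w <- k + 1L
  if (n < w) return(numeric(0))
  idx <- numeric(n - k)
  for (j in seq_len(w)) {
    idx <- idx * 4 + codes[j:(n - w + j)]
  }
  idx
}

#' Score a sequence window
#'
#' Returns the mean per-scored-base log-likelihood ratio
#' `log P_crm(base | context) - log P_bg(base | context)` over all positions
#' whose (order+1)-mer lies within the window and contains no `N`. A window
#' whose `N` content exceeds `max_n_frac` of its length scores `NA` (such
#' windows are dropped from genome scans, since k-mer statistics over
#' ambiguous bases are undefined).
#'
#' @param seq A single character string or `DNAString` (the window sequence).
#' @param crm_model,bg_model [train_markov()] models of equal order.
#' @param max_n_frac Maximum tolerated fraction of `N` bases (default 0.10).
#' @return A single numeric score, or `NA_real_`.
#' @export
score_window <- function(seq, crm_model, bg_model, max_n_frac = 0.10) {
  if (!is.character(seq)) seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  k <- crm_model$order
  llr <- .llr_table(crm_model, bg_model)
  codes <- .encode_dna(seq)
  n <- length(codes)
  if (n < k + 1L)
    stop(sprintf("sequence length %d is shorter than order + 1 = %d", n, k + 1L),
         call. = FALSE)
  if (sum(is.na(codes)) > max_n_frac * n) return(NA_real_)
  idx <- .kmer_index(codes, k)
  v <- llr[idx + 1]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}
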