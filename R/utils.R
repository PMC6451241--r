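# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#' A `NULL` seed evaluates `code` with the RNG as-is.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate and coerce an interval container to GRanges.
.as_granges <- function(x, arg = deparse(substitute(x))) {
  if (!methods::is(x, "GRanges"))
    stop(sprintf("`%s` must be a GRanges object", arg), call. = FALSE)
  x
}

# Format a GRanges element as "chrom:start-end" in 0-based half-open
# coordinates for error messages (matching the on-disk BED convention).
.gr_label <- function(gr, i = seq_along(gr)) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)[i]),
          start(gr)[i] - 1L, end(gr)[i])
}

# Deterministic ranking order used everywhere a ranked window/prediction list
# is produced: descending score, ties broken by (chrom, start) ascending.
.rank_order <- function(gr, score) {
  order(-score, as.character(seqnames(gr)), start(gr), end(gr))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Population standard deviation (divisor n, not n-1).
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Write a data.frame as a TSV with full-precision numerics so that a
# read-back recovers the numbers bit-exactly.
.write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
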