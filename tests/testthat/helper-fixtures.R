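# Shared test fixtures, built once per test run and memoised.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small planted-CRM fixture: fast enough for per-module tests while still
# carrying detectable signal.
small_fixture <- function() {
  cached("small_fixture", generate_fixture(fixture_config(
    genome_length = 4e5, n_chroms = 2L, crms_per_class = 20L,
    training_per_class = 10L, decoy_count = 20L, seed = 42L)))
}

# Scan models for class 1 of the small fixture.
small_models <- function() {
  fx <- small_fixture()
  cached("small_models",
         train_scan_models(fx$genome, fx$exons, fx$training_sets$class1))
}

# Single-instance scan (offset 0) of the small fixture under class-1 models.
small_scan <- function() {
  fx <- small_fixture()
  m <- small_models()
  cached("small_scan",
         scan_genome(fx$genome, fx$exons, m$crm_model, m$bg_model,
                     scan_config()))
}

# High-density bundle for the small fixture (class 1).
small_bundle <- function() {
  fx <- small_fixture()
  m <- small_models()
  cached("small_bundle",
         scan_hd(fx$genome, fx$exons, m$crm_model, m$bg_model))
}

# The default-scale fixture (2 Mb) and its high-density runs, shared by the
# end-to-end power checks. The pooled rank cutoff 7500 is the package's
# fixture-scale choice (see the methods vignette).
default_fixture <- function() {
  cached("default_fixture", generate_fixture(fixture_config(seed = 1L)))
}

real_hd_runs <- function() {
  cached("real_hd_runs", {
    fx <- default_fixture()
    lapply(1:3, function(cl) {
      run <- run_hd_protocol(fx$genome, fx$exons, fx$training_sets[[cl]],
                             rank_cutoff = 7500)
      ev <- evaluate_fixed(run$peaks, fx$database, fx$training_sets[[cl]],
                           target_term = fx$class_terms[cl])
      list(class = cl, peaks = run$peaks, theta = run$theta, ev = ev)
    })
  })
}

# GC-matched random-sequence control sets, run through the same protocol and
# evaluated for the class-1 expression pattern.
random_hd_runs <- function() {
  cached("random_hd_runs", {
    fx <- default_fixture()
    lapply(1:3, function(k) {
      rnd <- generate_random_training_set(
        fx$genome, fx$exons, n = 30,
        length_sample = width(fx$training_sets$class1), seed = 500 + k)
      run <- run_hd_protocol(fx$genome, fx$exons, rnd, rank_cutoff = 7500)
      ev <- evaluate_fixed(run$peaks, fx$database, rnd,
                           target_term = fx$class_terms[1])
      list(set = rnd, peaks = run$peaks, ev = ev)
    })
  })
}

# Random intervals on a toy chromosome set, for oracle comparisons.
random_intervals <- function(n, max_coord = 200L, chroms = c("c1", "c2"),
                             max_len = 40L) {
  st <- sample.int(max_coord - 1L, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(st, width = pmin(len, max_coord - st + 1L)))
}

# Brute-force overlap oracle: all-pairs overlap lengths, fraction on A.
oracle_hits <- function(a, b, min_frac) {
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a)[i]) != as.character(seqnames(b)[j])) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
    if (ov > 0 && (ov / width(a)[i]) >= min_frac)
      pairs <- rbind(pairs, c(i, j))
  }
  list(a_hit = sort(unique(pairs[, 1])), b_hit = sort(unique(pairs[, 2])),
       pair_count = nrow(pairs))
}

# Brute-force elbow oracle: explicit point-to-chord distance with arbitrary
# endpoints, computed independently of the implementation's simplification.
oracle_elbow <- function(values) {
  n <- length(values)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- if (max(values) == min(values)) rep(0, n)
       else (values - values[n]) / (values[1] - values[n])
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  d <- numeric(n)
  for (i in seq_len(n))
    d[i] <- abs((y2 - y1) * x[i] - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(d)
}

# Deterministic toy GRanges constructor in 0-based half-open coordinates, to
# keep test cases readable in the same convention as the file formats.
gr0 <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}
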