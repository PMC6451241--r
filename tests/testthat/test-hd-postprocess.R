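# High-density aggregation: pooled thresholding, bin explosion and
# summation, peak calling, and the two-criterion cutoff.

mk_windows <- function(starts0, scores, offsets = 0L, chrom = "c1",
                       window = 500L) {
  gr <- gr0(chrom, starts0, starts0 + window)
  mcols(gr)$score <- scores
  mcols(gr)$offset <- as.integer(offsets)
  gr
}

test_that("pooled thresholding keeps scores at or above the Nth rank", {
  b <- hd_bundle(list(`0` = mk_windows(c(0, 1000), c(5, 3)),
                      `10` = mk_windows(c(10, 1010), c(4, 2), 10L)))
  ct <- concat_and_threshold(b, rank_cutoff = 2)
  expect_equal(ct$theta, 4)
  expect_equal(sort(mcols(ct$kept)$score), c(4, 5))

  # fewer windows than the cutoff: theta is the smallest score, all kept
  ct2 <- concat_and_threshold(b, rank_cutoff = 5000)
  expect_equal(ct2$theta, 2)
  expect_equal(length(ct2$kept), 4L)

  # ties at theta are kept
  bt <- hd_bundle(list(`0` = mk_windows(c(0, 1000, 2000), c(5, 4, 4))))
  expect_equal(length(concat_and_threshold(bt, 2)$kept), 3L)

  # single instance degenerates to take_top semantics
  w <- mk_windows(seq(0, by = 1000, length.out = 6), c(6, 5, 4, 3, 2, 1))
  ct3 <- concat_and_threshold(hd_bundle(list(`0` = w)), 3)
  expect_identical(granges(ct3$kept), granges(take_top(w, 3)))
})

test_that("explode_bins splits windows on the bin grid and conserves mass", {
  w <- mk_windows(1000, 2.0)
  segs <- explode_bins(w)
  expect_equal(length(segs), 50L)
  expect_true(all(width(segs) == 10L))
  expect_true(all(mcols(segs)$score == 2.0))
  expect_equal(min(start(segs)) - 1L, 1000L)
  expect_equal(max(end(segs)), 1500L)

  expect_error(explode_bins(mk_windows(1005, 2.0)), "bin grid")

  many <- mk_windows(seq(0, by = 500, length.out = 7), rnorm(7))
  expect_equal(length(explode_bins(many)), 50L * 7L)
})

test_that("sum_bins adds overlapping segment scores and conserves total mass", {
  w <- mk_windows(c(1000, 1250), c(2, 3))
  track <- sum_bins(explode_bins(w))
  val_at <- function(pos0) mcols(track)$value[start(track) - 1L == pos0]
  expect_equal(val_at(1000), 2)
  expect_equal(val_at(1240), 2)
  expect_equal(val_at(1250), 5)
  expect_equal(val_at(1490), 5)
  expect_equal(val_at(1500), 3)
  expect_equal(val_at(1740), 3)
  # conservation: sum(bin values) * bin width == sum(score * window length)
  expect_equal(sum(mcols(track)$value) * 10, sum(mcols(w)$score * width(w)))

  disjoint <- mk_windows(c(0, 5000), c(1.5, 2.5))
  td <- sum_bins(explode_bins(disjoint))
  expect_equal(sort(unique(mcols(td)$value)), c(1.5, 2.5))
})

test_that("peak calling applies the gap-merge and minimum-length rules", {
  mk_track <- function(starts0, values, bin = 10L) {
    gr <- gr0("c1", starts0, starts0 + bin)
    mcols(gr)$value <- values
    gr
  }
  # 30 consecutive bins above cutoff: one peak of 300 bp
  t1 <- mk_track(seq(0, by = 10, length.out = 30), rep(5, 30))
  p1 <- call_peaks(t1, cutoff = 1)
  expect_equal(length(p1), 1L)
  expect_equal(width(p1), 300L)
  expect_equal(mcols(p1)$amplitude, 5)

  # two 150-bp runs separated by a 20-bp gap merge into one 320-bp peak
  t2 <- mk_track(c(seq(0, 140, 10), seq(170, 310, 10)), rep(4, 30))
  p2 <- call_peaks(t2, cutoff = 1)
  expect_equal(length(p2), 1L)
  expect_equal(width(p2), 320L)

  # a lone 100-bp run is shorter than min_length and discarded
  t3 <- mk_track(seq(0, 90, 10), rep(9, 10))
  expect_equal(length(call_peaks(t3, cutoff = 1)), 0L)

  # a 40-bp gap is not bridged
  t4 <- mk_track(c(seq(0, 190, 10), seq(240, 430, 10)), rep(4, 40))
  expect_equal(length(call_peaks(t4, cutoff = 1)), 2L)

  # strict > comparison: bins exactly at the cutoff do not qualify
  t5 <- mk_track(seq(0, by = 10, length.out = 30), rep(1, 30))
  expect_equal(length(call_peaks(t5, cutoff = 1)), 0L)
})

test_that("raising the cutoff only shrinks peak territory", {
  # Raising the cutoff can split a merged run in two (so the peak COUNT may
  # rise), but every high-cutoff peak lies within a low-cutoff peak and the
  # total peak territory never grows.
  set.seed(23)
  starts <- seq(0, by = 10, length.out = 500)
  gr <- gr0("c1", starts, starts + 10)
  mcols(gr)$value <- abs(rnorm(500, 2))
  lo <- call_peaks(gr, cutoff = 1)
  hi <- call_peaks(gr, cutoff = 2)
  expect_lte(sum(width(hi)), sum(width(lo)))
  if (length(hi)) {
    ov <- findOverlaps(hi, lo, type = "within")
    expect_equal(length(unique(queryHits(ov))), length(hi))
  }
  expect_equal(length(call_peaks(gr, cutoff = max(mcols(gr)$value))), 0L)
})

test_that("hd_top_predictions reproduces a hand-traced two-criterion example", {
  # Hand-traced construction (window 500, bin 10, theta = pooled minimum =
  # 0.5, so the 0.5-scoring singleton never exceeds the strict peak cutoff):
  #  * blocks A and B: two half-overlapping strong windows each
  #      A: amp 10+9 = 19, mws 10;  B: amp 8.5+8 = 16.5, mws 8.5
  #  * block C: ten stacked weak windows (starts 10 bp apart, score 1.0):
  #      amp = 10 (depth), mws = 1.0 -> passes amplitude, fails score
  #  * eight isolated singletons scoring 1.2 down to 0.5: sub-amplitude
  #    except that the 1.2 one sits exactly at both elbow cutoffs (the elbow
  #    is the corner of the L-curve, which belongs to the tail and is kept
  #    by the >= comparisons).
  # Amplitude curve: 19, 16.5, 10, 1.2, ..., 0.6 -> elbow value 1.2.
  # Score curve: 10, 8.5, 1.2, 1.1, 1.0, 1.0, ..., 0.6 -> elbow value 1.2.
  strong_a <- mk_windows(c(1000, 1250), c(10, 9))
  strong_b <- mk_windows(c(5000, 5250), c(8.5, 8))
  block_c <- mk_windows(seq(9000, by = 10, length.out = 10), rep(1.0, 10))
  tail_w <- mk_windows(seq(20000, by = 2000, length.out = 8),
                       seq(1.2, 0.5, length.out = 8))
  b <- hd_bundle(list(`0` = c(strong_a, strong_b, block_c, tail_w)))
  hd <- hd_top_predictions(b, rank_cutoff = 100)  # theta = min score = 0.5
  expect_equal(hd$theta, 0.5)
  expect_equal(length(hd$all_peaks), 10L)  # A, B, C and 7 singletons > theta
  expect_equal(start(hd$peaks) - 1L, c(1000, 5000, 20000))
  expect_equal(mcols(hd$peaks)$amplitude, c(19, 16.5, 1.2))
  expect_equal(mcols(hd$peaks)$max_window_score, c(10, 8.5, 1.2))
  # block C (amplitude 10, max window score 1.0) was cut by the score elbow
  expect_false(any(start(hd$peaks) - 1L == 9000))
})

test_that("instance concatenation order does not change the peak set", {
  b <- small_bundle()
  perm <- hd_bundle(b$instances[rev(seq_along(b$instances))],
                    window = b$window, shift = b$shift, bin = b$bin)
  hd1 <- hd_top_predictions(b, rank_cutoff = 1500)
  hd2 <- hd_top_predictions(perm, rank_cutoff = 1500)
  expect_equal(hd1$theta, hd2$theta)
  expect_identical(granges(hd1$peaks), granges(hd2$peaks))
})

test_that("peaks lie within the union of kept windows", {
  hd <- hd_top_predictions(small_bundle(), rank_cutoff = 1500)
  cover <- sort_merge(hd$kept)
  ov <- findOverlaps(hd$peaks, cover, type = "within")
  expect_equal(length(unique(queryHits(ov))), length(hd$peaks))
})

test_that("high-density output is robust to a global window-grid shift", {
  # The motivating property: trimming leading bases off every chromosome
  # changes which windows the default protocol scores, and with it the
  # prediction set; the pooled-offset protocol should be (nearly) immune.
  fx <- small_fixture()
  m <- small_models()
  trim <- 125L
  tg <- crmbench:::.trim_genome(fx$genome, fx$exons, trim)
  g2 <- tg$genome
  e2 <- tg$exons

  jaccard <- function(a, b) {
    ia <- sort_merge(a); ib <- sort_merge(b)
    inter <- sum(width(GenomicRanges::intersect(ia, ib)))
    inter / (sum(width(ia)) + sum(width(ib)) - inter)
  }
  hd0 <- hd_top_predictions(small_bundle(), rank_cutoff = 1500)
  b125 <- scan_hd(g2, e2, m$crm_model, m$bg_model)
  hd125 <- hd_top_predictions(b125, rank_cutoff = 1500)
  j_hd <- jaccard(hd0$peaks, shift(hd125$peaks, trim))

  d0 <- default_top_predictions(take_top(small_scan(), 1500))
  w125 <- scan_genome(g2, e2, m$crm_model, m$bg_model, scan_config())
  d125 <- default_top_predictions(take_top(w125, 1500))
  j_def <- jaccard(d0, shift(d125, trim))

  expect_gte(j_hd, j_def)
  expect_gt(j_hd, 0.5)
})
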