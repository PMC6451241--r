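# Genome fragmentation: length models, fragment plans, sequence/annotation
# transfer, coordinate lifting, and the robustness report.

test_that("length models use interpolated quartiles", {
  m <- build_length_model(1:8)
  expect_equal(m$quartile_bounds, c(2.75, 4.5, 6.25))
  expect_equal(build_length_model(rep(100, 6))$quartile_bounds, rep(100, 3))
  expect_equal(build_length_model(c(5, 1, 7, 3))$quartile_bounds,
               build_length_model(c(1, 3, 5, 7))$quartile_bounds)
  expect_error(build_length_model(1:3), "at least 4")
})

test_that("assembly presets parameterise synthetic length models by N50", {
  presets <- assembly_presets()
  expect_equal(presets$id, LETTERS[1:10])
  m <- preset_length_model("J", seed = 3)
  n50 <- function(x) {
    s <- sort(x, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1]]
  }
  expect_equal(n50(m$sample_lengths),
               presets$scaffold_n50[presets$id == "J"], tolerance = 0.05)
  expect_error(preset_length_model("A"), "halves")
  expect_error(preset_length_model("Z"), "unknown preset")
})

test_that("halves mode splits each chromosome into two equal fragments", {
  plan <- plan_fragments(c(chrA = 1000L, chrB = 999L), mode = "halves")
  a <- plan[as.character(seqnames(plan)) == "chrA"]
  expect_equal(start(a) - 1L, c(0L, 500L))  # [0,500) and [500,1000)
  expect_equal(end(a), c(500L, 1000L))
  b <- plan[as.character(seqnames(plan)) == "chrB"]
  expect_equal(abs(diff(width(b))), 1L)
  expect_false(anyDuplicated(mcols(plan)$scaffold) > 0)
})

test_that("quartile plans tile every chromosome exactly and match the model", {
  set.seed(55)
  model <- build_length_model(round(stats::rlnorm(200, log(5000), 0.6)))
  sizes <- c(c1 = 200000L, c2 = 150000L)
  frag_lens <- integer(0)
  for (seed in 1:20) {
    plan <- plan_fragments(sizes, model, seed = seed, mode = "quartile")
    for (ch in names(sizes)) {
      p <- plan[as.character(seqnames(plan)) == ch]
      p <- p[order(start(p))]
      expect_equal(start(p)[1], 1L)
      expect_equal(end(p)[length(p)], unname(sizes[ch]))
      expect_equal(sum(width(p)), unname(sizes[ch]))
      if (length(p) > 1)
        expect_equal(start(p)[-1], end(p)[-length(p)] + 1L)
    }
    # drop the truncated final fragment of each chromosome before comparing
    keep <- end(plan) != sizes[as.character(seqnames(plan))]
    frag_lens <- c(frag_lens, width(plan)[keep])
  }
  got <- quantile(frag_lens, c(.25, .5, .75), type = 7)
  expect_true(all(abs(got - model$quartile_bounds) / model$quartile_bounds < 0.25))
  # determinism
  expect_identical(plan_fragments(sizes, model, seed = 4, mode = "quartile"),
                   plan_fragments(sizes, model, seed = 4, mode = "quartile"))
})

test_that("fragmentation copies sequence verbatim and splits spanning features", {
  fx <- small_fixture()
  plan <- plan_fragments(fx$genome, mode = "halves")
  frag <- apply_fragmentation(fx$genome, fx$exons, plan)
  # concatenating fragments in plan order reconstructs each chromosome
  for (ch in names(fx$genome)) {
    idx <- which(as.character(seqnames(plan)) == ch)
    idx <- idx[order(start(plan)[idx])]
    rebuilt <- paste(vapply(mcols(plan)$scaffold[idx], function(s)
      as.character(frag$genome[[s]]), ""), collapse = "")
    expect_identical(rebuilt, as.character(fx$genome[[ch]]))
  }
  # total annotated mass is preserved
  expect_equal(sum(width(frag$annotations)), sum(width(fx$exons)))

  # an exon straddling a cut is split and re-based
  g <- DNAStringSet(c(cc = strrep("ACGT", 250)))  # 1000 bp
  exon <- gr0("cc", 450, 550)
  p <- plan_fragments(g, mode = "halves")
  f2 <- apply_fragmentation(g, exon, p)
  expect_equal(length(f2$annotations), 2L)
  expect_equal(width(f2$annotations), c(50L, 50L))
  expect_equal(start(f2$annotations) - 1L, c(450L, 0L))

  wrong <- DNAStringSet(c(other = "ACGT"))
  expect_error(apply_fragmentation(wrong, exon, p), "tile")
})

test_that("liftover_back inverts the re-basing exactly", {
  g <- DNAStringSet(c(cc = strrep("ACGT", 250)))
  plan <- plan_fragments(g, mode = "halves")
  scafB <- mcols(plan)$scaffold[2]
  lifted <- liftover_back(GRanges(scafB, IRanges(1, 50)), plan)
  expect_equal(start(lifted) - 1L, 500L)  # local [0,50) -> native [500,550)
  expect_equal(end(lifted), 550L)

  # identity plan: one fragment per chromosome
  fx <- small_fixture()
  idp <- GRanges(names(fx$genome), IRanges(1L, width(fx$genome)))
  mcols(idp)$scaffold <- names(fx$genome)
  tr <- fx$training_sets$class1
  idlift <- liftover_back(tr, idp)
  expect_equal(as.character(seqnames(idlift)), as.character(seqnames(tr)))
  expect_equal(start(idlift), start(tr))
  expect_equal(end(idlift), end(tr))

  # random round trip through a quartile plan
  set.seed(56)
  model <- build_length_model(round(stats::rlnorm(100, log(20000), 0.5)))
  plan2 <- plan_fragments(fx$genome, model, seed = 13, mode = "quartile")
  frag <- apply_fragmentation(fx$genome, tr, plan2)
  back <- liftover_back(frag$annotations, plan2)
  expect_equal(sum(width(sort_merge(back))), sum(width(sort_merge(tr))))
  expect_true(all(countOverlaps(back, tr, type = "within") >= 1L))

  expect_error(liftover_back(GRanges("nope", IRanges(1, 5)), plan), "unknown scaffold")
  expect_error(liftover_back(GRanges(scafB, IRanges(1, 9999)), plan),
               "past its scaffold end")
})

test_that("the robustness report scores identity and degenerate cases", {
  top <- gr0(rep("c1", 3), c(0, 1000, 2000), c(500, 1500, 2500))
  scored <- top
  mcols(scored)$score <- c(3, 2, 1)
  rep1 <- assess_robustness(top, scored, top, min_frac = 0.5,
                            sim_scored_lifted = scored)
  expect_equal(rep1$tp_percent, 100)
  expect_equal(rep1$fp_percent, 0)
  expect_equal(rep1$pearson_r, 1)
  expect_equal(rep1$n_common_windows, 3L)

  # simulated predictions entirely in sub-cutoff (scored but not top) land
  sub <- gr0(rep("c1", 2), c(5000, 6000), c(5500, 6500))
  all_scored <- c(scored, {x <- sub; mcols(x)$score <- c(0.1, 0.2); x})
  rep2 <- assess_robustness(top, all_scored, sub, min_frac = 0.5)
  expect_equal(rep2$tp_percent, 0)
  expect_equal(rep2$fp_percent, 100)
  expect_true(is.na(rep2$pearson_r))
})

test_that("window score correlation ignores ordering", {
  set.seed(91)
  w <- gr0("c1", seq(0, by = 200, length.out = 40),
           seq(100, by = 200, length.out = 40))
  mcols(w)$score <- rnorm(40)
  w2 <- w[sample(40)]
  rep1 <- assess_robustness(w[1:5], w, w2[1:5], min_frac = 0.5,
                            sim_scored_lifted = w2)
  expect_equal(rep1$pearson_r, 1)
  expect_equal(rep1$n_common_windows, 40L)
})
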