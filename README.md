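# crmbench

Benchmarking enhancer prediction, and making it robust to where the first
scoring window falls.

## The problem

Computational discovery of *cis*-regulatory modules (CRMs — enhancers and
similar elements) typically trains a sequence model on validated CRMs that
share an expression class, scores overlapping windows across a genome, and
reports the top-scoring windows as candidates. Evaluating such predictions
is hard because no genome has a complete CRM catalogue, and the predictions
themselves turn out to depend on an arbitrary detail: the position of the
first analysis window on each chromosome or scaffold — a real concern for
draft assemblies with thousands of scaffolds.

crmbench provides, as one tested R package:

* **An evaluation engine** for any BED-formatted prediction set, scored
  against a database of validated CRMs with expression annotations (a
  REDfly-style export). Five measures, each a percentage with the overlap
  fraction computed on the prediction's length (default minimum 10%):
  *database recovery* (predictions overlapping known CRMs / predictions),
  *database recall*, *training-set sensitivity* (distinct training CRMs
  recovered / training CRMs), *expression-pattern precision* (among
  predictions hitting an annotated CRM, the fraction hitting one with the
  expected term) and *expression-pattern recall* — at a fixed cutoff or
  every 250 predictions along the ranked list, with an empirical random
  expectation from exclusion-aware interval shuffling:
  `z = (observed − null mean) / null sd` over 100 permutations.
* **A supervised window scorer**: a fixed-order Markov log-likelihood ratio
  (default order 5, i.e. hexamer statistics; CRM model shrunk toward the
  background model), scanning 500-bp windows every 250 bp with a
  configurable start offset.
* **A high-density protocol** that removes the window-placement dependence:
  25 scan instances at offsets 0, 10, …, 240 bp are pooled; scores below the
  5000th-ranked pooled score θ are zeroed; kept windows are exploded into
  10-bp bins whose scores are summed; peaks are called on the summed track
  (cutoff θ, max gap 30 bp, min length 200 bp); and the top predictions are
  the peaks at or above the elbow points of **both** the peak-amplitude
  curve and the peak max-window-score curve (the elbow of a descending
  curve is the point furthest from the chord joining its ends, after
  min-max normalising both axes).
* **An assembly-robustness simulator** that fragments a genome to an
  empirical scaffold-length distribution (quartile draws, or chromosome
  halves as the best case), lifts annotations forward and predictions back,
  and reports the true-positive / false-positive percentages and the Pearson
  correlation of corresponding window scores.
* **A seeded synthetic-data generator** — a genome with planted,
  class-labelled, k-mer-enriched CRMs, a noisy incomplete database with
  decoys, training sets and exons — so the whole pipeline runs end-to-end
  with no external data.

See the methods vignette (`vignettes/crm-evaluation-methods.Rmd`) for the
model details, parameter choices and limitations.

## A worked example

```r
library(crmbench)

# a synthetic study system: genome + planted CRMs + database + exons
fx <- generate_fixture(fixture_config(seed = 1))
fx
#> crm_fixture: 2,000,000 bp over 4 chromosome(s); 180 planted CRMs in
#>   3 class(es); 185 database entries; 455 exons (seed 1)

# high-density protocol for expression class 1 (rank cutoff 7500 is the
# 2-Mb-scale analogue of the canonical full-genome 5000; see the vignette)
run <- run_hd_protocol(fx$genome, fx$exons, fx$training_sets$class1,
                       rank_cutoff = 7500)
length(run$peaks)   #> 58 top predictions
round(run$theta, 4) #> 8e-04  (score of the 7500th pooled window)

ev <- evaluate_fixed(run$peaks, fx$database, fx$training_sets$class1,
                     target_term = "class1_pattern")
print(ev, row.names = FALSE)
#>  n_predictions redfly_recovery redfly_recall training_set_sensitivity
#>             58        39.65517      14.54545                      100
#>  expression_pattern_precision expression_pattern_recall
#>                      86.66667                        50

space <- genome_space(fx$genome, fx$exons)
permutation_null(run$peaks, space, "training_set_sensitivity",
                 training_crms = fx$training_sets$class1,
                 n_perm = 100, seed = 2)
#> null_summary [training_set_sensitivity]: observed 100, null 9.433 +/- 5.438
#>   (100 perms), z = 16.7
```

Reading the numbers: all 30 training CRMs are recovered (sensitivity 100%,
z = 16.7 against shuffled placement), 40% of the 58 predictions coincide
with database entries — the rest are dominated by planted CRMs the noisy
database never recorded — and 87% of the predictions that hit an annotated
CRM hit one annotated with the expected class term.

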