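# Seeded synthetic test substrate: a genome with planted, class-labelled
# CRMs whose sequences are enriched for class-specific k-mers, a noisy
# partially annotated CRM database with decoys, per-class training sets, and
# an exon annotation. Everything downstream (scorer, high-density protocol,
# evaluation, fragmentation) is exercised on these fixtures, so their
# defaults define the study conditions.

#' Fixture configuration
#'
#' @param genome_length Total genome length in bp (default 2 Mb).
#' @param n_chroms Number of chromosomes the genome is split into (default 4).
#' @param n_classes Number of CRM expression classes (default 3).
#' @param crms_per_class Planted CRMs per class (default 60).
#' @param crm_length_range Planted CRM length range in bp (default 300-1500;
#'   kept under 2 kb so the database length filter is non-destructive).
#' @param kmers_per_class Number of enrichment k-mers per class (default 128).
#' @param kmer_length Length of the enrichment k-mers (default 6, matching
#'   the default scorer order of 5).
#' @param enrichment_strength Multiplier on the emission odds of a base that
#'   completes one of the class's k-mers (default 12; 1 = no signal). The
#'   defaults give a planted signal a hexamer scorer trained on 30 CRMs
#'   detects on held-out CRMs with AUROC above 0.9; odds-boosting acts only
#'   when a k-mer prefix is already present, so the realised k-mer frequency
#'   enrichment is much smaller than the nominal odds multiplier.
#' @param db_annotation_rate Fraction of planted CRMs entering the database
#'   (default 0.7).
#' @param db_term_rate Fraction of database entries that keep their
#'   expression terms (default 0.8).
#' @param decoy_count Database decoys placed on plain background (default 60).
#' @param exon_fraction Fraction of the genome covered by exons
#'   (default 0.25).
#' @param exon_length_range Exon length range in bp (default 200-2000).
#' @param training_per_class Planted CRMs per class used as the training set
#'   (default 30, leaving held-out planted CRMs).
#' @param jitter Maximum coordinate jitter (bp) applied to each end of a
#'   database entry, emulating reporter-construct imprecision (default 50).
#' @param seed Integer seed; the fixture is byte-reproducible given it.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(genome_length = 2e6, n_chroms = 4L, n_classes = 3L,
                           crms_per_class = 60L,
                           crm_length_range = c(300L, 1500L),
                           kmers_per_class = 128L, kmer_length = 6L,
                           enrichment_strength = 12.0,
                           db_annotation_rate = 0.7, db_term_rate = 0.8,
                           decoy_count = 60L, exon_fraction = 0.25,
                           exon_length_range = c(200L, 2000L),
                           training_per_class = 30L, jitter = 50L,
                           seed = 1L) {
  .assert_scalar_number(genome_length, "genome_length", lower = 1e4)
  .assert_scalar_number(enrichment_strength, "enrichment_strength", lower = 0)
  for (r in c(db_annotation_rate, db_term_rate, exon_fraction))
    .assert_scalar_number(r, "rate", lower = 0, upper = 1)
  if (crm_length_range[1] <= 0 || crm_length_range[2] >= 2000)
    stop("crm_length_range must lie within (0, 2000) bp", call. = FALSE)
  if (training_per_class > crms_per_class)
    stop("training_per_class cannot exceed crms_per_class", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms),
                 n_classes = as.integer(n_classes),
                 crms_per_class = as.integer(crms_per_class),
                 crm_length_range = as.integer(crm_length_range),
                 kmers_per_class = as.integer(kmers_per_class),
                 kmer_length = as.integer(kmer_length),
                 enrichment_strength = enrichment_strength,
                 db_annotation_rate = db_annotation_rate,
                 db_term_rate = db_term_rate,
                 decoy_count = as.integer(decoy_count),
                 exon_fraction = exon_fraction,
                 exon_length_range = as.integer(exon_length_range),
                 training_per_class = as.integer(training_per_class),
                 jitter = as.integer(jitter),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# Place `lengths` non-overlapping intervals uniformly on the genome,
# avoiding `occupied` (plus a safety margin) and each other. Rejection
# sampling on plain vectors (cheap at fixture scale); errors when the
# genome is too crowded.
.place_intervals <- function(lengths, chrom_sizes, occupied = GRanges(),
                             margin = 0L, max_tries = 2000L) {
  chroms <- names(chrom_sizes)
  weights <- as.numeric(chrom_sizes) / sum(as.numeric(chrom_sizes))
  occ <- lapply(chroms, function(ch) {
    g <- occupied[as.character(seqnames(occupied)) == ch]
    list(start = start(g), end = end(g))
  })
  names(occ) <- chroms
  out_chrom <- character(length(lengths))
  out_start <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1L, prob = weights)
      lim <- chrom_sizes[[ch]] - len + 1L
      if (lim < 1L) next
      st <- sample.int(lim, 1L)
      p1 <- max(1L, st - margin)
      p2 <- min(chrom_sizes[[ch]], st + len - 1L + margin)
      if (!any(p1 <= occ[[ch]]$end & p2 >= occ[[ch]]$start)) {
        occ[[ch]]$start <- c(occ[[ch]]$start, st)
        occ[[ch]]$end <- c(occ[[ch]]$end, st + len - 1L)
        out_chrom[i] <- ch
        out_start[i] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("infeasible packing: could not place an interval of length ", len,
           "; reduce counts or enlarge the genome", call. = FALSE)
  }
  GRanges(out_chrom, IRanges(out_start, width = lengths))
}

# Random order-2 transition matrix (16 x 4), moderately non-uniform.
.random_bg_chain <- function(concentration = 8) {
  g <- matrix(stats::rgamma(16L * 4L, shape = concentration), nrow = 16L)
  g / rowSums(g)
}

# Emission-odds boost table over all k-mers: boost[kmer] = strength for the
# enrichment k-mers, 1 elsewhere.
.boost_table <- function(kmers, k, strength) {
  boost <- rep(1, 4L^k)
  idx <- vapply(kmers, function(s) {
    codes <- .encode_dna(s)
    sum(codes * 4^((k - 1):0)) + 1
  }, 1.0)
  boost[idx] <- strength
  boost
}

.codes_to_string <- function(codes) {
  paste(.BASES[codes + 1L], collapse = "")
}

#' Generate a synthetic genome with planted CRMs
#'
#' Background sequence is drawn from a random order-2 Markov chain. Each
#' planted CRM is emitted from the same chain but with the emission odds of
#' bases completing one of its class's enrichment k-mers multiplied by
#' `enrichment_strength` (at strength 1 planted CRMs are statistically
#' indistinguishable from background). Exons are placed uniformly avoiding
#' planted CRMs; the database is a noisy view of the planted CRMs
#' (subsampled at `db_annotation_rate`, coordinates jittered, terms kept at
#' `db_term_rate`) plus decoys on plain background; the per-class training
#' set is a random subset of that class's planted CRMs. Fully deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [fixture_config()].
#' @return A list of class `crm_fixture`: `genome` (`DNAStringSet`),
#'   `planted` (`GRanges` with `name`, `class`, `terms`), `training_sets`
#'   (named list of `GRanges`), `database` (`GRanges` with `name`, `terms`),
#'   `exons` (`GRanges`), `class_terms` (chr vector), `bg_chain`,
#'   `class_kmers`, and `config`.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  local_seed(cfg$seed, {
    # --- layout -----------------------------------------------------------
    chrom_len <- rep(cfg$genome_length %/% cfg$n_chroms, cfg$n_chroms)
    chrom_len[1L] <- chrom_len[1L] + cfg$genome_length %% cfg$n_chroms
    chrom_sizes <- setNames(as.integer(chrom_len),
                            sprintf("chr%d", seq_len(cfg$n_chroms)))
    bg_chain <- .random_bg_chain()
    k <- cfg$kmer_length
    all_kmers <- .all_kmers(k)
    kmer_pick <- sample(all_kmers, cfg$n_classes * cfg$kmers_per_class)
    class_kmers <- split(kmer_pick,
                         rep(seq_len(cfg$n_classes), each = cfg$kmers_per_class))
    class_terms <- sprintf("class%d_pattern", seq_len(cfg$n_classes))

    n_crms <- cfg$n_classes * cfg$crms_per_class
    crm_len <- sample(seq(cfg$crm_length_range[1], cfg$crm_length_range[2]),
                      n_crms, replace = TRUE)
    # Margin keeps jittered database entries from bleeding into neighbours.
    planted <- .place_intervals(crm_len, chrom_sizes, margin = cfg$jitter + 10L)
    mcols(planted)$name <- sprintf("crm_%04d", seq_len(n_crms))
    cls <- rep(seq_len(cfg$n_classes), times = cfg$crms_per_class)[
      sample.int(n_crms)]
    mcols(planted)$class <- cls
    mcols(planted)$terms <- IRanges::CharacterList(
      as.list(class_terms[cls]))

    n_exons <- max(1L, round(cfg$exon_fraction * cfg$genome_length /
                               mean(cfg$exon_length_range)))
    exon_len <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                       n_exons, replace = TRUE)
    exons <- .place_intervals(exon_len, chrom_sizes, occupied = planted,
                              margin = 0L)
    exons <- sort_merge(exons)

    decoy_len <- sample(seq(cfg$crm_length_range[1], cfg$crm_length_range[2]),
                        cfg$decoy_count, replace = TRUE)
    decoys <- .place_intervals(decoy_len, chrom_sizes,
                               occupied = c(GRanges(seqnames(planted), ranges(planted)),
                                            exons),
                               margin = 0L)

    # --- sequence ---------------------------------------------------------
    genome_chr <- vapply(names(chrom_sizes), function(ch) {
      .codes_to_string(.sim_seq_cpp(chrom_sizes[[ch]], bg_chain, numeric(0), k))
    }, "")
    boosts <- lapply(class_kmers, .boost_table, k = k,
                     strength = cfg$enrichment_strength)
    for (i in seq_along(planted)) {
      crm_seq <- .codes_to_string(.sim_seq_cpp(width(planted)[i], bg_chain,
                                               boosts[[cls[i]]], k))
      ch <- as.character(seqnames(planted)[i])
      substr(genome_chr[[ch]], start(planted)[i], end(planted)[i]) <- crm_seq
    }
    genome <- Biostrings::DNAStringSet(genome_chr)
    names(genome) <- names(chrom_sizes)

    # --- noisy database ---------------------------------------------------
    in_db <- runif(n_crms) < cfg$db_annotation_rate
    db <- planted[in_db]
    if (length(db)) {
      j1 <- sample(seq(-cfg$jitter, cfg$jitter), length(db), replace = TRUE)
      j2 <- sample(seq(-cfg$jitter, cfg$jitter), length(db), replace = TRUE)
      ns <- pmax(1L, start(db) + j1)
      ne <- pmin(chrom_sizes[as.character(seqnames(db))], end(db) + j2)
      ne <- pmax(ne, ns + 50L)  # keep entries at least 50 bp
      ranges(db) <- IRanges(ns, ne)
      keep_terms <- runif(length(db)) < cfg$db_term_rate
      tl <- as.list(mcols(db)$terms)
      tl[!keep_terms] <- list(character(0))
      mcols(db)$terms <- IRanges::CharacterList(tl)
    }
    mcols(decoys)$name <- sprintf("decoy_%04d", seq_along(decoys))
    decoy_terms <- lapply(seq_along(decoys), function(i) {
      if (runif(1) < cfg$db_term_rate) sample(class_terms, 1L) else character(0)
    })
    mcols(decoys)$terms <- IRanges::CharacterList(decoy_terms)
    mcols(decoys)$class <- NA_integer_
    database <- c(db, decoys[, c("name", "class", "terms")])
    database <- database[order(as.character(seqnames(database)), start(database))]
    mcols(database)$class <- NULL

    training_sets <- lapply(seq_len(cfg$n_classes), function(cl) {
      pool <- which(cls == cl)
      sel <- sort(sample(pool, cfg$training_per_class))
      GRanges(seqnames(planted)[sel], ranges(planted)[sel],
              name = mcols(planted)$name[sel])
    })
    names(training_sets) <- sprintf("class%d", seq_len(cfg$n_classes))

    structure(list(genome = genome, planted = planted,
                   training_sets = training_sets, database = database,
                   exons = exons, class_terms = class_terms,
                   bg_chain = bg_chain, class_kmers = class_kmers,
                   config = cfg),
              class = "crm_fixture")
  })
}

#' @export
print.crm_fixture <- function(x, ...) {
  cat(sprintf("crm_fixture: %s bp over %d chromosome(s); %d planted CRMs in %d class(es); %d database entries; %d exons (seed %d)\n",
              format(sum(Biostrings::width(x$genome)), big.mark = ","),
              length(x$genome), length(x$planted), x$config$n_classes,
              length(x$database), length(x$exons), x$config$seed))
  invisible(x)
}

#' Random (control) training set matched on GC content
#'
#' Draws `n` non-exonic intervals with lengths sampled from `length_sample`,
#' accepting a candidate only when its GC fraction lies within
#' `gc_tolerance` of the genome-wide non-exonic GC fraction. Used as the
#' negative control against real training data.
#'
#' @param genome Named `DNAStringSet`.
#' @param exons `GRanges` of exons to avoid entirely.
#' @param n Number of intervals (default 30).
#' @param length_sample Vector of lengths (bp) sampled with replacement; the
#'   published control profile has median ~745 bp with quartiles 360/1200.
#' @param gc_tolerance Maximum absolute GC deviation (default 0.02);
#'   1 disables matching.
#' @param seed Optional integer seed.
#' @param max_tries Attempts per interval before giving up (default 10000).
#' @return A `GRanges` of `n` intervals.
#' @export
generate_random_training_set <- function(genome, exons, n = 30L,
                                         length_sample,
                                         gc_tolerance = 0.02, seed = NULL,
                                         max_tries = 10000L) {
  if (!is.numeric(length_sample) || length(length_sample) == 0L)
    stop("`length_sample` must be a non-empty numeric vector", call. = FALSE)
  segs <- extract_noncoding(genome, exons)
  seqs <- mcols(segs)$seq
  gc_all <- sum(Biostrings::letterFrequency(seqs, "GC")) /
    sum(Biostrings::width(seqs))
  seg_chrom <- as.character(seqnames(segs))
  seg_start <- start(segs)
  seg_width <- width(segs)
  local_seed(seed, {
    out_chrom <- character(n); out_start <- integer(n); out_len <- integer(n)
    for (i in seq_len(n)) {
      len <- as.integer(sample(length_sample, 1L))
      slots <- pmax(0L, seg_width - len + 1L)
      if (sum(slots) == 0L)
        stop("no non-exonic segment can hold an interval of length ", len,
             call. = FALSE)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        g <- sample.int(length(segs), 1L, prob = slots / sum(slots))
        off <- sample.int(slots[g], 1L)
        cand <- Biostrings::subseq(seqs[[g]], off, off + len - 1L)
        gc <- sum(Biostrings::letterFrequency(Biostrings::DNAStringSet(cand), "GC")) / len
        if (abs(gc - gc_all) <= gc_tolerance) {
          out_chrom[i] <- seg_chrom[g]
          out_start[i] <- seg_start[g] + off - 1L
          out_len[i] <- len
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("could not satisfy GC tolerance %.3g after %d attempts",
                     gc_tolerance, max_tries), call. = FALSE)
    }
    GRanges(out_chrom, IRanges(out_start, width = out_len))
  })
}

#' Write a fixture to disk
#'
#' Emits `genome.fasta`, `exons.gff`, `database.tsv` (expression table),
#' `database.bed`, `training_<class>.bed`, `truth.bed` (planted CRMs with
#' class labels as names) and `manifest.txt` (training-set manifest).
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "crm_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fixture$genome, file.path(dir, "genome.fasta"))
  .write_exon_gff3(fixture$exons, file.path(dir, "exons.gff"))
  write_expression_table(fixture$database, file.path(dir, "database.tsv"))
  write_bed(fixture$database[, "name"], file.path(dir, "database.bed"))
  truth <- fixture$planted
  mcols(truth)$name <- sprintf("%s|class%d", mcols(truth)$name,
                               mcols(truth)$class)
  write_bed(truth[, "name"], file.path(dir, "truth.bed"))
  manifest <- character(0)
  for (nm in names(fixture$training_sets)) {
    f <- sprintf("training_%s.bed", nm)
    write_bed(fixture$training_sets[[nm]], file.path(dir, f))
    manifest <- c(manifest, paste(nm, f, sep = "\t"))
  }
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
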