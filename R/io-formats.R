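# Readers and writers for the genomics formats the pipeline touches.
#
# Coordinate convention: files use 0-based half-open coordinates (BED and
# bedGraph natively; GFF is converted from 1-based inclusive on read). In
# memory every interval is a GRanges, i.e. 1-based inclusive; the conversion
# happens here and nowhere else.

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are upper-cased and validated: duplicate headers, empty
#' sequences and characters outside `A,C,G,T,N` are errors. Record order is
#' preserved. Header lines are truncated at the first whitespace, as is
#' conventional for genome FASTA identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtN"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # Parse with the B-string reader (accepts any byte) so that alphabet
  # violations are reported here, naming the offending character.
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("failed to parse FASTA ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA header: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence for record: ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(x))
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop(sprintf("illegal character '%s' in sequence '%s' (alphabet is A,C,G,T,N)",
                   bad[1L], names(seqs)[i]), call. = FALSE)
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write a DNAStringSet to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names", call. = FALSE)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = width)
  invisible(path)
}

# Shared tab-format line reader: drops track/comment/blank lines, keeping
# original line numbers for error messages.
.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !(grepl("^track($|[[:space:]])", lines) | grepl("^#", lines) |
              !nzchar(trimws(lines)))
  list(lines = lines[keep], lineno = which(keep))
}

.parse_coord <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)) || any(v != floor(v)))
    stop(sprintf("non-integer %s coordinate at line %d", what,
                 lineno[which(is.na(v) | v != floor(v))[1L]]), call. = FALSE)
  as.integer(v)
}

#' Read a BED file as GRanges
#'
#' Accepts BED3 to BED6. Coordinates on disk are 0-based half-open and are
#' converted to the 1-based inclusive GRanges convention. Columns 4-6 are
#' mapped to `name`, `score` and strand when present. Lines starting with
#' `track` or `#` are skipped. A record with `start >= end` or a non-integer
#' coordinate is an error reported with its line number.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] with optional `name` and `score`
#'   metadata columns.
#' @export
read_bed <- function(path) {
  tl <- .read_tab_lines(path)
  if (length(tl$lines) == 0L) return(GRanges())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop(sprintf("fewer than 3 tab-separated columns at line %d",
                 tl$lineno[which(ncol < 3L)[1L]]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- .parse_coord(vapply(fields, `[[`, "", 2L), tl$lineno, "start")
  end0 <- .parse_coord(vapply(fields, `[[`, "", 3L), tl$lineno, "end")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("start >= end at line %d", tl$lineno[bad[1L]]), call. = FALSE)
  if (any(start0 < 0L))
    stop(sprintf("negative start at line %d", tl$lineno[which(start0 < 0L)[1L]]),
         call. = FALSE)
  strand <- rep("*", length(fields))
  has6 <- ncol >= 6L
  if (any(has6)) {
    s <- vapply(fields[has6], `[[`, "", 6L)
    s[!s %in% c("+", "-")] <- "*"
    strand[has6] <- s
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (any(ncol >= 4L)) {
    nm <- rep(NA_character_, length(fields))
    nm[ncol >= 4L] <- vapply(fields[ncol >= 4L], `[[`, "", 4L)
    mcols(gr)$name <- nm
  }
  if (any(ncol >= 5L)) {
    sc <- rep(NA_real_, length(fields))
    sc[ncol >= 5L] <- suppressWarnings(
      as.numeric(vapply(fields[ncol >= 5L], `[[`, "", 5L)))
    mcols(gr)$score <- sc
  }
  gr
}

#' Write GRanges to a BED file
#'
#' Writes BED3 when the input carries no metadata, otherwise BED6 using the
#' `name` and `score` metadata columns (missing values become `.` and `0`).
#' Coordinates are emitted 0-based half-open; `read_bed(write_bed(x))`
#' round-trips exactly. An empty input produces an empty file.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  gr <- .as_granges(gr)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  if (length(gr) == 0L) return(invisible(path))
  md <- mcols(gr)
  extended <- ("name" %in% names(md)) || ("score" %in% names(md)) ||
    any(as.character(strand(gr)) != "*")
  if (!extended) {
    lines <- sprintf("%s\t%d\t%d", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr))
  } else {
    nm <- if ("name" %in% names(md)) as.character(md$name) else rep(NA_character_, length(gr))
    nm[is.na(nm)] <- "."
    sc <- if ("score" %in% names(md)) md$score else rep(NA_real_, length(gr))
    scs <- sprintf("%.17g", sc)
    scs[is.na(sc)] <- "0"
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr), nm, scs, st)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a bin track as bedGraph
#'
#' One line per bin, in coordinate order; adjacent equal-valued bins are NOT
#' merged so the file is bit-stable with respect to the bin structure.
#'
#' @param track A bin track as returned by [sum_bins()]: a `GRanges` with a
#'   `value` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- .as_granges(track)
  if (!"value" %in% names(mcols(track)))
    stop("track must carry a `value` metadata column", call. = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  if (length(track) == 0L) return(invisible(path))
  o <- order(as.character(seqnames(track)), start(track))
  track <- track[o]
  writeLines(sprintf("%s\t%d\t%d\t%.17g", as.character(seqnames(track)),
                     start(track) - 1L, end(track), mcols(track)$value), con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @return A `GRanges` with a `value` metadata column.
#' @export
read_bedgraph <- function(path) {
  tl <- .read_tab_lines(path)
  if (length(tl$lines) == 0L) {
    gr <- GRanges()
    mcols(gr)$value <- numeric(0)
    return(gr)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L))
    stop(sprintf("bedGraph line without 4 columns at line %d",
                 tl$lineno[which(lengths(fields) != 4L)[1L]]), call. = FALSE)
  start0 <- .parse_coord(vapply(fields, `[[`, "", 2L), tl$lineno, "start")
  end0 <- .parse_coord(vapply(fields, `[[`, "", 3L), tl$lineno, "end")
  gr <- GRanges(vapply(fields, `[[`, "", 1L), IRanges(start0 + 1L, end0))
  mcols(gr)$value <- as.numeric(vapply(fields, `[[`, "", 4L))
  gr
}

#' Read exon intervals from a GFF3 file
#'
#' Returns all features whose type matches `feature_type` (default `"exon"`),
#' converted from the 1-based inclusive GFF convention to `GRanges`. This is
#' the single point where 1-based data enters the package.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type(s) to keep (column 3).
#' @return A `GRanges` of the selected features.
#' @export
read_gff_exons <- function(path, feature_type = "exon") {
  if (!file.exists(path)) stop("GFF file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[as.character(gr$type) %in% feature_type]
  gr <- GRanges(seqnames(gr), ranges(gr))
  names(gr) <- NULL
  gr
}

# Minimal exon-only GFF3 emitter, used for fixture and fragmented-genome
# output so read_gff_exons() can consume them. Not a general GFF writer.
.write_exon_gff3 <- function(exons, path, source = "crmbench") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(exons) == 0L) return(invisible(path))
  o <- order(as.character(seqnames(exons)), start(exons))
  exons <- exons[o]
  writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t+\t.\tID=exon%05d",
                     as.character(seqnames(exons)), source,
                     start(exons), end(exons), seq_along(exons)), con)
  invisible(path)
}

#' Read an expression-annotated CRM table
#'
#' The canonical dialect is a 5-column TSV — `chrom`, `start`, `end`, `name`,
#' `terms` — with 0-based half-open coordinates and `terms` a
#' semicolon-separated list of expression terms (possibly empty). Terms are
#' split, trimmed and de-duplicated. This emulates a database export in which
#' validated CRMs carry tissue/stage expression annotations.
#'
#' @param path Path to the TSV.
#' @param header Whether the first line is a header (auto-detected when the
#'   second column of the first line is non-numeric).
#' @return A `GRanges` with `name` (character) and `terms`
#'   ([IRanges::CharacterList]) metadata columns.
#' @export
read_expression_table <- function(path, header = NA) {
  tl <- .read_tab_lines(path)
  if (length(tl$lines) == 0L) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$terms <- IRanges::CharacterList()
    return(gr)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  # A trailing empty terms column is legal: pad 4-field splits to 5.
  fields <- lapply(fields, function(f) if (length(f) == 4L) c(f, "") else f)
  if (is.na(header)) {
    header <- is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))
  }
  if (header) {
    fields <- fields[-1L]
    tl$lineno <- tl$lineno[-1L]
  }
  if (length(fields) == 0L) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$terms <- IRanges::CharacterList()
    return(gr)
  }
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop(sprintf("expected 5 tab-separated columns (chrom,start,end,name,terms) at line %d, found %d",
                 tl$lineno[bad[1L]], lengths(fields)[bad[1L]]), call. = FALSE)
  start0 <- .parse_coord(vapply(fields, `[[`, "", 2L), tl$lineno, "start")
  end0 <- .parse_coord(vapply(fields, `[[`, "", 3L), tl$lineno, "end")
  if (any(start0 >= end0))
    stop(sprintf("start >= end at line %d", tl$lineno[which(start0 >= end0)[1L]]),
         call. = FALSE)
  terms <- lapply(vapply(fields, `[[`, "", 5L), function(s) {
    t <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    unique(t[nzchar(t)])
  })
  gr <- GRanges(vapply(fields, `[[`, "", 1L), IRanges(start0 + 1L, end0))
  mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  mcols(gr)$terms <- IRanges::CharacterList(terms)
  gr
}

#' Write an expression-annotated CRM table
#'
#' Inverse of [read_expression_table()]; writes the canonical 5-column TSV
#' with a header line.
#'
#' @param crms A `GRanges` with `name` and `terms` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(crms, path) {
  crms <- .as_granges(crms)
  nm <- if ("name" %in% names(mcols(crms))) as.character(mcols(crms)$name)
        else sprintf("crm%05d", seq_along(crms))
  terms <- if ("terms" %in% names(mcols(crms)))
    vapply(as.list(mcols(crms)$terms), paste, "", collapse = ";")
  else rep("", length(crms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tstart\tend\tname\tterms", con)
  if (length(crms))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", as.character(seqnames(crms)),
                       start(crms) - 1L, end(crms), nm, terms), con)
  invisible(path)
}

#' Read a training-set manifest
#'
#' A manifest is a plain-text file with one training set per line: a set name
#' and the path to its BED file, whitespace- or tab-separated. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path Path to the manifest.
#' @return A data.frame with columns `name` and `path`.
#' @export
read_training_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) != 2L))
    stop("each manifest line must be: <set-name> <bed-path>", call. = FALSE)
  name <- vapply(parts, `[[`, "", 1L)
  p <- vapply(parts, `[[`, "", 2L)
  abs <- grepl("^/", p)
  p[!abs] <- file.path(dirname(path), p[!abs])
  if (anyDuplicated(name))
    stop("duplicate training-set name in manifest", call. = FALSE)
  data.frame(name = name, path = p, stringsAsFactors = FALSE)
}
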