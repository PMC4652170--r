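#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Interval containers.  All coordinates are 0-based half-open (BED
# convention) throughout the package; GTF input is converted on read.
# ---------------------------------------------------------------------------

#' Construct a peak set
#'
#' A peak set is a collection of genomic intervals from one sample and one
#' mark (a histone modification or a transcription/epigenetic factor).
#' Intervals are stored 0-based half-open and kept sorted by chromosome and
#' start; overlapping or duplicate intervals are retained as given.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `score` and `strand`.
#' @param sample_id Non-empty sample identifier.
#' @param mark Non-empty mark or factor name.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(intervals, sample_id, mark) {
  assert_that(is.character(sample_id) && nzchar(sample_id),
              "sample_id must be a non-empty string")
  assert_that(is.character(mark) && nzchar(mark),
              "mark must be a non-empty string")
  if (nrow(intervals) > 0) {
    assert_that(all(nzchar(intervals$chrom)), "chrom must be non-empty")
    assert_that(all(intervals$start >= 0) && all(intervals$start < intervals$end),
                "intervals must satisfy 0 <= start < end")
  }
  if (is.null(intervals[["score"]]))
    intervals[["score"]] <- rep(NA_real_, nrow(intervals))
  if (is.null(intervals[["strand"]]))
    intervals[["strand"]] <- rep("*", nrow(intervals))
  intervals <- intervals[order(intervals$chrom, intervals$start, intervals$end),
                         c("chrom", "start", "end", "score", "strand"),
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(sample_id = sample_id, mark = mark, intervals = intervals),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %s / %s, %d interval(s)\n",
              x$sample_id, x$mark, nrow(x$intervals)))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$intervals)

# GRanges view of a 0-based half-open interval data.frame (1-based closed
# internally, widths preserved).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# ---------------------------------------------------------------------------
# TSS annotation and promoter windows
# ---------------------------------------------------------------------------

#' Read transcription start sites from a GENCODE-style GTF
#'
#' Parses `transcript` features and returns one TSS record per transcript:
#' the feature start for `+` strand transcripts and the feature end for `-`
#' strand transcripts, converted from the 1-based GTF convention to 0-based
#' coordinates.
#'
#' @param path Path to a GTF file (plain text; `#` comment lines skipped).
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `position` (0-based), `strand`.
#' @export
read_tss_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                 idx[which(nf != 9L)[1]], nf[nf != 9L][1]))
  feat <- vapply(fields, `[[`, "", 3L)
  tidx <- which(feat == "transcript")
  if (length(tidx) == 0)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), position = integer(),
                      strand = character()))
  get_attr <- function(attr, key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attr)
    out <- rep(NA_character_, length(attr))
    out[m != -1L] <- sub(pat, "\\1", regmatches(attr, m))
    out
  }
  attrs <- vapply(fields[tidx], `[[`, "", 9L)
  tx <- get_attr(attrs, "transcript_id")
  gene <- get_attr(attrs, "gene_id")
  if (anyNA(tx) || any(!nzchar(tx)))
    stop(sprintf("GTF record error at line %d: missing transcript_id",
                 idx[tidx][which(is.na(tx) | !nzchar(tx))[1]]))
  chrom <- vapply(fields[tidx], `[[`, "", 1L)
  start1 <- as.integer(vapply(fields[tidx], `[[`, "", 4L))
  end1 <- as.integer(vapply(fields[tidx], `[[`, "", 5L))
  strand <- vapply(fields[tidx], `[[`, "", 7L)
  assert_that(all(strand %in% c("+", "-")),
              "transcript strand must be + or -")
  pos <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
  data.frame(transcript_id = tx, gene_id = gene, chrom = chrom,
             position = as.integer(pos), strand = strand)
}

#' Strand-aware promoter windows around TSSs
#'
#' Builds the promoter window for each TSS: `upstream` bp 5' of the TSS and
#' `downstream` bp 3' of it (defaults -1000/+2000).  On the `-` strand the
#' window mirrors the `+` strand in transcript-relative coordinates:
#' `[position - downstream + 1, position + upstream + 1)`.  Starts are
#' clamped at 0 at chromosome edges.
#'
#' @param tss data.frame as returned by [read_tss_annotation()].
#' @param upstream,downstream Non-negative window extents in bp.
#' @return `tss` with added columns `start`, `end`, `upstream`, `downstream`.
#' @export
promoter_windows <- function(tss, upstream = 1000, downstream = 2000) {
  assert_that(upstream >= 0 && downstream >= 0,
              "upstream and downstream must be >= 0")
  assert_that(all(tss$strand %in% c("+", "-")), "strand must be + or -")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$position - upstream, tss$position - downstream + 1)
  end <- ifelse(plus, tss$position + downstream, tss$position + upstream + 1)
  out <- tss
  out$start <- as.integer(pmax(start, 0))
  out$end <- as.integer(end)
  out$upstream <- as.integer(upstream)
  out$downstream <- as.integer(downstream)
  out
}

# ---------------------------------------------------------------------------
# BED / bedGraph / TSV / FASTA I/O
# ---------------------------------------------------------------------------

#' Read a BED file into a peak set
#'
#' Accepts BED3+ (tab-separated).  Column 5, when present, is parsed as the
#' score and column 6 as the strand.  Records with `start >= end` are
#' rejected with a single warning; the number rejected is available as
#' `attr(x, "n_rejected")`.  `track`, `browser` and `#` lines are skipped.
#'
#' @param path Path to a BED file.
#' @param sample_id,mark Identifiers attached to the returned [peak_set()].
#' @return A `peak_set`.
#' @export
read_bed <- function(path, sample_id, mark) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    out <- peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer()), sample_id, mark)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(nf < 3L)[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  score <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 5L) f[[5]] else NA_character_, "")))
  strand <- vapply(fields, function(f)
    if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "*", "")
  bad <- start >= end | start < 0
  if (any(bad))
    warning(sprintf("%d BED record(s) with start >= end or start < 0 rejected",
                    sum(bad)))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   score = score, strand = strand)[!bad, , drop = FALSE]
  out <- peak_set(df, sample_id, mark)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a peak set to BED
#'
#' Writes BED3 when no scores/strands are present, BED6 otherwise (name
#' column `.`).  Re-reading the file reproduces the intervals exactly.
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- x$intervals
  if (all(is.na(df$score)) && all(df$strand == "*")) {
    out <- df[, c("chrom", "start", "end")]
  } else {
    out <- data.frame(df$chrom, df$start, df$end, ".",
                      ifelse(is.na(df$score), 0, df$score),
                      ifelse(df$strand == "*", ".", df$strand))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a 4-column bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  assert_that(all(df$start < df$end), "bedGraph intervals must have start < end")
  df
}

#' Read / write tab-separated tables
#'
#' Thin wrappers with the package's TSV conventions (header, no quoting).
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return `read_tsv` returns a data.frame; `write_tsv` returns `path`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' @param path FASTA file path.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return `read_genome_fasta` returns a `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Overlap engine
# ---------------------------------------------------------------------------

#' Test regions for overlap with a peak set
#'
#' A region overlaps when it shares at least 1 bp with some peak on the same
#' chromosome (half-open intersection non-empty); strand is ignored and no
#' minimum-fraction rule is applied.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [promoter_windows()].
#' @param peaks A [peak_set()].
#' @return Logical vector, one flag per region.
#' @export
overlaps_any <- function(regions, peaks) {
  if (nrow(peaks$intervals) == 0 || nrow(regions) == 0)
    return(rep(FALSE, nrow(regions)))
  # disjoint chromosome sets are a legitimate query, not a warning
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(regions),
                                 as_granges0(peaks$intervals))) > 0
}

# Hits between two 0-based interval data.frames, as (query, subject) index
# pairs.  Used by co-location and density code.
overlap_hits <- function(query, subject) {
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject)))
  data.frame(query = queryHits(h), subject = subjectHits(h))
}
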