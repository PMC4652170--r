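# Fixed k-mer occurrence statistics: containing fraction and positional
# density around TSSs.

check_motif <- function(motif) {
  assert_that(is.character(motif) && length(motif) == 1 && nchar(motif) >= 3,
              "motif must be a single string of length >= 3")
  assert_that(grepl("^[ACGT]+$", motif),
              "motif must contain only A, C, G, T")
  motif
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# occurrence counts of motif (and optionally its reverse complement) per
# sequence; overlapping occurrences allowed, N never matches
motif_counts <- function(sequences, motif, both_strands = TRUE) {
  seqs <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  n <- Biostrings::vcountPattern(motif, seqs)
  rc <- revcomp(motif)
  if (both_strands && rc != motif)
    n <- n + Biostrings::vcountPattern(rc, seqs)
  n
}

#' Fraction of sequences containing a motif
#'
#' Share of promoter sequences with at least one occurrence of the motif
#' or (by default) its reverse complement; overlapping occurrences count.
#'
#' @param sequences Character vector or `DNAStringSet` of promoter
#'   sequences.
#' @param motif DNA k-mer over A, C, G, T (length >= 3).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Fraction in \[0, 1\].
#' @export
motif_fraction <- function(sequences, motif, both_strands = TRUE) {
  check_motif(motif)
  mean(motif_counts(sequences, motif, both_strands) > 0)
}

#' Positional motif density around TSSs
#'
#' Extracts the strand-oriented `-span`..`+span` window around each TSS,
#' finds all occurrences of the motif (and, by default, its reverse
#' complement) that lie fully inside the window, assigns each occurrence
#' to the bin of its 5'-most base in transcript-relative coordinates, and
#' reports mean occurrences per promoter per bin.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tss TSS table.
#' @param motif DNA k-mer.
#' @param span Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 50).
#' @param both_strands Scan both strands (default TRUE).
#' @return A `motif_profile`: list with `motif`, `bin_size`, `span`,
#'   `density` (per-bin mean occurrences per promoter),
#'   `containing_fraction`, `per_promoter_counts`, `n_promoters`.
#' @export
motif_density_profile <- function(genome, tss, motif, span = 2000, bin = 50,
                                  both_strands = TRUE) {
  check_motif(motif)
  assert_that((2 * span) %% bin == 0, "bin must divide 2 * span")
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  n_bins <- as.integer(2 * span / bin)
  m <- nchar(motif)
  rc <- revcomp(motif)
  patterns <- if (both_strands && rc != motif) c(motif, rc) else motif
  density <- numeric(n_bins)
  counts <- setNames(integer(nrow(tss)), tss$transcript_id)
  for (i in seq_len(nrow(tss))) {
    chrom_seq <- genome[[tss$chrom[i]]]
    pos <- tss$position[i]
    g_start <- if (tss$strand[i] == "+") pos - span else pos - span + 1
    lo <- max(g_start, 0)
    hi <- min(g_start + 2 * span, length(chrom_seq))
    if (lo >= hi) next
    win <- Biostrings::subseq(chrom_seq, lo + 1, hi)
    if (tss$strand[i] == "-") win <- Biostrings::reverseComplement(win)
    # bp trimmed off the transcript's 5' side by chromosome-edge clamping
    shift <- if (tss$strand[i] == "+") lo - g_start else (g_start + 2 * span) - hi
    for (pat in patterns) {
      starts <- Biostrings::start(Biostrings::matchPattern(pat, win))
      # transcript-relative start offsets, 0-based within [0, 2*span)
      rel <- starts - 1L + shift
      rel <- rel[rel + m <= 2 * span]
      if (length(rel)) {
        density <- density + tabulate(rel %/% bin + 1L, nbins = n_bins)
        counts[i] <- counts[i] + length(rel)
      }
    }
  }
  structure(list(motif = motif, bin_size = bin, span = span,
                 density = density / nrow(tss),
                 containing_fraction = mean(counts > 0),
                 per_promoter_counts = counts, n_promoters = nrow(tss)),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif_profile: %s over +/-%d bp (%d-bp bins), %.1f%% of %d promoters contain it\n",
              x$motif, x$span, x$bin_size, 100 * x$containing_fraction,
              x$n_promoters))
  invisible(x)
}
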