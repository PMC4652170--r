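# CpG observed/expected ratios, TSS-centred CpG density profiles, and
# CpG-island overlap percentages per consensus class.

#' CpG observed/expected ratio of a sequence
#'
#' Gardiner-Garden & Frommer ratio: `(N_CpG * L) / (N_C * N_G)`, where
#' N_CpG counts CG dinucleotides and L is the full sequence length.
#' Returns 0 when the sequence contains no C or no G.  `N` bases never
#' match; input is case-insensitive.
#'
#' @param sequence Character vector of DNA sequences over A, C, G, T, N.
#' @return Numeric vector of ratios (>= 0).
#' @export
cpg_obs_exp_ratio <- function(sequence) {
  assert_that(is.character(sequence) && all(nchar(sequence) >= 1),
              "sequence must be non-empty")
  seqs <- Biostrings::DNAStringSet(toupper(sequence))
  n_cg <- Biostrings::vcountPattern("CG", seqs)
  freq <- Biostrings::letterFrequency(seqs, c("C", "G"))
  len <- Biostrings::width(seqs)
  denom <- freq[, "C"] * freq[, "G"]
  unname(ifelse(denom == 0, 0, n_cg * len / denom))
}

#' TSS-centred CpG obs/exp profiles
#'
#' For each TSS, extracts the window from `-span` to `+span` around the TSS
#' (strand-oriented: minus-strand windows are reverse-complemented so bin 1
#' is always the 5'-most), tiles it into `bin`-bp bins and computes the CpG
#' observed/expected ratio of each bin independently.  Bins falling off a
#' chromosome end get value 0 and are flagged in the `masked` matrix.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tss TSS table ([read_tss_annotation()]).
#' @param span Half-window in bp (default 5000).
#' @param bin Bin width in bp (default 100); must divide `2 * span`.
#' @return List with `values` and `masked` matrices
#'   (promoters x `2 * span / bin` bins) and `bin_size`, `span`.
#' @export
cpg_profiles <- function(genome, tss, span = 5000, bin = 100) {
  assert_that((2 * span) %% bin == 0, "bin must divide 2 * span")
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  n_bins <- as.integer(2 * span / bin)
  values <- matrix(0, nrow(tss), n_bins,
                   dimnames = list(tss$transcript_id, NULL))
  masked <- matrix(FALSE, nrow(tss), n_bins,
                   dimnames = list(tss$transcript_id, NULL))
  bin_views <- IRanges::successiveIRanges(rep(bin, n_bins))
  for (i in seq_len(nrow(tss))) {
    chrom_seq <- genome[[tss$chrom[i]]]
    clen <- length(chrom_seq)
    pos <- tss$position[i]
    g_start <- if (tss$strand[i] == "+") pos - span else pos - span + 1
    g_end <- g_start + 2 * span            # 0-based half-open window
    lo <- max(g_start, 0)
    hi <- min(g_end, clen)
    if (lo >= hi) { masked[i, ] <- TRUE; next }
    win <- paste0(strrep("N", lo - g_start),
                  as.character(Biostrings::subseq(chrom_seq, lo + 1, hi)),
                  strrep("N", g_end - hi))
    win <- Biostrings::DNAString(win)
    if (tss$strand[i] == "-") win <- Biostrings::reverseComplement(win)
    v <- Biostrings::Views(win, bin_views)
    freq <- Biostrings::letterFrequency(v, c("C", "G"))
    starts <- Biostrings::start(Biostrings::matchPattern("CG", win))
    # drop CG pairs straddling a bin boundary: they belong to neither bin
    starts <- starts[((starts - 1) %% bin) != (bin - 1)]
    n_cg <- tabulate((starts - 1) %/% bin + 1L, nbins = n_bins)
    denom <- freq[, "C"] * freq[, "G"]
    values[i, ] <- ifelse(denom == 0, 0, n_cg * bin / denom)
    # a bin is masked if any of its bases lies off the chromosome
    off_left <- lo - g_start
    off_right <- g_end - hi
    if (tss$strand[i] == "-") { tmp <- off_left; off_left <- off_right; off_right <- tmp }
    if (off_left > 0) masked[i, seq_len(ceiling(off_left / bin))] <- TRUE
    if (off_right > 0)
      masked[i, (n_bins - ceiling(off_right / bin) + 1):n_bins] <- TRUE
    values[i, masked[i, ]] <- 0
  }
  list(values = values, masked = masked, bin_size = bin, span = span)
}

#' Percentage of promoters overlapping a CpG island, per consensus class
#'
#' @param promoters Promoter windows.
#' @param classes data.frame with `promoter_id`, `class`
#'   ([consensus_classify()] output).
#' @param cgi A [peak_set()] of CpG-island intervals.
#' @return data.frame with `class`, `n`, `n_overlapping`, `pct` (NA for an
#'   empty class).
#' @export
cgi_overlap_by_class <- function(promoters, classes, cgi) {
  assert_that(all(promoters$transcript_id %in% classes$promoter_id),
              "every promoter needs a consensus class")
  cls <- classes$class[match(promoters$transcript_id, classes$promoter_id)]
  ov <- overlaps_any(promoters, cgi)
  do.call(rbind, lapply(HC_CLASSES, function(cl) {
    idx <- which(cls == cl)
    data.frame(class = cl, n = length(idx), n_overlapping = sum(ov[idx]),
               pct = if (length(idx) == 0) NA_real_ else
                 100 * sum(ov[idx]) / length(idx))
  }))
}
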