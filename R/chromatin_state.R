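# Per-sample promoter chromatin states and high-confidence consensus
# classes under the strict >70% agreement rule.

#' Call the chromatin state of a promoter in one sample
#'
#' A promoter carrying both marks is BIVALENT, H3K4me3 only is ACTIVE,
#' H3K27me3 only is REPRESSED, neither is LATENT.
#'
#' @param k4_overlap,k27_overlap Logical vectors: does an H3K4me3
#'   (H3K27me3) peak overlap the promoter window?
#' @return Character vector of states.
#' @export
call_sample_state <- function(k4_overlap, k27_overlap) {
  assert_that(length(k4_overlap) == length(k27_overlap),
              "k4_overlap and k27_overlap must have equal length")
  c("LATENT", "ACTIVE", "REPRESSED", "BIVALENT")[
    1L + as.integer(k4_overlap) + 2L * as.integer(k27_overlap)]
}

#' Build a promoters-by-samples state matrix
#'
#' @param promoters Promoter windows from [promoter_windows()]; row identity
#'   is `transcript_id`.
#' @param samples List of per-sample entries, each a list with `sample_id`
#'   and [peak_set()]s `k4` and `k27`.
#' @return A `state_matrix`: list with `states` (character matrix, promoters
#'   x samples), `promoter_ids`, `sample_ids`.
#' @export
build_state_matrix <- function(promoters, samples) {
  assert_that(length(samples) >= 1, "need at least one sample")
  states <- vapply(samples, function(s) {
    call_sample_state(overlaps_any(promoters, s$k4),
                      overlaps_any(promoters, s$k27))
  }, character(nrow(promoters)))
  states <- matrix(states, nrow = nrow(promoters))
  rownames(states) <- promoters$transcript_id
  colnames(states) <- vapply(samples, `[[`, "", "sample_id")
  structure(list(states = states,
                 promoter_ids = promoters$transcript_id,
                 sample_ids = colnames(states)),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("state_matrix: %d promoters x %d samples\n",
              length(x$promoter_ids), length(x$sample_ids)))
  invisible(x)
}

#' Minimum sample count for consensus under a strict fraction rule
#'
#' Smallest k with k/n strictly greater than `fraction`; with the default
#' 0.7 this gives 8 of 11 and 6 of 8 samples.
#'
#' @param n_samples Number of samples (>= 1).
#' @param fraction Agreement fraction, strictly between 0 and 1.
#' @return Integer threshold.
#' @export
consensus_threshold <- function(n_samples, fraction = 0.7) {
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  assert_that(is.numeric(fraction) && fraction > 0 && fraction < 1,
              "fraction must be in (0, 1)")
  # tolerance guards against binary representation of e.g. 0.7 * 10
  as.integer(floor(fraction * n_samples + 1e-9)) + 1L
}

#' Consensus chromatin classes from a state matrix
#'
#' A promoter is `HC_<STATE>` when that state occurs in strictly more than
#' `fraction` of the samples, and UNCLASSIFIED otherwise.  With
#' `fraction >= 0.5` at most one state can pass, so the class is unique.
#'
#' @param sm A `state_matrix` from [build_state_matrix()].
#' @param fraction Agreement fraction (default 0.7).
#' @return data.frame with `promoter_id`, `class`, and per-state counts
#'   `n_bivalent`, `n_active`, `n_repressed`, `n_latent`.
#' @export
consensus_classify <- function(sm, fraction = 0.7) {
  n <- length(sm$sample_ids)
  k <- consensus_threshold(n, fraction)
  counts <- vapply(SAMPLE_STATES, function(s) rowSums(sm$states == s),
                   numeric(length(sm$promoter_ids)))
  counts <- matrix(counts, ncol = length(SAMPLE_STATES),
                   dimnames = list(NULL, SAMPLE_STATES))
  hit <- counts >= k
  cls <- rep("UNCLASSIFIED", nrow(counts))
  for (s in SAMPLE_STATES) cls[hit[, s]] <- paste0("HC_", s)
  data.frame(promoter_id = sm$promoter_ids, class = cls,
             n_bivalent = counts[, "BIVALENT"], n_active = counts[, "ACTIVE"],
             n_repressed = counts[, "REPRESSED"], n_latent = counts[, "LATENT"])
}

#' Detection curve for one state
#'
#' Entry n of the curve is the number of promoters showing `state` in at
#' least n samples; the curve is non-increasing in n.
#'
#' @param sm A `state_matrix`.
#' @param state One of BIVALENT, ACTIVE, REPRESSED, LATENT.
#' @return Integer vector of length `n_samples`.
#' @export
detection_curve <- function(sm, state) {
  assert_that(state %in% SAMPLE_STATES, "unknown state")
  cnt <- rowSums(sm$states == state)
  vapply(seq_along(sm$sample_ids), function(n) sum(cnt >= n), integer(1))
}

#' Per-promoter signal score from overlapping peaks
#'
#' Sums the scores of peaks overlapping each promoter window.  When the
#' peak set carries no scores, the total number of overlapped bp is used
#' instead.
#'
#' @param promoters Promoter windows.
#' @param peaks A [peak_set()].
#' @return Named numeric vector (names are transcript ids).
#' @export
promoter_signal_scores <- function(promoters, peaks) {
  out <- setNames(numeric(nrow(promoters)), promoters$transcript_id)
  if (nrow(peaks$intervals) == 0) return(out)
  h <- overlap_hits(promoters, peaks$intervals)
  if (nrow(h) == 0) return(out)
  if (all(is.na(peaks$intervals$score))) {
    ov_bp <- pmin(promoters$end[h$query], peaks$intervals$end[h$subject]) -
      pmax(promoters$start[h$query], peaks$intervals$start[h$subject])
    agg <- tapply(ov_bp, h$query, sum)
  } else {
    agg <- tapply(peaks$intervals$score[h$subject], h$query, sum)
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Overlap of a sample's top-scoring promoters with a high-confidence set
#'
#' Takes the |hc_set| highest-scoring promoters in one sample (ties broken
#' by promoter id, ascending) and returns the fraction of the HC set they
#' cover.
#'
#' @param scores Named numeric vector of per-promoter scores for one sample.
#' @param hc_set Character vector of promoter ids (non-empty, all scored).
#' @return Fraction in \[0, 1\].
#' @export
top_signal_overlap <- function(scores, hc_set) {
  assert_that(length(hc_set) > 0, "hc_set must be non-empty")
  assert_that(length(hc_set) <= length(scores),
              "hc_set larger than the number of scored promoters")
  ord <- order(-scores, names(scores))
  top <- names(scores)[ord][seq_along(hc_set)]
  sum(hc_set %in% top) / length(hc_set)
}

#' Fraction of promoters where the two marks' peaks co-locate
#'
#' Among promoters carrying both marks in a sample pair, the fraction where
#' some H3K4me3 peak overlapping the window shares at least 1 bp with some
#' H3K27me3 peak overlapping the same window.
#'
#' @param k4_peaks,k27_peaks [peak_set()]s for the two marks of one sample.
#' @param promoters Promoter windows (all expected to carry both marks).
#' @return Fraction in \[0, 1\] (NaN for zero promoters).
#' @export
mark_colocation_fraction <- function(k4_peaks, k27_peaks, promoters) {
  if (nrow(promoters) == 0) return(NaN)
  h4 <- overlap_hits(promoters, k4_peaks$intervals)
  h27 <- overlap_hits(promoters, k27_peaks$intervals)
  cross <- overlap_hits(k4_peaks$intervals, k27_peaks$intervals)
  coloc <- logical(nrow(promoters))
  if (nrow(h4) && nrow(h27) && nrow(cross)) {
    # promoter -> peak index sets; co-located if some (k4, k27) hit pair
    # is also a cross-overlap pair
    key_cross <- paste(cross$query, cross$subject)
    pairs <- merge(h4, h27, by = "query", suffixes = c("_k4", "_k27"))
    ok <- paste(pairs$subject_k4, pairs$subject_k27) %in% key_cross
    coloc[unique(pairs$query[ok])] <- TRUE
  }
  mean(coloc)
}

#' Cross-sample QC summary of a state matrix
#'
#' Counts each state per sample and summarises the counts across samples
#' (mean, sample SD, relative SD = 100 * SD / mean).  When per-sample read
#' depths are supplied, the Pearson correlation between counts and depth is
#' reported per state.
#'
#' @param sm A `state_matrix` (>= 2 samples).
#' @param read_depths Optional numeric vector aligned with the samples.
#' @return List with `counts` (state x sample matrix) and `summary`
#'   (data.frame: state, mean, sd, relative_sd_pct, depth_cor).  A state
#'   whose mean count is 0 gets `relative_sd_pct = NA`.
#' @export
sample_qc <- function(sm, read_depths = NULL) {
  assert_that(length(sm$sample_ids) >= 2, "need >= 2 samples for SD")
  if (!is.null(read_depths))
    assert_that(length(read_depths) == length(sm$sample_ids),
                "read_depths must align with samples")
  counts <- vapply(sm$sample_ids, function(s) {
    tab <- table(factor(sm$states[, s], levels = SAMPLE_STATES))
    as.integer(tab)
  }, integer(length(SAMPLE_STATES)))
  rownames(counts) <- SAMPLE_STATES
  summ <- do.call(rbind, lapply(SAMPLE_STATES, function(s) {
    x <- counts[s, ]
    m <- mean(x)
    sdv <- stats::sd(x)
    data.frame(state = s, mean = m, sd = sdv,
               relative_sd_pct = if (m == 0) NA_real_ else 100 * sdv / m,
               depth_cor = if (is.null(read_depths)) NA_real_ else
                 suppressWarnings(stats::cor(x, read_depths)))
  }))
  list(counts = counts, summary = summ)
}
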