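# Shared fixtures and independent brute-force oracles.  Oracles are kept
# deliberately naive (loops, enumeration, closed forms) and never call the
# implementation they check.

make_peaks <- function(chrom, start, end, score = NA_real_,
                       sample_id = "S01", mark = "H3K4me3") {
  peak_set(data.frame(chrom = chrom, start = start, end = end, score = score),
           sample_id, mark)
}

make_tss <- function(position, strand, chrom = "chr1",
                     id = sprintf("T%03d", seq_along(position))) {
  data.frame(transcript_id = id, gene_id = sub("^T", "G", id),
             chrom = chrom, position = as.integer(position), strand = strand)
}

make_state_matrix <- function(states, promoter_ids = NULL, sample_ids = NULL) {
  promoter_ids <- promoter_ids %||% sprintf("P%03d", seq_len(nrow(states)))
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(ncol(states)))
  dimnames(states) <- list(promoter_ids, sample_ids)
  structure(list(states = states, promoter_ids = promoter_ids,
                 sample_ids = sample_ids), class = "state_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_state_matrix <- function(n_prom, n_samp, seed) {
  set.seed(seed)
  make_state_matrix(matrix(sample(c("BIVALENT", "ACTIVE", "REPRESSED",
                                    "LATENT"), n_prom * n_samp, TRUE),
                           n_prom, n_samp))
}

# --- oracles ---------------------------------------------------------------

# all-pairs interval overlap scan
oracle_overlaps_any <- function(regions, peaks) {
  iv <- peaks$intervals
  vapply(seq_len(nrow(regions)), function(i) {
    any(iv$chrom == regions$chrom[i] &
          iv$start < regions$end[i] & iv$end > regions$start[i])
  }, logical(1))
}

# closed-form hypergeometric upper tail via binomial coefficients
oracle_hyper_upper <- function(x, K, n, N) {
  hi <- min(K, n)
  if (x > hi) return(0)
  sum(choose(K, x:hi) * choose(N - K, n - (x:hi))) / choose(N, n)
}

# per-promoter recount of state occurrences
oracle_detection_curve <- function(sm, state) {
  out <- integer(length(sm$sample_ids))
  for (n in seq_along(out)) {
    cnt <- 0
    for (i in seq_along(sm$promoter_ids)) {
      if (sum(sm$states[i, ] == state) >= n) cnt <- cnt + 1
    }
    out[n] <- cnt
  }
  out
}

# literal consensus recount
oracle_consensus <- function(sm, fraction = 0.7) {
  n <- length(sm$sample_ids)
  vapply(seq_along(sm$promoter_ids), function(i) {
    tab <- table(sm$states[i, ])
    top <- names(tab)[which.max(tab)]
    if (max(tab) / n > fraction) paste0("HC_", top) else "UNCLASSIFIED"
  }, character(1))
}

# pair-counting adjusted Rand index (quadratic scan over item pairs)
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- (2 * s11 + s10 + s01) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# --- planted-archetype density matrices ------------------------------------

# four TSS-profile archetypes (sharp peak, upstream shoulder, downstream
# shoulder, flat) with i.i.d. noise; returns matrices plus true labels
make_archetype_matrices <- function(n_per_cluster = 50, n_bins = 100,
                                    noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  third <- n_bins %/% 3
  arch <- rbind(
    c(rep(0, third), rep(1, n_bins - 2 * third), rep(0, third)),
    c(rep(1, third), rep(0, n_bins - third)),
    c(rep(0, n_bins - third), rep(1, third)),
    rep(0.15, n_bins))
  labels <- rep(1:4, each = n_per_cluster)
  vals <- arch[labels, ] + matrix(rnorm(4 * n_per_cluster * n_bins, 0, noise_sd),
                                  4 * n_per_cluster)
  vals[vals < 0] <- 0
  rownames(vals) <- sprintf("P%04d", seq_len(nrow(vals)))
  dm <- structure(list(values = vals, factor = "toy", bin_size = 100,
                       span = n_bins * 50, library_size = 1e6,
                       mode = "fragments"), class = "density_matrix")
  list(matrix = dm, labels = labels)
}

random_dna_string <- function(L, letters = c("A", "C", "G", "T"),
                              prob = rep(0.25, 4)) {
  paste(sample(letters, L, replace = TRUE, prob = prob), collapse = "")
}
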