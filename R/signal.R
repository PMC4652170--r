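# TSS-centred read-density matrices, k-means clustering of bivalent
# promoters, and per-promoter mark density comparisons.

# Genomic bin coordinates around each TSS, strand-oriented: row-major list
# of (start, end) with bin 1 always 5'-most on the transcript.
tss_bins <- function(tss, span, bin) {
  n_bins <- as.integer(2 * span / bin)
  starts <- lapply(seq_len(nrow(tss)), function(i) {
    pos <- tss$position[i]
    g_start <- if (tss$strand[i] == "+") pos - span else pos - span + 1
    g_start + bin * (seq_len(n_bins) - 1L)
  })
  df <- data.frame(chrom = rep(tss$chrom, each = n_bins),
                   start = unlist(starts))
  df$end <- df$start + bin
  list(bins = df, n_bins = n_bins)
}

#' TSS-centred normalized read-density matrix
#'
#' Bins the `-span`..`+span` window around each TSS into `bin`-bp bins and
#' fills each cell with either the number of fragments overlapping the bin,
#' scaled to reads per million (`fragments` mode; a fragment spanning two
#' bins counts in both), or the coverage-weighted mean bedGraph value
#' (`coverage` mode).  Minus-strand rows are reversed so bin 1 is always
#' 5'-most.
#'
#' @param fragments A [peak_set()] of fragment intervals, or a bedGraph
#'   data.frame from [read_bedgraph()].
#' @param tss TSS table.
#' @param span,bin Window half-width and bin size in bp.
#' @param library_size Total fragment count used for per-million scaling;
#'   defaults to the number of fragment intervals.  Must be > 0.
#' @param factor Label stored on the matrix (e.g. the mark name).
#' @return A `density_matrix`: list with `values` (promoters x bins),
#'   `factor`, `bin_size`, `span`, `library_size`, `mode`.
#' @export
binned_density <- function(fragments, tss, span = 5000, bin = 100,
                           library_size = NULL, factor = "signal") {
  assert_that((2 * span) %% bin == 0, "bin must divide 2 * span")
  tb <- tss_bins(tss, span, bin)
  n_bins <- tb$n_bins
  if (inherits(fragments, "peak_set")) {
    library_size <- library_size %||% nrow(fragments$intervals)
    assert_that(library_size > 0, "library_size must be > 0")
    cnt <- suppressWarnings(
      GenomicRanges::countOverlaps(as_granges0(tb$bins),
                                   as_granges0(fragments$intervals)))
    values <- matrix(cnt * 1e6 / library_size, nrow = nrow(tss),
                     ncol = n_bins, byrow = TRUE)
    mode <- "fragments"
  } else {
    h <- overlap_hits(tb$bins, fragments)
    acc <- numeric(nrow(tb$bins))
    if (nrow(h)) {
      w <- pmin(tb$bins$end[h$query], fragments$end[h$subject]) -
        pmax(tb$bins$start[h$query], fragments$start[h$subject])
      contrib <- tapply(w * fragments$value[h$subject], h$query, sum)
      acc[as.integer(names(contrib))] <- as.numeric(contrib)
    }
    values <- matrix(acc / bin, nrow = nrow(tss), ncol = n_bins, byrow = TRUE)
    library_size <- library_size %||% NA_real_
    mode <- "coverage"
  }
  minus <- tss$strand == "-"
  values[minus, ] <- values[minus, n_bins:1, drop = FALSE]
  rownames(values) <- tss$transcript_id
  structure(list(values = values, factor = factor, bin_size = bin,
                 span = span, library_size = library_size, mode = mode),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf("density_matrix: %s, %d promoters x %d bins (%s mode)\n",
              x$factor, nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Cluster promoters on concatenated density matrices
#'
#' Each factor's matrix is scaled to unit maximum, the matrices are
#' concatenated per promoter, and the rows are clustered with k-means
#' (fixed seed, `nstart` restarts, minimum-inertia solution).  Cluster
#' labels are renumbered by descending mean of the first factor's block so
#' the output labelling is deterministic across equal-quality solutions.
#'
#' @param matrices List of `density_matrix` objects over the same promoters
#'   in the same order.
#' @param k Number of clusters (default 4).
#' @param seed RNG seed for initialisation.
#' @param nstart Number of k-means restarts (>= 10 recommended).
#' @return A `cluster_assignment`: list with `labels` (named integer
#'   vector), `k`, `seed`, `inertia`, `centers`.
#' @export
cluster_promoters <- function(matrices, k = 4, seed = 17, nstart = 10) {
  assert_that(length(matrices) >= 1, "need at least one density matrix")
  ids <- rownames(matrices[[1]]$values)
  for (m in matrices)
    assert_that(identical(rownames(m$values), ids),
                "matrices must cover the same promoters in the same order")
  assert_that(k <= length(ids), "k must not exceed the number of promoters")
  scaled <- lapply(matrices, function(m) {
    mx <- max(m$values)
    if (mx > 0) m$values / mx else m$values
  })
  x <- do.call(cbind, scaled)
  fit <- with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart,
                                       iter.max = 100))
  # renumber by descending cluster mean over the first factor's bins
  first_cols <- seq_len(ncol(scaled[[1]]))
  level <- vapply(seq_len(k), function(cl)
    mean(x[fit$cluster == cl, first_cols, drop = FALSE]), numeric(1))
  remap <- integer(k)
  remap[order(-level)] <- seq_len(k)
  labels <- setNames(remap[fit$cluster], ids)
  structure(list(labels = labels, k = k, seed = seed,
                 inertia = fit$tot.withinss,
                 centers = fit$centers[order(-level), , drop = FALSE]),
            class = "cluster_assignment")
}

#' Per-cluster mean density profiles
#'
#' @param assignment A `cluster_assignment` from [cluster_promoters()].
#' @param matrix A `density_matrix` over the clustered promoters.
#' @return Matrix k x bins of mean member profiles; empty clusters get a
#'   zero row and are listed in `attr(, "empty_clusters")`.
#' @export
cluster_mean_profiles <- function(assignment, matrix) {
  ids <- rownames(matrix$values)
  assert_that(all(ids %in% names(assignment$labels)),
              "assignment must cover all matrix promoters")
  lab <- assignment$labels[ids]
  out <- base::matrix(0, assignment$k, ncol(matrix$values))
  empty <- integer(0)
  for (cl in seq_len(assignment$k)) {
    rows <- which(lab == cl)
    if (length(rows) == 0) empty <- c(empty, cl)
    else out[cl, ] <- colMeans(matrix$values[rows, , drop = FALSE])
  }
  attr(out, "empty_clusters") <- empty
  out
}

#' Per-promoter mark density
#'
#' Fragments overlapping the promoter window, scaled to reads per million.
#'
#' @param fragments A [peak_set()] of fragment intervals.
#' @param promoters Promoter windows.
#' @param library_size Defaults to the fragment count; must be > 0.
#' @return Named numeric vector.
#' @export
promoter_mark_density <- function(fragments, promoters, library_size = NULL) {
  library_size <- library_size %||% nrow(fragments$intervals)
  assert_that(library_size > 0, "library_size must be > 0")
  cnt <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(promoters),
                                 as_granges0(fragments$intervals)))
  setNames(cnt * 1e6 / library_size, promoters$transcript_id)
}

#' Compare a numeric signal between promoter groups
#'
#' Two-sided Student's t test for two groups, or Kruskal-Wallis rank test
#' for two or more.
#'
#' @param values Numeric vector.
#' @param labels Group labels aligned with `values`.
#' @param test `"t"` or `"kruskal"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
group_compare <- function(values, labels, test = c("t", "kruskal")) {
  test <- match.arg(test)
  labels <- as.factor(as.character(labels))
  tab <- table(labels)
  assert_that(length(tab) >= 2, "need >= 2 groups")
  assert_that(all(tab >= 2), "every group needs >= 2 values")
  if (test == "t") {
    assert_that(length(tab) == 2, "t test requires exactly 2 groups")
    fit <- stats::t.test(values ~ labels)
  } else {
    fit <- stats::kruskal.test(values, labels)
  }
  list(statistic = unname(fit$statistic), p_value = fit$p.value, test = test)
}
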