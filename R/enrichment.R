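# Hypergeometric overlap statistics, TF density, and expression analyses
# by consensus class.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for X ~ Hypergeometric(N, K, n): drawing `n` items without
#' replacement from a universe of `N` containing `K` marked items.
#' Computed in log space via [stats::phyper()].
#'
#' @param x Observed overlap (>= 0).
#' @param K Marked-category size.
#' @param n Draw (set) size.
#' @param N Universe size.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(x, K, n, N) {
  assert_that(all(c(x, K, n, N) >= 0), "sizes must be non-negative")
  assert_that(K <= N && n <= N, "K and n must not exceed N")
  assert_that(x <= min(K, n), "x must not exceed min(K, n)")
  exp(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Factor-binding enrichment in a promoter class
#'
#' A promoter is "bound" by a factor when at least one of the factor's
#' peaks overlaps its window.  Enrichment of bound promoters in the class
#' is tested with the one-sided (upper tail) hypergeometric test.
#'
#' @param factor_peaks Named list of [peak_set()]s, one per factor.
#' @param class_ids Character vector of promoter ids forming the class.
#' @param universe Promoter windows for the whole universe (must contain
#'   the class).
#' @return data.frame with `factor`, `N`, `K`, `n_bound`, `overlap`,
#'   `p_value`, sorted by `p_value`.
#' @export
factor_enrichment <- function(factor_peaks, class_ids, universe) {
  assert_that(nrow(universe) > 0, "universe must be non-empty")
  assert_that(all(class_ids %in% universe$transcript_id),
              "class must be a subset of the universe")
  N <- nrow(universe)
  K <- length(class_ids)
  in_class <- universe$transcript_id %in% class_ids
  res <- do.call(rbind, lapply(names(factor_peaks), function(f) {
    bound <- overlaps_any(universe, factor_peaks[[f]])
    x <- sum(bound & in_class)
    data.frame(factor = f, N = N, K = K, n_bound = sum(bound), overlap = x,
               p_value = hypergeom_upper_tail(x, K, sum(bound), N))
  }))
  res[order(res$p_value), ]
}

#' Transcription-factor density per promoter
#'
#' Number of distinct factors with at least one peak overlapping each
#' promoter window; multiple peaks of one factor count once.
#'
#' @param promoters Promoter windows.
#' @param factor_peaks Named list of [peak_set()]s (>= 1).
#' @return Named integer vector.
#' @export
tf_density <- function(promoters, factor_peaks) {
  assert_that(length(factor_peaks) >= 1, "need at least one factor")
  bound <- vapply(factor_peaks, function(p) overlaps_any(promoters, p),
                  logical(nrow(promoters)))
  bound <- matrix(bound, nrow = nrow(promoters))
  setNames(as.integer(rowSums(bound)), promoters$transcript_id)
}

#' Summarise TF density by consensus class
#'
#' @param density Named vector from [tf_density()].
#' @param classes data.frame with `promoter_id`, `class`.
#' @return List with per-class `summary` (n, mean, median) and the
#'   Kruskal-Wallis `p_value` across classes.
#' @export
tf_density_by_class <- function(density, classes) {
  cls <- classes$class[match(names(density), classes$promoter_id)]
  keep <- !is.na(cls)
  summ <- do.call(rbind, lapply(unique(cls[keep]), function(cl) {
    v <- density[keep][cls[keep] == cl]
    data.frame(class = cl, n = length(v), mean = mean(v),
               median = stats::median(v))
  }))
  kw <- stats::kruskal.test(density[keep], as.factor(cls[keep]))
  list(summary = summ, p_value = kw$p.value)
}

#' Fraction of perturbation gene lists significantly overlapping a class
#'
#' Each differentially-expressed gene list is tested for upper-tail
#' hypergeometric overlap with the class genes inside the universe; the
#' share of lists with `p < alpha` is returned.  Empty lists are skipped
#' with a warning.
#'
#' @param de_gene_lists Named list of character gene-id vectors.
#' @param class_genes Character vector of class gene ids.
#' @param universe Character vector of all gene ids.
#' @param alpha Significance level (default 1e-3).
#' @return List with per-list `results` data.frame and
#'   `fraction_significant`.
#' @export
perturbation_overlap <- function(de_gene_lists, class_genes, universe,
                                 alpha = 1e-3) {
  class_genes <- intersect(class_genes, universe)
  N <- length(universe)
  K <- length(class_genes)
  rows <- lapply(names(de_gene_lists), function(nm) {
    genes <- intersect(de_gene_lists[[nm]], universe)
    if (length(genes) == 0) {
      warning(sprintf("DE list '%s' empty after universe restriction; skipped",
                      nm))
      return(NULL)
    }
    x <- length(intersect(genes, class_genes))
    data.frame(list = nm, n = length(genes), overlap = x,
               p_value = hypergeom_upper_tail(x, K, length(genes), N))
  })
  results <- do.call(rbind, rows)
  list(results = results,
       fraction_significant = mean(results$p_value < alpha))
}

#' Expression summaries per consensus class
#'
#' Median and quartiles of expression (e.g. FPKM) per class plus an
#' omnibus Kruskal-Wallis rank test across classes.
#'
#' @param expression data.frame with `gene_id`, `fpkm`.
#' @param classes data.frame with `gene_id`, `class`.
#' @return List with `summary` (class, n, median, q25, q75) and `p_value`.
#'   Classes absent from the table are reported with n = 0.
#' @export
expression_by_class <- function(expression, classes) {
  cls <- classes$class[match(expression$gene_id, classes$gene_id)]
  keep <- !is.na(cls)
  tab <- table(cls[keep])
  assert_that(sum(tab >= 2) >= 2, "need >= 2 classes with >= 2 genes")
  summ <- do.call(rbind, lapply(unique(classes$class), function(cl) {
    v <- expression$fpkm[keep][cls[keep] == cl]
    data.frame(class = cl, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
  }))
  kw <- stats::kruskal.test(expression$fpkm[keep], as.factor(cls[keep]))
  list(summary = summ, statistic = unname(kw$statistic), p_value = kw$p.value)
}

#' Fraction of single cells not expressing each gene
#'
#' For genes that are lowly expressed in bulk (FPKM below `threshold`,
#' when a bulk table is supplied), the per-gene fraction of cells with
#' exactly zero expression.
#'
#' @param sc Numeric matrix, genes (rows, named) x cells.
#' @param genes Character vector of gene ids to evaluate.
#' @param bulk Optional data.frame with `gene_id`, `fpkm` used to restrict
#'   `genes` to those with bulk FPKM < `threshold`.
#' @param threshold Bulk low-expression cutoff on the FPKM scale
#'   (default 4).
#' @return Named numeric vector of fractions in \[0, 1\]; genes absent
#'   from the matrix are skipped with a warning.
#' @export
nonexpressing_fraction <- function(sc, genes, bulk = NULL, threshold = 4) {
  if (!is.null(bulk)) {
    low <- bulk$gene_id[bulk$fpkm < threshold]
    genes <- intersect(genes, low)
  }
  missing <- setdiff(genes, rownames(sc))
  if (length(missing))
    warning(sprintf("%d gene(s) absent from the single-cell matrix; skipped",
                    length(missing)))
  genes <- setdiff(genes, missing)
  vapply(genes, function(g) mean(sc[g, ] == 0), numeric(1))
}
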