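# Cross-species comparison of consensus chromatin classes over one-to-one
# ortholog pairs.

default_divergence_spec <- function() {
  list(I   = c("HC_BIVALENT", "HC_BIVALENT"),
       II  = c("HC_ACTIVE", "HC_ACTIVE"),
       III = c("HC_LATENT", "HC_LATENT"),
       IV  = c("HC_BIVALENT", "HC_ACTIVE"),
       V   = c("HC_ACTIVE", "HC_BIVALENT"))
}

check_pairs <- function(pairs) {
  assert_that(all(c("gene_a", "gene_b") %in% names(pairs)),
              "pairs needs columns gene_a, gene_b")
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("ortholog pairs must be one-to-one: duplicated gene id found")
  pairs
}

# join class labels onto pairs; drops pairs where either side is missing
# from its class table
paired_classes <- function(classes_a, classes_b, pairs) {
  check_pairs(pairs)
  ca <- as_hc_class(classes_a$class[match(pairs$gene_a, classes_a$gene_id)])
  cb <- as_hc_class(classes_b$class[match(pairs$gene_b, classes_b$gene_id)])
  keep <- !is.na(ca) & !is.na(cb)
  data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
             class_a = ca[keep], class_b = cb[keep])
}

#' Cross-species chromatin-state overlap matrix
#'
#' Counts of (class in species A, class in species B) over one-to-one
#' ortholog pairs, with row-normalized percentages in both directions.
#' Pairs where either gene lacks a class are dropped; the grand total of
#' the count matrix equals the number of fully classified pairs.
#'
#' @param classes_a,classes_b data.frames with `gene_id`, `class` (HC
#'   classes, or plain state names which are promoted to HC form).
#' @param pairs data.frame with `gene_a`, `gene_b`; one-to-one in both
#'   directions (duplicates are an error).
#' @return List with `counts_ab`, `pct_ab` (rows = species A classes),
#'   `counts_ba`, `pct_ba` (the transpose direction), and `n_pairs`.
#' @export
state_overlap <- function(classes_a, classes_b, pairs) {
  pc <- paired_classes(classes_a, classes_b, pairs)
  lv <- HC_CLASSES
  counts_ab <- table(factor(pc$class_a, lv), factor(pc$class_b, lv))
  counts_ab <- unclass(counts_ab)
  names(dimnames(counts_ab)) <- NULL
  row_pct <- function(m) {
    rs <- rowSums(m)
    p <- 100 * sweep(m, 1, pmax(rs, 1), "/")
    p[rs == 0, ] <- NA_real_
    p
  }
  counts_ba <- t(counts_ab)
  list(counts_ab = counts_ab, pct_ab = row_pct(counts_ab),
       counts_ba = counts_ba, pct_ba = row_pct(counts_ba),
       n_pairs = nrow(pc))
}

#' Conserved/divergent chromatin-state groups over orthologs
#'
#' Assigns each ortholog pair to a named group by its (species A class,
#' species B class) pattern.  The default groups are the conserved states
#' I (bivalent/bivalent), II (active/active), III (latent/latent) and the
#' divergent states IV (bivalent in A, active in B) and V (the mirror:
#' active in A, bivalent in B).  Pairs matching no pattern get `"other"`.
#'
#' @param classes_a,classes_b,pairs As in [state_overlap()].
#' @param group_spec Named list mapping group label to a length-2 character
#'   vector `c(class_a, class_b)`; duplicate patterns are an error.
#' @return data.frame with `gene_a`, `gene_b`, `class_a`, `class_b`,
#'   `group`.
#' @export
divergence_groups <- function(classes_a, classes_b, pairs,
                              group_spec = default_divergence_spec()) {
  pats <- vapply(group_spec, function(p) paste(as_hc_class(p), collapse = "|"),
                 character(1))
  if (anyDuplicated(pats))
    stop("group_spec contains overlapping patterns")
  pc <- paired_classes(classes_a, classes_b, pairs)
  key <- paste(pc$class_a, pc$class_b, sep = "|")
  idx <- match(key, pats)
  pc$group <- ifelse(is.na(idx), "other", names(group_spec)[idx])
  pc
}
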