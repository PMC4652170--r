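# End-to-end driver: simulate -> classify -> consensus -> CpG -> cluster
# -> enrichment -> cross-species -> motif on the default synthetic study.

#' Run the full synthetic study end to end
#'
#' Generates the default synthetic study (reference, `n_samples` ChIP
#' sample pairs, factors, expression, a conserved second species) and runs
#' every analysis stage on it: per-sample state calls and >70% consensus,
#' detection curves and QC, CGI overlap per class, read-density k-means
#' clustering of HC bivalent promoters, factor/perturbation enrichment and
#' TF density, expression by class, cross-species state overlap, and motif
#' fractions per class.
#'
#' @param seed Master seed driving every stochastic component.
#' @param n_promoters Number of promoters (default 2000).
#' @param n_samples Number of ChIP sample pairs (default 10).
#' @param n_factors Number of factor peak sets (default 20).
#' @param n_de_lists Number of perturbation gene lists (default 30).
#' @param fragment_samples Sample indices for which fragment files (and
#'   hence density matrices) are generated; keep small for speed.
#' @param cluster_k k for promoter clustering (default 4).
#' @param verbose Print stage progress.
#' @return A list with every intermediate and result object (see the
#'   elements `ref`, `chip`, `state_matrix`, `consensus`, `qc`,
#'   `detection`, `cgi_by_class`, `clusters`, `factor_enrichment`,
#'   `tf_density`, `expression`, `perturbation`, `cross_species`,
#'   `motif`).
#' @export
run_synthetic_study <- function(seed = 1, n_promoters = 2000, n_samples = 10,
                                n_factors = 20, n_de_lists = 30,
                                fragment_samples = 1, cluster_k = 4,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating reference (%d promoters)", n_promoters)
  ref <- simulate_reference(n_promoters = n_promoters, seed = seed)
  promoters <- promoter_windows(ref$tss)
  say("simulating %d ChIP sample pairs", n_samples)
  chip <- simulate_chip_samples(ref, n_samples = n_samples, fragments = TRUE,
                                fragment_samples = fragment_samples,
                                seed = sub_seed(seed, 11))
  say("classifying per-sample states and consensus")
  sm <- build_state_matrix(promoters, chip$samples)
  consensus <- consensus_classify(sm)
  qc <- sample_qc(sm, read_depths = vapply(chip$samples, `[[`, 0, "depth"))
  detection <- lapply(setNames(SAMPLE_STATES, SAMPLE_STATES),
                      function(s) detection_curve(sm, s))
  say("CpG-island overlap by class")
  cgi_by_class <- cgi_overlap_by_class(promoters, consensus, ref$cgi)
  say("density matrices + clustering of HC bivalent promoters")
  hc_biv <- consensus$promoter_id[consensus$class == "HC_BIVALENT"]
  s1 <- chip$samples[[fragment_samples[1]]]
  biv_tss <- ref$tss[ref$tss$transcript_id %in% hc_biv, , drop = FALSE]
  dm_k4 <- binned_density(s1$k4_fragments, biv_tss, factor = "H3K4me3")
  dm_k27 <- binned_density(s1$k27_fragments, biv_tss, factor = "H3K27me3")
  clusters <- cluster_promoters(list(dm_k27, dm_k4), k = cluster_k,
                                seed = sub_seed(seed, 12))
  say("mark-density comparison (bivalent vs repressed)")
  cls_map <- setNames(consensus$class, consensus$promoter_id)
  br <- promoters[cls_map[promoters$transcript_id] %in%
                    c("HC_BIVALENT", "HC_REPRESSED"), , drop = FALSE]
  k27_density <- promoter_mark_density(s1$k27_fragments, br)
  density_test <- group_compare(log10(k27_density + 1),
                                cls_map[br$transcript_id], test = "t")
  say("factor enrichment, TF density")
  factors <- simulate_factors(ref$truth, n_factors = n_factors,
                              seed = sub_seed(seed, 13))
  fe <- factor_enrichment(factors, hc_biv, promoters)
  tfd <- tf_density(promoters, factors)
  tfd_by_class <- tf_density_by_class(
    tfd, data.frame(promoter_id = consensus$promoter_id,
                    class = consensus$class))
  say("expression by class, single cells, perturbation overlap")
  expr <- simulate_expression(ref$truth, n_de_lists = n_de_lists,
                              seed = sub_seed(seed, 14))
  gene_classes <- data.frame(gene_id = ref$tss$gene_id,
                             class = cls_map[ref$tss$transcript_id])
  ebc <- expression_by_class(expr$bulk, gene_classes)
  biv_genes <- gene_classes$gene_id[gene_classes$class == "HC_BIVALENT"]
  pert <- perturbation_overlap(expr$de_lists, biv_genes,
                               gene_classes$gene_id)
  nonexpr <- nonexpressing_fraction(expr$sc, biv_genes, bulk = expr$bulk)
  say("cross-species comparison")
  orth <- simulate_orthologs(ref$truth, seed = sub_seed(seed, 15))
  classes_a <- data.frame(gene_id = gene_classes$gene_id,
                          class = gene_classes$class)
  classes_b <- data.frame(gene_id = orth$truth_b$gene_id,
                          class = as_hc_class(orth$truth_b$true_class))
  xsp <- state_overlap(classes_a, classes_b, orth$pairs)
  groups <- divergence_groups(classes_a, classes_b, orth$pairs)
  say("motif fractions per class")
  windows_by_class <- function(cl) {
    idx <- which(cls_map[promoters$transcript_id] == cl)
    extract_windows(ref$genome, promoters[idx, , drop = FALSE])
  }
  motif <- list(
    tcccc_bivalent = motif_fraction(windows_by_class("HC_BIVALENT"),
                                    ref$motif_bivalent),
    tcccc_active = motif_fraction(windows_by_class("HC_ACTIVE"),
                                  ref$motif_bivalent),
    cggaa_active = motif_fraction(windows_by_class("HC_ACTIVE"),
                                  ref$motif_active),
    cggaa_bivalent = motif_fraction(windows_by_class("HC_BIVALENT"),
                                    ref$motif_active))
  list(ref = ref, promoters = promoters, chip = chip, state_matrix = sm,
       consensus = consensus, qc = qc, detection = detection,
       cgi_by_class = cgi_by_class, clusters = clusters,
       density = list(k4 = dm_k4, k27 = dm_k27),
       density_test = density_test, factors = factors,
       factor_enrichment = fe,
       tf_density = list(values = tfd, by_class = tfd_by_class),
       expression = list(bulk = expr$bulk, by_class = ebc,
                         nonexpressing = nonexpr, de_lists = expr$de_lists),
       perturbation = pert,
       cross_species = list(overlap = xsp, groups = groups),
       motif = motif, seed = seed)
}

#' Extract strand-oriented promoter window sequences
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param promoters Promoter windows ([promoter_windows()]).
#' @return Character vector of sequences, 5'->3' on the transcript strand,
#'   named by transcript id.
#' @export
extract_windows <- function(genome, promoters) {
  out <- character(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    chrom_seq <- genome[[promoters$chrom[i]]]
    lo <- max(promoters$start[i], 0)
    hi <- min(promoters$end[i], length(chrom_seq))
    if (lo >= hi) { out[i] <- ""; next }
    s <- Biostrings::subseq(chrom_seq, lo + 1, hi)
    if (promoters$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  setNames(out, promoters$transcript_id)
}
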