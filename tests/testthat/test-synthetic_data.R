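# synthetic_data: determinism, planted structure, file round-trips

test_that("the generator is byte-deterministic under a master seed", {
  r1 <- simulate_reference(n_promoters = 60, seed = 5)
  r2 <- simulate_reference(n_promoters = 60, seed = 5)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$truth, r2$truth)
  c1 <- simulate_chip_samples(r1, n_samples = 3, seed = 6)
  c2 <- simulate_chip_samples(r2, n_samples = 3, seed = 6)
  expect_identical(c1$samples[[2]]$k27$intervals, c2$samples[[2]]$k27$intervals)
  o1 <- simulate_orthologs(r1$truth, seed = 7)
  o2 <- simulate_orthologs(r2$truth, seed = 7)
  expect_identical(o1$truth_b, o2$truth_b)
  # a different seed changes the genome
  r3 <- simulate_reference(n_promoters = 60, seed = 8)
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("class proportions are honoured; zero classes are absent", {
  cls <- simulate_truth_classes(500, c(BIVALENT = 0.5, ACTIVE = 0.5,
                                       REPRESSED = 0, LATENT = 0), seed = 9)
  expect_true(all(cls %in% c("BIVALENT", "ACTIVE")))
  ref <- simulate_reference(n_promoters = 40,
                            class_proportions = c(BIVALENT = 0.5,
                                                  ACTIVE = 0.3,
                                                  REPRESSED = 0,
                                                  LATENT = 0.2), seed = 9)
  expect_false(any(ref$truth$true_class == "REPRESSED"))
  expect_error(simulate_reference(n_promoters = 10, spacing = 8000),
               "config error")
  expect_error(simulate_truth_classes(10, c(BIVALENT = 0.5, ACTIVE = 0.2)),
               "sum to 1")
})

test_that("generated files parse back through genomic_io unchanged", {
  ref <- simulate_reference(n_promoters = 50, seed = 10)
  out <- tempfile()
  expect_no_warning(paths <- write_reference(ref, out))
  expect_no_warning(genome <- read_genome_fasta(paths["genome"]))
  expect_identical(as.character(genome), as.character(ref$genome))
  expect_no_warning(tss <- read_tss_annotation(paths["gtf"]))
  expect_equal(tss$position, ref$tss$position)
  expect_equal(tss$strand, ref$tss$strand)
  expect_equal(tss$transcript_id, ref$tss$transcript_id)
  expect_no_warning(cgi <- read_bed(paths["cgi"], "reference", "CGI"))
  expect_equal(cgi$intervals[, c("chrom", "start", "end")],
               ref$cgi$intervals[, c("chrom", "start", "end")])
  chip <- simulate_chip_samples(ref, n_samples = 2, seed = 10)
  bed <- tempfile(fileext = ".bed")
  write_bed(chip$samples[[1]]$k27, bed)
  expect_no_warning(back <- read_bed(bed, "S01", "H3K27me3"))
  expect_equal(back$intervals$start, chip$samples[[1]]$k27$intervals$start)
})

test_that("planted CpG structure separates classes", {
  ref <- simulate_reference(n_promoters = 150, seed = 11)
  prom <- promoter_windows(ref$tss)
  seqs <- extract_windows(ref$genome, prom)
  ratio <- cpg_obs_exp_ratio(seqs)
  rich <- ref$truth$cpg_rich
  expect_gt(mean(ratio[rich]), 0.6)       # CGI promoters are CpG rich
  expect_lt(mean(ratio[!rich]), 0.35)     # others carry suppressed CpG
  core <- extract_windows(ref$genome,
                          promoter_windows(ref$tss, upstream = 750,
                                           downstream = 750))
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(core[rich]), "GC", as.prob = TRUE)
  expect_gt(mean(gc), 0.5)
  # CGI intervals are recorded exactly for the CpG-rich promoters
  expect_equal(sum(rich), nrow(ref$cgi$intervals))
  expect_equal(unname(overlaps_any(prom, ref$cgi)), rich)
})

test_that("noiseless ChIP detection recovers the planted classes exactly", {
  ref <- simulate_reference(n_promoters = 120, seed = 12)
  chip <- simulate_chip_samples(ref, n_samples = 4, k4_detect_p = 1,
                                k27_detect_p = 1, false_positive_rate = 0,
                                seed = 13)
  sm <- build_state_matrix(promoter_windows(ref$tss), chip$samples)
  cons <- consensus_classify(sm)
  expect_equal(cons$class, paste0("HC_", ref$truth$true_class))
})

test_that("H3K27me3 detection varies across samples far more than H3K4me3", {
  ref <- simulate_reference(n_promoters = 400, seed = 14)
  chip <- simulate_chip_samples(ref, n_samples = 10, seed = 15)
  sm <- build_state_matrix(promoter_windows(ref$tss), chip$samples)
  # per-sample counts of K4-marked (ACTIVE+BIVALENT) and K27-marked
  # (REPRESSED+BIVALENT) promoters
  k4_marked <- colSums(sm$states == "ACTIVE" | sm$states == "BIVALENT")
  k27_marked <- colSums(sm$states == "REPRESSED" | sm$states == "BIVALENT")
  rel_sd <- function(x) 100 * sd(x) / mean(x)
  expect_lt(rel_sd(k4_marked), 10)
  expect_gt(rel_sd(k27_marked), 20)
})

test_that("factor simulation respects class odds", {
  ref <- simulate_reference(n_promoters = 300, seed = 16)
  factors <- simulate_factors(ref$truth, n_factors = 15, seed = 17)
  expect_length(factors, 15)
  d <- tf_density(promoter_windows(ref$tss), factors)
  mean_by <- tapply(d, ref$truth$true_class, mean)
  expect_gt(mean_by["ACTIVE"], mean_by["BIVALENT"])
  expect_gt(mean_by["BIVALENT"], mean_by["REPRESSED"])
  expect_length(simulate_factors(ref$truth, n_factors = 0), 0)
})

test_that("expression simulation plants ordering, dropout and DE bias", {
  ref <- simulate_reference(n_promoters = 400, seed = 18)
  expr <- simulate_expression(ref$truth, seed = 19)
  classes <- data.frame(gene_id = ref$truth$gene_id,
                        class = ref$truth$true_class)
  res <- expression_by_class(expr$bulk, classes)
  med <- setNames(res$summary$median, res$summary$class)
  expect_true(med["ACTIVE"] > med["BIVALENT"] &&
                med["BIVALENT"] > med["LATENT"])
  expect_lt(res$p_value, 1e-4)
  expect_equal(ncol(expr$sc), 63)
  # dropout 1.0 -> every cell zero
  expr2 <- simulate_expression(ref$truth, n_cells = 5,
                               dropout = c(ACTIVE = 1, BIVALENT = 1,
                                           REPRESSED = 1, LATENT = 1),
                               n_de_lists = 1, seed = 20)
  frac <- nonexpressing_fraction(expr2$sc, ref$truth$gene_id)
  expect_true(all(frac == 1))
  # DE lists enriched for bivalent genes
  biv <- classes$gene_id[classes$class == "BIVALENT"]
  po <- perturbation_overlap(expr$de_lists, biv, classes$gene_id)
  expect_gt(po$fraction_significant, 0.9)
})

test_that("ortholog conservation rates are planted per class", {
  truth <- data.frame(gene_id = sprintf("G%04d", 1:2000),
                      true_class = simulate_truth_classes(2000, seed = 21))
  orth <- simulate_orthologs(truth, conservation = c(BIVALENT = 1,
                                                     ACTIVE = 1,
                                                     REPRESSED = 1,
                                                     LATENT = 1), seed = 22)
  expect_identical(orth$truth_b$true_class, truth$true_class)
  ov <- state_overlap(
    data.frame(gene_id = truth$gene_id, class = truth$true_class),
    data.frame(gene_id = orth$truth_b$gene_id,
               class = orth$truth_b$true_class), orth$pairs)
  expect_true(all(ov$counts_ab[upper.tri(ov$counts_ab)] == 0) &&
                all(ov$counts_ab[lower.tri(ov$counts_ab)] == 0))
})
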