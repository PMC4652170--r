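# Deterministic synthetic-study generator with planted ground truth:
# genome + annotation + CGIs, multi-sample H3K4me3/H3K27me3 peak and
# fragment sets, factor-binding peaks, bulk/single-cell expression,
# perturbation gene lists, and a class-conserved second species.
#
# Seed discipline: every generator takes one seed and derives sub-seeds
# with sub_seed(seed, i), so the same master seed reproduces every file
# byte-for-byte.

# -- sequence building blocks ----------------------------------------------

# i.i.d. background at ~40% GC with CpG suppression (80% of CG pairs have
# the C deaminated to T), giving obs/exp ~ 0.2 as in bulk genomic DNA
bg_dna <- function(L) {
  x <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(x[-L] == "C" & x[-1] == "G")
  if (length(cg)) {
    hit <- cg[stats::runif(length(cg)) < 0.8]
    x[hit] <- "T"
  }
  x
}

# i.i.d. CpG-island shoulder: 60% GC, no suppression (obs/exp ~ 1)
core_dna <- function(L) {
  sample(c("A", "C", "G", "T"), L, replace = TRUE,
         prob = c(0.2, 0.3, 0.3, 0.2))
}

# CpG-boosted island centre: literal CG dinucleotides injected on top of a
# 60% GC background, pushing obs/exp well above 1
boost_dna <- function(L) {
  tokens <- sample(c("CG", "."), L, replace = TRUE, prob = c(0.25, 0.75))
  singles <- core_dna(sum(tokens == "."))
  tokens[tokens == "."] <- singles
  x <- strsplit(paste(tokens, collapse = ""), "")[[1]]
  x[seq_len(L)]
}

# Remove every occurrence of the given k-mers from a character-vector
# region by mutating the third base; iterated because a mutation can in
# principle create a new occurrence.
scrub_motifs <- function(chars, motifs) {
  s <- paste(chars, collapse = "")
  for (pass in 1:10) {
    found <- FALSE
    for (m in motifs) {
      idx <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (idx[1] != -1L) {
        found <- TRUE
        repl <- if (substr(m, 3, 3) == "T") "A" else "T"
        for (p in idx + 2L) substr(s, p, p) <- repl
      }
    }
    if (!found) break
  }
  strsplit(s, "")[[1]]
}

#' Draw planted promoter classes
#'
#' @param n Number of promoters.
#' @param proportions Named numeric vector over BIVALENT, ACTIVE,
#'   REPRESSED, LATENT summing to 1.
#' @param seed RNG seed.
#' @return Character vector of classes.
#' @export
simulate_truth_classes <- function(n,
                                   proportions = c(BIVALENT = 0.25,
                                                   ACTIVE = 0.35,
                                                   REPRESSED = 0.10,
                                                   LATENT = 0.30),
                                   seed = 1) {
  assert_that(abs(sum(proportions) - 1) < 1e-8, "proportions must sum to 1")
  assert_that(all(names(proportions) %in% SAMPLE_STATES),
              "proportions must be named by the four states")
  with_seed(seed,
            sample(names(proportions), n, replace = TRUE, prob = proportions))
}

#' Simulate a reference: genome, TSS annotation, CpG islands, ground truth
#'
#' Lays promoters on equally spaced loci (`spacing` bp apart, TSS at the
#' locus centre minus `span` headroom), builds a CpG-suppressed background
#' genome (~40% GC, obs/exp ~0.2), plants a 1.5-kb CpG-rich core (60% GC,
#' CpG-boosted 300-bp centre) at BIVALENT and ACTIVE promoters (recorded
#' in the CGI set), leaves REPRESSED and LATENT promoters CpG-poor, and
#' plants the bivalent motif (default `TCCCC`) in a share of bivalent
#' promoters and the active motif (default `CGGAA`) in a share of active
#' ones.  Both motifs (and reverse complements) are scrubbed from every
#' promoter neighbourhood first, so the containing fraction measures the
#' planting rate, not chance occurrence.
#'
#' @param n_promoters Number of promoters (default 2000).
#' @param class_proportions Passed to [simulate_truth_classes()].
#' @param classes Optional explicit class vector overriding the draw.
#' @param spacing Locus width in bp (>= 12000; smaller is a config error
#'   because the +/-5 kb profile windows would collide).
#' @param plant_rate_bivalent,plant_rate_active Motif planting shares.
#' @param motif_bivalent,motif_active The planted k-mers.
#' @param n_chroms Number of chromosomes the loci are split over.
#' @param seed Master seed.
#' @return List with `genome` (DNAStringSet), `tss` (TSS table), `cgi`
#'   ([peak_set()]), `truth` (per-promoter data.frame with `true_class`,
#'   `cpg_rich`, `motif_planted`, `plant_offset`, `k4_strength`,
#'   `k27_strength`), and the generation parameters.
#' @export
simulate_reference <- function(n_promoters = 2000,
                               class_proportions = c(BIVALENT = 0.25,
                                                     ACTIVE = 0.35,
                                                     REPRESSED = 0.10,
                                                     LATENT = 0.30),
                               classes = NULL,
                               spacing = 12000,
                               plant_rate_bivalent = 0.5,
                               plant_rate_active = 0.4,
                               motif_bivalent = "TCCCC",
                               motif_active = "CGGAA",
                               n_chroms = 2,
                               seed = 1) {
  assert_that(spacing >= 12000,
              "config error: spacing must be >= 12000 bp (profile windows collide)")
  classes <- classes %||%
    simulate_truth_classes(n_promoters, class_proportions, sub_seed(seed, 1))
  assert_that(length(classes) == n_promoters,
              "classes must have length n_promoters")
  scrub <- unique(c(motif_bivalent, revcomp(motif_bivalent),
                    motif_active, revcomp(motif_active)))
  tss_off <- spacing %/% 2                 # TSS offset inside each locus
  with_seed(sub_seed(seed, 2), {
    chrom_idx <- rep(seq_len(n_chroms), each = ceiling(n_promoters / n_chroms))[
      seq_len(n_promoters)]
    locus_rank <- stats::ave(seq_len(n_promoters), chrom_idx,
                             FUN = seq_along)
    strand <- sample(c("+", "-"), n_promoters, replace = TRUE)
    cpg_rich <- classes %in% c("BIVALENT", "ACTIVE")
    plant_p <- ifelse(classes == "BIVALENT", plant_rate_bivalent,
                      ifelse(classes == "ACTIVE", plant_rate_active, 0))
    planted <- stats::runif(n_promoters) < plant_p
    plant_offset <- ifelse(planted,
                           sample(seq(-250L, 245L), n_promoters, replace = TRUE),
                           NA_integer_)
    # per-promoter ChIP signal strengths (arbitrary units): bivalent
    # promoters carry more H3K27me3 than repressed ones and less H3K4me3
    # than active ones
    k4_strength <- ifelse(classes == "ACTIVE", stats::rlnorm(n_promoters, log(15), 0.3),
                   ifelse(classes == "BIVALENT", stats::rlnorm(n_promoters, log(8), 0.3), 0))
    k27_strength <- ifelse(classes == "BIVALENT", stats::rlnorm(n_promoters, log(12), 0.3),
                    ifelse(classes == "REPRESSED", stats::rlnorm(n_promoters, log(6), 0.3), 0))
    loci <- vector("list", n_promoters)
    for (i in seq_len(n_promoters)) {
      x <- bg_dna(spacing)
      if (cpg_rich[i]) {
        x[(tss_off - 750 + 1):(tss_off + 750)] <- core_dna(1500)
        x[(tss_off - 150 + 1):(tss_off + 150)] <- boost_dna(300)
      }
      lo <- tss_off - 2100 + 1
      hi <- tss_off + 2100
      x[lo:hi] <- scrub_motifs(x[lo:hi], scrub)
      if (planted[i]) {
        mot <- if (classes[i] == "BIVALENT") motif_bivalent else motif_active
        d <- plant_offset[i]
        if (strand[i] == "+") {
          at <- tss_off + d + 1          # 1-based index of motif start
          x[at:(at + nchar(mot) - 1)] <- strsplit(mot, "")[[1]]
        } else {
          at <- tss_off - d - nchar(mot) + 1 + 1
          x[at:(at + nchar(mot) - 1)] <- strsplit(revcomp(mot), "")[[1]]
        }
      }
      loci[[i]] <- paste(x, collapse = "")
    }
  })
  chrom <- paste0("chr", chrom_idx)
  locus_start <- (locus_rank - 1L) * spacing
  pos <- locus_start + tss_off
  chrom_seqs <- vapply(seq_len(n_chroms), function(ci)
    paste(unlist(loci[chrom_idx == ci]), collapse = ""), character(1))
  genome <- Biostrings::DNAStringSet(chrom_seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  ids <- sprintf("T%05d", seq_len(n_promoters))
  gene_ids <- sprintf("G%05d", seq_len(n_promoters))
  tss <- data.frame(transcript_id = ids, gene_id = gene_ids, chrom = chrom,
                    position = as.integer(pos), strand = strand)
  truth <- cbind(tss,
                 data.frame(true_class = classes, cpg_rich = cpg_rich,
                            motif_planted = planted,
                            plant_offset = plant_offset,
                            k4_strength = k4_strength,
                            k27_strength = k27_strength))
  cgi_df <- data.frame(chrom = chrom[cpg_rich],
                       start = as.integer(pos[cpg_rich] - 750),
                       end = as.integer(pos[cpg_rich] + 750))
  cgi <- peak_set(cgi_df, "reference", "CGI")
  list(genome = genome, tss = tss, cgi = cgi, truth = truth,
       spacing = spacing, seed = seed,
       motif_bivalent = motif_bivalent, motif_active = motif_active,
       plant_rate_bivalent = plant_rate_bivalent,
       plant_rate_active = plant_rate_active)
}

# peak geometry helpers: peaks centred on the TSS, jittered, mirrored on
# the minus strand
mark_peak_coords <- function(pos, strand, up, down, jitter) {
  j1 <- as.integer(round(stats::runif(length(pos), 0, jitter)))
  j2 <- as.integer(round(stats::runif(length(pos), 0, jitter)))
  start <- ifelse(strand == "+", pos - up - j1, pos - down - j1)
  end <- ifelse(strand == "+", pos + down + j2, pos + up + j2)
  data.frame(start = as.integer(pmax(start, 0)), end = as.integer(end))
}

#' Simulate per-sample ChIP peak calls and fragment files
#'
#' For each sample, each promoter truly carrying a mark emits a peak with
#' that mark's detection probability.  H3K4me3 detection is high and
#' stable across samples; H3K27me3 detection is drawn per sample from an
#' interval (default 0.4-0.95), reproducing the strong cross-sample
#' variability of H3K27me3 peak counts relative to H3K4me3.  Promoters
#' not carrying a mark emit a spurious peak at `false_positive_rate`.
#' Optional fragment sets place ~70% of a sample's library inside its
#' detected peaks (proportionally to planted signal strength) and the rest
#' uniformly over the genome.
#'
#' @param ref Output of [simulate_reference()].
#' @param n_samples Number of sample pairs (default 10).
#' @param k4_detect_p Per-sample H3K4me3 detection probability (scalar).
#' @param k27_detect_p Either a scalar (fixed probability) or a length-2
#'   interval from which each sample's probability is drawn.
#' @param false_positive_rate Spurious-peak probability per promoter.
#' @param depth_range Length-2 interval for per-sample library sizes
#'   (fragment counts; desk-scale, far below real sequencing depth).
#' @param fragments Logical: also generate fragment sets (slower).
#' @param fragment_samples Indices of samples for which fragments are
#'   generated when `fragments = TRUE` (default: all).
#' @param seed Master seed.
#' @return List with `samples` (per sample: `sample_id`, `k4`, `k27`
#'   peak sets, optional `k4_fragments`/`k27_fragments`, `depth`,
#'   `k27_p`) and `pairs` (data.frame sample_id, k4, k27 labels).
#' @export
simulate_chip_samples <- function(ref, n_samples = 10,
                                  k4_detect_p = 0.97,
                                  k27_detect_p = c(0.4, 0.95),
                                  false_positive_rate = 0.01,
                                  depth_range = c(1e5, 4e5),
                                  fragments = FALSE,
                                  fragment_samples = seq_len(n_samples),
                                  seed = 1) {
  assert_that(k4_detect_p >= 0 && k4_detect_p <= 1,
              "k4_detect_p must be in [0, 1]")
  assert_that(all(k27_detect_p >= 0 & k27_detect_p <= 1),
              "k27_detect_p must be in [0, 1]")
  truth <- ref$truth
  n <- nrow(truth)
  genome_len <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  frag_len <- 150L
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    samples[[s]] <- with_seed(sub_seed(seed, 100 + s), {
      p27 <- if (length(k27_detect_p) == 2)
        stats::runif(1, k27_detect_p[1], k27_detect_p[2]) else k27_detect_p
      has_k4 <- truth$true_class %in% c("ACTIVE", "BIVALENT")
      has_k27 <- truth$true_class %in% c("REPRESSED", "BIVALENT")
      det_k4 <- (has_k4 & stats::runif(n) < k4_detect_p) |
        (!has_k4 & stats::runif(n) < false_positive_rate)
      det_k27 <- (has_k27 & stats::runif(n) < p27) |
        (!has_k27 & stats::runif(n) < false_positive_rate)
      mk_peaks <- function(det, up, down, strength, mark) {
        idx <- which(det)
        co <- mark_peak_coords(truth$position[idx], truth$strand[idx],
                               up, down, 200)
        # spurious peaks get a weak nominal strength
        str_eff <- ifelse(strength[idx] > 0, strength[idx], 1)
        df <- data.frame(chrom = truth$chrom[idx], start = co$start,
                         end = co$end,
                         score = round(str_eff *
                                         stats::rlnorm(length(idx), 0, 0.2), 3))
        list(ps = peak_set(df[order(df$chrom, df$start), , drop = FALSE],
                           sprintf("S%02d", s), mark),
             idx = idx, strength = str_eff,
             start = co$start, end = co$end)
      }
      k4 <- mk_peaks(det_k4, 500, 1500, truth$k4_strength, "H3K4me3")
      k27 <- mk_peaks(det_k27, 1500, 2500, truth$k27_strength, "H3K27me3")
      depth <- round(stats::runif(1, depth_range[1], depth_range[2]))
      out <- list(sample_id = sprintf("S%02d", s), k4 = k4$ps, k27 = k27$ps,
                  depth = depth, k27_p = p27)
      if (fragments && s %in% fragment_samples) {
        # Foreground fragments pile up wherever the mark truly is (with
        # per-promoter efficiency noise); failing to call a peak is a
        # property of peak detection, not of the underlying signal.
        mk_frags <- function(strength, up, down, mark) {
          n_fg <- round(0.7 * depth)
          n_bg <- depth - n_fg
          frag <- NULL
          idx <- which(strength > 0)
          if (length(idx) > 0 && n_fg > 0) {
            w <- strength[idx] * stats::rlnorm(length(idx), 0, 0.3)
            cnt <- as.integer(stats::rmultinom(1, n_fg, w / sum(w)))
            rep_i <- rep(idx, cnt)
            rstart <- ifelse(truth$strand[rep_i] == "+",
                             truth$position[rep_i] - up,
                             truth$position[rep_i] - down)
            span <- up + down - frag_len
            fs <- pmax(rstart +
                         as.integer(floor(stats::runif(length(rep_i)) * span)), 0L)
            frag <- data.frame(chrom = truth$chrom[rep_i],
                               start = fs, end = fs + frag_len)
          }
          if (n_bg > 0) {
            chr <- sample(names(genome_len), n_bg, replace = TRUE,
                          prob = genome_len / sum(genome_len))
            bs <- as.integer(floor(stats::runif(n_bg) *
                                     (genome_len[chr] - frag_len)))
            frag <- rbind(frag, data.frame(chrom = chr, start = bs,
                                           end = bs + frag_len))
          }
          peak_set(frag, sprintf("S%02d", s), paste0(mark, "_fragments"))
        }
        out$k4_fragments <- mk_frags(truth$k4_strength, 500, 1500, "H3K4me3")
        out$k27_fragments <- mk_frags(truth$k27_strength, 1500, 2500, "H3K27me3")
      }
      out
    })
  }
  pairs <- data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"),
                      k4 = "H3K4me3", k27 = "H3K27me3")
  list(samples = samples, pairs = pairs)
}

#' Simulate factor-binding peak sets
#'
#' Each factor binds each promoter independently with probability
#' `min(base_rate * odds[class], 0.95)`.  Under the default odds more
#' factors bind ACTIVE than BIVALENT than REPRESSED/LATENT promoters.
#'
#' @param truth Truth table from [simulate_reference()].
#' @param n_factors Number of factors (default 20).
#' @param base_rate Baseline binding probability.
#' @param class_odds Named odds multipliers per true class (all > 0), or a
#'   matrix (n_factors x 4, columns named by state) for per-factor odds.
#' @param seed Master seed.
#' @return Named list of [peak_set()]s (`F01`, `F02`, ...).
#' @export
simulate_factors <- function(truth, n_factors = 20, base_rate = 0.08,
                             class_odds = c(ACTIVE = 6, BIVALENT = 3,
                                            REPRESSED = 1, LATENT = 0.5),
                             seed = 1) {
  if (n_factors == 0) return(setNames(list(), character(0)))
  if (is.matrix(class_odds))
    assert_that(nrow(class_odds) == n_factors,
                "odds matrix must have n_factors rows")
  assert_that(all(class_odds > 0), "odds must be > 0")
  out <- lapply(seq_len(n_factors), function(f) {
    with_seed(sub_seed(seed, 300 + f), {
      odds <- if (is.matrix(class_odds)) class_odds[f, ] else class_odds
      p <- pmin(base_rate * unname(odds[truth$true_class]), 0.95)
      idx <- which(stats::runif(nrow(truth)) < p)
      co <- mark_peak_coords(truth$position[idx], truth$strand[idx],
                             300, 300, 100)
      peak_set(data.frame(chrom = truth$chrom[idx], start = co$start,
                          end = co$end), sprintf("F%02d", f), "factor")
    })
  })
  setNames(out, sprintf("F%02d", seq_len(n_factors)))
}

#' Simulate class-dependent expression and perturbation gene lists
#'
#' Bulk FPKM is zero with a class-dependent probability and log-normal
#' otherwise (default medians: ACTIVE 30, BIVALENT 3, REPRESSED 1,
#' LATENT 0.3, so medians order ACTIVE > BIVALENT > LATENT as in ES
#' cells).  The single-cell matrix is zero-inflated around the bulk value
#' with class-dependent dropout.  Differentially-expressed gene lists are
#' drawn without replacement with odds `de_odds` for BIVALENT genes,
#' planting the perturbation-overlap signal.
#'
#' @param truth Truth table from [simulate_reference()].
#' @param class_means Named log-normal medians (FPKM) per class.
#' @param sdlog Log-normal sdlog.
#' @param zero_prob Named probability of exact zero bulk FPKM per class.
#' @param n_cells Number of single cells (default 63).
#' @param dropout Named per-class single-cell dropout probability.
#' @param n_de_lists Number of perturbation lists (default 30).
#' @param de_list_size Genes per list.
#' @param de_odds Sampling odds for BIVALENT genes (1 = null).
#' @param seed Master seed.
#' @return List with `bulk` (gene_id, fpkm), `sc` (genes x cells matrix),
#'   `de_lists` (named list of gene-id vectors).
#' @export
simulate_expression <- function(truth,
                                class_means = c(ACTIVE = 30, BIVALENT = 3,
                                                REPRESSED = 1, LATENT = 0.3),
                                sdlog = 1,
                                zero_prob = c(ACTIVE = 0, BIVALENT = 0.05,
                                              REPRESSED = 0.3, LATENT = 0.7),
                                n_cells = 63,
                                dropout = c(ACTIVE = 0.3, BIVALENT = 0.6,
                                            REPRESSED = 0.75, LATENT = 0.9),
                                n_de_lists = 30, de_list_size = 200,
                                de_odds = 8, seed = 1) {
  assert_that(n_cells >= 1, "n_cells must be >= 1")
  n <- nrow(truth)
  cls <- truth$true_class
  bulk <- with_seed(sub_seed(seed, 500), {
    fpkm <- stats::rlnorm(n, log(unname(class_means[cls])), sdlog)
    fpkm[stats::runif(n) < unname(zero_prob[cls])] <- 0
    data.frame(gene_id = truth$gene_id, fpkm = round(fpkm, 4))
  })
  sc <- with_seed(sub_seed(seed, 501), {
    drop_p <- unname(dropout[cls])
    m <- matrix(stats::rlnorm(n * n_cells,
                              rep(log(pmax(bulk$fpkm, 0.1)), n_cells), 0.8),
                nrow = n)
    zero <- matrix(stats::runif(n * n_cells), nrow = n) < drop_p
    m[zero] <- 0
    rownames(m) <- truth$gene_id
    colnames(m) <- sprintf("cell%02d", seq_len(n_cells))
    round(m, 4)
  })
  de_lists <- lapply(seq_len(n_de_lists), function(l) {
    with_seed(sub_seed(seed, 600 + l), {
      w <- ifelse(cls == "BIVALENT", de_odds, 1)
      sample(truth$gene_id, min(de_list_size, n), prob = w)
    })
  })
  names(de_lists) <- sprintf("perturbation%02d", seq_len(n_de_lists))
  list(bulk = bulk, sc = sc, de_lists = de_lists)
}

#' Simulate a second species with class-level conservation
#'
#' For each species-A gene, the species-B class matches with the A class's
#' conservation rate and is otherwise resampled uniformly from the other
#' three states.  The ortholog mapping is one-to-one by construction.
#'
#' @param truth_a Species-A truth table (needs `gene_id`, `true_class`).
#' @param conservation Named per-class conservation rates in \[0, 1\]
#'   (default bivalent 0.66, as the headline mouse-to-human rate).
#' @param seed Master seed.
#' @return List with `pairs` (gene_a, gene_b) and `truth_b` (gene_id,
#'   true_class).
#' @export
simulate_orthologs <- function(truth_a,
                               conservation = c(BIVALENT = 0.66, ACTIVE = 0.8,
                                                REPRESSED = 0.2, LATENT = 0.8),
                               seed = 1) {
  assert_that(all(conservation >= 0 & conservation <= 1),
              "conservation rates must be in [0, 1]")
  cls_a <- truth_a$true_class
  n <- length(cls_a)
  cls_b <- with_seed(sub_seed(seed, 700), {
    keep <- stats::runif(n) < unname(conservation[cls_a])
    out <- cls_a
    flip <- which(!keep)
    out[flip] <- vapply(cls_a[flip], function(c0)
      sample(setdiff(SAMPLE_STATES, c0), 1), character(1))
    out
  })
  gene_b <- sub("^G", "GB", truth_a$gene_id)
  list(pairs = data.frame(gene_a = truth_a$gene_id, gene_b = gene_b),
       truth_b = data.frame(gene_id = gene_b, true_class = cls_b))
}

#' Write a simulated reference to disk
#'
#' Emits `genome.fa`, `tss.gtf` (GENCODE-style transcript lines),
#' `cgi.bed` and `ground_truth.tsv` into `out_dir`; all files re-parse
#' through the package's readers.
#'
#' @param ref Output of [simulate_reference()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_reference <- function(ref, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             gtf = file.path(out_dir, "tss.gtf"),
             cgi = file.path(out_dir, "cgi.bed"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  write_genome_fasta(ref$genome, paths["genome"])
  write_tss_gtf(ref$tss, paths["gtf"])
  write_bed(ref$cgi, paths["cgi"])
  write_tsv(ref$truth, paths["truth"])
  invisible(paths)
}

#' Write a TSS table as GENCODE-style GTF transcript features
#'
#' @param tss TSS table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_gtf <- function(tss, path) {
  start1 <- ifelse(tss$strand == "+", tss$position + 1, tss$position - 998)
  end1 <- ifelse(tss$strand == "+", tss$position + 1000, tss$position + 1)
  start1 <- pmax(start1, 1)
  lines <- sprintf(
    '%s\tbivalscan_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tss$chrom, start1, end1, tss$strand, tss$gene_id, tss$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
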