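# signal: density matrices, clustering, group comparisons

test_that("binned_density counts fragments per bin with RPM scaling", {
  tss <- make_tss(10000, "+")
  # 5 fragments inside the first 100-bp bin [5000, 5100)
  frags <- make_peaks("chr1", rep(5010, 5), rep(5060, 5), mark = "frag")
  dm <- binned_density(frags, tss, span = 5000, bin = 100,
                       library_size = 1e6)
  expect_equal(unname(dm$values[1, 1]), 5.0)
  expect_equal(sum(dm$values), 5.0)
  # no fragments near the TSS -> all-zero row
  far <- make_peaks("chr2", 1, 100, mark = "frag")
  expect_true(all(binned_density(far, tss, library_size = 10)$values == 0))
  # a fragment spanning two bins is counted in both
  span2 <- make_peaks("chr1", 5090, 5120, mark = "frag")
  dm2 <- binned_density(span2, tss, span = 5000, bin = 100, library_size = 1e6)
  expect_equal(unname(dm2$values[1, 1:2]), c(1, 1))
  expect_error(binned_density(span2, tss, library_size = 0), "library_size")
})

test_that("density normalization is linear in library size", {
  set.seed(11)
  st <- sample(4000:16000, 300)
  frags <- make_peaks("chr1", st, st + 150, mark = "frag")
  tss <- make_tss(10000, "+")
  d1 <- binned_density(frags, tss, library_size = 1e5)
  d2 <- binned_density(frags, tss, library_size = 2e5)
  expect_equal(d1$values, 2 * d2$values)
})

test_that("minus-strand rows are reversed to transcript orientation", {
  frags <- make_peaks("chr1", 5010, 5060, mark = "frag")   # 5' on + strand
  plus <- binned_density(frags, make_tss(10000, "+"), library_size = 1e6)
  minus <- binned_density(frags, make_tss(10000, "-"), library_size = 1e6)
  expect_equal(which(plus$values[1, ] > 0), 1L)
  expect_equal(which(minus$values[1, ] > 0), 100L)
})

test_that("coverage mode averages bedGraph values over bins", {
  tss <- make_tss(1000, "+")
  bg <- data.frame(chrom = "chr1", start = c(0, 900), end = c(900, 3000),
                   value = c(2, 6))
  dm <- binned_density(bg, tss, span = 500, bin = 100)
  expect_equal(unname(dm$values[1, 1]), 2)        # [500,600) fully in value-2 block
  expect_equal(unname(dm$values[1, 4]), 2)        # [800,900) still value 2
  expect_equal(unname(dm$values[1, 5]), 6)        # [900,1000) fully in value-6 block
  expect_equal(dm$mode, "coverage")
})

test_that("k-means recovers planted archetypes deterministically", {
  fx <- make_archetype_matrices(n_per_cluster = 40, noise_sd = 0.12, seed = 3)
  cl <- cluster_promoters(list(fx$matrix), k = 4, seed = 9)
  expect_gte(adjusted_rand_index(cl$labels, fx$labels), 0.95)
  cl2 <- cluster_promoters(list(fx$matrix), k = 4, seed = 9)
  expect_identical(cl$labels, cl2$labels)           # same seed, same labels
  # well-separated data: a different seed still yields the same renumbered
  # labelling because labels are ordered by first-factor cluster means
  cl3 <- cluster_promoters(list(fx$matrix), k = 4, seed = 1234)
  expect_identical(cl$labels, cl3$labels)
  expect_error(cluster_promoters(list(fx$matrix), k = 1000), "k must not")
})

test_that("identical rows collapse to one cluster with zero inertia", {
  vals <- matrix(1, 10, 20)
  rownames(vals) <- sprintf("P%02d", 1:10)
  dm <- structure(list(values = vals, factor = "x", bin_size = 100,
                       span = 1000, library_size = 1, mode = "fragments"),
                  class = "density_matrix")
  cl <- cluster_promoters(list(dm), k = 1, seed = 2)
  expect_equal(unname(cl$labels), rep(1L, 10))
  expect_equal(cl$inertia, 0)
})

test_that("adjusted_rand_index agrees with the pair-counting oracle", {
  set.seed(13)
  for (i in 1:5) {
    a <- sample(1:3, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
  }
  expect_equal(adjusted_rand_index(rep(1:2, 10), rep(c("x", "y"), 10)), 1)
})

test_that("cluster_mean_profiles averages member rows", {
  vals <- rbind(c(0, 2), c(2, 0), c(5, 5))
  rownames(vals) <- c("a", "b", "c")
  dm <- structure(list(values = vals, factor = "x", bin_size = 1, span = 1,
                       library_size = 1, mode = "fragments"),
                  class = "density_matrix")
  asn <- structure(list(labels = c(a = 1L, b = 1L, c = 2L), k = 3L,
                        seed = 1L, inertia = 0), class = "cluster_assignment")
  prof <- cluster_mean_profiles(asn, dm)
  expect_equal(prof[1, ], c(1, 1))
  expect_equal(prof[2, ], c(5, 5))                  # singleton -> own row
  expect_equal(prof[3, ], c(0, 0))                  # empty cluster
  expect_equal(attr(prof, "empty_clusters"), 3L)
})

test_that("promoter_mark_density and group_compare detect a planted shift", {
  set.seed(14)
  n <- 200
  tss <- make_tss(seq(10000, by = 12000, length.out = 2 * n),
                  rep("+", 2 * n))
  prom <- promoter_windows(tss)
  # group A promoters get ~3x the fragment mass of group B
  counts <- c(rpois(n, 30), rpois(n, 10))
  rep_i <- rep(seq_len(2 * n), counts)
  st <- tss$position[rep_i] + sample(-900:1800, length(rep_i), TRUE)
  frags <- make_peaks("chr1", st, st + 150, mark = "frag")
  d <- promoter_mark_density(frags, prom)
  labels <- rep(c("A", "B"), each = n)
  tt <- group_compare(log10(d + 1), labels, test = "t")
  expect_lt(tt$p_value, 0.01)
  kw <- group_compare(d, labels, test = "kruskal")
  expect_lt(kw$p_value, 0.01)
  expect_error(group_compare(d, rep("A", 2 * n)), ">= 2 groups")
  expect_error(group_compare(d[1:3], c("A", "A", "B")), ">= 2 values")
  # empty overlap -> density 0
  none <- make_peaks("chr2", 1, 50, mark = "frag")
  expect_true(all(promoter_mark_density(none, prom) == 0))
})

test_that("identical groups give calibrated p-values under the null", {
  set.seed(15)
  p <- replicate(200, {
    v <- rnorm(40)
    group_compare(v, rep(c("A", "B"), each = 20), test = "t")$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
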