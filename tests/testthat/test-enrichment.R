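test_that("fold increase handles saturating and constructed cases", {
  g <- genome_def("c1", 100000)
  a <- cluster_set(data.frame(chrom = "c1", start = c(1000, 50000),
                              end = c(2000, 51000)), g, "A")
  # feature class spanning the whole genome: expected = |A|, fold = 1
  whole <- feature_set(data.frame(chrom = "c1", start = 0, end = 100000),
                       g, "other")
  fr <- fold_increase(a, whole)
  expect_equal(fr$observed, total_bases(a))
  expect_equal(fr$fold, 1)

  # half of A's bases in a class occupying 5% of the genome: fold = 10
  f5 <- feature_set(data.frame(chrom = "c1", start = 0, end = 5000), g, "TER")
  expect_equal(fold_increase(a, f5)$fold, (1000 / 2000) / 0.05)

  empty <- cluster_set(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), g)
  expect_error(fold_increase(empty, f5), "undefined fold")
})

test_that("analytic fold is scale-consistent under genome duplication", {
  g1 <- genome_def("c1", 50000)
  g2 <- genome_def(c("c1", "c2"), c(50000, 50000))
  a1 <- cluster_set(data.frame(chrom = "c1", start = c(0, 10000),
                               end = c(800, 11000)), g1, "A")
  f1 <- feature_set(data.frame(chrom = "c1", start = c(300, 20000),
                               end = c(1300, 21000)), g1, "TER")
  a2 <- cluster_set(data.frame(chrom = c("c1", "c1", "c2", "c2"),
                               start = c(0, 10000, 0, 10000),
                               end = c(800, 11000, 800, 11000)), g2, "A")
  f2 <- feature_set(data.frame(chrom = c("c1", "c1", "c2", "c2"),
                               start = c(300, 20000, 300, 20000),
                               end = c(1300, 21000, 1300, 21000)), g2, "TER")
  expect_equal(fold_increase(a1, f1)$fold, fold_increase(a2, f2)$fold)
})

test_that("uniformly placed clusters give mean fold near 1", {
  g <- genome_def(c("c1", "c2"), c(100000, 100000))
  fs <- place_features(g, list(TER = list(n = 15, length_range = c(800, 1500))),
                       seed = 21)$TER
  set.seed(22)
  folds <- replicate(100, {
    a <- make_cluster_set(g, n_clusters = 25, length_median = 800,
                          anchor_fraction = 0)
    fold_increase(a, fs)$fold
  })
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 3 * se)
})

test_that("Monte-Carlo expectation agrees with the analytic one on sparse sets", {
  g <- genome_def(c("c1", "c2"), c(200000, 200000))
  set.seed(31)
  a <- make_cluster_set(g, n_clusters = 15, length_median = 800, protein = "A")
  fs <- place_features(g, list(TER = list(n = 12, length_range = c(2000, 4000))),
                       seed = 32)$TER
  an <- fold_increase(a, fs, mode = "analytic")
  mc <- fold_increase(a, fs, mode = "montecarlo", n_iterations = 1000,
                      seed = 33)
  expect_lt(abs(mc$expected - an$expected) / an$expected, 0.10)
})

test_that("bound feature calls agree with a per-feature bitmap oracle", {
  sizes <- c(c1 = 10000)
  g <- toy_genome(sizes)
  set.seed(41)
  raw <- random_intervals(15, sizes, max_len = 300)
  a <- cluster_set(raw, g, "A")
  feats <- random_intervals(20, sizes, max_len = 200)
  feats$id <- sprintf("f%02d", seq_len(nrow(feats)))
  fs <- feature_set(feats, g, "TER")
  bf <- bound_features(a, fs, min_overlap_bp = 25)
  bm <- bitmap_of(raw, sizes)[[1]]
  for (i in seq_len(nrow(feats))) {
    ov <- sum(bm[(feats$start[i] + 1):feats$end[i]])
    expect_equal(unname(bf$overlap_bp[feats$id[i]]), ov)
    expect_equal(feats$id[i] %in% bf$ids, ov >= 25)
  }
})

test_that("bound feature edge cases and thresholds behave", {
  g <- genome_def("c1", 10000)
  fs <- feature_set(data.frame(id = c("a", "b"), chrom = "c1",
                               start = c(100, 5000), end = c(200, 5100)),
                    g, "CEN")
  far <- cluster_set(data.frame(chrom = "c1", start = 8000, end = 9000), g)
  expect_equal(bound_features(far, fs)$count, 0)
  expect_length(bound_features(far, fs)$ids, 0)
  all_cover <- cluster_set(data.frame(chrom = "c1", start = 0, end = 10000), g)
  expect_equal(bound_features(all_cover, fs)$count, 2)
  expect_error(bound_features(far, fs, min_overlap_bp = 0), ">= 1")
  # raising the threshold never increases the bound count
  part <- cluster_set(data.frame(chrom = "c1", start = 150, end = 5050), g)
  counts <- vapply(c(1, 25, 50, 75), function(m) {
    bound_features(part, fs, m)$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("co-occupancy counts partition the features and sum to 100%", {
  g <- genome_def("c1", 1000000)
  feats <- data.frame(id = sprintf("TER%02d", 1:20), chrom = "c1",
                      start = seq(0, 950000, by = 50000),
                      end = seq(0, 950000, by = 50000) + 1000)
  fs <- feature_set(feats, g, "TER")
  a <- cover_features(fs, sprintf("TER%02d", 1:12), "A")
  b <- cover_features(fs, sprintf("TER%02d", 7:16), "B")
  co <- cooccupancy(list(A = a, B = b), fs)
  expect_equal(sum(co$combinations$count), 20)
  expect_equal(sum(co$combinations$percent), 100)
  both <- co$combinations$count[co$combinations$combination == "A+B"]
  expect_equal(both, 6)  # TER07..TER12
  none <- co$combinations$count[co$combinations$combination == "none"]
  expect_equal(none, 4)  # TER17..TER20
  # all proteins on all features: single combination at 100%
  co_all <- cooccupancy(list(A = cover_features(fs, feats$id, "A"),
                             B = cover_features(fs, feats$id, "B")), fs)
  expect_equal(co_all$combinations$percent[
    co_all$combinations$combination == "A+B"], 100)
  expect_error(cooccupancy(list(A = a, A = a), fs), "duplicate")
})

test_that("estimated enrichment rises with the anchoring fraction", {
  g <- genome_def(c("c1", "c2", "c3", "c4"), rep(250000, 4))
  fs <- place_features(g, list(TER = list(n = 20, length_range = c(800, 1500))),
                       seed = 51)$TER
  set.seed(52)
  ladder <- c(0, 0.25, 0.5, 0.75)
  mean_folds <- vapply(ladder, function(f) {
    mean(replicate(20, {
      a <- make_cluster_set(g, n_clusters = 40, length_median = 1000,
                            anchors = fs, anchor_fraction = f)
      fold_increase(a, fs)$fold
    }))
  }, numeric(1))
  expect_true(all(diff(mean_folds) > 0))
})
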