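test_that("overlap score matches simple intersections and is symmetric", {
  g <- genome_def("c1", 1000)
  a <- cluster_set(data.frame(chrom = "c1", start = 100, end = 200), g, "A")
  b <- cluster_set(data.frame(chrom = "c1", start = 150, end = 250), g, "B")
  expect_equal(overlap_bases(a, b), 50)
  expect_equal(overlap_bases(b, a), 50)
  expect_equal(overlap_bases(a, a), total_bases(a))
  g2 <- genome_def("c1", 2000)
  a2 <- cluster_set(data.frame(chrom = "c1", start = 100, end = 200), g2)
  expect_error(overlap_bases(a, a2), "different genomes")
})

test_that("overlap score equals the bitmap oracle on random pairs", {
  sizes <- c(c1 = 10000)
  g <- toy_genome(sizes)
  set.seed(202)
  for (rep in 1:25) {
    ra <- random_intervals(20, sizes)
    rb <- random_intervals(20, sizes)
    a <- cluster_set(ra, g, "A")
    b <- cluster_set(rb, g, "B")
    ov <- overlap_bases(a, b)
    expect_equal(ov, bitmap_overlap_bp(ra, rb, sizes))
    expect_lte(ov, min(total_bases(a), total_bases(b)))
  }
})

test_that("overlap score agrees with GenomicRanges intersect", {
  skip_if_not_installed("GenomicRanges")
  sizes <- c(c1 = 10000, c2 = 8000)
  g <- toy_genome(sizes)
  set.seed(17)
  for (rep in 1:10) {
    ra <- random_intervals(25, sizes)
    rb <- random_intervals(25, sizes)
    gr <- function(df) GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1, df$end)))
    expected <- sum(GenomicRanges::width(
      GenomicRanges::intersect(gr(ra), gr(rb))))
    expect_equal(overlap_bases(cluster_set(ra, g), cluster_set(rb, g)),
                 expected)
  }
})

test_that("randomized placement conserves lengths and chromosome assignment", {
  g <- toy_genome(c(c1 = 10000, c2 = 5000))
  cs <- cluster_set(data.frame(chrom = c("c1", "c1", "c2"),
                               start = c(0, 5000, 100),
                               end = c(1000, 5600, 300)), g, "A")
  for (s in 1:5) {
    r <- randomize_placement(cs, seed = s)
    expect_equal(total_bases(r), total_bases(cs))
    expect_equal(sort(r$intervals$end - r$intervals$start),
                 sort(cs$intervals$end - cs$intervals$start))
    expect_equal(table(r$intervals$chrom), table(cs$intervals$chrom))
  }
  # interval covering a whole chromosome has a single placement
  full <- cluster_set(data.frame(chrom = "c2", start = 0, end = 5000), g)
  expect_identical(randomize_placement(full, seed = 1)$intervals,
                   full$intervals)
})

test_that("single-interval starts are uniform over valid positions", {
  G <- 1000
  L <- 100
  g <- genome_def("c1", G)
  cs <- cluster_set(data.frame(chrom = "c1", start = 0, end = L), g)
  set.seed(404)
  starts <- replicate(10000, randomize_placement(cs)$intervals$start)
  expect_gte(min(starts), 0)
  expect_lte(max(starts), G - L)
  # mean within 3 standard errors of (G - L) / 2
  se <- sqrt(((G - L + 1)^2 - 1) / 12 / length(starts))
  expect_lt(abs(mean(starts) - (G - L) / 2), 3 * se)
})

test_that("infeasibly dense sets fail with advice, allow_overlap succeeds", {
  g <- genome_def("c1", 1000)
  dense <- cluster_set(data.frame(chrom = "c1",
                                  start = seq(0, 900, by = 100) + c(0, rep(1, 9)),
                                  end = seq(0, 900, by = 100) + 99),
                       g, "dense")
  expect_error(randomize_placement(dense, seed = 1, max_retries = 20),
               "allow_overlap")
  r <- randomize_placement(dense, seed = 1, allow_overlap = TRUE)
  expect_lte(total_bases(r), total_bases(dense))
})

test_that("degenerate Monte-Carlo cases give p = 1", {
  g <- genome_def("c1", 10000)
  a <- cluster_set(data.frame(chrom = "c1", start = 100, end = 600), g, "A")
  empty <- cluster_set(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), g, "E")
  res <- monte_carlo_colocalization(a, empty, n_iterations = 100, seed = 1)
  expect_equal(res$observed_overlap_bp, 0)
  expect_true(all(res$null_scores == 0))
  expect_equal(res$empirical_p, 1)

  whole <- cluster_set(data.frame(chrom = "c1", start = 0, end = 10000), g)
  b <- cluster_set(data.frame(chrom = "c1", start = 200, end = 700), g, "B")
  res <- monte_carlo_colocalization(whole, b, n_iterations = 100, seed = 1)
  expect_true(all(res$null_scores == total_bases(b)))
  expect_equal(res$empirical_p, 1)
  expect_error(monte_carlo_colocalization(a, b, n_iterations = 0), ">= 1")
})

test_that("empirical p converges to the exhaustive-placement probability", {
  # A = [0,100), B = [50,150) on a 1000 bp chromosome; overlap = 50.
  # Enumerate all 901 placements of A for the exact null tail.
  G <- 1000
  g <- genome_def("c1", G)
  a <- cluster_set(data.frame(chrom = "c1", start = 0, end = 100), g, "A")
  b <- cluster_set(data.frame(chrom = "c1", start = 50, end = 150), g, "B")
  obs <- overlap_bases(a, b)
  starts <- 0:(G - 100)
  null_ov <- pmax(0, pmin(starts + 100, 150) - pmax(starts, 50))
  exact <- mean(null_ov >= obs)
  res <- monte_carlo_colocalization(a, b, n_iterations = 4000, seed = 77)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$empirical_p - exact), 4 * se + 1 / 4001)
})

test_that("Monte-Carlo results are bit-reproducible given the seed", {
  g <- toy_genome(c(c1 = 20000, c2 = 15000))
  set.seed(5)
  a <- make_cluster_set(g, n_clusters = 10, length_median = 500, protein = "A")
  b <- make_cluster_set(g, n_clusters = 10, length_median = 500, protein = "B")
  r1 <- monte_carlo_colocalization(a, b, n_iterations = 200, seed = 99)
  r2 <- monte_carlo_colocalization(a, b, n_iterations = 200, seed = 99)
  expect_identical(r1$null_scores, r2$null_scores)
  expect_identical(r1$empirical_p, r2$empirical_p)
  r3 <- monte_carlo_colocalization(a, b, n_iterations = 200, seed = 100)
  expect_false(identical(r1$null_scores, r3$null_scores))
})

test_that("randomizing B or both sets is supported", {
  g <- toy_genome(c(c1 = 50000))
  set.seed(6)
  a <- make_cluster_set(g, n_clusters = 8, length_median = 800, protein = "A")
  b <- make_cluster_set(g, n_clusters = 8, length_median = 800, protein = "B")
  for (mode in c("b", "both")) {
    r <- monte_carlo_colocalization(a, b, n_iterations = 100, seed = 1,
                                    randomize = mode)
    expect_length(r$null_scores, 100)
    expect_true(all(r$null_scores >= 0))
  }
})

test_that("Fisher test equals hypergeometric enumeration and fisher.test", {
  # the all-or-nothing table (5,0,0,5) on a 10 bp genome
  expect_equal(fisher_overlap_p(5, 5, 5, 10), 1 / choose(10, 5))
  # balanced table: observed at independence expectation, not significant
  expect_gt(fisher_overlap_p(1, 2, 2, 4), 0.5)
  set.seed(313)
  for (rep in 1:50) {
    G <- sample(20:200, 1)
    m1 <- sample.int(G - 1, 1)
    m2 <- sample.int(G - 1, 1)
    a <- sample(max(0, m1 + m2 - G):min(m1, m2), 1)
    p <- fisher_overlap_p(a, m1, m2, G)
    expect_equal(p, enum_fisher_p(a, m1, m2, G), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, m2 - a, m1 - a, G - m1 - m2 + a), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_overlap_p(6, 5, 5, 10), "negative cell")
})

test_that("set-level Fisher test reproduces the constructed table", {
  st <- sets_for_table(a = 30, m1 = 60, m2 = 50, G = 150)
  expect_equal(fisher_colocalization_test(st$A, st$B),
               enum_fisher_p(30, 60, 50, 150), tolerance = 1e-12)
})

test_that("genome coverage percent is footprint over genome length", {
  g <- genome_def("c1", 12000000)
  empty <- cluster_set(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), g)
  expect_equal(genome_coverage_percent(empty), 0)
  whole <- cluster_set(data.frame(chrom = "c1", start = 0, end = 12000000), g)
  expect_equal(genome_coverage_percent(whole), 100)
  half_mb <- cluster_set(data.frame(chrom = "c1", start = 0, end = 500000), g)
  expect_equal(genome_coverage_percent(half_mb), 100 * 500000 / 12000000)
})
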