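# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own interval code paths.

toy_genome <- function(sizes = c(c1 = 10000)) {
  genome_def(names(sizes), unname(sizes))
}

# n random raw intervals on one or more chromosomes (may overlap)
random_intervals <- function(n, sizes, max_len = 500) {
  chrom <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  len <- pmin(len, sizes[chrom])
  start <- floor(runif(n) * (sizes[chrom] - len + 1))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# per-base boolean membership over every base of every chromosome
bitmap_of <- function(df, sizes) {
  lapply(names(sizes), function(cn) {
    v <- logical(sizes[[cn]])
    sub <- df[df$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    v
  })
}

bitmap_union_bp <- function(df, sizes) {
  sum(vapply(bitmap_of(df, sizes), sum, numeric(1)))
}

bitmap_overlap_bp <- function(df_a, df_b, sizes) {
  ba <- bitmap_of(df_a, sizes)
  bb <- bitmap_of(df_b, sizes)
  sum(mapply(function(x, y) sum(x & y), ba, bb))
}

# one-tailed Fisher p by explicit enumeration over all same-margin tables:
# P(X >= a) where X ~ count in cell (1,1) with margins (m1, m2) on G trials
enum_fisher_p <- function(a, m1, m2, G) {
  lo <- max(0, m1 + m2 - G)
  hi <- min(m1, m2)
  k <- lo:hi
  probs <- choose(m1, k) * choose(G - m1, m2 - k) / choose(G, m2)
  sum(probs[k >= a])
}

# build two cluster sets realizing a given 2x2 base-count table on a
# single-chromosome genome of length G
sets_for_table <- function(a, m1, m2, G) {
  g <- genome_def("c1", G)
  A <- cluster_set(data.frame(chrom = "c1", start = 0, end = m1), g, "A")
  B <- cluster_set(data.frame(chrom = "c1", start = m1 - a,
                              end = m1 - a + m2), g, "B")
  list(A = A, B = B, g = g)
}

# cluster set covering the bodies of the given feature ids
cover_features <- function(fs, ids, protein) {
  sel <- fs$features$id %in% ids
  cluster_set(fs$features[sel, c("chrom", "start", "end")], fs$genome,
              protein = protein)
}
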