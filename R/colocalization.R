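# The core statistic: base-overlap score between two cluster sets, a
# Monte-Carlo randomization null for it, the one-tailed Fisher's exact test
# on the genome-wide base-count 2x2 table, and genome coverage percent.
#
# The score is the total number of overlapping bases between the two sets'
# genomic footprints. The null randomizes the placement of one set's
# clusters (per chromosome, same number of clusters with the same lengths,
# placed disjointly at uniform starts) and rescores; the empirical p-value
# uses the add-one estimator so it is never exactly 0. The Fisher test
# treats every base of the genome as a trial (in A / not-in-A vs in-B /
# not-in-B); because neighbouring bases are strongly autocorrelated it is
# anti-conservative, and the Monte-Carlo empirical p is the recommended
# headline statistic. Reports carry both, labeled.

#' Base overlap between two genomic footprints
#'
#' Total number of bases shared by the footprints of `A` and `B`
#' (the co-localization score). Symmetric in its arguments.
#'
#' @param A,B `cluster_set` or `feature_set` objects on the same genome.
#' @return Number of overlapping bases (integer-valued).
#' @examples
#' g <- genome_def("c1", 1000)
#' a <- cluster_set(data.frame(chrom = "c1", start = 100, end = 200), g, "A")
#' b <- cluster_set(data.frame(chrom = "c1", start = 150, end = 250), g, "B")
#' overlap_bases(a, b)  # 50
#' @export
overlap_bases <- function(A, B) {
  a <- .as_footprint(A)
  b <- .as_footprint(B)
  .check_same_genome(a$genome, b$genome)
  chroms <- intersect(unique(a$intervals$chrom), unique(b$intervals$chrom))
  total <- 0
  for (cn in chroms) {
    sa <- a$intervals$chrom == cn
    sb <- b$intervals$chrom == cn
    bpa <- sum(a$intervals$end[sa] - a$intervals$start[sa])
    bpb <- sum(b$intervals$end[sb] - b$intervals$start[sb])
    u <- .iv_union_bp2(a$intervals$start[sa], a$intervals$end[sa],
                       b$intervals$start[sb], b$intervals$end[sb])
    total <- total + bpa + bpb - u
  }
  total
}

#' Genome coverage percentage of a cluster set
#'
#' @param A A `cluster_set` (or `feature_set`).
#' @return `100 * total_bases(A) / total genome length`.
#' @export
genome_coverage_percent <- function(A) {
  f <- .as_footprint(A)
  100 * sum(f$intervals$end - f$intervals$start) / f$genome$total_length
}

# Place intervals of the given lengths uniformly on a chromosome of length
# G. Disjoint mode rejection-samples whole-chromosome proposals until the
# placed intervals are pairwise disjoint with at least 1 bp gap (book-ended
# placements would be merged by the cluster_set constructor, changing the
# interval count). Returns a sorted (start, end) matrix.
.place_lengths <- function(lens, G, allow_overlap = FALSE,
                           max_retries = 1000L) {
  n <- length(lens)
  if (n == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  if (any(lens > G)) {
    .stopf("cluster length %g exceeds chromosome length %g", max(lens), G)
  }
  k <- G - lens + 1  # number of valid starts per interval
  if (allow_overlap) {
    starts <- pmin(floor(stats::runif(n) * k), k - 1)
    o <- order(starts)
    return(cbind(start = starts[o], end = starts[o] + lens[o]))
  }
  for (i in seq_len(max_retries)) {
    starts <- pmin(floor(stats::runif(n) * k), k - 1)
    o <- order(starts)
    s <- starts[o]
    e <- s + lens[o]
    if (n == 1L || all(s[-1L] > e[-n])) {
      return(cbind(start = s, end = e))
    }
  }
  .stopf(paste0(
    "could not place %d intervals (%g bp total) disjointly on a %g bp ",
    "chromosome after %d attempts; consider allow_overlap = TRUE"),
    n, sum(lens), G, max_retries)
}

#' Randomize the placement of a cluster set
#'
#' Per chromosome, keeps the same number of clusters with the same multiset
#' of lengths, draws starts uniformly from the valid positions and
#' rejection-samples until placements are pairwise disjoint, so
#' `total_bases` is preserved exactly. With `allow_overlap = TRUE`
#' placements may collide and are merged before scoring (for dense sets
#' where disjoint placement is infeasible).
#'
#' @param A A `cluster_set`.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @param allow_overlap Permit colliding placements (merged afterwards).
#' @param max_retries Rejection-sampling attempts per chromosome before
#'   giving up.
#' @return A `cluster_set` with randomized positions.
#' @export
randomize_placement <- function(A, seed = NULL, allow_overlap = FALSE,
                                max_retries = 1000L) {
  stopifnot(inherits(A, "cluster_set"))
  sz <- chrom_sizes(A$genome)
  with_seed(seed, {
    pieces <- lapply(unique(A$intervals$chrom), function(cn) {
      sel <- A$intervals$chrom == cn
      lens <- A$intervals$end[sel] - A$intervals$start[sel]
      m <- .place_lengths(lens, sz[[cn]], allow_overlap = allow_overlap,
                          max_retries = max_retries)
      data.frame(chrom = rep(cn, nrow(m)), start = m[, "start"],
                 end = m[, "end"], stringsAsFactors = FALSE)
    })
    df <- if (length(pieces)) do.call(rbind, pieces) else A$intervals
    cluster_set(df, A$genome, protein = A$protein)
  })
}

#' One-tailed Fisher's exact test on a base-count overlap table
#'
#' Builds the 2x2 table `a = |A intersect B|`, `b = |A| - a`,
#' `c = |B| - a`, `d = G - a - b - c` (cells sum to the genome length `G`)
#' and returns the exact hypergeometric upper tail `P(X >= a)` with margins
#' fixed — the one-tailed test in the enrichment direction.
#'
#' @param observed_bp Observed overlap in bases.
#' @param bases_a,bases_b Footprint sizes of the two sets in bases.
#' @param genome_length Total genome length in bases.
#' @return The one-tailed p-value.
#' @seealso [fisher_colocalization_test()] for the set-level interface.
#' @export
fisher_overlap_p <- function(observed_bp, bases_a, bases_b, genome_length) {
  a <- observed_bp
  b <- bases_a - a
  cc <- bases_b - a
  d <- genome_length - a - b - cc
  if (any(c(a, b, cc, d) < 0)) {
    .stopf("inconsistent 2x2 table (a=%g b=%g c=%g d=%g): negative cell",
           a, b, cc, d)
  }
  stats::phyper(a - 1, bases_a, genome_length - bases_a, bases_b,
                lower.tail = FALSE)
}

#' @rdname fisher_overlap_p
#' @param A,B `cluster_set` or `feature_set` objects on the same genome.
#' @export
fisher_colocalization_test <- function(A, B) {
  a <- .as_footprint(A)
  b <- .as_footprint(B)
  .check_same_genome(a$genome, b$genome)
  fisher_overlap_p(overlap_bases(A, B),
                   sum(a$intervals$end - a$intervals$start),
                   sum(b$intervals$end - b$intervals$start),
                   a$genome$total_length)
}

# Per-chromosome scaffold used by the Monte-Carlo loop: for every
# chromosome carrying clusters from either set, the merged intervals and
# lengths of both sets plus the chromosome size.
.mc_scaffold <- function(a, b, sz) {
  chroms <- union(unique(a$intervals$chrom), unique(b$intervals$chrom))
  lapply(chroms, function(cn) {
    sa <- a$intervals$chrom == cn
    sb <- b$intervals$chrom == cn
    list(G = sz[[cn]],
         sA = a$intervals$start[sa], eA = a$intervals$end[sa],
         lenA = a$intervals$end[sa] - a$intervals$start[sa],
         sB = b$intervals$start[sb], eB = b$intervals$end[sb],
         lenB = b$intervals$end[sb] - b$intervals$start[sb])
  })
}

# Score one Monte-Carlo iteration on the scaffold.
.mc_score_once <- function(sc, randomize, allow_overlap, max_retries) {
  score <- 0
  for (ch in sc) {
    if (randomize %in% c("a", "both") && length(ch$lenA)) {
      m <- .place_lengths(ch$lenA, ch$G, allow_overlap, max_retries)
      if (allow_overlap && nrow(m) > 1L) m <- .iv_merge1(m[, 1L], m[, 2L])
      sA <- m[, 1L]; eA <- m[, 2L]
    } else {
      sA <- ch$sA; eA <- ch$eA
    }
    if (randomize %in% c("b", "both") && length(ch$lenB)) {
      m <- .place_lengths(ch$lenB, ch$G, allow_overlap, max_retries)
      if (allow_overlap && nrow(m) > 1L) m <- .iv_merge1(m[, 1L], m[, 2L])
      sB <- m[, 1L]; eB <- m[, 2L]
    } else {
      sB <- ch$sB; eB <- ch$eB
    }
    if (!length(sA) || !length(sB)) next
    u <- .iv_union_bp2(sA, eA, sB, eB)
    score <- score + sum(eA - sA) + sum(eB - sB) - u
  }
  score
}

#' Monte-Carlo co-localization test between two cluster sets
#'
#' Scores the observed base overlap between `A` and `B`, then builds a null
#' distribution by randomizing the placement of one set (default `A`) and
#' rescoring `n_iterations` times. The empirical p-value is the add-one
#' estimator `(1 + #{null >= observed}) / (n_iterations + 1)`; ties count
#' as at least as extreme, and p is never 0. The one-tailed Fisher's exact
#' p on the base-count table is computed alongside.
#'
#' @param A,B `cluster_set` objects on the same genome (feature sets are
#'   accepted and treated as footprints).
#' @param n_iterations Number of randomization iterations (default 1000).
#' @param seed Seed for the randomization; results are bit-reproducible
#'   given the seed.
#' @param randomize Which set to randomize per iteration: `"a"` (default),
#'   `"b"`, or `"both"`.
#' @param allow_overlap Passed to the placement sampler (see
#'   [randomize_placement()]).
#' @param max_retries Rejection-sampling attempts per chromosome.
#' @return Object of class `coloc_result`: observed and expected (null
#'   mean) overlap in bp, fold, `empirical_p`, `fisher_p`, the null scores,
#'   `n_iterations` and `seed`.
#' @export
monte_carlo_colocalization <- function(A, B, n_iterations = 1000L,
                                       seed = NULL,
                                       randomize = c("a", "b", "both"),
                                       allow_overlap = FALSE,
                                       max_retries = 1000L) {
  randomize <- match.arg(randomize)
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    .stopf("n_iterations must be >= 1")
  }
  n_iterations <- as.integer(n_iterations)
  a <- .as_footprint(A)
  b <- .as_footprint(B)
  .check_same_genome(a$genome, b$genome)
  observed <- overlap_bases(A, B)
  sc <- .mc_scaffold(a, b, chrom_sizes(a$genome))
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      .mc_score_once(sc, randomize, allow_overlap, max_retries)
    }, numeric(1L))
  })
  expected <- mean(null_scores)
  structure(
    list(
      protein_a = a$label, protein_b = b$label,
      observed_overlap_bp = observed,
      expected_overlap_bp = expected,
      fold = if (expected > 0) observed / expected else NA_real_,
      empirical_p = (1 + sum(null_scores >= observed)) / (n_iterations + 1),
      fisher_p = fisher_colocalization_test(A, B),
      null_scores = null_scores,
      n_iterations = n_iterations,
      seed = if (is.null(seed)) NA_real_ else seed,
      randomized = randomize
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s vs %s\n", x$protein_a, x$protein_b))
  cat(sprintf("  observed overlap : %s bp\n",
              format(x$observed_overlap_bp, big.mark = ",")))
  cat(sprintf("  null mean overlap: %.1f bp (%d iterations, set '%s' randomized)\n",
              x$expected_overlap_bp, x$n_iterations, x$randomized))
  cat(sprintf("  fold             : %.3f\n", x$fold))
  cat(sprintf("  empirical p      : %.4g\n", x$empirical_p))
  cat(sprintf("  Fisher p (1-tail): %.4g\n", x$fisher_p))
  invisible(x)
}

#' @export
as_report_row.coloc_result <- function(x) {
  data.frame(
    analysis = "colocalization",
    proteins = paste(x$protein_a, x$protein_b, sep = "|"),
    feature_class = NA_character_,
    observed_bp = x$observed_overlap_bp,
    expected_bp = x$expected_overlap_bp,
    fold = x$fold,
    empirical_p = x$empirical_p,
    fisher_p = x$fisher_p,
    n_iterations = x$n_iterations,
    seed = x$seed,
    stringsAsFactors = FALSE
  )
}
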