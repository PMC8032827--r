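# Fold increase of a protein's clusters at a feature class versus random
# binding, discrete-feature binding calls, and multi-protein co-occupancy
# tables over a feature class.

#' Fold increase of a cluster set at a feature class
#'
#' The observed quantity is the base overlap between the clusters and the
#' feature-class footprint. "Expected for random binding" is either the
#' analytic independence expectation `|A| * |F| / G` (default) or the mean
#' of a Monte-Carlo null that randomizes the cluster placements; fold is
#' observed / expected. A one-tailed Fisher's exact p accompanies either
#' mode; Monte-Carlo mode also yields an empirical p.
#'
#' The secondary `unit = "features"` mode works on discrete feature counts:
#' observed is the fraction of features bound (see [bound_features()]) and
#' the expectation comes from the Monte-Carlo null (Monte-Carlo mode only).
#'
#' @param A A `cluster_set`.
#' @param F A `feature_set`.
#' @param mode `"analytic"` or `"montecarlo"` expectation.
#' @param n_iterations,seed Monte-Carlo parameters (montecarlo mode).
#' @param unit `"bases"` (default) or `"features"`.
#' @param min_overlap_bp Binding threshold for `unit = "features"`.
#' @param flank Extend each feature by this many bp on both sides (clipped
#'   to the chromosome) before computing overlap. Default 0: feature bodies
#'   only.
#' @return Object of class `fold_result`.
#' @export
fold_increase <- function(A, F, mode = c("analytic", "montecarlo"),
                          n_iterations = 1000L, seed = NULL,
                          unit = c("bases", "features"),
                          min_overlap_bp = 1L, flank = 0L) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  stopifnot(inherits(A, "cluster_set"), inherits(F, "feature_set"))
  .check_same_genome(A$genome, F$genome)
  if (nrow(A$intervals) == 0L || nrow(F$features) == 0L) {
    .stopf("undefined fold: empty %s",
           if (nrow(A$intervals) == 0L) "cluster set" else "feature set")
  }
  Fuse <- if (flank > 0) .flank_features(F, flank) else F
  G <- A$genome$total_length
  empirical_p <- NA_real_
  if (unit == "bases") {
    observed <- overlap_bases(A, Fuse)
    fisher_p <- fisher_colocalization_test(A, Fuse)
    if (mode == "analytic") {
      expected <- total_bases(A) * total_bases(Fuse) / G
    } else {
      mc <- monte_carlo_colocalization(A, Fuse, n_iterations = n_iterations,
                                       seed = seed, randomize = "a")
      expected <- mc$expected_overlap_bp
      empirical_p <- mc$empirical_p
    }
  } else {
    if (mode != "montecarlo") {
      .stopf("unit = \"features\" requires mode = \"montecarlo\"")
    }
    nf <- nrow(Fuse$features)
    obs_count <- bound_features(A, Fuse, min_overlap_bp)$count
    observed <- obs_count / nf
    null_frac <- with_seed(seed, vapply(seq_len(n_iterations), function(i) {
      bound_features(randomize_placement(A), Fuse, min_overlap_bp)$count / nf
    }, numeric(1L)))
    expected <- mean(null_frac)
    empirical_p <- (1 + sum(null_frac >= observed)) / (n_iterations + 1)
    fisher_p <- fisher_colocalization_test(A, Fuse)
  }
  structure(
    list(
      protein = A$protein, feature_class = F$class_label, unit = unit,
      observed = observed, expected = expected, expectation_mode = mode,
      fold = if (expected > 0) observed / expected else NA_real_,
      fisher_p = fisher_p, empirical_p = empirical_p,
      n_iterations = if (mode == "montecarlo") as.integer(n_iterations) else NA_integer_,
      seed = if (is.null(seed)) NA_real_ else seed
    ),
    class = "fold_result"
  )
}

.flank_features <- function(F, flank) {
  sz <- chrom_sizes(F$genome)
  df <- F$features
  df$start <- pmax(0, df$start - flank)
  df$end <- pmin(sz[df$chrom], df$end + flank)
  feature_set(df, F$genome, class_label = F$class_label)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s at %s (%s, %s expectation)\n",
              x$protein, x$feature_class, x$unit, x$expectation_mode))
  cat(sprintf("  observed %.4g, expected %.4g, fold %.3f\n",
              x$observed, x$expected, x$fold))
  cat(sprintf("  Fisher p %.4g%s\n", x$fisher_p,
              if (is.na(x$empirical_p)) ""
              else sprintf(", empirical p %.4g", x$empirical_p)))
  invisible(x)
}

#' @export
as_report_row.fold_result <- function(x) {
  data.frame(
    analysis = paste0("fold_increase_", x$unit),
    proteins = x$protein,
    feature_class = x$feature_class,
    observed_bp = x$observed,
    expected_bp = x$expected,
    fold = x$fold,
    empirical_p = x$empirical_p,
    fisher_p = x$fisher_p,
    n_iterations = ifelse(is.na(x$n_iterations), NA_real_,
                          as.numeric(x$n_iterations)),
    seed = x$seed,
    stringsAsFactors = FALSE
  )
}

#' Which discrete features are bound by a cluster set
#'
#' A feature is bound iff its interval overlaps the cluster footprint by at
#' least `min_overlap_bp` bases (default 1 bp — the weakest defensible
#' criterion; surface it when you need a stricter one).
#'
#' @param A A `cluster_set`.
#' @param F A `feature_set`.
#' @param min_overlap_bp Minimum overlap in bp to call a feature bound.
#' @return List with `ids` (sorted bound feature ids), `count`, and
#'   `overlap_bp` (named per-feature overlap for all features).
#' @export
bound_features <- function(A, F, min_overlap_bp = 1L) {
  stopifnot(inherits(A, "cluster_set"), inherits(F, "feature_set"))
  .check_same_genome(A$genome, F$genome)
  if (min_overlap_bp < 1) .stopf("min_overlap_bp must be >= 1")
  ov <- numeric(nrow(F$features))
  for (cn in unique(F$features$chrom)) {
    fi <- which(F$features$chrom == cn)
    sel <- A$intervals$chrom == cn
    s <- A$intervals$start[sel]
    e <- A$intervals$end[sel]
    ov[fi] <- .iv_cov_upto(F$features$end[fi], s, e) -
      .iv_cov_upto(F$features$start[fi], s, e)
  }
  names(ov) <- F$features$id
  bound <- ov >= min_overlap_bp
  list(ids = sort(F$features$id[bound]), count = sum(bound), overlap_bp = ov)
}

#' Co-occupancy of a feature class across several proteins
#'
#' Calls [bound_features()] for every protein, then counts features in
#' every protein combination (each feature is assigned to the exact subset
#' of proteins binding it, including `"none"`), with percentages of the
#' total feature count. Percentages are raw reals; rounding is the
#' caller's concern.
#'
#' @param sets List of `cluster_set` objects; protein labels must be
#'   unique (names of the list override the sets' own labels).
#' @param F A `feature_set`.
#' @param min_overlap_bp Binding threshold passed to [bound_features()].
#' @return Object of class `cooccupancy_matrix`: `bound` (features x
#'   proteins logical matrix), `combinations` (data frame `combination`,
#'   `count`, `percent` over all 2^k subsets), `n_features`,
#'   `class_label`.
#' @examples
#' # the in-text arithmetic: 56 of 71 TERs bound by both of two proteins
#' # gives a both-bound percentage of 100 * 56 / 71 = 78.87
#' @export
cooccupancy <- function(sets, F, min_overlap_bp = 1L) {
  stopifnot(is.list(sets), length(sets) >= 1L, inherits(F, "feature_set"))
  labels <- if (!is.null(names(sets)) && all(nzchar(names(sets)))) {
    names(sets)
  } else {
    vapply(sets, function(s) s$protein, character(1L))
  }
  if (anyDuplicated(labels)) {
    .stopf("duplicate protein labels: %s", labels[duplicated(labels)][1L])
  }
  if (nrow(F$features) == 0L) .stopf("empty feature set")
  bound <- vapply(sets, function(s) {
    bf <- bound_features(s, F, min_overlap_bp)
    bf$overlap_bp >= min_overlap_bp
  }, logical(nrow(F$features)))
  bound <- matrix(bound, nrow = nrow(F$features),
                  dimnames = list(F$features$id, labels))
  k <- length(labels)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  combo_label <- apply(subsets, 1L, function(m) {
    if (!any(m)) "none" else paste(labels[as.logical(m)], collapse = "+")
  })
  sig <- apply(bound, 1L, function(r) paste(as.integer(r), collapse = ""))
  subset_sig <- apply(subsets, 1L, function(m) {
    paste(as.integer(m), collapse = "")
  })
  counts <- vapply(subset_sig, function(s) sum(sig == s), numeric(1L))
  combos <- data.frame(
    combination = combo_label,
    count = counts,
    percent = 100 * counts / nrow(F$features),
    stringsAsFactors = FALSE
  )
  rownames(combos) <- NULL
  structure(
    list(bound = bound, combinations = combos,
         n_features = nrow(F$features), class_label = F$class_label,
         min_overlap_bp = min_overlap_bp),
    class = "cooccupancy_matrix"
  )
}

#' @export
print.cooccupancy_matrix <- function(x, ...) {
  cat(sprintf("<cooccupancy_matrix> %d %s features x %d proteins (>= %d bp overlap)\n",
              x$n_features, x$class_label, ncol(x$bound), x$min_overlap_bp))
  df <- x$combinations
  df$percent <- sprintf("%.2f", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}
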