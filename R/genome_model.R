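# Core data model: genomes, intervals, cluster sets, feature annotations.
# Coordinates are 0-based half-open (BED convention) everywhere internally;
# 1-based fully-closed input must be declared at the reader (see read_bed).
# Strand is ignored throughout: cluster/feature overlap is strand-agnostic.

#' Define a genome as an ordered set of named chromosomes
#'
#' The genome definition is the universe for all interval validation and for
#' the randomization null: randomized clusters stay on their chromosome and
#' starts are drawn uniformly from the positions that keep the interval
#' inside it.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param sizes Integer vector of chromosome lengths in bp (all >= 1).
#' @return An object of class `genome_def` with elements `chromosomes`
#'   (data frame with columns `chrom`, `size`, in input order) and
#'   `total_length` (sum of sizes).
#' @examples
#' g <- genome_def(c("chrI", "chrII"), c(230218, 813184))
#' g$total_length
#' @export
genome_def <- function(chrom, sizes) {
  chrom <- as.character(chrom)
  sizes <- as.numeric(sizes)
  if (length(chrom) == 0L) .stopf("no chromosomes")
  if (length(sizes) != length(chrom)) {
    .stopf("chrom and sizes must have the same length")
  }
  dup <- chrom[duplicated(chrom)]
  if (length(dup)) .stopf("duplicate chromosome name: %s", dup[1L])
  bad <- !is.finite(sizes) | sizes < 1 | sizes != floor(sizes)
  if (any(bad)) {
    .stopf("chromosome %s has invalid length %s (must be a positive integer)",
           chrom[bad][1L], format(sizes[bad][1L]))
  }
  structure(
    list(
      chromosomes = data.frame(chrom = chrom, size = sizes,
                               stringsAsFactors = FALSE),
      total_length = sum(sizes)
    ),
    class = "genome_def"
  )
}

#' Named vector of chromosome sizes
#' @param genome A `genome_def`.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
chrom_sizes <- function(genome) {
  stopifnot(inherits(genome, "genome_def"))
  stats::setNames(genome$chromosomes$size, genome$chromosomes$chrom)
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def> %d chromosomes, %s bp total\n",
              nrow(x$chromosomes),
              format(x$total_length, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

.check_same_genome <- function(g1, g2) {
  if (!identical(chrom_sizes(g1), chrom_sizes(g2))) {
    .stopf("inputs are defined on different genomes")
  }
  invisible(TRUE)
}

# Validate an interval data frame (chrom, start, end[, name/id]) against a
# genome; errors name the offending chromosome and coordinates.
.validate_intervals <- function(df, genome, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (nrow(df) == 0L) return(df)
  sz <- chrom_sizes(genome)
  unknown <- !(df$chrom %in% names(sz))
  if (any(unknown)) {
    .stopf("unknown chromosome '%s' (not in genome definition)",
           df$chrom[unknown][1L])
  }
  nonint <- !is.finite(df$start) | !is.finite(df$end) |
    df$start != floor(df$start) | df$end != floor(df$end)
  if (any(nonint)) {
    i <- which(nonint)[1L]
    .stopf("%s %s:%s-%s has non-integer coordinates", what,
           df$chrom[i], format(df$start[i]), format(df$end[i]))
  }
  bad <- df$start < 0 | df$end > sz[df$chrom] | df$start >= df$end
  if (any(bad)) {
    i <- which(bad)[1L]
    .stopf(
      "%s %s:%d-%d out of bounds or empty (chromosome length %d; need 0 <= start < end <= length)",
      what, df$chrom[i], df$start[i], df$end[i], sz[df$chrom[i]])
  }
  df
}

#' Merge raw intervals into sorted, disjoint interval lists
#'
#' Overlapping and book-ended intervals (end == next start) are merged:
#' clusters are maximal runs of enrichment, and adjacency is an artifact of
#' tiling resolution. The union base count is preserved.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome Optional `genome_def`; when supplied, intervals are
#'   validated against it first.
#' @return Data frame with columns `chrom`, `start`, `end`, sorted by
#'   chromosome (genome order when a genome is supplied) then start, with
#'   pairwise disjoint, non-adjacent intervals per chromosome.
#' @examples
#' merge_intervals(data.frame(chrom = "c1", start = c(100, 150),
#'                            end = c(200, 250)))
#' @export
merge_intervals <- function(intervals, genome = NULL) {
  if (!is.null(genome)) {
    intervals <- .validate_intervals(intervals, genome)
    chrom_order <- genome$chromosomes$chrom
  } else {
    stopifnot(is.data.frame(intervals),
              all(c("chrom", "start", "end") %in% names(intervals)))
    intervals$chrom <- as.character(intervals$chrom)
    intervals$start <- as.numeric(intervals$start)
    intervals$end <- as.numeric(intervals$end)
    if (nrow(intervals) && any(intervals$start >= intervals$end)) {
      .stopf("empty or reversed interval (start >= end)")
    }
    chrom_order <- unique(intervals$chrom)
  }
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  pieces <- lapply(intersect(chrom_order, unique(intervals$chrom)), function(cn) {
    sel <- intervals$chrom == cn
    m <- .iv_merge1(intervals$start[sel], intervals$end[sel])
    data.frame(chrom = rep(cn, nrow(m)), start = m[, "start"],
               end = m[, "end"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Construct a protein cluster set
#'
#' A cluster set holds one protein's chromatin-binding clusters as
#' per-chromosome sorted, disjoint intervals (merged on construction).
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param genome A `genome_def` the intervals must be valid against.
#' @param protein Label for the protein (e.g. `"Top3-Flag"`).
#' @return Object of class `cluster_set`: list with `protein`, `intervals`
#'   (merged data frame) and `genome`.
#' @export
cluster_set <- function(intervals, genome, protein = "protein") {
  stopifnot(inherits(genome, "genome_def"), is.character(protein),
            length(protein) == 1L)
  merged <- merge_intervals(intervals, genome)
  structure(list(protein = protein, intervals = merged, genome = genome),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %s: %d clusters, %s bp (%.3f%% of genome)\n",
              x$protein, nrow(x$intervals),
              format(total_bases(x), big.mark = ","),
              100 * total_bases(x) / x$genome$total_length))
  invisible(x)
}

#' Total genomic footprint of a set, in bases
#'
#' For a `cluster_set` this is the sum of (disjoint) interval lengths; for a
#' `feature_set` it is the merged footprint of all features (features of a
#' class may touch, so raw widths can overcount).
#'
#' @param x A `cluster_set` or `feature_set`.
#' @return Number of bases covered (0 for an empty set).
#' @export
total_bases <- function(x) UseMethod("total_bases")

#' @export
total_bases.cluster_set <- function(x) {
  sum(x$intervals$end - x$intervals$start)
}

#' @export
total_bases.feature_set <- function(x) {
  m <- merge_intervals(x$features[, c("chrom", "start", "end")])
  sum(m$end - m$start)
}

.FEATURE_CLASSES <- c("tRNA", "CEN", "TER", "ARS", "other")

#' Construct a labeled feature annotation set
#'
#' Holds one class of discrete annotated elements (tRNA genes, centromeres,
#' replication termination regions, ARS, or other) with stable per-feature
#' ids. Features are validated but not merged, so each element keeps its
#' identity for co-occupancy counting.
#'
#' @param features Data frame with columns `chrom`, `start`, `end` and
#'   optionally `id` (unique; generated as `<class>_001`... when absent).
#' @param genome A `genome_def`.
#' @param class_label One of `"tRNA"`, `"CEN"`, `"TER"`, `"ARS"`, `"other"`.
#' @return Object of class `feature_set`: list with `class_label`,
#'   `features` (data frame `id`, `chrom`, `start`, `end`) and `genome`.
#' @export
feature_set <- function(features, genome, class_label = "other") {
  class_label <- match.arg(class_label, .FEATURE_CLASSES)
  df <- .validate_intervals(features, genome, what = "feature")
  if (!"id" %in% names(df)) {
    df$id <- sprintf("%s_%03d", class_label, seq_len(nrow(df)))
  }
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) .stopf("duplicate feature id: %s", dup[1L])
  df <- df[, c("id", "chrom", "start", "end")]
  rownames(df) <- NULL
  structure(list(class_label = class_label, features = df, genome = genome),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d features, %s bp footprint\n",
              x$class_label, nrow(x$features),
              format(total_bases(x), big.mark = ",")))
  invisible(x)
}

# Coerce a cluster_set or feature_set to its merged genomic footprint:
# list(intervals = merged df, genome, label).
.as_footprint <- function(x) {
  if (inherits(x, "cluster_set")) {
    list(intervals = x$intervals, genome = x$genome, label = x$protein)
  } else if (inherits(x, "feature_set")) {
    list(intervals = merge_intervals(x$features[, c("chrom", "start", "end")]),
         genome = x$genome, label = x$class_label)
  } else {
    .stopf("expected a cluster_set or feature_set, got %s", class(x)[1L])
  }
}
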