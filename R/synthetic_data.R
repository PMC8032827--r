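# Seeded generators for every input the pipeline consumes: genomes,
# feature annotations (TER / CEN / tRNA / ARS), protein cluster sets with a
# controllable co-localization parameter, labeled EM joint-molecule records
# and qPCR Ct tables. All generators are pure functions of their arguments
# and the seed, and every artifact passes the corresponding module's
# validators.

# S. cerevisiae (sacCer3) nuclear chromosome lengths; used as the length
# profile for the default 16-chromosome synthetic genome so per-chromosome
# cluster densities are realistic.
.SC_CHROM_BP <- c(
  chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
  chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
  chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
  chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066
)

#' Generate a synthetic genome definition
#'
#' Defaults emulate the budding-yeast nuclear genome: 16 chromosomes, 12 Mb
#' total, with the real chromosome length profile scaled to the requested
#' total. With other chromosome counts (or `randomize_lengths = TRUE`)
#' chromosome proportions are drawn from a gamma profile.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param total_length Total genome length in bp.
#' @param randomize_lengths Draw chromosome proportions at random instead
#'   of using the fixed profile.
#' @param seed Seed (needed only when `randomize_lengths = TRUE`).
#' @return A [genome_def()].
#' @export
make_genome <- function(n_chromosomes = 16L, total_length = 12e6,
                        randomize_lengths = FALSE, seed = NULL) {
  if (n_chromosomes < 1L) .stopf("zero chromosomes")
  props <- if (randomize_lengths) {
    with_seed(seed, {
      w <- stats::rgamma(n_chromosomes, shape = 5)
      w / sum(w)
    })
  } else if (n_chromosomes == 16L) {
    .SC_CHROM_BP / sum(.SC_CHROM_BP)
  } else {
    rep(1 / n_chromosomes, n_chromosomes)
  }
  sizes <- floor(total_length * props)
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] +
    (total_length - sum(sizes))
  names <- paste0("chr", as.character(utils::as.roman(seq_len(n_chromosomes))))
  genome_def(names, sizes)
}

.DEFAULT_FEATURE_SPECS <- list(
  TER = list(n = 71L, length_range = c(2000, 8000)),
  CEN = list(n = 16L, length_range = c(120, 120), one_per_chromosome = TRUE),
  tRNA = list(n = 275L, length_range = c(70, 100))
)

#' Place synthetic feature annotations on a genome
#'
#' Defaults mirror the annotated pausing-site classes of budding yeast: 71
#' replication termination regions (2-8 kb), one ~120 bp centromere per
#' chromosome, and 275 tRNA genes (70-100 bp). All features (across
#' classes) are placed mutually non-overlapping; non-CEN features land on a
#' chromosome with probability proportional to its length.
#'
#' @param genome A `genome_def`.
#' @param class_specs Named list per class: `n`, `length_range` (uniform
#'   length draw), optional `one_per_chromosome`. Class names must be valid
#'   feature classes.
#' @param seed Seed.
#' @param max_retries Placement attempts per feature before giving up.
#' @return Named list of [feature_set()] objects.
#' @export
place_features <- function(genome, class_specs = NULL, seed = NULL,
                           max_retries = 1000L) {
  if (is.null(class_specs)) class_specs <- .DEFAULT_FEATURE_SPECS
  stopifnot(inherits(genome, "genome_def"))
  sz <- chrom_sizes(genome)
  with_seed(seed, {
    occupied <- lapply(sz, function(G) cbind(start = numeric(0),
                                             end = numeric(0)))
    out <- list()
    for (cls in names(class_specs)) {
      spec <- class_specs[[cls]]
      n <- spec$n
      lr <- spec$length_range
      one_per <- isTRUE(spec$one_per_chromosome)
      if (one_per && n != length(sz)) {
        .stopf("%s: one_per_chromosome requires n == number of chromosomes",
               cls)
      }
      chrom <- character(n)
      start <- numeric(n)
      end <- numeric(n)
      for (i in seq_len(n)) {
        len <- floor(stats::runif(1L, lr[1L], lr[2L] + 1))
        cn <- if (one_per) names(sz)[i] else {
          sample(names(sz), 1L, prob = sz)
        }
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          s <- floor(stats::runif(1L) * (sz[[cn]] - len + 1))
          occ <- occupied[[cn]]
          if (!nrow(occ) ||
              all(s + len <= occ[, "start"] | s >= occ[, "end"])) {
            occupied[[cn]] <- rbind(occ, cbind(start = s, end = s + len))
            chrom[i] <- cn
            start[i] <- s
            end[i] <- s + len
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          .stopf("%s: could not place feature %d disjointly (density too high)",
                 cls, i)
        }
      }
      ids <- sprintf("%s%03d", cls, seq_len(n))
      lab <- if (cls %in% .FEATURE_CLASSES) cls else "other"
      out[[cls]] <- feature_set(
        data.frame(id = ids, chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE),
        genome, class_label = lab)
    }
    out
  })
}

# midpoints (chrom, mid) of the anchoring set
.anchor_midpoints <- function(anchors) {
  f <- .as_footprint(anchors)
  df <- if (inherits(anchors, "feature_set")) {
    anchors$features
  } else {
    anchors$intervals
  }
  data.frame(chrom = df$chrom, mid = floor((df$start + df$end) / 2),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic protein cluster set
#'
#' Cluster lengths are log-normal (median `length_median`, log-sd
#' `length_log_sd`). A fraction `anchor_fraction` of clusters is centered
#' on anchor midpoints (feature bodies, or a partner protein's clusters)
#' plus Gaussian positional jitter — this creates exactly the base-overlap
#' signal the co-localization score measures, with one interpretable knob.
#' The remaining clusters are placed uniformly, chromosome chosen with
#' probability proportional to its length. Everything is clipped to
#' chromosome bounds and merged.
#'
#' When the number of anchored clusters is at least the number of available
#' anchors, anchors are recycled so each is used at least once; otherwise a
#' random subset of anchors (without replacement) is used.
#'
#' @param genome A `genome_def`.
#' @param n_clusters Number of clusters before merging.
#' @param length_median Median cluster length in bp.
#' @param length_log_sd Log-scale sd of the cluster length distribution.
#' @param anchors Optional `feature_set` or `cluster_set` supplying anchor
#'   midpoints.
#' @param anchor_fraction Fraction of clusters anchored, in \[0, 1\].
#' @param jitter_sd Gaussian sd (bp) of anchored cluster centers around the
#'   anchor midpoint.
#' @param protein Protein label.
#' @param seed Seed.
#' @return A [cluster_set()].
#' @export
make_cluster_set <- function(genome, n_clusters = 300L,
                             length_median = 1000, length_log_sd = 0.5,
                             anchors = NULL, anchor_fraction = 0,
                             jitter_sd = 0, protein = "protein",
                             seed = NULL) {
  stopifnot(inherits(genome, "genome_def"),
            anchor_fraction >= 0, anchor_fraction <= 1)
  if (anchor_fraction > 0 && is.null(anchors)) {
    .stopf("anchor_fraction > 0 requires anchors")
  }
  sz <- chrom_sizes(genome)
  with_seed(seed, {
    lens <- pmax(1, round(stats::rlnorm(n_clusters, log(length_median),
                                        length_log_sd)))
    n_anchor <- round(anchor_fraction * n_clusters)
    chrom <- character(n_clusters)
    start <- numeric(n_clusters)
    if (n_anchor > 0L) {
      mids <- .anchor_midpoints(anchors)
      idx <- if (n_anchor >= nrow(mids)) {
        rep_len(seq_len(nrow(mids)), n_anchor)
      } else {
        sample.int(nrow(mids), n_anchor)
      }
      centers <- mids$mid[idx] +
        if (jitter_sd > 0) round(stats::rnorm(n_anchor, 0, jitter_sd)) else 0
      chrom[seq_len(n_anchor)] <- mids$chrom[idx]
      start[seq_len(n_anchor)] <- round(centers - lens[seq_len(n_anchor)] / 2)
    }
    if (n_anchor < n_clusters) {
      rest <- (n_anchor + 1L):n_clusters
      chrom[rest] <- sample(names(sz), length(rest), replace = TRUE,
                            prob = sz)
      start[rest] <- floor(stats::runif(length(rest)) *
                             (sz[chrom[rest]] - lens[rest] + 1))
    }
    lens <- pmin(lens, sz[chrom])
    start <- pmin(pmax(start, 0), sz[chrom] - lens)
    cluster_set(data.frame(chrom = chrom, start = start, end = start + lens,
                           stringsAsFactors = FALSE),
                genome, protein = protein)
  })
}

# noise-free branch geometries per category; each satisfies exactly its
# defining rule at the default 5% tolerance (cross-category length ratios
# keep a wide margin from the tolerance boundary)
.jm_geometry <- function(category) {
  switch(category,
    linear = list(nj = 0L, b = stats::runif(2L, 500, 3000)),
    fork = list(nj = 1L, b = stats::runif(3L, 200, 2000)),
    bubble = list(nj = 2L, b = stats::runif(3L, 200, 2000)),
    dHJ = list(nj = 2L, b = stats::runif(4L, 200, 2000)),
    reversed_fork = {
      d <- stats::runif(1L, 600, 1200)         # equal daughter arms
      r <- d * stats::runif(1L, 0.2, 0.8)      # regressed arm <= daughters
      p <- d * stats::runif(1L, 1.3, 2.0)      # parent arm, clearly longer
      list(nj = 1L, b = c(d, d, p, r))
    },
    hemicatenane = {
      # two through-going filaments of the same total length L, crossed at
      # interior points; no branch pair is equal within tolerance
      L <- stats::runif(1L, 1500, 2500)
      x <- L * stats::runif(1L, 0.08, 0.22)
      y <- L * stats::runif(1L, 0.32, 0.46)
      list(nj = 1L, b = c(x, L - x, y, L - y))
    },
    unclassified = {
      L <- stats::runif(1L, 1000, 3000)
      list(nj = 1L, b = L * c(0.10, 0.20, 0.37, 0.62))
    },
    .stopf("unknown JM category: %s", category)
  )
}

#' Generate labeled synthetic joint-molecule records
#'
#' At `noise_sd = 0` every record's geometry satisfies exactly its
#' category's defining rule, so the classifier recovers the labels
#' perfectly; `noise_sd > 0` applies multiplicative log-normal noise to
#' each branch length.
#'
#' @param n_per_category Named counts, names among `linear`, `fork`,
#'   `bubble`, `dHJ`, `reversed_fork`, `hemicatenane`, `unclassified`.
#' @param genotype Genotype label for all records.
#' @param noise_sd Log-scale sd of multiplicative branch-length noise.
#' @param seed Seed.
#' @param start_id First molecule number (for concatenating genotypes).
#' @return JM record data frame with a `true_category` column.
#' @export
make_jm_records <- function(n_per_category = c(fork = 60L, bubble = 20L,
                                               reversed_fork = 5L, dHJ = 5L,
                                               hemicatenane = 8L,
                                               unclassified = 2L),
                            genotype = "WT", noise_sd = 0, seed = NULL,
                            start_id = 1L) {
  bad <- setdiff(names(n_per_category), c("linear", .JM_CATEGORIES))
  if (length(bad)) .stopf("unknown JM category: %s", bad[1L])
  with_seed(seed, {
    cats <- rep(names(n_per_category), times = n_per_category)
    n <- length(cats)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- .jm_geometry(cats[i])
      b <- g$b
      if (noise_sd > 0) b <- b * exp(stats::rnorm(length(b), 0, noise_sd))
      b4 <- rep(NA_real_, 4L)
      b4[seq_along(b)] <- round(b, 1L)
      rows[[i]] <- data.frame(
        molecule_id = sprintf("%s_%04d", genotype, start_id + i - 1L),
        genotype = genotype, n_junctions = g$nj,
        branch1_nm = b4[1L], branch2_nm = b4[2L], branch3_nm = b4[3L],
        branch4_nm = b4[4L], n_branches = length(b),
        true_category = cats[i], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Joint-molecule category mixes emulating unperturbed vs mutant profiles
#'
#' Convenience count vectors for [make_jm_records()]: the unperturbed
#' profile is dominated by forks and bubbles with ~1% reversed forks, no
#' dHJs and a low hemicatenane level; the mutant profile carries 5-8%
#' reversed forks, 7-9% dHJs and elevated hemicatenanes, as seen when STR
#' or Smc5/6 function is lost.
#'
#' @param profile `"unperturbed"` or `"mutant"`.
#' @param n Total molecule count.
#' @return Named integer vector of per-category counts summing to `n`.
#' @export
jm_profile <- function(profile = c("unperturbed", "mutant"), n = 200L) {
  profile <- match.arg(profile)
  frac <- switch(profile,
    unperturbed = c(fork = 0.64, bubble = 0.25, reversed_fork = 0.01,
                    dHJ = 0, hemicatenane = 0.06, unclassified = 0.04),
    mutant = c(fork = 0.48, bubble = 0.15, reversed_fork = 0.06,
               dHJ = 0.08, hemicatenane = 0.16, unclassified = 0.07)
  )
  counts <- round(n * frac)
  counts["fork"] <- counts["fork"] + (n - sum(counts))
  counts
}

#' Generate a synthetic ChIP-qPCR Ct table with known truth
#'
#' Inverts the percent-input formula: for each replicate an input Ct is
#' drawn around `ct_input_base` and the IP Ct is set so that the replicate's
#' true percent input equals the requested value, before adding independent
#' Gaussian Ct noise to both wells. At `ct_noise_sd = 0`,
#' [percent_input_table()] recovers the truth exactly.
#'
#' @param truth Data frame with columns `target_region`, `strain`,
#'   `percent_input` (> 0).
#' @param ct_input_base Mean input Ct.
#' @param input_dilution Fraction of chromatin used as input.
#' @param n_replicates Replicates per (target, strain).
#' @param ct_noise_sd Gaussian sd added to each Ct value.
#' @param seed Seed.
#' @return Long qPCR table (one IP row and one input row per replicate)
#'   with a `true_percent_input` column.
#' @export
make_qpcr_table <- function(truth, ct_input_base = 20,
                            input_dilution = 0.01, n_replicates = 3L,
                            ct_noise_sd = 0, seed = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("target_region", "strain", "percent_input") %in%
                  names(truth)),
            all(truth$percent_input > 0))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      for (r in seq_len(n_replicates)) {
        ct_in <- ct_input_base + stats::rnorm(1L, 0, ct_noise_sd)
        ct_ip <- (ct_input_base - log2(input_dilution)) -
          log2(truth$percent_input[i] / 100) +
          stats::rnorm(1L, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          target_region = rep(truth$target_region[i], 2L),
          strain = rep(truth$strain[i], 2L),
          replicate = rep(r, 2L),
          role = c("IP", "input"),
          Ct = c(ct_ip, ct_in),
          input_dilution = rep(input_dilution, 2L),
          true_percent_input = rep(truth$percent_input[i], 2L),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
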