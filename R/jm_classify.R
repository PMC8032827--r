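# Rule-based classification of psoralen-EM DNA molecules into replication
# intermediates and joint molecules (JMs) from branch-length records, plus
# nm <-> bp calibration and per-genotype frequency tables.
#
# The taxonomy: linear molecules, replication forks (one three-way
# junction), bubbles (two three-way junctions sharing arcs), reversed forks
# (one four-way junction with two equal daughter arms and a regressed arm
# no longer than them), double Holliday Junctions (two four-way junctions
# on one molecule), hemicatenanes (one four-way junction whose branches
# pair into two through-going filaments of the same size), and unclassified
# four-way junctions. Expert visual classification is replaced here by
# explicit geometric rules with a surfaced relative tolerance.

.JM_CATEGORIES <- c("fork", "bubble", "reversed_fork", "dHJ",
                    "hemicatenane", "unclassified")

#' Convert an EM contour length from nanometres to base pairs
#'
#' The default calibration is 500 bp per 180 nm of spread duplex DNA
#' (about 2.778 bp/nm).
#'
#' @param length_nm Length(s) in nm, all >= 0.
#' @param bp_per_nm Calibration constant, strictly positive.
#' @return Length(s) in bp.
#' @examples
#' nm_to_bp(180)  # 500
#' @export
nm_to_bp <- function(length_nm, bp_per_nm = 500 / 180) {
  if (!is.numeric(bp_per_nm) || length(bp_per_nm) != 1L ||
      !is.finite(bp_per_nm) || bp_per_nm <= 0) {
    .stopf("bp_per_nm must be a single positive number")
  }
  if (any(!is.finite(length_nm)) || any(length_nm < 0)) {
    .stopf("lengths must be finite and >= 0")
  }
  length_nm * bp_per_nm
}

# relative difference of two positive lengths, against their mean
.rel_diff <- function(x, y) abs(x - y) / ((x + y) / 2)

#' Classify one molecule from its junction count and branch lengths
#'
#' Deterministic, ordered rules on the record geometry:
#' 1. no junction, two ends: `linear` (excluded from the JM tally);
#' 2. one three-way junction: `fork`;
#' 3. two three-way junctions: `bubble`;
#' 4. two four-way junctions on one molecule: `dHJ` (junction count alone —
#'    no length criterion);
#' 5. one four-way junction with two branches equal within `rel_tol` (the
#'    daughter arms) and the shortest remaining branch (the regressed arm)
#'    no longer than the daughters: `reversed_fork`;
#' 6. one four-way junction whose branches pair into two filaments of
#'    equal total length within `rel_tol` (any of the three pairings),
#'    when rule 5 fails: `hemicatenane`;
#' 7. otherwise `unclassified`.
#'
#' Rules are relative, so classification is invariant to branch-order
#' permutation and to uniform rescaling of all lengths.
#'
#' @param n_junctions Number of junctions on the molecule (0, 1 or 2).
#' @param branch_lengths_nm Positive branch lengths in nm (2, 3 or 4
#'   values; NA entries are dropped).
#' @param n_branches Branch count; defaults to the number of lengths given.
#' @param rel_tol Relative tolerance for "equal" lengths (default 0.05).
#' @return Category string.
#' @examples
#' classify_jm(1, c(800, 800, 1500, 300))  # reversed_fork
#' classify_jm(2, c(700, 900, 1100, 600))  # dHJ
#' @export
classify_jm <- function(n_junctions, branch_lengths_nm,
                        n_branches = NULL, rel_tol = 0.05) {
  b <- branch_lengths_nm[!is.na(branch_lengths_nm)]
  if (is.null(n_branches) || is.na(n_branches)) n_branches <- length(b)
  if (length(b) != n_branches) {
    .stopf("record has %d branch lengths but n_branches = %d",
           length(b), n_branches)
  }
  if (any(b <= 0) || any(!is.finite(b))) {
    .stopf("branch lengths must be positive and finite")
  }
  key <- paste(n_junctions, n_branches)
  if (key == "0 2") return("linear")
  if (key == "1 3") return("fork")
  if (key == "2 3") return("bubble")
  if (key == "2 4") return("dHJ")
  if (key != "1 4") {
    .stopf("branch count %d inconsistent with %d junction(s)",
           n_branches, n_junctions)
  }
  # single four-way junction: resolve by length rules
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                c(2L, 3L), c(2L, 4L), c(3L, 4L))
  for (p in pairs) {
    if (.rel_diff(b[p[1L]], b[p[2L]]) <= rel_tol) {
      rest <- b[-p]
      if (min(rest) <= max(b[p])) return("reversed_fork")
    }
  }
  pairings <- list(list(c(1L, 2L), c(3L, 4L)),
                   list(c(1L, 3L), c(2L, 4L)),
                   list(c(1L, 4L), c(2L, 3L)))
  for (pp in pairings) {
    if (.rel_diff(sum(b[pp[[1L]]]), sum(b[pp[[2L]]])) <= rel_tol) {
      return("hemicatenane")
    }
  }
  "unclassified"
}

#' Classify a table of joint-molecule records
#'
#' @param records Data frame with columns `molecule_id`, `genotype`,
#'   `n_junctions`, `branch1_nm`..`branch4_nm`, `n_branches` (see
#'   [read_jm_records()]).
#' @param rel_tol Relative tolerance passed to [classify_jm()].
#' @return The records with a `category` column appended.
#' @export
classify_jm_records <- function(records, rel_tol = 0.05) {
  stopifnot(is.data.frame(records))
  bcols <- paste0("branch", 1:4, "_nm")
  need <- c("n_junctions", bcols, "n_branches")
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  records$category <- vapply(seq_len(nrow(records)), function(i) {
    classify_jm(records$n_junctions[i],
                unlist(records[i, bcols], use.names = FALSE),
                records$n_branches[i], rel_tol = rel_tol)
  }, character(1L))
  records
}

#' Per-genotype frequency table of intermediate categories
#'
#' Linear molecules are excluded from the tally; percentages per genotype
#' are over that genotype's analysed molecule count `n` and sum to 100.
#'
#' @param records JM records; classified first with [classify_jm_records()]
#'   (using `rel_tol`) if no `category` column is present.
#' @param rel_tol Relative tolerance for classification, when needed.
#' @return Data frame with columns `genotype`, `n`, `category`, `count`,
#'   `percent` (one row per genotype x category).
#' @export
tabulate_jm <- function(records, rel_tol = 0.05) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!"category" %in% names(records)) {
    records <- classify_jm_records(records, rel_tol = rel_tol)
  }
  records <- records[records$category != "linear", , drop = FALSE]
  if (nrow(records) == 0L) .stopf("no non-linear molecules to tabulate")
  out <- do.call(rbind, lapply(unique(records$genotype), function(g) {
    sub <- records[records$genotype == g, , drop = FALSE]
    counts <- vapply(.JM_CATEGORIES, function(cc) sum(sub$category == cc),
                     numeric(1L))
    data.frame(genotype = g, n = nrow(sub), category = .JM_CATEGORIES,
               count = counts, percent = 100 * counts / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
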