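# ChIP-qPCR percent-input quantification by the 2^(-dCt) method with
# input-dilution correction, replicate aggregation (mean +/- SEM) and
# unpaired two-tailed t-tests between groups.

#' Percent input from a pair of Ct values
#'
#' `100 * 2^(Ct_input_adjusted - Ct_IP)` where
#' `Ct_input_adjusted = Ct_input - log2(input_dilution)` corrects for the
#' fraction of chromatin used as input. One cycle of delay in the IP halves
#' the percent input.
#'
#' @param ct_ip IP cycle-threshold value(s), finite and > 0.
#' @param ct_input Input cycle-threshold value(s).
#' @param input_dilution Fraction of chromatin used as input, in (0, 1]
#'   (e.g. 0.01 for a 1% input).
#' @return Percent input (vectorized).
#' @examples
#' percent_input(30, 20, 0.01)  # ~9.77
#' @export
percent_input <- function(ct_ip, ct_input, input_dilution) {
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)) ||
      any(ct_ip <= 0) || any(ct_input <= 0)) {
    .stopf("Ct values must be finite and > 0")
  }
  if (any(!is.finite(input_dilution)) || any(input_dilution <= 0) ||
      any(input_dilution > 1)) {
    .stopf("input_dilution must be in (0, 1]")
  }
  adj <- ct_input - log2(input_dilution)
  res <- 100 * 2^(adj - ct_ip)
  if (any(!is.finite(res))) .stopf("non-finite percent input")
  res
}

#' Percent input for every replicate in a long Ct table
#'
#' Pairs the `IP` and `input` rows of each (target_region, strain,
#' replicate) and applies [percent_input()].
#'
#' @param df qPCR table as from [read_qpcr_table()] or [make_qpcr_table()].
#' @return Data frame with columns `target_region`, `strain`, `replicate`,
#'   `percent_input`.
#' @export
percent_input_table <- function(df) {
  need <- c("target_region", "strain", "replicate", "role", "Ct",
            "input_dilution")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  key <- interaction(df$target_region, df$strain, df$replicate, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    ip <- sub[sub$role == "IP", , drop = FALSE]
    inp <- sub[sub$role == "input", , drop = FALSE]
    if (nrow(ip) != 1L || nrow(inp) != 1L) {
      .stopf("replicate %s/%s/%s needs exactly one IP and one input row",
             sub$target_region[1L], sub$strain[1L], sub$replicate[1L])
    }
    data.frame(target_region = ip$target_region, strain = ip$strain,
               replicate = ip$replicate,
               percent_input = percent_input(ip$Ct, inp$Ct,
                                             ip$input_dilution),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize two replicate groups and test their difference
#'
#' Means, SEMs (sample sd / sqrt(n)), and the unpaired two-tailed Student
#' t-test (pooled variance by default, matching the classical test; Welch
#' available with `var_equal = FALSE`).
#'
#' @param group_a,group_b Numeric vectors of percent-input values, each of
#'   length >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return Object of class `group_summary`: list with `mean_a`, `sem_a`,
#'   `n_a`, `mean_b`, `sem_b`, `n_b`, `t`, `df`, `p_value`.
#' @examples
#' summarize_and_test(c(1, 2, 3), c(4, 5, 6))
#' @export
summarize_and_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    .stopf("each group needs n >= 2 for SEM and t-test")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(
    list(
      mean_a = mean(group_a),
      sem_a = stats::sd(group_a) / sqrt(length(group_a)),
      n_a = length(group_a),
      mean_b = mean(group_b),
      sem_b = stats::sd(group_b) / sqrt(length(group_b)),
      n_b = length(group_b),
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      var_equal = var_equal
    ),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s t-test\n",
              if (x$var_equal) "pooled-variance (Student)" else "Welch"))
  cat(sprintf("  group A: %.4g +/- %.4g (n = %d)\n", x$mean_a, x$sem_a, x$n_a))
  cat(sprintf("  group B: %.4g +/- %.4g (n = %d)\n", x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Per-group summaries of a percent-input table with tests vs a reference
#'
#' Aggregates replicates per (target_region, strain) and, when a reference
#' strain is given, tests every other strain against it within each target
#' region.
#'
#' @param pct Data frame from [percent_input_table()].
#' @param reference_strain Strain to test against (e.g. the no-tag
#'   control), or `NULL` for summaries only.
#' @param var_equal Passed to [summarize_and_test()].
#' @return Data frame with columns `target_region`, `strain`, `n`, `mean`,
#'   `sem`, `p_vs_reference`.
#' @export
qpcr_summary <- function(pct, reference_strain = NULL, var_equal = TRUE) {
  stopifnot(all(c("target_region", "strain", "percent_input") %in% names(pct)))
  groups <- unique(pct[, c("target_region", "strain")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    tr <- groups$target_region[i]
    st <- groups$strain[i]
    v <- pct$percent_input[pct$target_region == tr & pct$strain == st]
    p <- NA_real_
    if (!is.null(reference_strain) && st != reference_strain) {
      ref <- pct$percent_input[pct$target_region == tr &
                                 pct$strain == reference_strain]
      if (length(ref) >= 2L && length(v) >= 2L) {
        p <- summarize_and_test(v, ref, var_equal = var_equal)$p_value
      }
    }
    data.frame(target_region = tr, strain = st, n = length(v),
               mean = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               p_vs_reference = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
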