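# Readers/writers for the plain-text formats the pipeline touches:
# chrom.sizes, BED3/BED6, TSV report tables (also JSON), qPCR Ct tables and
# EM joint-molecule records. Readers reject rather than clamp out-of-bounds
# coordinates, and carry line numbers in parse errors.

#' Read a chrom.sizes file into a genome definition
#'
#' @param path Two-column whitespace/tab-separated text: chromosome name,
#'   length in bp. Blank lines and lines starting with `#` are skipped.
#' @return A [genome_def()] with chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) .stopf("%s: no chromosomes", path)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  chrom <- character(length(keep))
  sizes <- numeric(length(keep))
  for (i in seq_along(keep)) {
    f <- fields[[i]]
    if (length(f) < 2L) {
      .stopf("%s line %d: expected 'name<TAB>length'", path, keep[i])
    }
    len <- suppressWarnings(as.numeric(f[2L]))
    if (!is.finite(len) || len < 1 || len != floor(len)) {
      .stopf("%s line %d: invalid chromosome length '%s'", path, keep[i], f[2L])
    }
    chrom[i] <- f[1L]
    sizes[i] <- len
  }
  if (anyDuplicated(chrom)) {
    .stopf("%s: duplicate chromosome name: %s", path,
           chrom[duplicated(chrom)][1L])
  }
  genome_def(chrom, sizes)
}

#' Write a genome definition as chrom.sizes
#' @param genome A `genome_def`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_def"))
  writeLines(sprintf("%s\t%d", genome$chromosomes$chrom,
                     genome$chromosomes$size), path)
  invisible(path)
}

#' Read a BED file as a cluster set or feature set
#'
#' Accepts BED3 or BED6-style records (columns beyond the fourth are
#' ignored; the name column becomes the feature id). Comment, `track` and
#' `browser` lines are skipped. Coordinates are validated against `genome`
#' and never clamped.
#'
#' @param path BED file path.
#' @param genome A `genome_def`.
#' @param one_based Set `TRUE` when the file uses 1-based fully-closed
#'   coordinates; they are converted to 0-based half-open on read
#'   (start-1, end), so a declared 1-based `100 200` becomes `[99, 200)`.
#' @param as `"clusters"` (merged [cluster_set()]) or `"features"`
#'   (unmerged [feature_set()] preserving ids).
#' @param protein Protein label for `as = "clusters"`.
#' @param class_label Feature class for `as = "features"`. When `NULL`, a
#'   uniform `class:id` prefix in the name column is used if present,
#'   otherwise `"other"`.
#' @return A `cluster_set` or `feature_set`.
#' @export
read_bed <- function(path, genome, one_based = FALSE,
                     as = c("clusters", "features"),
                     protein = "protein", class_label = NULL) {
  as <- match.arg(as)
  stopifnot(inherits(genome, "genome_def"))
  lines <- readLines(path, warn = FALSE)
  skip <- !nzchar(trimws(lines)) | startsWith(lines, "#") |
    startsWith(lines, "track") | startsWith(lines, "browser")
  idx <- which(!skip)
  chrom <- character(length(idx))
  start <- numeric(length(idx))
  end <- numeric(length(idx))
  name <- rep(NA_character_, length(idx))
  for (i in seq_along(idx)) {
    f <- strsplit(lines[idx[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- strsplit(trimws(lines[idx[i]]), "[ \t]+")[[1L]]
    if (length(f) < 3L) .stopf("%s line %d: malformed BED record", path, idx[i])
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (!is.finite(s) || !is.finite(e)) {
      .stopf("%s line %d: non-numeric coordinates", path, idx[i])
    }
    chrom[i] <- f[1L]
    start[i] <- s
    end[i] <- e
    if (length(f) >= 4L) name[i] <- f[4L]
  }
  if (one_based) start <- start - 1
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (as == "clusters") {
    return(cluster_set(df, genome, protein = protein))
  }
  has_names <- length(idx) > 0L && !anyNA(name)
  if (has_names) {
    df$id <- name
    if (is.null(class_label) && all(grepl(":", name, fixed = TRUE))) {
      # "class:id" convention in the name column
      cls <- unique(sub(":.*$", "", name))
      if (length(cls) == 1L && cls %in% .FEATURE_CLASSES) {
        class_label <- cls
        df$id <- sub("^[^:]+:", "", name)
      }
    }
  }
  if (is.null(class_label)) class_label <- "other"
  feature_set(df, genome, class_label = class_label)
}

#' Write a cluster set or feature set as BED
#'
#' Cluster sets are written as BED3; feature sets as BED4 with
#' `class:id` in the name column (round-trips through [read_bed()]).
#'
#' @param x A `cluster_set` or `feature_set`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "cluster_set")) {
    df <- x$intervals
    lines <- sprintf("%s\t%d\t%d", df$chrom, df$start, df$end)
  } else if (inherits(x, "feature_set")) {
    df <- x$features
    lines <- sprintf("%s\t%d\t%d\t%s:%s", df$chrom, df$start, df$end,
                     x$class_label, df$id)
  } else {
    .stopf("write_bed: expected a cluster_set or feature_set")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a side table assigning classes to feature ids
#' @param path TSV with columns `id`, `class`.
#' @return Data frame with columns `id`, `class`.
#' @export
read_feature_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(df))) {
    .stopf("%s: need columns 'id' and 'class'", path)
  }
  df[, c("id", "class")]
}

# ---- report tables -------------------------------------------------------

.REPORT_COLS <- c("analysis", "proteins", "feature_class", "observed_bp",
                  "expected_bp", "fold", "empirical_p", "fisher_p",
                  "n_iterations", "seed")

#' Assemble analysis results into a report table
#'
#' Binds the one-row summaries of [monte_carlo_colocalization()] and
#' [fold_increase()] results into a single data frame with a fixed column
#' order, ready for [write_report()].
#'
#' @param ... `coloc_result` / `fold_result` objects (or data frames already
#'   in report layout).
#' @return Data frame with columns analysis, proteins, feature_class,
#'   observed_bp, expected_bp, fold, empirical_p, fisher_p, n_iterations,
#'   seed.
#' @export
report_table <- function(...) {
  rows <- lapply(list(...), function(x) {
    if (is.data.frame(x)) x else as_report_row(x)
  })
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.REPORT_COLS)), .REPORT_COLS),
      stringsAsFactors = FALSE)
    num <- c("observed_bp", "expected_bp", "fold", "empirical_p", "fisher_p",
             "n_iterations", "seed")
    for (cn in num) out[[cn]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, .REPORT_COLS]
}

#' One-row report layout for a result object
#' @param x A `coloc_result` or `fold_result`.
#' @return One-row data frame in report layout.
#' @export
as_report_row <- function(x) UseMethod("as_report_row")

#' Write a report table as TSV or JSON
#'
#' Floats are serialized with 6 significant digits in both formats, so TSV
#' and JSON carry identical values.
#'
#' @param report Data frame from [report_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(report))
  num <- vapply(report, is.numeric, logical(1L))
  report[num] <- lapply(report[num], signif, digits = 6L)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report table written by [write_report()]
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return Data frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}

# ---- qPCR and JM tables --------------------------------------------------

#' Read a ChIP-qPCR Ct table
#'
#' @param path TSV with columns `target_region`, `strain`, `replicate`,
#'   `role` (one of `IP`, `input`), `Ct`, `input_dilution`. The no-tag
#'   control is a strain (e.g. `strain = "no_tag"`), not a separate role.
#' @return Data frame with those columns.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_region", "strain", "replicate", "role", "Ct",
            "input_dilution")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", "))
  bad <- !df$role %in% c("IP", "input")
  if (any(bad)) .stopf("%s: invalid role '%s'", path, df$role[bad][1L])
  df
}

#' Write a ChIP-qPCR Ct table as TSV
#' @param df qPCR table data frame.
#' @param path Output path.
#' @export
write_qpcr_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EM joint-molecule record table
#'
#' @param path TSV with columns `molecule_id`, `genotype`, `n_junctions`,
#'   `branch1_nm`..`branch4_nm` (blank/NA where absent), `n_branches` and
#'   optionally `true_category` (synthetic truth labels).
#' @return Data frame of records.
#' @export
read_jm_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "genotype", "n_junctions",
            paste0("branch", 1:4, "_nm"), "n_branches")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", "))
  df
}

#' Write EM joint-molecule records as TSV
#' @param records JM record data frame.
#' @param path Output path.
#' @export
write_jm_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
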