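# Time-series expression tables: construction, reading, writing, and
# baseline normalization.

#' Default 13-point sampling grid (hours after treatment)
#'
#' The post-baseline sampling times used throughout: 0.5, 1, 1.5, 2, 4, 6, 8,
#' 12, 18, 24, 36, 48 and 72 h. Values in the expression table are changes
#' relative to the 0 h baseline, so the baseline itself does not appear.
#'
#' @return Numeric vector of length 13.
#' @export
default_time_grid <- function() c(0.5, 1, 1.5, 2, 4, 6, 8, 12, 18, 24, 36, 48, 72)

#' Construct a time-series expression matrix
#'
#' The universal input container of the pipeline: one row per phosphopeptide,
#' one column per post-baseline time point, holding relative expression
#' changes versus the 0 h baseline (dimensionless). Peptides mapping to
#' several protein accessions (protein groups) keep all accessions separated
#' by `;`.
#'
#' @param peptide_id Character vector of unique peptide labels.
#' @param protein_id Character vector of protein accessions, same length;
#'   multiple accessions may be `;`-separated.
#' @param values Numeric matrix, one row per peptide, `length(time_grid)`
#'   columns, no missing values.
#' @param time_grid Strictly increasing positive sampling times (hours).
#'
#' @return An object of class `ts_matrix`: a list with elements
#'   `peptide_id`, `protein_id`, `values` (matrix with peptide row names)
#'   and `time_grid`.
#' @export
ts_matrix <- function(peptide_id, protein_id, values,
                      time_grid = default_time_grid()) {
  peptide_id <- as.character(peptide_id)
  protein_id <- as.character(protein_id)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  time_grid <- as.numeric(time_grid)
  if (anyDuplicated(peptide_id)) {
    stop("duplicate peptide_id: ",
         paste(unique(peptide_id[duplicated(peptide_id)]), collapse = ", "))
  }
  if (length(protein_id) != length(peptide_id)) {
    stop("peptide_id and protein_id lengths differ")
  }
  if (nrow(values) != length(peptide_id)) {
    stop("values must have one row per peptide")
  }
  if (ncol(values) != length(time_grid)) {
    stop("every row must have exactly ", length(time_grid), " values")
  }
  if (any(!is.finite(time_grid)) || any(time_grid <= 0) ||
      any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing and positive")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and complete; drop incomplete rows first")
  }
  rownames(values) <- peptide_id
  colnames(values) <- paste0("t", format(time_grid, trim = TRUE))
  structure(
    list(peptide_id = peptide_id, protein_id = protein_id,
         values = values, time_grid = time_grid),
    class = "ts_matrix"
  )
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d peptides x %d time points (%s..%s h)\n",
              length(x$peptide_id), length(x$time_grid),
              format(min(x$time_grid)), format(max(x$time_grid))))
  invisible(x)
}

#' Number of peptide rows
#' @param x A `ts_matrix`.
#' @return Integer row count.
#' @export
n_peptides <- function(x) length(x$peptide_id)

#' Protein accessions of a `ts_matrix`
#'
#' Protein-group fields are split on `;` so a peptide contributes every
#' accession it lists.
#'
#' @param x A `ts_matrix`.
#' @return Sorted character vector of unique accessions.
#' @export
proteins <- function(x) {
  sort(unique(unlist(strsplit(x$protein_id, ";", fixed = TRUE))))
}

guess_sep <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L) stop("empty file: ", path)
  if (grepl("\t", first[1L], fixed = TRUE)) "\t" else ","
}

#' Read a time-series expression table
#'
#' Expects UTF-8 delimited text (tab by default, comma accepted) with a
#' header row: columns `peptide`, `protein`, then one numeric column per time
#' point in increasing time order. Lines starting with `#` are ignored.
#' Sampling times are parsed from the numeric part of the time column names
#' (e.g. `t0.5` ... `t72`); if they cannot be parsed, the default grid is
#' assumed for 13 columns and a unit-spaced grid otherwise.
#'
#' Rows containing missing values are dropped; the number of dropped rows is
#' reported via a message and recorded in the `n_dropped` attribute.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A [ts_matrix()] with attribute `n_dropped`.
#' @export
read_timeseries <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  for (col in c("peptide", "protein")) {
    if (!col %in% names(df)) {
      stop("format error: required column '", col, "' is missing")
    }
  }
  value_cols <- setdiff(names(df), c("peptide", "protein"))
  if (length(value_cols) < 13L) {
    stop("format error: expected at least 13 time columns, found ",
         length(value_cols))
  }
  raw <- as.matrix(df[, value_cols, drop = FALSE])
  raw[raw %in% c("", "NA", "na", "NaN")] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- !is.na(raw) & is.na(num)
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1L]
    stop("parse error: non-numeric value '",
         raw[row, which(bad[row, ])[1L]], "' in data row ", row)
  }
  keep <- stats::complete.cases(num)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing values dropped")
  }
  grid <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", value_cols)))
  if (anyNA(grid) || any(diff(grid) <= 0)) {
    grid <- if (length(value_cols) == 13L) default_time_grid()
            else seq_along(value_cols)
  }
  out <- ts_matrix(df$peptide[keep], df$protein[keep],
                   num[keep, , drop = FALSE], grid)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a time-series expression table
#'
#' Tab-separated with a `#` comment header recording the package version and
#' parameters. Values are written at full precision so a write/read cycle
#' reproduces the matrix exactly.
#'
#' @param x A `ts_matrix`.
#' @param path Output path.
#' @param params Named list echoed into the comment header.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, params = list()) {
  vals <- apply(x$values, 2L, num_chr)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  df <- data.frame(peptide = x$peptide_id, protein = x$protein_id,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("peptide", "protein", colnames(x$values))
  write_tsv_with_header(df, path, params)
}

#' Normalize a raw-intensity table to the 0 h baseline
#'
#' Converts a 14-column raw table (first column is the 0 h baseline) into the
#' 13-column relative-expression form the pipeline consumes.
#'
#' @param raw Data frame with columns `peptide`, `protein` and 14 numeric
#'   columns, the first of which is the 0 h baseline; or a numeric matrix
#'   with peptide row names plus `peptide_id`/`protein_id` supplied through
#'   `...` is not supported -- use the data-frame form.
#' @param method `"log2_ratio"` (default): `log2(v_t / v_0)`; `"ratio"`:
#'   `v_t / v_0`; `"difference"`: `v_t - v_0`.
#' @param time_grid Sampling times of the 13 post-baseline columns.
#' @return A [ts_matrix()]. Rows whose baseline makes the method undefined
#'   (`v_0 <= 0` with ratio/log2_ratio) are dropped; their peptide ids are in
#'   the `dropped_rows` attribute and reported via a message.
#' @export
normalize_to_baseline <- function(raw,
                                  method = c("log2_ratio", "ratio", "difference"),
                                  time_grid = default_time_grid()) {
  method <- match.arg(method)
  if (!is.data.frame(raw)) stop("raw must be a data frame")
  for (col in c("peptide", "protein")) {
    if (!col %in% names(raw)) {
      stop("format error: required column '", col, "' is missing")
    }
  }
  value_cols <- setdiff(names(raw), c("peptide", "protein"))
  if (length(value_cols) != length(time_grid) + 1L) {
    stop("format error: expected ", length(time_grid) + 1L,
         " value columns (0 h baseline first), found ", length(value_cols))
  }
  vals <- as.matrix(raw[, value_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  v0 <- vals[, 1L]
  rest <- vals[, -1L, drop = FALSE]
  keep <- rep(TRUE, nrow(vals))
  if (method %in% c("log2_ratio", "ratio")) {
    keep <- is.finite(v0) & v0 > 0
  }
  keep <- keep & stats::complete.cases(vals)
  dropped <- raw$peptide[!keep]
  if (length(dropped)) {
    message(length(dropped), " row(s) dropped during baseline normalization (",
            method, "): ", paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  rel <- switch(method,
    log2_ratio = log2(rest[keep, , drop = FALSE] / v0[keep]),
    ratio      = rest[keep, , drop = FALSE] / v0[keep],
    difference = rest[keep, , drop = FALSE] - v0[keep]
  )
  out <- ts_matrix(raw$peptide[keep], raw$protein[keep], rel, time_grid)
  attr(out, "dropped_rows") <- as.character(dropped)
  out
}
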