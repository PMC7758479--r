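# Reference protein-protein interaction sets (DIP-like), used to score
# predictions.

#' Construct a reference PPI set
#'
#' Stores unordered, deduplicated accession pairs. Self-pairs are discarded
#' and counted.
#'
#' @param a,b Character vectors of accessions (pair endpoints), or `a` may be
#'   a two-column matrix/data frame of pairs with `b` missing.
#' @return Object of class `ppi_set`: list with `pairs` (two-column character
#'   matrix, lexicographically ordered within pair), `keys`, `universe`, and
#'   `n_self_discarded`.
#' @export
ppi_set <- function(a, b = NULL) {
  if (is.null(b)) {
    m <- as.matrix(a)
    if (ncol(m) < 2L) stop("need two columns of accessions")
    b <- as.character(m[, 2L])
    a <- as.character(m[, 1L])
  }
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("pair endpoint lengths differ")
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  keys <- unique(pair_key(a, b))
  pairs <- key_to_pair(keys)
  structure(
    list(pairs = pairs, keys = keys,
         universe = sort(unique(c(pairs))), n_self_discarded = n_self),
    class = "ppi_set"
  )
}

#' @export
print.ppi_set <- function(x, ...) {
  cat(sprintf("ppi_set: %d unordered pairs over %d accessions\n",
              length(x$keys), length(x$universe)))
  invisible(x)
}

#' Symmetric membership test
#'
#' @param ppi A [ppi_set()].
#' @param a,b Accession vectors (recycled to common length).
#' @return Logical vector; `ppi_contains(p, A, B)` equals
#'   `ppi_contains(p, B, A)`.
#' @export
ppi_contains <- function(ppi, a, b) {
  pair_key(a, b) %in% ppi$keys
}

# MITAB identifier columns look like "uniprotkb:P41236|intact:EBI-123"; take
# the uniprotkb entry when present, else the first identifier, and strip the
# "db:" prefix.
parse_mitab_id <- function(field, line_no) {
  alts <- strsplit(field, "|", fixed = TRUE)[[1L]]
  hit <- grep("^uniprotkb:", alts, value = TRUE)
  id <- if (length(hit)) hit[1L] else alts[1L]
  id <- sub("^[A-Za-z0-9_.-]+:", "", id)
  id <- sub("\\(.*\\)$", "", id)
  if (is.na(id) || !nzchar(id)) {
    stop("parse error: unparseable identifier on line ", line_no)
  }
  id
}

#' Read a reference PPI set
#'
#' Two dialects: `two_column_tsv` (two whitespace/tab-separated accessions
#' per line, optional header ignored if it repeats on data lines) and
#' `mitab25` (PSI-MI TAB; identifiers parsed from columns 1-2, `uniprotkb:`
#' prefixes preferred). Pairs are stored unordered and deduplicated;
#' self-pairs are discarded and counted.
#'
#' @param path File path.
#' @param dialect `"two_column_tsv"` or `"mitab25"`.
#' @return A [ppi_set()].
#' @export
read_ppi_reference <- function(path,
                               dialect = c("two_column_tsv", "mitab25")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (dialect == "two_column_tsv") {
    parts <- strsplit(trimws(lines), "[\t ]+")
    bad <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(bad)) {
      stop("parse error: fewer than two identifiers on line ", line_no[bad[1L]])
    }
    a <- vapply(parts, `[`, character(1), 1L)
    b <- vapply(parts, `[`, character(1), 2L)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(bad)) {
      stop("parse error: fewer than two identifier columns on line ",
           line_no[bad[1L]])
    }
    a <- mapply(function(p, n) parse_mitab_id(p[1L], n), parts, line_no)
    b <- mapply(function(p, n) parse_mitab_id(p[2L], n), parts, line_no)
  }
  ppi_set(a, b)
}
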