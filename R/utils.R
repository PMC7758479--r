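# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  ifelse(a <= b, paste(a, b, sep = "\x1f"), paste(b, a, sep = "\x1f"))
}

key_to_pair <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  m <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  colnames(m) <- c("a", "b")
  m
}

# 32-bit FNV-1a over a character vector; used as a config fingerprint in
# output headers. Arithmetic kept below 2^53 so doubles stay exact.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte because b < 256
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Comment header stamped on every TSV the package writes: version, a
# fingerprint of the effective configuration, and the configuration itself.
output_header <- function(params = list()) {
  lines <- character(0)
  if (length(params)) {
    lines <- vapply(
      seq_along(params),
      function(i) paste0(names(params)[i], "=",
                         paste(format(params[[i]], trim = TRUE), collapse = ",")),
      character(1)
    )
  }
  c(
    sprintf("# dcaa %s", as.character(utils::packageVersion("dcaa"))),
    sprintf("# config_hash=%s", fnv1a32(lines)),
    paste0("# ", lines)
  )
}

write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# Full-precision number formatting so that write -> read round-trips exactly.
num_chr <- function(x) sprintf("%.17g", x)

# Run code with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards; all stochastic operations go through this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
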