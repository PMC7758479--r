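# End-to-end orchestration: configuration, the staged pipeline, and the
# TSV serialization of every intermediate (each file carries a comment
# header with the package version, a config fingerprint and the seed).

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with the field's customary
#' defaults: window length 9 of 12 periods, delays 1-3, confidence 0.9,
#' angle threshold 10 degrees, Pearson threshold |r| > 0.97, 100 baseline
#' replicates.
#'
#' @param method Clustering method: `"full_trend"`, `"angle"` or
#'   `"pearson"`.
#' @param zero_eps Unchanging-step tolerance shared by trend signatures and
#'   the both-unchanged branch of the delayed comparison; default 0.
#' @param angle_deg Angle threshold (degrees) for `method = "angle"`.
#' @param r_threshold Correlation threshold for `method = "pearson"`.
#' @param time_scale Slope scale for angle clustering: `"index"` or
#'   `"hours"`.
#' @param require_trend Whether angle clustering additionally requires equal
#'   trend signatures.
#' @param window_len,max_delay Delayed-comparison window geometry.
#' @param min_support Fixed minimum support; `NULL` (default) tunes it on
#'   `support_grid`.
#' @param support_grid Candidate supports scanned when `min_support` is
#'   `NULL`; default `0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001`.
#' @param target_rules Acceptable pairwise-rule-count range for the tuner.
#' @param min_confidence Minimum rule confidence; default 0.9.
#' @param max_rule_size Largest itemset expanded into rules; default 2.
#' @param max_depth Reasoning depth 1-3; default 3.
#' @param replicates Random-baseline replicates; default 100.
#' @param seed Integer seed governing every stochastic stage.
#' @return Object of class `dcaa_config` (a validated named list).
#' @export
dcaa_config <- function(method = c("full_trend", "angle", "pearson"),
                        zero_eps = 0, angle_deg = 10, r_threshold = 0.97,
                        time_scale = c("index", "hours"),
                        require_trend = FALSE,
                        window_len = 9L, max_delay = 3L,
                        min_support = NULL,
                        support_grid = c(0.5, 0.2, 0.1, 0.05, 0.02,
                                         0.01, 0.005, 0.002, 0.001),
                        target_rules = c(50L, 600L),
                        min_confidence = 0.9, max_rule_size = 2L,
                        max_depth = 3L, replicates = 100L, seed = 1L) {
  method <- match.arg(method)
  time_scale <- match.arg(time_scale)
  if (zero_eps < 0) stop("zero_eps must be non-negative")
  if (angle_deg <= 0) stop("angle_deg must be positive")
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0, 1)")
  if (window_len < 1L || max_delay < 1L) stop("window geometry must be positive")
  if (!is.null(min_support) && (min_support <= 0 || min_support > 1)) {
    stop("min_support must lie in (0, 1]")
  }
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]")
  }
  if (!max_depth %in% 1:3) stop("max_depth must be 1, 2 or 3")
  if (replicates < 1L) stop("replicates must be positive")
  structure(
    list(method = method, zero_eps = zero_eps, angle_deg = angle_deg,
         r_threshold = r_threshold, time_scale = time_scale,
         require_trend = require_trend,
         window_len = as.integer(window_len),
         max_delay = as.integer(max_delay),
         min_support = min_support, support_grid = support_grid,
         target_rules = as.integer(target_rules),
         min_confidence = min_confidence,
         max_rule_size = as.integer(max_rule_size),
         max_depth = as.integer(max_depth),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "dcaa_config"
  )
}

config_params <- function(config) {
  p <- unclass(config)
  p$min_support <- p$min_support %||% "tuned"
  p
}

#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key=value` (comments `#` and blank lines ignored);
#' vector values are comma-separated. Unknown keys are an error. Values are
#' passed through [dcaa_config()] and validated there.
#'
#' @param path File path.
#' @return A [dcaa_config()].
#' @export
read_dcaa_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(dcaa_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  known <- names(formals(dcaa_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    args[[keys[i]]] <- if (!anyNA(num)) num
      else if (all(v %in% c("TRUE", "FALSE"))) as.logical(v)
      else v
  }
  do.call(dcaa_config, args)
}

#' Run the full discovery pipeline
#'
#' Executes clustering, delayed-window basket construction, Apriori rule
#' mining (with support tuning unless fixed), multi-step reasoning, protein
#' expansion, and -- when a reference set is supplied -- pooled and per-depth
#' hit-rate evaluation against the seeded random baseline. Deterministic for
#' a fixed configuration and seed. When no class co-moves with any other
#' (empty basket dataset) the downstream stages degrade gracefully to empty
#' results and the evaluation is skipped with a notice.
#'
#' @param matrix A [ts_matrix()].
#' @param reference Optional [ppi_set()]; without it, evaluation is skipped.
#' @param config A [dcaa_config()].
#' @param universe Accessions for the random baseline; default all proteins
#'   of `matrix`.
#' @param verbose Emit per-stage count messages; default `TRUE`.
#' @return Object of class `dcaa_result`: list with `config`, `clustering`,
#'   `representatives`, `specs`, `baskets`, `support_scan`, `min_support`,
#'   `itemsets`, `rules`, `graph`, `class_pairs`, `predictions`, `report`
#'   (pooled `dcaa_hit_report` or `NULL`), `report_by_depth`.
#' @export
run_pipeline <- function(matrix, reference = NULL, config = dcaa_config(),
                         universe = NULL, verbose = TRUE) {
  stopifnot(inherits(matrix, "ts_matrix"), inherits(config, "dcaa_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  clustering <- switch(config$method,
    full_trend = cluster_full_trend(matrix, config$zero_eps),
    angle = cluster_angle(matrix, config$angle_deg, config$time_scale,
                          config$require_trend, config$zero_eps),
    pearson = cluster_pearson(matrix, config$r_threshold))
  say("clustering: %d peptides -> %d classes", n_peptides(matrix),
      n_classes(clustering))
  reps <- class_representatives(clustering, matrix)
  periods <- period_matrix(reps)

  specs <- enumerate_windows(ncol(periods), config$window_len,
                             config$max_delay)
  say("windows: %d specs (%s)", nrow(specs),
      paste(specs$label, collapse = ", "))

  empty_rules <- data.frame(antecedent = character(0),
                            consequent = character(0),
                            rule_size = integer(0), support = numeric(0),
                            confidence = numeric(0), stringsAsFactors = FALSE)
  result <- list(config = config, clustering = clustering,
                 representatives = reps, specs = specs,
                 baskets = NULL, support_scan = NULL,
                 min_support = config$min_support,
                 itemsets = NULL, rules = empty_rules, graph = NULL,
                 class_pairs = NULL,
                 predictions = classes_to_proteins(list(), clustering, matrix),
                 report = NULL, report_by_depth = NULL)
  class(result) <- "dcaa_result"

  if (n_classes(clustering) < 2L) {
    say("fewer than two classes: nothing to compare, pipeline stops early")
    return(result)
  }
  baskets <- build_baskets(periods, specs, config$zero_eps)
  result$baskets <- baskets
  say("baskets: %d records", baskets$n_records)
  if (baskets$n_records == 0L) {
    say("notice: no co-moving classes; mining skipped")
    return(result)
  }

  if (is.null(config$min_support)) {
    tuned <- tune_support(baskets, config$min_confidence,
                          config$support_grid, config$target_rules)
    result$support_scan <- tuned$scan
    result$min_support <- tuned$min_support
    say("support tuned to %g", tuned$min_support)
  }
  itemsets <- mine_frequent_itemsets(baskets, result$min_support)
  rules <- derive_rules(itemsets, config$min_confidence,
                        config$max_rule_size)
  result$itemsets <- itemsets
  result$rules <- rules
  say("mining: %d frequent itemsets, %d rules (%d pairwise)",
      nrow(itemsets), nrow(rules), n_pair_rules(rules))

  graph <- suppressWarnings(build_rule_graph(rules))
  class_pairs <- infer_class_pairs(graph, config$max_depth)
  predictions <- classes_to_proteins(class_pairs, clustering, matrix, graph)
  result$graph <- graph
  result$class_pairs <- class_pairs
  result$predictions <- predictions
  say("inference: %s class pairs by depth; %d protein pairs",
      paste(vapply(class_pairs, nrow, integer(1)), collapse = "/"),
      nrow(predictions))

  if (!is.null(reference)) {
    if (nrow(predictions) == 0L) {
      say("notice: no predictions; evaluation skipped")
    } else {
      universe <- universe %||% proteins(matrix)
      result$report <- evaluate_hit_rate(predictions, reference, universe,
                                         config$replicates, config$seed)
      result$report_by_depth <- lapply(
        split(predictions, predictions$depth),
        function(df) evaluate_hit_rate(df, reference, universe,
                                       config$replicates, config$seed))
      say("evaluation: R = %.4f (baseline %.4f, p = %.4g)",
          result$report$R, result$report$baseline_mean,
          result$report$p_empirical)
    }
  }
  result
}

#' @export
print.dcaa_result <- function(x, ...) {
  cat(sprintf("dcaa_result (%s clustering)\n", x$config$method))
  cat(sprintf("  classes: %d | basket records: %d | pairwise rules: %d\n",
              n_classes(x$clustering),
              if (is.null(x$baskets)) 0L else x$baskets$n_records,
              n_pair_rules(x$rules)))
  cat(sprintf("  predictions: %d protein pairs\n", nrow(x$predictions)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

# ---- TSV serialization of intermediates -------------------------------

#' Write a clustering as TSV
#' @param clustering A `dcaa_clustering`.
#' @param matrix The underlying [ts_matrix()].
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, matrix, path, params = list()) {
  df <- data.frame(peptide = names(clustering$assignment),
                   protein = matrix$protein_id[match(
                     names(clustering$assignment), matrix$peptide_id)],
                   class_id = as.integer(clustering$assignment),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, c(list(method = clustering$method),
                                    clustering$params, params))
}

#' Read a clustering TSV back into a `dcaa_clustering`
#' @param path File written by [write_clustering()].
#' @return A `dcaa_clustering` (method `"loaded"`).
#' @export
read_clustering <- function(path) {
  df <- read_tsv_skip_comments(path)
  new_clustering("loaded", list(), df$peptide, df$class_id)
}

#' Write class representatives as TSV
#' @param representatives Matrix from [class_representatives()].
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_representatives <- function(representatives, path, params = list()) {
  vals <- apply(representatives, 2L, num_chr)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  df <- data.frame(class_id = rownames(representatives), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("class_id", colnames(representatives) %||%
                   paste0("v", seq_len(ncol(representatives))))
  write_tsv_with_header(df, path, params)
}

#' Read class representatives from TSV
#' @param path File written by [write_representatives()].
#' @return Numeric matrix with class-id row names.
#' @export
read_representatives <- function(path) {
  df <- read_tsv_skip_comments(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a basket dataset as TSV
#'
#' One line per record: anchor class id, then the comma-separated member
#' class ids.
#'
#' @param baskets A `dcaa_baskets`.
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_baskets <- function(baskets, path, params = list()) {
  df <- data.frame(
    anchor = vapply(baskets$records, function(r) r$anchor, integer(1)),
    items = vapply(baskets$records,
                   function(r) paste(r$items, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write_tsv_with_header(df, path,
                        c(list(n_classes = length(baskets$class_ids)), params))
}

#' Read a basket dataset from TSV
#' @param path File written by [write_baskets()].
#' @return A `dcaa_baskets`.
#' @export
read_baskets <- function(path) {
  df <- read_tsv_skip_comments(path, colClasses = "character")
  records <- lapply(seq_len(nrow(df)), function(i) {
    list(anchor = as.integer(df$anchor[i]),
         items = sort(as.integer(strsplit(df$items[i], ",")[[1L]])))
  })
  ids <- sort(unique(unlist(lapply(records, `[[`, "items"))))
  structure(list(records = records, n_records = length(records),
                 class_ids = ids),
            class = "dcaa_baskets")
}

#' Write association rules as TSV
#' @param rules A [derive_rules()] data frame.
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path, params = list()) {
  out <- rules
  out$support <- num_chr(out$support)
  out$confidence <- num_chr(out$confidence)
  write_tsv_with_header(out, path, params)
}

#' Read association rules from TSV
#' @param path File written by [write_rules()].
#' @return Data frame in [derive_rules()] layout.
#' @export
read_rules <- function(path) {
  df <- read_tsv_skip_comments(path, colClasses = c(
    antecedent = "character", consequent = "character"))
  df$rule_size <- as.integer(df$rule_size)
  df$support <- as.numeric(df$support)
  df$confidence <- as.numeric(df$confidence)
  df
}

#' Write protein-pair predictions as TSV
#' @param predictions A [classes_to_proteins()] data frame.
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, params = list()) {
  write_tsv_with_header(predictions, path, params)
}

#' Read protein-pair predictions from TSV
#' @param path File written by [write_predictions()].
#' @return Prediction data frame.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_skip_comments(path, colClasses = c(
    protein_a = "character", protein_b = "character"))
  df
}

#' Write a hit-rate report as key-value TSV
#'
#' The scalar report fields go to `path`; the full baseline replicate vector
#' goes to a `*.baseline.tsv` side file for plotting.
#'
#' @param report A `dcaa_hit_report`.
#' @param path Output path.
#' @param params Extra header parameters.
#' @return `path`, invisibly.
#' @export
write_hit_report <- function(report, path, params = list()) {
  fields <- c("m", "M", "R", "baseline_mean", "baseline_sd", "replicates",
              "p_empirical", "z_score", "seed")
  df <- data.frame(key = fields,
                   value = vapply(fields, function(f)
                     num_chr(as.numeric(report[[f]])), character(1)),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, params)
  side <- sub("(\\.[^.]*)?$", ".baseline.tsv", path)
  write_tsv_with_header(
    data.frame(replicate = seq_along(report$baseline),
               R_prime = num_chr(report$baseline)),
    side, params)
  invisible(path)
}

#' Persist every pipeline output into a directory
#'
#' Writes the clustering, representatives, baskets, support scan, rules,
#' predictions and (when present) the hit-rate report as headed TSVs.
#' Running the pipeline twice with the same configuration and seed produces
#' byte-identical directories.
#'
#' @param result A [run_pipeline()] result.
#' @param matrix The input [ts_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
dcaa_write_result <- function(result, matrix, dir) {
  stopifnot(inherits(result, "dcaa_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- config_params(result$config)
  write_clustering(result$clustering, matrix,
                   file.path(dir, "clustering.tsv"), params)
  write_representatives(result$representatives,
                        file.path(dir, "representatives.tsv"), params)
  if (!is.null(result$baskets)) {
    write_baskets(result$baskets, file.path(dir, "baskets.tsv"), params)
  }
  if (!is.null(result$support_scan)) {
    scan <- result$support_scan
    scan$min_support <- num_chr(scan$min_support)
    write_tsv_with_header(scan, file.path(dir, "support_scan.tsv"), params)
  }
  write_rules(result$rules, file.path(dir, "rules.tsv"),
              c(params, list(chosen_min_support = result$min_support %||% NA)))
  write_predictions(result$predictions, file.path(dir, "predictions.tsv"),
                    params)
  if (!is.null(result$report)) {
    write_hit_report(result$report, file.path(dir, "hit_report.tsv"), params)
  }
  invisible(dir)
}
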