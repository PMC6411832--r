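# End-to-end orchestration: flat key=value run configuration, staged
# execution (discover -> quantify -> call expressed -> optional repeat
# enrichment) and an output manifest.

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Repeated keys
#' (e.g. several `bedgraph` entries) accumulate into vectors. Numeric
#' values are coerced; every discovery constant has a named option
#' defaulting to its canonical value.
#'
#' @param path Path to the configuration file.
#' @return A named list of options merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parsed <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(parsed) != 2)
  if (length(bad)) {
    abort(sprintf("config line %d is not 'key = value'", bad[1]))
  }
  keys <- vapply(parsed, `[`, character(1), 1)
  vals <- vapply(parsed, `[`, character(1), 2)
  vals <- gsub('^"|"$', "", vals)
  opts <- lapply(split(vals, keys), function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  modifyList(default_run_config(), opts)
}

default_run_config <- function() {
  list(
    mu = 2.5, bin_size = 10, merge_gap = 150, near_exon_distance = 10000,
    extension_gap = 50, extension_max_coverage_diff = 0.5,
    read_length = 75, expression_threshold = 25, alpha = 0.05,
    min_diff = 10, seed = 1
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("%s stage failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full pipeline from files to tables
#'
#' Executes discover, quantify and expressed-element calling, plus repeat
#' enrichment when a repeat track is configured, writing each product to
#' `output_dir` and a manifest listing every output with its row count.
#' Identical configuration and inputs yield identical outputs.
#'
#' @param config A named list (see [read_run_config()]) or a path to a
#'   config file. Required entries: `gtf`, `bedgraph` (one or more
#'   paths), `library_sizes` (comma-separated, aligned with `bedgraph`),
#'   `sample_ids` (idem). Optional: `groups` (comma-separated cell type
#'   per sample; defaults to one shared cell type), `repeats` (repeat
#'   track path), and any discovery option.
#' @param output_dir Directory for outputs (created if needed).
#' @return The manifest tibble (`file`, `n_rows`), invisibly; also
#'   written as `manifest.tsv`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  for (key in c("gtf", "bedgraph", "library_sizes", "sample_ids")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config is missing required entry '%s'", key))
    }
  }
  split_csv <- function(x) {
    if (is.character(x)) unlist(strsplit(x, ",\\s*")) else x
  }
  bedgraphs <- split_csv(config$bedgraph)
  sample_ids <- split_csv(config$sample_ids)
  lib_sizes <- as.numeric(split_csv(config$library_sizes))
  if (length(bedgraphs) != length(sample_ids) ||
      length(bedgraphs) != length(lib_sizes)) {
    abort("bedgraph, sample_ids and library_sizes must align")
  }
  if (anyDuplicated(sample_ids)) abort("sample ids must be unique")
  missing_files <- c(config$gtf, bedgraphs, config$repeats)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files)) {
    abort(sprintf("input file not found: %s", missing_files[1]))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- discovery_config(
    mu = config$mu, bin_size = config$bin_size,
    merge_gap = config$merge_gap,
    near_exon_distance = config$near_exon_distance,
    extension_gap = config$extension_gap,
    extension_max_coverage_diff = config$extension_max_coverage_diff,
    read_length = config$read_length
  )

  universe <- run_stage("annotation", {
    build_exon_universe(read_gene_annotation(config$gtf))
  })
  tracks <- run_stage("coverage", {
    tr <- purrr::pmap(
      list(bedgraphs, lib_sizes, sample_ids),
      function(p, l, s) read_bedgraph(p, library_size = l, sample_id = s)
    )
    names(tr) <- sample_ids
    tr
  })
  discovery <- run_stage("discover", discover(tracks, universe, cfg))
  for (i in seq_along(tracks)) {
    inform(sprintf(
      "sample %s: mu=%.2f RPM over %s reads -> absolute depth threshold %.3f",
      sample_ids[i], cfg$mu, format(lib_sizes[i], scientific = FALSE),
      discovery$thresholds$absolute_depth[i]
    ))
  }
  expression <- run_stage(
    "quantify",
    quantify_res(discovery, tracks, read_length = cfg$read_length)
  )
  groups <- split_csv(config$groups %||% rep("all", length(sample_ids)))
  names(groups) <- sample_ids
  calls <- run_stage("call_expressed", {
    call_expressed(expression, groups,
                   threshold = config$expression_threshold)
  })

  outputs <- list()
  re_bed <- file.path(output_dir, "res.bed")
  re_tsv <- file.path(output_dir, "res.tsv")
  write_res(discovery, bed_path = re_bed, tsv_path = re_tsv)
  outputs[[re_bed]] <- nrow(discovery$elements)
  outputs[[re_tsv]] <- nrow(discovery$elements)
  rpkm_tsv <- file.path(output_dir, "rpkm.tsv")
  write_expression_tsv(expression, rpkm_tsv, elements = discovery)
  outputs[[rpkm_tsv]] <- length(unique(expression$re_id))
  expressed_tsv <- file.path(output_dir, "expressed.tsv")
  readr::write_tsv(calls, expressed_tsv)
  outputs[[expressed_tsv]] <- nrow(calls)

  if (!is.null(config$repeats)) {
    enrichment <- run_stage("enrich", {
      repeats <- read_repeat_track(config$repeats)
      purrr::map_dfr(unique(calls$cell_type), function(ct) {
        ids <- calls$re_id[calls$cell_type == ct & calls$expressed]
        test_repeat_enrichment(
          discovery, ids, repeats,
          alpha = config$alpha, min_diff = config$min_diff
        ) |> mutate(cell_type = ct, .before = 1)
      })
    })
    enr_tsv <- file.path(output_dir, "enrichment.tsv")
    readr::write_tsv(enrichment, enr_tsv)
    outputs[[enr_tsv]] <- nrow(enrichment)
  }

  manifest <- tibble(
    file = basename(names(outputs)),
    n_rows = unlist(outputs, use.names = FALSE)
  )
  readr::write_tsv(manifest, file.path(output_dir, "manifest.tsv"))
  invisible(manifest)
}
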