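# RPKM quantification of RNA elements and expressed-RE calling at the
# 25 RPKM median threshold.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * read_count / (library_size * re_length)`.
#'
#' @param read_count Reads overlapping the element (vectorised).
#' @param re_length Element length in bp.
#' @param library_size Mapped reads in the library.
#' @return Numeric RPKM values.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6) # 10
rpkm <- function(read_count, re_length, library_size) {
  if (any(re_length <= 0)) abort("re_length must be > 0")
  if (any(library_size <= 0)) abort("library_size must be > 0")
  if (any(read_count < 0)) abort("read_count must be >= 0")
  1e9 * read_count / (library_size * re_length)
}

#' Quantify RNA elements from coverage tracks
#'
#' Estimates per-element read counts from coverage as the total per-base
#' depth over the element divided by the read length, then converts to
#' RPKM per sample. Elements on chromosomes absent from a sample's track
#' get 0 with a warning.
#'
#' @param discovery An `re_discovery` or an element tibble with `id`,
#'   `chrom`, `start`, `end`.
#' @param tracks List of `coverage_track` objects.
#' @param read_length Read length in bp used to convert depth mass to an
#'   approximate read count (default 75).
#' @return An `re_expression` tibble in long form: `re_id`, `sample_id`,
#'   `read_count`, `rpkm`.
#' @export
quantify_res <- function(discovery, tracks, read_length = 75L) {
  el <- if (inherits(discovery, "re_discovery")) discovery$elements
        else as_tibble(discovery)
  if (anyDuplicated(el$id)) abort("element ids must be unique")
  stopifnot(read_length > 0)
  gi <- as_granges0(el[c("chrom", "start", "end")])
  out <- purrr::map_dfr(tracks, function(track) {
    tr <- as_tibble(track)
    lib <- attr(track, "library_size")
    sid <- attr(track, "sample_id")
    missing_chrom <- setdiff(unique(el$chrom), unique(tr$chrom))
    if (length(missing_chrom)) {
      warn(sprintf(
        "sample '%s' has no coverage on chromosome(s) %s; affected elements set to 0",
        sid, paste(missing_chrom, collapse = ", ")
      ))
    }
    mass <- numeric(nrow(el))
    if (nrow(tr)) {
      # the absent-chromosome case is reported above; silence the
      # no-common-seqlevels chatter from the overlap engine
      hits <- suppressWarnings(GenomicRanges::findOverlaps(
        gi, as_granges0(tr[c("chrom", "start", "end")])
      ))
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        ov <- pmin(el$end[q], tr$end[s]) - pmax(el$start[q], tr$start[s])
        agg <- tapply(ov * tr$depth[s], q, sum)
        mass[as.integer(names(agg))] <- agg
      }
    }
    count <- mass / read_length
    tibble(
      re_id = el$id,
      sample_id = sid,
      read_count = count,
      rpkm = rpkm(count, el$end - el$start, lib)
    )
  })
  class(out) <- c("re_expression", class(out))
  out
}

#' Quantify RNA elements from explicit read placements
#'
#' Counts reads by at-least-one-base overlap with each element; a read
#' overlapping two elements counts once in each.
#'
#' @param discovery An `re_discovery` or element tibble.
#' @param reads Named list (by sample id) of read-interval tibbles
#'   (`chrom`, `start`, `end`).
#' @param library_sizes Named numeric vector of mapped-read totals.
#' @return An `re_expression` tibble: `re_id`, `sample_id`, `read_count`,
#'   `rpkm`.
#' @export
quantify_res_from_reads <- function(discovery, reads, library_sizes) {
  el <- if (inherits(discovery, "re_discovery")) discovery$elements
        else as_tibble(discovery)
  if (anyDuplicated(el$id)) abort("element ids must be unique")
  stopifnot(!is.null(names(reads)), all(names(reads) %in% names(library_sizes)))
  gi <- as_granges0(el[c("chrom", "start", "end")])
  out <- purrr::imap_dfr(reads, function(rd, sid) {
    count <- integer(nrow(el))
    if (nrow(rd)) {
      hits <- GenomicRanges::findOverlaps(
        gi, as_granges0(rd[c("chrom", "start", "end")])
      )
      cnt <- table(S4Vectors::queryHits(hits))
      count[as.integer(names(cnt))] <- as.integer(cnt)
    }
    tibble(
      re_id = el$id,
      sample_id = sid,
      read_count = as.numeric(count),
      rpkm = rpkm(count, el$end - el$start, library_sizes[[sid]])
    )
  })
  class(out) <- c("re_expression", class(out))
  out
}

#' Call expressed RNA elements per cell type
#'
#' Aggregates each element's RPKM over the samples of a cell type
#' (median by default, matching the expressed-RE definition) and calls
#' the element expressed when the aggregate strictly exceeds the
#' threshold (default 25 RPKM).
#'
#' @param expression An `re_expression` tibble from [quantify_res()] (or
#'   any tibble with `re_id`, `sample_id`, `rpkm`).
#' @param groups Named character vector mapping sample id to cell type.
#' @param threshold Expression threshold in RPKM (default 25; strict `>`).
#' @param aggregator `"median"` (default) or `"mean"`.
#' @return Tibble with `re_id`, `cell_type`, `n_samples`, `agg_rpkm`,
#'   `expressed`.
#' @export
#' @examples
#' expr <- tibble::tibble(
#'   re_id = "re1", sample_id = c("a", "b", "c"), rpkm = c(24, 26, 30)
#' )
#' call_expressed(expr, c(a = "sperm", b = "sperm", c = "sperm"))
call_expressed <- function(expression, groups, threshold = 25,
                           aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  agg_fun <- if (aggregator == "median") stats::median else mean
  missing_group <- setdiff(unique(expression$sample_id), names(groups))
  if (length(missing_group)) {
    abort(sprintf(
      "no cell type assigned to sample(s): %s",
      paste(missing_group, collapse = ", ")
    ))
  }
  expression |>
    mutate(cell_type = unname(groups[.data$sample_id])) |>
    group_by(.data$re_id, .data$cell_type) |>
    summarise(
      n_samples = dplyr::n(),
      agg_rpkm = agg_fun(.data$rpkm),
      .groups = "drop"
    ) |>
    mutate(expressed = .data$agg_rpkm > threshold)
}

#' Write an expression matrix as TSV (elements x samples)
#'
#' @param expression An `re_expression` tibble.
#' @param elements Optional element tibble supplying `class` and
#'   `gene_names` columns for annotation.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path, elements = NULL) {
  wide <- expression |>
    select("re_id", "sample_id", "rpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm")
  if (!is.null(elements)) {
    el <- if (inherits(elements, "re_discovery")) elements$elements
          else elements
    wide <- wide |>
      left_join(
        el |> select(re_id = "id", class = "re_class", "gene_names"),
        by = "re_id"
      ) |>
      dplyr::relocate("class", "gene_names", .after = "re_id")
  }
  readr::write_tsv(wide, path)
  invisible(path)
}
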