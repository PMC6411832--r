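# The discovery core: expressed-bin calling outside exons, gap-merging
# into novel RNA elements, positional classification, cross-sample
# merging, and extension of exonic elements into adjacent novel signal.

#' Discovery configuration
#'
#' Bundles the tunable parameters of RNA-element discovery. Defaults are
#' the canonical values: mean coverage per 10 bp bin, a threshold of
#' mu = 2.5 reads per million, merging across gaps of up to 150 bp, the
#' 10 kb near-exon distance, and exon extension within 50 bp at < 50%
#' relative coverage difference.
#'
#' @param mu Expression threshold in reads per million (RPM).
#' @param bin_size Bin width in bp.
#' @param merge_gap Maximum gap (bp) bridged when fusing expressed bins or
#'   per-sample elements; tolerates coverage holes from fragmentation.
#' @param near_exon_distance Maximum exon distance (bp) for the NearExon
#'   class; greater distances are Orphan.
#' @param extension_gap Maximum gap (bp) between an exonic RE and a
#'   near-exon RE for exon extension.
#' @param extension_max_coverage_diff Maximum relative coverage difference
#'   (fraction of the larger mean depth) for exon extension; the rule is
#'   strict (`< 0.5` by default).
#' @param strict_threshold If `TRUE` (default) a bin must strictly exceed
#'   the absolute depth threshold ("surpassing"); if `FALSE`, `>=` is used.
#' @param read_length Read length (bp) used to estimate read counts from
#'   coverage when quantifying.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(mu = 2.5,
                             bin_size = 10L,
                             merge_gap = 150L,
                             near_exon_distance = 10000L,
                             extension_gap = 50L,
                             extension_max_coverage_diff = 0.5,
                             strict_threshold = TRUE,
                             read_length = 75L) {
  vals <- list(
    mu = mu, bin_size = as.integer(bin_size),
    merge_gap = as.integer(merge_gap),
    near_exon_distance = as.integer(near_exon_distance),
    extension_gap = as.integer(extension_gap),
    extension_max_coverage_diff = extension_max_coverage_diff,
    strict_threshold = isTRUE(strict_threshold),
    read_length = as.integer(read_length)
  )
  num <- c(
    "mu", "bin_size", "merge_gap", "near_exon_distance", "extension_gap",
    "extension_max_coverage_diff", "read_length"
  )
  bad <- num[vapply(vals[num], function(v) !is.numeric(v) || v <= 0,
                    logical(1))]
  if (length(bad)) {
    abort(sprintf("discovery_config: %s must be > 0", bad[1]))
  }
  if (vals$extension_max_coverage_diff > 1) {
    abort("extension_max_coverage_diff must lie in (0, 1]")
  }
  structure(vals, class = "discovery_config")
}

#' @export
print.discovery_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<discovery_config> mu=%.2f RPM, bin=%d bp, merge_gap=%d bp, ",
      "near_exon=%d bp, extend<=%d bp @ <%.0f%% depth diff\n"
    ),
    x$mu, x$bin_size, x$merge_gap, x$near_exon_distance, x$extension_gap,
    100 * x$extension_max_coverage_diff
  ))
  invisible(x)
}

#' Call expressed bins outside annotated exons
#'
#' Retains bins whose mean depth surpasses the sample's absolute depth
#' threshold and which do not overlap any exonic RE by even one base.
#'
#' @param binned A `binned_coverage` from [bin_coverage()].
#' @param threshold One-row tibble from [rpm_to_depth()] (or a single
#'   numeric absolute depth).
#' @param universe An `exon_universe`; bins overlapping its exonic REs are
#'   excluded.
#' @param strict Use strict `>` against the threshold (default `TRUE`).
#' @return Tibble of retained bin intervals: `chrom`, `start`, `end`,
#'   `mean_depth`.
#' @export
call_expressed_bins <- function(binned, threshold, universe,
                                strict = TRUE) {
  depth <- if (is.data.frame(threshold)) threshold$absolute_depth else threshold
  stopifnot(is.numeric(depth), length(depth) == 1)
  bins <- as_tibble(binned)
  keep <- if (strict) bins$mean_depth > depth else bins$mean_depth >= depth
  bins <- bins[keep, , drop = FALSE]
  if (nrow(bins) && nrow(universe$exonic_res)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(bins[c("chrom", "start", "end")]),
      as_granges0(universe$exonic_res[c("chrom", "start", "end")])
    )
    if (length(hits)) {
      bins <- bins[-unique(S4Vectors::queryHits(hits)), , drop = FALSE]
    }
  }
  select(bins, "chrom", "start", "end", "mean_depth")
}

#' Merge intervals separated by at most a fixed gap
#'
#' Fuses intervals whose gap (start of the later minus end of the earlier,
#' half-open coordinates) is at most `merge_gap`; a gap of exactly
#' `merge_gap` is merged. The result is sorted with all pairwise gaps
#' greater than `merge_gap`, independent of input order.
#'
#' @param bins Tibble with `chrom`, `start`, `end`.
#' @param merge_gap Maximum bridged gap in bp (default 150).
#' @return Tibble of merged intervals `chrom`, `start`, `end`.
#' @export
#' @examples
#' merge_bins(tibble::tibble(chrom = "chr1",
#'                           start = c(0, 160), end = c(10, 170)))
merge_bins <- function(bins, merge_gap = 150L) {
  if (nrow(bins) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  check_intervals(bins, "bin")
  merged <- GenomicRanges::reduce(
    as_granges0(bins[c("chrom", "start", "end")]),
    min.gapwidth = merge_gap + 1L
  )
  as_interval_tbl(GenomicRanges::sort(merged)) |>
    arrange(.data$chrom, .data$start)
}

# clip merged novel elements so they never overlap an exonic RE: merging
# across a gap can bridge over an exon shorter than the merge gap
subtract_exons <- function(intervals, universe) {
  if (nrow(intervals) == 0 || nrow(universe$exonic_res) == 0) {
    return(intervals[c("chrom", "start", "end")])
  }
  out <- GenomicRanges::setdiff(
    as_granges0(intervals[c("chrom", "start", "end")]),
    as_granges0(universe$exonic_res[c("chrom", "start", "end")])
  )
  as_interval_tbl(GenomicRanges::sort(out)) |>
    arrange(.data$chrom, .data$start)
}

#' Classify novel RNA elements by position relative to exons
#'
#' Each interval (which must not overlap any exonic RE) is labelled
#' `Intronic` if it lies entirely within an intron of some gene,
#' otherwise `NearExon` if its minimum gap to any exonic RE is at most
#' `near_exon_distance`, otherwise `Orphan`. Intronic takes precedence:
#' near-exon is defined among non-intronic elements only.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (one or more rows).
#' @param universe An `exon_universe`.
#' @param near_exon_distance Distance cutoff in bp (default 10000).
#' @return Character vector of labels, one per row of `intervals`.
#' @export
classify_re <- function(intervals, universe, near_exon_distance = 10000L) {
  if (nrow(intervals) == 0) return(character())
  check_intervals(intervals, "novel RE")
  gr <- as_granges0(intervals[c("chrom", "start", "end")])
  ex <- as_granges0(universe$exonic_res[c("chrom", "start", "end")])

  bad <- GenomicRanges::findOverlaps(gr, ex)
  if (length(bad)) {
    i <- S4Vectors::queryHits(bad)[1]
    abort(sprintf(
      "interval %s:%d-%d overlaps an exonic RE and cannot be classified as novel",
      intervals$chrom[i], intervals$start[i], intervals$end[i]
    ))
  }

  labels <- rep("Orphan", nrow(intervals))

  if (nrow(universe$introns)) {
    within_hits <- GenomicRanges::findOverlaps(
      gr,
      as_granges0(universe$introns[c("chrom", "start", "end")]),
      type = "within"
    )
    labels[unique(S4Vectors::queryHits(within_hits))] <- "Intronic"
  }

  not_intronic <- which(labels != "Intronic")
  if (length(not_intronic) && length(ex)) {
    d <- GenomicRanges::distanceToNearest(gr[not_intronic], ex)
    gap <- rep(Inf, length(not_intronic))
    gap[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    labels[not_intronic[gap <= near_exon_distance]] <- "NearExon"
  }
  labels
}

# host genes of intronic elements (comma-joined), "" otherwise
intronic_host_genes <- function(intervals, universe) {
  out <- rep("", nrow(intervals))
  if (nrow(intervals) == 0 || nrow(universe$introns) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(intervals[c("chrom", "start", "end")]),
    as_granges0(universe$introns[c("chrom", "start", "end")]),
    type = "within"
  )
  if (!length(hits)) return(out)
  genes <- split(
    universe$introns$gene_name[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits)
  )
  joined <- vapply(genes, function(g) paste(sort(unique(g)), collapse = ","),
                   character(1))
  out[as.integer(names(joined))] <- joined
  out
}

#' Merge per-sample novel elements into a collective set
#'
#' Pools every sample's novel (non-exonic) elements, fuses those separated
#' by at most `merge_gap` bp, re-classifies the fused elements, and keeps
#' the union of contributing sample ids. Exonic REs are excluded from the
#' merging and appended unchanged.
#'
#' @param per_sample_novel Named list (by sample id) of tibbles with
#'   `chrom`, `start`, `end`.
#' @param universe An `exon_universe`.
#' @param config A [discovery_config()].
#' @return Tibble of RNA elements: `id`, `chrom`, `start`, `end`,
#'   `re_class`, `gene_names`, `source_samples` (list column),
#'   `n_source_samples`.
#' @export
merge_across_samples <- function(per_sample_novel, universe,
                                 config = discovery_config()) {
  pooled <- bind_rows(per_sample_novel, .id = "sample_id")
  if (nrow(pooled) == 0) {
    novel <- tibble(
      id = character(), chrom = character(), start = integer(),
      end = integer(), re_class = character(), gene_names = character(),
      source_samples = list(), n_source_samples = integer()
    )
  } else {
    merged <- merge_bins(pooled[c("chrom", "start", "end")],
                         merge_gap = config$merge_gap)
    merged <- subtract_exons(merged, universe)
    hits <- GenomicRanges::findOverlaps(
      as_granges0(merged),
      as_granges0(pooled[c("chrom", "start", "end")])
    )
    sources <- lapply(
      split(
        pooled$sample_id[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(merged)))
      ),
      function(s) sort(unique(s))
    )
    merged$re_class <- classify_re(merged, universe,
                                   config$near_exon_distance)
    merged$gene_names <- intronic_host_genes(merged, universe)
    novel <- merged |>
      mutate(
        id = re_id(.data$chrom, .data$start, .data$end),
        source_samples = unname(sources),
        n_source_samples = unname(lengths(sources))
      ) |>
      select(
        "id", "chrom", "start", "end", "re_class", "gene_names",
        "source_samples", "n_source_samples"
      )
  }
  exonic <- universe$exonic_res |>
    mutate(
      re_class = "Exonic",
      source_samples = list(character()),
      n_source_samples = 0L
    ) |>
    select(
      "id", "chrom", "start", "end", "re_class", "gene_names",
      "source_samples", "n_source_samples"
    )
  bind_rows(exonic, novel) |>
    arrange(.data$chrom, .data$start)
}

#' Extend an exonic RE into an adjacent near-exon RE
#'
#' An exonic element absorbs a neighbouring near-exon element when the gap
#' between them is at most `extension_gap` (50 bp by default) and the
#' relative difference in mean read coverage, measured against the larger
#' of the two depths, is strictly below `extension_max_coverage_diff`
#' (50%). The result spans both elements, keeps class `Exonic` and the
#' exonic element's gene names.
#'
#' @param exonic One-row tibble for the exonic element (`chrom`, `start`,
#'   `end`, `gene_names`, optionally `id`).
#' @param novel One-row tibble for the near-exon element.
#' @param exonic_mean_depth,novel_mean_depth Mean per-base depth over each
#'   element.
#' @param config A [discovery_config()].
#' @return The extended one-row tibble, or `NULL` when the rule does not
#'   fire (including when both depths are zero, where the relative
#'   difference is undefined).
#' @export
extend_exonic <- function(exonic, novel, exonic_mean_depth,
                          novel_mean_depth, config = discovery_config()) {
  if (exonic$chrom != novel$chrom) return(NULL)
  gap <- interval_gap(exonic$start, exonic$end, novel$start, novel$end)
  if (gap > config$extension_gap) return(NULL)
  hi <- max(exonic_mean_depth, novel_mean_depth)
  if (hi <= 0) return(NULL)
  rel_diff <- abs(exonic_mean_depth - novel_mean_depth) / hi
  if (rel_diff >= config$extension_max_coverage_diff) return(NULL)
  start <- min(exonic$start, novel$start)
  end <- max(exonic$end, novel$end)
  tibble(
    id = re_id(exonic$chrom, start, end),
    chrom = exonic$chrom, start = start, end = end,
    re_class = "Exonic",
    gene_names = exonic$gene_names
  )
}

# mean per-base depth of each interval, pooled over tracks
pooled_mean_depth <- function(intervals, tracks) {
  if (nrow(intervals) == 0) return(numeric())
  mass <- numeric(nrow(intervals))
  gi <- as_granges0(intervals[c("chrom", "start", "end")])
  for (track in tracks) {
    tr <- as_tibble(track)
    if (nrow(tr) == 0) next
    hits <- GenomicRanges::findOverlaps(
      gi, as_granges0(tr[c("chrom", "start", "end")])
    )
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(intervals$end[q], tr$end[s]) -
      pmax(intervals$start[q], tr$start[s])
    contrib <- tapply(ov * tr$depth[s], q, sum)
    mass[as.integer(names(contrib))] <-
      mass[as.integer(names(contrib))] + contrib
  }
  mass / (length(tracks) * (intervals$end - intervals$start))
}

# one extension pass: each near-exon element may be absorbed by its
# nearest eligible exonic neighbour; no iterative chaining
apply_extension <- function(elements, tracks, config) {
  near <- which(elements$re_class == "NearExon")
  exonic <- which(elements$re_class == "Exonic")
  if (!length(near) || !length(exonic)) return(elements)
  depth <- pooled_mean_depth(elements[c("chrom", "start", "end")], tracks)
  drop <- integer()
  replaced <- list()
  used_exonic <- logical(nrow(elements))
  for (i in near) {
    cand <- exonic[elements$chrom[exonic] == elements$chrom[i] &
                     !used_exonic[exonic]]
    if (!length(cand)) next
    gaps <- interval_gap(
      elements$start[cand], elements$end[cand],
      elements$start[i], elements$end[i]
    )
    cand <- cand[order(gaps)]
    gaps <- sort(gaps)
    if (gaps[1] > config$extension_gap) next
    j <- cand[1]
    ext <- extend_exonic(
      elements[j, ], elements[i, ], depth[j], depth[i], config
    )
    if (is.null(ext)) next
    ext$source_samples <- elements$source_samples[j]
    ext$n_source_samples <- elements$n_source_samples[j]
    replaced[[length(replaced) + 1L]] <- ext
    drop <- c(drop, i, j)
    used_exonic[j] <- TRUE
  }
  if (!length(drop)) return(elements)
  bind_rows(elements[-drop, ], bind_rows(replaced)) |>
    arrange(.data$chrom, .data$start)
}

#' Discover RNA elements from coverage tracks
#'
#' Runs the full discovery pipeline. Per sample: the RPM threshold mu is
#' converted to an absolute depth via the library size, coverage is
#' reduced to mean depth per bin, bins surpassing the threshold outside
#' exons are retained and merged across gaps of up to `merge_gap` bp into
#' per-sample novel elements. Novel elements are then merged across
#' samples (same gap), re-classified, and combined with the exonic REs;
#' finally exonic REs are extended into adjacent near-exon elements where
#' coverage is similar.
#'
#' @param tracks List of `coverage_track` objects (one per sample).
#' @param universe An `exon_universe`.
#' @param config A [discovery_config()].
#' @param extend Apply the exon-extension step (default `TRUE`).
#' @return An `re_discovery` object: list with `elements` (the collective
#'   RE tibble), `per_sample` (per-sample novel elements before
#'   cross-sample merging), `thresholds` (per-sample absolute depths), and
#'   `config`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
discover <- function(tracks, universe, config = discovery_config(),
                     extend = TRUE) {
  stopifnot(length(tracks) >= 1, inherits(universe, "exon_universe"))
  ids <- vapply(tracks, function(t) attr(t, "sample_id"), character(1))
  if (anyDuplicated(ids)) abort("sample ids must be unique")
  names(tracks) <- ids

  thresholds <- purrr::map_dfr(tracks, function(track) {
    rpm_to_depth(config$mu, attr(track, "library_size"))
  }) |> mutate(sample_id = ids, .before = 1)

  per_sample <- purrr::map2(tracks, thresholds$absolute_depth,
    function(track, depth) {
      binned <- bin_coverage(track, config$bin_size)
      bins <- call_expressed_bins(
        binned, depth, universe, strict = config$strict_threshold
      )
      el <- merge_bins(bins, config$merge_gap)
      el <- subtract_exons(el, universe)
      if (nrow(el)) {
        el$re_class <- classify_re(el, universe, config$near_exon_distance)
      } else {
        el$re_class <- character()
      }
      el
    })

  elements <- merge_across_samples(per_sample, universe, config)
  if (extend) {
    elements <- apply_extension(elements, tracks, config)
  }
  structure(
    list(
      elements = elements,
      per_sample = per_sample,
      thresholds = thresholds,
      config = config
    ),
    class = "re_discovery"
  )
}

#' @export
print.re_discovery <- function(x, ...) {
  counts <- table(x$elements$re_class)
  cat(sprintf(
    "<re_discovery> %d RNA elements from %d sample(s) at mu=%.2f RPM\n",
    nrow(x$elements), nrow(x$thresholds), x$config$mu
  ))
  print(counts)
  invisible(x)
}

#' @describeIn discover Tidy the element table of a discovery result.
#' @param x An `re_discovery`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.re_discovery <- function(x, ...) {
  x$elements
}

#' @describeIn discover One-row summary: element counts per class and the
#'   per-sample depth thresholds used.
#' @exportS3Method generics::glance
glance.re_discovery <- function(x, ...) {
  cls <- factor(
    x$elements$re_class,
    levels = c("Exonic", "Intronic", "NearExon", "Orphan")
  )
  counts <- table(cls)
  tibble(
    n_elements = nrow(x$elements),
    n_exonic = as.integer(counts[["Exonic"]]),
    n_intronic = as.integer(counts[["Intronic"]]),
    n_near_exon = as.integer(counts[["NearExon"]]),
    n_orphan = as.integer(counts[["Orphan"]]),
    n_samples = nrow(x$thresholds),
    mu = x$config$mu
  )
}

#' Write RNA elements as BED6 and TSV
#'
#' The BED name column is `id|class|genes`; the TSV carries one row per
#' element with the source-sample count.
#'
#' @param discovery An `re_discovery` (or its `elements` tibble).
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the element tibble written.
#' @export
write_res <- function(discovery, bed_path = NULL, tsv_path = NULL) {
  el <- if (inherits(discovery, "re_discovery")) discovery$elements
        else discovery
  if (!is.null(bed_path)) {
    readr::write_tsv(
      tibble(
        chrom = el$chrom, start = el$start, end = el$end,
        name = paste(el$id, el$re_class, el$gene_names, sep = "|"),
        score = 0L, strand = "."
      ),
      bed_path,
      col_names = FALSE
    )
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(
      el |>
        mutate(source_samples = vapply(
          .data$source_samples, paste, character(1), collapse = ","
        )) |>
        select(
          "id", "chrom", "start", "end",
          class = "re_class", "gene_names", "n_source_samples"
        ),
      tsv_path
    )
  }
  invisible(el)
}
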