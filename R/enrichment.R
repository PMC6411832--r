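# Repeat-family enrichment/depletion of expressed RNA elements:
# hypergeometric tails, Bonferroni correction and the >10-element
# observed-vs-expected effect filter.

#' Read a RepeatMasker-style repeat annotation
#'
#' Accepts BED-like TSV with columns chrom, start, end, repeat name and
#' optionally repeat class and family (header optional; detected when the
#' first line's coordinates are non-numeric).
#'
#' @param path Path to the repeat track.
#' @return Tibble with `chrom`, `start`, `end`, `repeat_name`,
#'   `repeat_class`, `repeat_family`.
#' @export
read_repeat_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("repeat track not found: %s", path))
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2 && is.na(suppressWarnings(as.numeric(fields[2])))
  tb <- readr::read_tsv(
    path, col_names = has_header, show_col_types = FALSE,
    comment = "#", progress = FALSE
  )
  if (!has_header) {
    nm <- c("chrom", "start", "end", "repeat_name", "repeat_class",
            "repeat_family")
    names(tb)[seq_len(min(ncol(tb), length(nm)))] <-
      nm[seq_len(min(ncol(tb), length(nm)))]
  }
  need <- c("chrom", "start", "end", "repeat_name")
  if (!all(need %in% names(tb))) {
    abort("repeat track needs columns chrom, start, end, repeat_name")
  }
  if (!"repeat_class" %in% names(tb)) tb$repeat_class <- NA_character_
  if (!"repeat_family" %in% names(tb)) tb$repeat_family <- NA_character_
  out <- as_tibble(tb)[c("chrom", "start", "end", "repeat_name",
                         "repeat_class", "repeat_family")]
  check_intervals(out, "repeat")
  out
}

#' Assign repeat names to RNA elements by overlap
#'
#' An element carries a repeat name when the two intervals intersect by at
#' least one base; an element may carry several repeat names.
#'
#' @param elements Element tibble (`id`, `chrom`, `start`, `end`) or an
#'   `re_discovery`.
#' @param repeats Repeat tibble from [read_repeat_track()].
#' @return Tibble of distinct (`re_id`, `repeat_name`) pairs, with
#'   `repeat_class` and `repeat_family` carried along.
#' @export
annotate_repeat_overlap <- function(elements, repeats) {
  el <- if (inherits(elements, "re_discovery")) elements$elements
        else as_tibble(elements)
  if (nrow(el) == 0 || nrow(repeats) == 0) {
    return(tibble(
      re_id = character(), repeat_name = character(),
      repeat_class = character(), repeat_family = character()
    ))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges0(el[c("chrom", "start", "end")]),
    as_granges0(repeats[c("chrom", "start", "end")])
  )
  tibble(
    re_id = el$id[S4Vectors::queryHits(hits)],
    repeat_name = repeats$repeat_name[S4Vectors::subjectHits(hits)],
    repeat_class = repeats$repeat_class[S4Vectors::subjectHits(hits)],
    repeat_family = repeats$repeat_family[S4Vectors::subjectHits(hits)]
  ) |>
    distinct(.data$re_id, .data$repeat_name, .keep_all = TRUE)
}

#' Hypergeometric enrichment and depletion tails
#'
#' For X ~ Hypergeometric(N, K, n) (a sample of `n` elements drawn without
#' replacement from a universe of `N` of which `K` overlap the repeat),
#' returns `p_enrich = P(X >= k)` and `p_deplete = P(X <= k)`.
#'
#' @param k Observed overlapping elements in the sample (vectorised).
#' @param n Sample size (expressed elements).
#' @param K Universe hits (elements overlapping the repeat).
#' @param N Universe size (all elements).
#' @return Tibble with `p_enrich`, `p_deplete`.
#' @export
#' @examples
#' hypergeom_enrichment(4, 4, 5, 10) # p_enrich = 5/210
hypergeom_enrichment <- function(k, n, K, N) {
  args <- tibble(k = k, n = n, K = K, N = N)
  with(args, {
    if (any(K > N | n > N | k > n | k > K | k < 0 | pmin(N, K, n) < 0)) {
      abort("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
    }
  })
  tibble(
    p_enrich = phyper(args$k - 1, args$K, args$N - args$K, args$n,
                      lower.tail = FALSE),
    p_deplete = phyper(args$k, args$K, args$N - args$K, args$n)
  )
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with `m` defaulting to the number of tests.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Test repeat enrichment and depletion among expressed elements
#'
#' For each repeat name, the universe is the full element set (size `N`,
#' of which `K` overlap the repeat — the repeat's universe proportion),
#' the sample is the set of expressed elements for the cell type (size
#' `n`, of which `k` overlap). Both hypergeometric tails are computed, the
#' tail matching the observed direction is Bonferroni-corrected over the
#' number of repeat names tested, and repeats are retained when the
#' adjusted p-value is below `alpha` and the observed count differs from
#' expectation (`n * K / N`) by more than `min_diff` elements.
#'
#' @param elements Element tibble or `re_discovery` (the universe).
#' @param expressed_ids Character vector of expressed element ids for one
#'   cell type.
#' @param repeats Repeat tibble from [read_repeat_track()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param min_diff Minimum |observed - expected| in elements (default 10,
#'   strict `>`).
#' @param level Test at the `repeat_name` (default), `repeat_family` or
#'   `repeat_class` level.
#' @return An `re_enrichment` tibble: `repeat_name`, `N`, `K`, `n`, `k`,
#'   `expected`, `p_enrich`, `p_deplete`, `p_adj`, `direction`,
#'   `retained`.
#' @export
test_repeat_enrichment <- function(elements, expressed_ids, repeats,
                                   alpha = 0.05, min_diff = 10,
                                   level = c("repeat_name", "repeat_family",
                                             "repeat_class")) {
  level <- match.arg(level)
  el <- if (inherits(elements, "re_discovery")) elements$elements
        else as_tibble(elements)
  overlap <- annotate_repeat_overlap(el, repeats)
  overlap$feature <- overlap[[level]]
  overlap <- distinct(overlap, .data$re_id, .data$feature)
  N <- nrow(el)
  n <- sum(el$id %in% expressed_ids)
  per_repeat <- overlap |>
    group_by(.data$feature) |>
    summarise(
      K = dplyr::n_distinct(.data$re_id),
      k = dplyr::n_distinct(.data$re_id[.data$re_id %in% expressed_ids]),
      .groups = "drop"
    )
  if (nrow(per_repeat) == 0) {
    out <- tibble(
      repeat_name = character(), N = integer(), K = integer(),
      n = integer(), k = integer(), expected = numeric(),
      p_enrich = numeric(), p_deplete = numeric(), p_adj = numeric(),
      direction = character(), retained = logical()
    )
    class(out) <- c("re_enrichment", class(out))
    return(out)
  }
  tails <- hypergeom_enrichment(per_repeat$k, n, per_repeat$K, N)
  m <- nrow(per_repeat)
  out <- per_repeat |>
    mutate(
      repeat_name = .data$feature,
      N = N, n = n,
      expected = n * .data$K / N,
      p_enrich = tails$p_enrich,
      p_deplete = tails$p_deplete,
      direction = dplyr::case_when(
        .data$k > .data$expected ~ "enriched",
        .data$k < .data$expected ~ "depleted",
        TRUE ~ "none"
      ),
      p_adj = bonferroni(
        ifelse(.data$direction == "depleted", .data$p_deplete,
               .data$p_enrich),
        m
      ),
      retained = abs(.data$k - .data$expected) > min_diff &
        .data$p_adj < alpha
    ) |>
    select(
      "repeat_name", "N", "K", "n", "k", "expected",
      "p_enrich", "p_deplete", "p_adj", "direction", "retained"
    ) |>
    arrange(.data$p_adj)
  class(out) <- c("re_enrichment", class(out))
  out
}

#' Filter enrichment results by effect size
#'
#' Keeps repeats whose observed expressed-element count differs from the
#' expected count by strictly more than `min_diff` elements and whose
#' adjusted p-value is below `alpha`.
#'
#' @param results An `re_enrichment` tibble.
#' @param min_diff Minimum |observed - expected| (default 10).
#' @param alpha Significance level (default 0.05).
#' @return The filtered tibble.
#' @export
effect_filter <- function(results, min_diff = 10, alpha = 0.05) {
  filter(
    results,
    abs(.data$k - .data$expected) > min_diff, .data$p_adj < alpha
  )
}

#' @describeIn test_repeat_enrichment One-row summary of an enrichment
#'   table.
#' @param x An `re_enrichment`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.re_enrichment <- function(x, ...) {
  tibble(
    n_repeats_tested = nrow(x),
    n_retained = sum(x$retained),
    n_enriched = sum(x$direction == "enriched" & x$retained),
    n_depleted = sum(x$direction == "depleted" & x$retained)
  )
}
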