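# Internal interval plumbing. All user-visible coordinates are 0-based,
# half-open [start, end), matching BED/bedGraph. GRanges (1-based, closed)
# are used internally for overlap and distance queries.

#' Convert an interval tibble to GRanges
#'
#' @param df data frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @return A `GRanges` with any extra columns carried as metadata.
#' @keywords internal
#' @noRd
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[extra])
  }
  gr
}

#' Convert a GRanges back to a 0-based half-open interval tibble
#' @keywords internal
#' @noRd
as_interval_tbl <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) {
    out <- dplyr::bind_cols(out, as_tibble(as.data.frame(mc)))
  }
  out
}

#' Validate an interval tibble
#' @keywords internal
#' @noRd
check_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    abort(sprintf(
      "%s record %d is invalid: start=%s end=%s (need 0 <= start < end)",
      what, bad[1], df$start[bad[1]], df$end[bad[1]]
    ))
  }
  invisible(df)
}

#' Gap between two half-open intervals on the same chromosome
#'
#' Defined as `start(later) - end(earlier)`; overlapping or touching
#' intervals have gap <= 0.
#' @keywords internal
#' @noRd
interval_gap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) - pmin(end1, end2)
}

#' Stable coordinate-derived element id, "chrom_start_end"
#' @keywords internal
#' @noRd
re_id <- function(chrom, start, end) {
  sprintf("%s_%d_%d", chrom, as.integer(start), as.integer(end))
}

#' Total per-base size of the union of a set of intervals
#' @keywords internal
#' @noRd
union_bp <- function(df) {
  if (nrow(df) == 0) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(as_granges0(df))))
}

#' Per-base Jaccard index between two interval sets
#'
#' @param a,b data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return Intersection size over union size in base pairs; 1 when both
#'   sets are empty.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' jaccard_bp(a, b) # 50 / 150
jaccard_bp <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
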