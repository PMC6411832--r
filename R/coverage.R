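# Coverage input and binning: bedGraph step tracks, mean depth per fixed
# 10 bp bin, and the RPM -> absolute-depth threshold conversion.

#' Read a bedGraph coverage track
#'
#' bedGraph records are 0-based half-open and are kept that way. Records
#' are validated to be non-overlapping within each chromosome; positions
#' not listed have depth 0.
#'
#' @param path Path to a bedGraph file (optional `track`/`#` header lines
#'   are skipped). BigWig input can be converted upstream to bedGraph; the
#'   step representation used here is identical.
#' @param library_size Total mapped reads for the sample (used for RPM and
#'   RPKM normalisation).
#' @param sample_id Sample identifier.
#' @return A `coverage_track`: a tibble with columns `chrom`, `start`,
#'   `end`, `depth`, sorted within chromosome, with attributes
#'   `library_size` and `sample_id`.
#' @export
read_bedgraph <- function(path, library_size, sample_id = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("bedGraph file not found: %s", path))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  tb <- as_interval_tbl(gr)
  names(tb)[names(tb) == "score"] <- "depth"
  if (nrow(tb) == 0) {
    tb <- tibble(
      chrom = character(), start = integer(), end = integer(),
      depth = numeric()
    )
  }
  coverage_track(tb, library_size = library_size, sample_id = sample_id)
}

#' Construct a coverage track from a step tibble
#'
#' @param steps Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `depth`.
#' @param library_size Total mapped reads.
#' @param sample_id Sample identifier.
#' @return A `coverage_track` tibble.
#' @export
coverage_track <- function(steps, library_size, sample_id) {
  stopifnot(is.numeric(library_size), length(library_size) == 1,
            library_size > 0)
  steps <- as_tibble(steps)[c("chrom", "start", "end", "depth")]
  check_intervals(steps, "bedGraph")
  if (any(steps$depth < 0)) {
    abort("bedGraph depths must be >= 0")
  }
  if (nrow(steps) > 1) {
    same_chrom <- steps$chrom[-1] == steps$chrom[-nrow(steps)]
    unsorted <- which(same_chrom & steps$start[-1] < steps$start[-nrow(steps)])
    if (length(unsorted)) {
      i <- unsorted[1] + 1L
      abort(sprintf(
        "bedGraph records are not sorted within chromosome (record %d: %s:%d-%d)",
        i, steps$chrom[i], steps$start[i], steps$end[i]
      ))
    }
  }
  steps <- arrange(steps, .data$chrom, .data$start)
  if (nrow(steps) > 1) {
    same_chrom <- steps$chrom[-1] == steps$chrom[-nrow(steps)]
    overl <- which(same_chrom & steps$start[-1] < steps$end[-nrow(steps)])
    if (length(overl)) {
      i <- overl[1] + 1L
      abort(sprintf(
        "overlapping bedGraph records at record %d (%s:%d-%d)",
        i, steps$chrom[i], steps$start[i], steps$end[i]
      ))
    }
  }
  structure(
    steps,
    library_size = library_size,
    sample_id = sample_id,
    class = c("coverage_track", class(steps))
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> sample '%s', library %s reads, %d steps on %d chromosome(s)\n",
    attr(x, "sample_id"), format(attr(x, "library_size"), big.mark = ","),
    nrow(x), length(unique(x$chrom))
  ))
  NextMethod()
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(
    as_tibble(track)[c("chrom", "start", "end", "depth")],
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Depth of a coverage track at single positions
#' @keywords internal
#' @noRd
depth_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(out)
  for (i in seq_along(pos)) {
    hit <- which(tr$start <= pos[i] & pos[i] < tr$end)
    if (length(hit)) out[i] <- tr$depth[hit[1]]
  }
  out
}

#' Reduce a coverage track to mean depth per fixed bin
#'
#' Bins lie on a fixed genome-wide grid anchored at coordinate 0: bin `b`
#' covers `[b * bin_size, (b + 1) * bin_size)`. Each bin's value is the
#' arithmetic mean of per-base depth over its `bin_size` bases, with
#' unlisted bases counted as depth 0. Bins with mean 0 are omitted.
#'
#' @param track A `coverage_track`.
#' @param bin_size Bin width in bp (default 10).
#' @return A `binned_coverage`: tibble with `chrom`, `bin`, `start`, `end`,
#'   `mean_depth`, carrying `bin_size`, `library_size` and `sample_id`
#'   attributes.
#' @export
bin_coverage <- function(track, bin_size = 10L) {
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  steps <- as_tibble(track) |> filter(.data$depth > 0)
  if (nrow(steps) == 0) {
    binned <- tibble(
      chrom = character(), bin = integer(), start = integer(),
      end = integer(), mean_depth = numeric()
    )
  } else {
    b0 <- steps$start %/% bin_size
    b1 <- (steps$end - 1L) %/% bin_size
    nb <- b1 - b0 + 1L
    idx <- rep.int(seq_len(nrow(steps)), nb)
    bin <- b0[idx] + sequence(nb) - 1L
    ov <- pmin(steps$end[idx], (bin + 1L) * bin_size) -
      pmax(steps$start[idx], bin * bin_size)
    binned <- tibble(
      chrom = steps$chrom[idx], bin = bin,
      mass = steps$depth[idx] * ov
    ) |>
      group_by(.data$chrom, .data$bin) |>
      summarise(mass = sum(.data$mass), .groups = "drop") |>
      mutate(
        start = .data$bin * bin_size,
        end = (.data$bin + 1L) * bin_size,
        mean_depth = .data$mass / bin_size
      ) |>
      select("chrom", "bin", "start", "end", "mean_depth") |>
      arrange(.data$chrom, .data$bin)
  }
  structure(
    binned,
    bin_size = bin_size,
    library_size = attr(track, "library_size"),
    sample_id = attr(track, "sample_id"),
    class = c("binned_coverage", class(binned))
  )
}

#' Convert a reads-per-million threshold to absolute depth
#'
#' The discovery threshold mu is expressed in reads per million mapped
#' reads (RPM) and converted per sample to an absolute read depth:
#' `absolute_depth = mu * library_size / 1e6`.
#'
#' @param mu Threshold in RPM (default 2.5).
#' @param library_size Mapped reads in the sample's library.
#' @return One-row tibble with `mu`, `library_size`, `absolute_depth`.
#' @export
#' @examples
#' rpm_to_depth(2.5, 2e7) # absolute_depth 50
rpm_to_depth <- function(mu = 2.5, library_size) {
  if (!is.numeric(mu) || mu <= 0) abort("mu must be > 0")
  if (!is.numeric(library_size) || library_size <= 0) {
    abort("library_size must be > 0")
  }
  tibble(
    mu = mu,
    library_size = library_size,
    absolute_depth = mu * library_size / 1e6
  )
}
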