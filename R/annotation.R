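# Gene-annotation input: parse GTF/GFF exons and build the disjoint exon
# universe (exonic REs) plus per-gene introns used by discovery.

#' Parse a gene annotation into exon records
#'
#' Reads a GTF/GFF gene annotation and returns one record per exon feature,
#' converted from the 1-based inclusive GTF convention to 0-based half-open
#' coordinates. Non-coding entries are treated as exons: any `transcript`
#' (or `gene`) feature whose transcript carries no `exon` children is kept
#' as a single exon spanning the feature.
#'
#' @param path Path to a GTF/GFF file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_name`, `feature_biotype` (one row per exon).
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste(
#'   "chr1\tsrc\texon\t101\t200\t.\t+\t.",
#'   "gene_id \"g1\"; gene_name \"G1\";"), gtf)
#' read_gene_annotation(gtf)
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path))
  }
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"type" %in% names(S4Vectors::mcols(gr))) {
    abort("annotation has no feature-type column; is this a GTF/GFF file?")
  }
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    abort("annotation lacks a gene_id attribute")
  }
  tb <- as_interval_tbl(gr)
  tb$type <- as.character(tb$type)
  if (!"gene_name" %in% names(tb)) tb$gene_name <- NA_character_
  if (!"strand" %in% names(tb)) tb$strand <- "*"
  biotype_col <- intersect(
    c("gene_type", "gene_biotype", "transcript_type", "transcript_biotype"),
    names(tb)
  )
  tb$feature_biotype <- if (length(biotype_col)) {
    as.character(tb[[biotype_col[1]]])
  } else {
    NA_character_
  }
  if ("transcript_id" %in% names(tb)) {
    tx_with_exons <- unique(tb$transcript_id[tb$type == "exon"])
  } else {
    tb$transcript_id <- NA_character_
    tx_with_exons <- character()
  }

  exons <- tb[tb$type == "exon", , drop = FALSE]
  # non-coding / exon-less entries kept as single-exon records
  orphans <- tb[
    tb$type %in% c("transcript", "gene") &
      !(tb$transcript_id %in% tx_with_exons) &
      !(tb$type == "gene" & tb$gene_id %in% exons$gene_id),
    ,
    drop = FALSE
  ]
  if (nrow(orphans)) {
    # prefer the transcript row when both gene and transcript rows exist
    has_tx <- orphans$gene_id[orphans$type == "transcript"]
    orphans <- orphans[orphans$type == "transcript" |
      !(orphans$gene_id %in% has_tx), , drop = FALSE]
  }
  out <- bind_rows(exons, orphans)
  missing_id <- which(is.na(out$gene_id) | out$gene_id == "")
  if (length(missing_id)) {
    abort(sprintf(
      "exon record %d (%s:%d-%d) has no gene_id",
      missing_id[1], out$chrom[missing_id[1]],
      out$start[missing_id[1]], out$end[missing_id[1]]
    ))
  }
  out$gene_name <- ifelse(
    is.na(out$gene_name) | out$gene_name == "", out$gene_id, out$gene_name
  )
  out <- out[c(
    "chrom", "start", "end", "strand", "gene_id", "gene_name",
    "feature_biotype"
  )]
  check_intervals(as_tibble(out), "exon")
  as_tibble(out)
}

# cheap structural validation so malformed lines are reported by number
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8)) {
    lineno <- which(body)[which(nfield < 8)[1]]
    abort(sprintf(
      "malformed annotation line %d: expected >= 8 tab-separated fields, found %d",
      lineno, nfield[which(nfield < 8)[1]]
    ))
  }
  invisible(TRUE)
}

#' Build the exon universe from exon records
#'
#' Collapses redundant transcript-level exons into a single disjoint exon
#' track: overlapping or duplicated exon intervals on a chromosome (from
#' the same or different genes) are merged into disjoint "exonic REs", each
#' carrying the union of contributing gene names. Per-gene introns are
#' computed as the gaps between each gene's own merged exons within the
#' gene's span.
#'
#' @param exons A tibble of exon records as returned by
#'   [read_gene_annotation()] (needs `chrom`, `start`, `end`, `gene_id`,
#'   `gene_name`).
#' @return An object of class `exon_universe`: a list with
#'   \describe{
#'     \item{exonic_res}{tibble of disjoint merged exon intervals with
#'       `id`, `chrom`, `start`, `end`, `gene_names` (comma-joined)}
#'     \item{introns}{tibble of per-gene intron intervals with `chrom`,
#'       `start`, `end`, `gene_id`, `gene_name`}
#'   }
#' @export
build_exon_universe <- function(exons) {
  if (nrow(exons) == 0) {
    out <- list(
      exonic_res = tibble(
        id = character(), chrom = character(),
        start = integer(), end = integer(), gene_names = character()
      ),
      introns = tibble(
        chrom = character(), start = integer(), end = integer(),
        gene_id = character(), gene_name = character()
      )
    )
    class(out) <- "exon_universe"
    return(out)
  }
  check_intervals(exons, "exon")
  if (!"gene_name" %in% names(exons)) exons$gene_name <- exons$gene_id
  gr <- as_granges0(exons[c("chrom", "start", "end")])
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  names_by_merged <- vapply(
    split(
      exons$gene_name[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits)
    ),
    function(x) paste(sort(unique(x)), collapse = ","),
    character(1)
  )
  exonic <- as_interval_tbl(merged)
  exonic$gene_names <- ""
  exonic$gene_names[as.integer(names(names_by_merged))] <- names_by_merged
  exonic <- exonic |>
    arrange(.data$chrom, .data$start) |>
    mutate(id = re_id(.data$chrom, .data$start, .data$end)) |>
    select("id", "chrom", "start", "end", "gene_names")

  introns <- exons |>
    group_by(.data$gene_id, .data$gene_name, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      g <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      if (length(g) < 2) {
        return(tibble(start = integer(), end = integer()))
      }
      # gap between consecutive merged exons, back in 0-based half-open
      tibble(
        start = IRanges::end(g)[-length(g)],
        end = IRanges::start(g)[-1] - 1L
      )
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "gene_id", "gene_name") |>
    arrange(.data$chrom, .data$start)

  out <- list(exonic_res = exonic, introns = introns)
  class(out) <- "exon_universe"
  out
}

#' @export
print.exon_universe <- function(x, ...) {
  cat(sprintf(
    "<exon_universe> %d exonic REs (%d bp), %d introns across %d genes\n",
    nrow(x$exonic_res), union_bp(x$exonic_res), nrow(x$introns),
    length(unique(x$introns$gene_id))
  ))
  invisible(x)
}

#' Write the exon universe as BED6
#'
#' One line per exonic RE; the BED name column holds the comma-joined gene
#' names contributing to the merged exon.
#'
#' @param universe An `exon_universe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_universe <- function(universe, path) {
  stopifnot(inherits(universe, "exon_universe"))
  df <- universe$exonic_res
  readr::write_tsv(
    tibble(
      chrom = df$chrom, start = df$start, end = df$end,
      name = df$gene_names, score = 0L, strand = "."
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}
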