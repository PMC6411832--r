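# Deterministic synthetic fixtures: a toy genome with genes and exons,
# repeat features, planted RNA elements of every class, and noisy
# per-sample coverage tracks, plus recovery scoring against the planted
# truth. Everything needed to exercise the pipeline without external data.

#' Fixture generator configuration
#'
#' The generated genome places its genes in the left part of each
#' chromosome and keeps the right part gene-free, so orphan elements can
#' be planted more than 10 kb from every exon. Background coverage is
#' over-dispersed negative-binomial noise per 10 bp bin, truncated safely
#' below the mu = 2.5 RPM depth threshold for the configured library
#' size; planted elements are written at `depth_multiplier` times that
#' threshold.
#'
#' @param seed Integer RNG seed; the fixture is fully determined by it.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param n_genes Total genes, distributed round-robin over chromosomes.
#' @param exons_per_gene Exons per gene.
#' @param exon_length,intron_length Exon and intron sizes in bp.
#' @param planted_res Tibble with `class` (Exonic/Intronic/NearExon/
#'   Orphan), `length` (bp) and `depth_multiplier` (times the mu = 2.5
#'   absolute depth threshold); one planted element per row, distributed
#'   round-robin over chromosomes.
#' @param background_mean Mean background depth per bin (reads).
#' @param background_dispersion Negative-binomial size parameter.
#' @param library_size Mapped reads per sample.
#' @param read_length Read length in bp (for RPKM quantification).
#' @param n_samples Number of samples.
#' @param repeat_density Repeat features per 10 kb; the default of 15
#'   features of 300 bp makes roughly 45% of the genome repetitive,
#'   comparable to a mammalian genome.
#' @param repeat_length Repeat feature length in bp.
#' @param fragmentation Punch one random zero-coverage hole of up to
#'   150 bp into each planted element (exercises the merge-gap logic).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_chromosomes = 2L,
                           chromosome_length = 200000L,
                           n_genes = 6L,
                           exons_per_gene = 4L,
                           exon_length = 300L,
                           intron_length = 2500L,
                           planted_res = default_planted_res(),
                           background_mean = 5,
                           background_dispersion = 5,
                           library_size = 2e7,
                           read_length = 75L,
                           n_samples = 4L,
                           repeat_density = 15,
                           repeat_length = 300L,
                           fragmentation = FALSE) {
  planted_res <- as_tibble(planted_res)
  if (nrow(planted_res)) {
    stopifnot(all(c("class", "length", "depth_multiplier") %in%
                    names(planted_res)))
    bad <- setdiff(planted_res$class,
                   c("Exonic", "Intronic", "NearExon", "Orphan"))
    if (length(bad)) {
      abort(sprintf("unknown planted class: %s", bad[1]))
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = as.integer(chromosome_length),
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_length = as.integer(exon_length),
      intron_length = as.integer(intron_length),
      planted_res = planted_res,
      background_mean = background_mean,
      background_dispersion = background_dispersion,
      library_size = library_size, read_length = as.integer(read_length),
      n_samples = as.integer(n_samples),
      repeat_density = repeat_density,
      repeat_length = as.integer(repeat_length),
      fragmentation = isTRUE(fragmentation)
    ),
    class = "fixture_config"
  )
}

#' @rdname fixture_config
#' @export
default_planted_res <- function() {
  tibble(
    class = c("Exonic", "Intronic", "Intronic", "NearExon", "NearExon",
              "Orphan", "Orphan"),
    length = 600L,
    depth_multiplier = 10
  )
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# fixed palette of repeat names with family and class
repeat_palette <- function() {
  tibble(
    repeat_name = c("AluY", "L1HS", "HERVK-int", "HSAT1", "(AATGG)n"),
    repeat_family = c("Alu", "L1", "ERVK", "HSAT", "Simple_repeat"),
    repeat_class = c("SINE", "LINE", "LTR", "Satellite", "Simple_repeat")
  )
}

#' Generate a synthetic fixture
#'
#' Builds a toy annotation, repeat track, per-sample noisy coverage
#' tracks with planted RNA elements, and the planted ground truth.
#' Deterministic given `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config A [fixture_config()].
#' @return An `re_fixture` list: `exons` (annotation records), `universe`
#'   (from [build_exon_universe()]), `repeats`, `tracks` (named list of
#'   `coverage_track`), `truth` (planted elements: `chrom`, `start`,
#'   `end`, `class`, `depth`), and `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_fixture_seed(config$seed, build_fixture(config))
}

build_fixture <- function(cfg) {
  bin <- 10L
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  gene_span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  gene_gap <- 3000L
  gene_chrom <- chroms[(seq_len(cfg$n_genes) - 1L) %% cfg$n_chromosomes + 1L]

  exons <- purrr::map_dfr(seq_len(cfg$n_genes), function(g) {
    chrom <- gene_chrom[g]
    idx_on_chrom <- sum(gene_chrom[seq_len(g)] == chrom) - 1L
    gstart <- 1000L + idx_on_chrom * (gene_span + gene_gap)
    tibble(
      chrom = chrom,
      start = gstart + (seq_len(cfg$exons_per_gene) - 1L) *
        (cfg$exon_length + cfg$intron_length),
      end = gstart + (seq_len(cfg$exons_per_gene) - 1L) *
        (cfg$exon_length + cfg$intron_length) + cfg$exon_length,
      strand = "+",
      gene_id = sprintf("GENE%02d", g),
      gene_name = sprintf("Gene%02d", g),
      feature_biotype = "protein_coding"
    )
  })
  last_exon_end <- vapply(
    chroms, function(ch) max(exons$end[exons$chrom == ch]), numeric(1)
  )
  orphan_zone_start <- last_exon_end + 10000L + 500L
  if (any(orphan_zone_start + 5000L > cfg$chromosome_length)) {
    abort(paste(
      "chromosome too short for the gene layout plus an orphan zone;",
      "increase chromosome_length or reduce n_genes"
    ))
  }
  universe <- build_exon_universe(exons)

  threshold <- rpm_to_depth(2.5, cfg$library_size)$absolute_depth
  snap <- function(x) as.integer(bin * round(x / bin))

  # plant elements round-robin over chromosomes, at grid-aligned positions
  planted <- cfg$planted_res
  truth <- NULL
  if (nrow(planted)) {
    near_off <- setNames(rep(0L, length(chroms)), chroms)
    orph_off <- setNames(rep(0L, length(chroms)), chroms)
    intr_used <- setNames(rep(0L, length(chroms)), chroms)
    exon_used <- setNames(rep(0L, length(chroms)), chroms)
    truth <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      cls <- planted$class[i]
      len <- snap(planted$length[i])
      chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
      if (cls == "Orphan") {
        start <- snap(orphan_zone_start[[chrom]] + orph_off[[chrom]])
        orph_off[[chrom]] <<- orph_off[[chrom]] + len + 1000L
        if (start + len > cfg$chromosome_length) {
          abort("chromosome too short for the requested orphan elements")
        }
      } else if (cls == "NearExon") {
        start <- snap(last_exon_end[[chrom]] + 500L + near_off[[chrom]])
        near_off[[chrom]] <<- near_off[[chrom]] + len + 1000L
        if (start + len - last_exon_end[[chrom]] > 9500L) {
          abort("too many near-exon elements to keep all within 10 kb")
        }
      } else if (cls == "Intronic") {
        introns <- universe$introns |>
          filter(.data$chrom == !!chrom,
                 .data$end - .data$start >= len + 600L)
        if (nrow(introns) <= intr_used[[chrom]]) {
          abort("not enough intron space for the requested intronic elements")
        }
        intr <- introns[intr_used[[chrom]] + 1L, ]
        intr_used[[chrom]] <<- intr_used[[chrom]] + 1L
        start <- snap(intr$start + 300L)
        if (start + len > intr$end - 300L) {
          abort("intron too short for the requested intronic element")
        }
      } else { # Exonic: boost an annotated exon
        ex <- universe$exonic_res |> filter(.data$chrom == !!chrom)
        if (nrow(ex) <= exon_used[[chrom]]) {
          abort("not enough exons for the requested exonic elements")
        }
        e <- ex[exon_used[[chrom]] + 1L, ]
        exon_used[[chrom]] <<- exon_used[[chrom]] + 1L
        start <- e$start
        len <- e$end - e$start
      }
      tibble(
        chrom = chrom, start = as.integer(start),
        end = as.integer(start + len), class = cls,
        depth = planted$depth_multiplier[i] * threshold
      )
    })
    # self-consistency: planted novel classes must match the classifier
    novel_truth <- truth[truth$class != "Exonic", , drop = FALSE]
    if (nrow(novel_truth)) {
      got <- classify_re(novel_truth, universe)
      if (!identical(got, novel_truth$class)) {
        abort("internal placement error: planted class disagrees with classify_re")
      }
    }
  } else {
    truth <- tibble(
      chrom = character(), start = integer(), end = integer(),
      class = character(), depth = numeric()
    )
  }

  # repeat features: uniform placements from a fixed palette
  pal <- repeat_palette()
  repeats <- purrr::map_dfr(chroms, function(ch) {
    n_rep <- max(1L, round(cfg$repeat_density * cfg$chromosome_length / 1e4))
    start <- sort(sample.int(cfg$chromosome_length - cfg$repeat_length, n_rep))
    pick <- sample.int(nrow(pal), n_rep, replace = TRUE)
    tibble(
      chrom = ch, start = start, end = start + cfg$repeat_length,
      repeat_name = pal$repeat_name[pick],
      repeat_class = pal$repeat_class[pick],
      repeat_family = pal$repeat_family[pick]
    )
  })

  # coverage: truncated NB background per bin plus planted signal
  n_bins <- cfg$chromosome_length %/% bin
  noise_cap <- floor(0.8 * threshold)
  tracks <- lapply(seq_len(cfg$n_samples), function(s) {
    steps <- purrr::map_dfr(chroms, function(ch) {
      depth <- rnbinom(n_bins, mu = cfg$background_mean,
                       size = cfg$background_dispersion)
      depth <- pmin(depth, noise_cap)
      tr_ch <- truth[truth$chrom == ch, , drop = FALSE]
      if (nrow(tr_ch)) {
        for (j in seq_len(nrow(tr_ch))) {
          b0 <- tr_ch$start[j] %/% bin + 1L
          b1 <- (tr_ch$end[j] - 1L) %/% bin + 1L
          depth[b0:b1] <- tr_ch$depth[j]
          if (cfg$fragmentation) {
            span <- b1 - b0 + 1L
            hole_bins <- sample.int(15L, 1L) # up to 150 bp
            if (span > hole_bins + 2L) {
              h0 <- b0 + sample.int(span - hole_bins - 1L, 1L)
              depth[h0:(h0 + hole_bins - 1L)] <- 0
            }
          }
        }
      }
      nz <- which(depth > 0)
      tibble(
        chrom = ch,
        start = (nz - 1L) * bin,
        end = nz * bin,
        depth = as.numeric(depth[nz])
      )
    })
    coverage_track(steps, library_size = cfg$library_size,
                   sample_id = sprintf("S%d", s))
  })
  names(tracks) <- vapply(tracks, attr, character(1), "sample_id")

  structure(
    list(
      exons = exons, universe = universe, repeats = repeats,
      tracks = tracks, truth = truth, config = cfg
    ),
    class = "re_fixture"
  )
}

#' @export
print.re_fixture <- function(x, ...) {
  cat(sprintf(
    "<re_fixture> seed %d: %d chrom x %s bp, %d genes, %d planted REs, %d samples\n",
    x$config$seed, x$config$n_chromosomes,
    format(x$config$chromosome_length, big.mark = ","),
    x$config$n_genes, nrow(x$truth), x$config$n_samples
  ))
  invisible(x)
}

#' Write a fixture to standard file formats
#'
#' Writes the annotation as GTF, repeats as BED-like TSV, one bedGraph
#' per sample, the planted truth as TSV, and a plain-text manifest echoing
#' the configuration (including the seed).
#'
#' @param fixture An `re_fixture`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "re_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.gtf"),
             repeats = file.path(dir, "repeats.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  ex <- fixture$exons
  gtf <- sprintf(
    "%s\tredar_fixture\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.1\"; gene_name \"%s\"; gene_type \"%s\";",
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
    ex$gene_id, ex$gene_name, ex$feature_biotype
  )
  writeLines(gtf, paths[["annotation"]])
  readr::write_tsv(fixture$repeats, paths[["repeats"]])
  readr::write_tsv(fixture$truth, paths[["truth"]])
  for (sid in names(fixture$tracks)) {
    p <- file.path(dir, paste0(sid, ".bedgraph"))
    write_bedgraph(fixture$tracks[[sid]], p)
    paths[[sid]] <- p
  }
  cfg <- fixture$config
  scalar <- cfg[vapply(cfg, function(v) is.atomic(v) && length(v) == 1,
                       logical(1))]
  writeLines(
    c(
      sprintf("%s = %s", names(scalar), unlist(lapply(scalar, format))),
      sprintf("sample %s library_size = %s", names(fixture$tracks),
              format(cfg$library_size, scientific = FALSE))
    ),
    paths[["manifest"]]
  )
  invisible(paths)
}

#' Score discovery output against the planted truth
#'
#' A truth element counts as recovered when a discovered element of the
#' same class overlaps it by at least one base; precision counts
#' discovered elements of a class that overlap some truth element of that
#' class. The overall per-base Jaccard compares the union of discovered
#' novel (non-exonic) elements with the union of planted novel elements.
#'
#' @param discovered An `re_discovery` or element tibble with `chrom`,
#'   `start`, `end`, `re_class`.
#' @param truth Planted-truth tibble (`chrom`, `start`, `end`, `class`).
#' @return List with `by_class` (tibble: `class`, `n_truth`,
#'   `n_discovered`, `n_recovered`, `sensitivity`, `precision`) and
#'   `overall` (one-row tibble: `sensitivity`, `precision`, `jaccard`).
#' @export
score_recovery <- function(discovered, truth) {
  el <- if (inherits(discovered, "re_discovery")) discovered$elements
        else as_tibble(discovered)
  classes <- sort(unique(truth$class))
  by_class <- purrr::map_dfr(classes, function(cls) {
    tr <- truth[truth$class == cls, , drop = FALSE]
    dc <- el[el$re_class == cls, , drop = FALSE]
    n_rec <- 0L
    n_prec <- 0L
    if (nrow(tr) && nrow(dc)) {
      hits <- GenomicRanges::findOverlaps(
        as_granges0(tr[c("chrom", "start", "end")]),
        as_granges0(dc[c("chrom", "start", "end")])
      )
      n_rec <- length(unique(S4Vectors::queryHits(hits)))
      n_prec <- length(unique(S4Vectors::subjectHits(hits)))
    }
    tibble(
      class = cls, n_truth = nrow(tr), n_discovered = nrow(dc),
      n_recovered = n_rec,
      sensitivity = if (nrow(tr)) n_rec / nrow(tr) else NA_real_,
      precision = if (nrow(dc)) n_prec / nrow(dc) else NA_real_
    )
  })
  novel_truth <- truth[truth$class != "Exonic", , drop = FALSE]
  novel_disc <- el[el$re_class != "Exonic", , drop = FALSE]
  novel_classes <- setdiff(classes, "Exonic")
  bc <- by_class[by_class$class %in% novel_classes, , drop = FALSE]
  overall <- tibble(
    sensitivity = if (sum(bc$n_truth)) {
      sum(bc$n_recovered) / sum(bc$n_truth)
    } else NA_real_,
    precision = if (nrow(novel_disc)) {
      n_hit <- if (nrow(novel_truth)) {
        length(unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
          as_granges0(novel_disc[c("chrom", "start", "end")]),
          as_granges0(novel_truth[c("chrom", "start", "end")])
        ))))
      } else 0L
      n_hit / nrow(novel_disc)
    } else NA_real_,
    jaccard = jaccard_bp(
      novel_disc[c("chrom", "start", "end")],
      novel_truth[c("chrom", "start", "end")]
    )
  )
  list(by_class = by_class, overall = overall)
}
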