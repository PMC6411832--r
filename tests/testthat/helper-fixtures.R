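# Small in-code fixtures shared across tests.

# exon universe from a bare exon table
make_universe <- function(chrom, start, end, gene_id = "g1",
                          gene_name = gene_id) {
  build_exon_universe(tibble::tibble(
    chrom = chrom, start = start, end = end,
    gene_id = gene_id, gene_name = gene_name
  ))
}

make_track <- function(chrom, start, end, depth, library_size, sample_id) {
  coverage_track(
    tibble::tibble(chrom = chrom, start = start, end = end, depth = depth),
    library_size = library_size, sample_id = sample_id
  )
}

# four theoretical samples with different library sizes: two carry novel
# signal above their thresholds in regions 100 bp apart, two stay below
# threshold everywhere
four_sample_scenario <- function() {
  universe <- make_universe("chr1", 1000, 1300, gene_id = "g1",
                            gene_name = "GeneA")
  tracks <- list(
    # threshold 25: region A expressed
    make_track("chr1", c(1000, 5000), c(1300, 5400), c(40, 60),
               1e7, "S1"),
    # threshold 10: everywhere below
    make_track("chr1", c(5000, 5500), c(5400, 5900), c(5, 5),
               4e6, "S2"),
    # threshold 50: region B expressed
    make_track("chr1", c(1000, 5500), c(1300, 5900), c(80, 120),
               2e7, "S3"),
    # threshold 20: everywhere below
    make_track("chr1", c(5000, 5500), c(5400, 5900), c(12, 12),
               8e6, "S4")
  )
  list(universe = universe, tracks = tracks)
}

# random interval table on a small genome
random_intervals <- function(n, chroms = c("chrA", "chrB"), len = 50000L,
                             max_width = 400L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}
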