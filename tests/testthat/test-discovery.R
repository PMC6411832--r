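# Expressed-bin calling, gap-merging, classification, cross-sample
# merging, exon extension and the assembled discovery pipeline.

test_that("expressed bins require strictly surpassing the threshold, outside exons", {
  uni <- make_universe("chr1", 10000, 10300)
  track <- make_track("chr1", c(0, 10, 20), c(10, 20, 30), c(51, 50, 49),
                      2e7, "s")
  bins <- call_expressed_bins(bin_coverage(track), rpm_to_depth(2.5, 2e7),
                              uni)
  expect_equal(bins$start, 0) # only the 51x bin beats the 50x threshold
  # one base of exon overlap excludes a bin
  edge <- make_track("chr1", 9990, 10001, 200, 2e7, "s")
  bins2 <- call_expressed_bins(bin_coverage(edge), rpm_to_depth(2.5, 2e7),
                               uni)
  expect_equal(bins2$start, 9990) # bin [10000,10010) overlaps the exon
  # non-strict comparison is available
  bins3 <- call_expressed_bins(bin_coverage(track),
                               rpm_to_depth(2.5, 2e7), uni, strict = FALSE)
  expect_equal(bins3$start, c(0, 10))
})

test_that("a gap of exactly 150 bp merges and 151 bp does not", {
  two <- tibble::tibble(chrom = "chr1", start = c(0, 160), end = c(10, 170))
  m <- merge_bins(two, 150)
  expect_equal(nrow(m), 1)
  expect_equal(m$end, 170)
  three <- tibble::tibble(chrom = "chr1", start = c(0, 161), end = c(10, 171))
  expect_equal(nrow(merge_bins(three, 150)), 2)
})

test_that("merging matches the linear-scan oracle and is order-independent", {
  set.seed(21)
  for (rep in 1:15) {
    bins <- tibble::tibble(
      chrom = "chr1",
      start = sample(seq(0, 49990, by = 10), 200)
    ) |> dplyr::mutate(end = start + 10)
    got <- merge_bins(bins, 150)
    want <- oracle_gap_merge(bins, 150, len = 50000L)
    expect_equal(got, want, ignore_attr = TRUE)
    # permutation of the input changes nothing
    shuffled <- bins[sample.int(nrow(bins)), ]
    expect_equal(merge_bins(shuffled, 150), got)
    # idempotence
    expect_equal(merge_bins(got, 150), got)
  }
})

test_that("classification follows intron containment then exon distance", {
  uni <- make_universe("chr1", c(1000, 3000), c(1500, 3500))
  # inside the intron, within 10 kb of both exons: Intronic wins
  expect_equal(classify_re(tibble::tibble(chrom = "chr1", start = 1700,
                                          end = 2800), uni), "Intronic")
  # intergenic, with a gap of exactly 10 kb to the nearest exon: NearExon
  expect_equal(
    classify_re(tibble::tibble(chrom = "chr1", start = 13500, end = 13600),
                uni),
    "NearExon"
  )
  # one base farther: Orphan
  expect_equal(
    classify_re(tibble::tibble(chrom = "chr1", start = 13501, end = 13601),
                uni),
    "Orphan"
  )
  expect_error(
    classify_re(tibble::tibble(chrom = "chr1", start = 1400, end = 1600),
                uni),
    "overlaps an exonic RE"
  )
})

test_that("an element straddling an intron boundary is not Intronic", {
  uni <- make_universe("chr1", c(1000, 3000), c(1500, 3500))
  # spills out of the gene into intergenic space
  expect_equal(
    classify_re(tibble::tibble(chrom = "chr1", start = 3600, end = 3900),
                uni),
    "NearExon"
  )
})

test_that("cross-sample merging pools, fuses within 150 bp and unions sources", {
  uni <- make_universe("chr1", 100000, 100300)
  per_sample <- list(
    A = tibble::tibble(chrom = "chr1", start = 1000, end = 1200),
    B = tibble::tibble(chrom = "chr1", start = 1300, end = 1400)
  )
  out <- merge_across_samples(per_sample, uni)
  novel <- out[out$re_class != "Exonic", ]
  expect_equal(nrow(novel), 1)
  expect_equal(novel$start, 1000)
  expect_equal(novel$end, 1400)
  expect_equal(novel$source_samples[[1]], c("A", "B"))
  expect_equal(novel$n_source_samples, 2)
  # identical element in three samples -> one element, three sources
  tri <- merge_across_samples(list(
    A = tibble::tibble(chrom = "chr1", start = 5000, end = 5200),
    B = tibble::tibble(chrom = "chr1", start = 5000, end = 5200),
    C = tibble::tibble(chrom = "chr1", start = 5000, end = 5200)
  ), uni)
  expect_equal(tri$n_source_samples[tri$re_class != "Exonic"], 3)
})

test_that("cross-sample merging equals the pooled-merge oracle on random input", {
  set.seed(22)
  uni <- make_universe("chrA", 90000, 90400)
  for (rep in 1:10) {
    per_sample <- lapply(setNames(1:4, paste0("S", 1:4)), function(i) {
      merge_bins(random_intervals(20, chroms = "chrA", len = 60000L), 150)
    })
    got <- merge_across_samples(per_sample, uni)
    got_novel <- got[got$re_class != "Exonic",
                     c("chrom", "start", "end")]
    pooled <- dplyr::bind_rows(per_sample)
    want <- oracle_gap_merge(pooled, 150, len = 95000L)
    expect_equal(got_novel, want, ignore_attr = TRUE)
    # re-classification matches direct classification
    expect_equal(
      got$re_class[got$re_class != "Exonic"],
      classify_re(got_novel, uni)
    )
  }
})

test_that("exon extension obeys both the 50 bp gap and the <50% depth rule", {
  cfg <- discovery_config()
  exonic <- tibble::tibble(id = "e", chrom = "chr1", start = 1000,
                           end = 1500, gene_names = "G")
  near <- tibble::tibble(id = "n", chrom = "chr1", start = 1550, end = 1800)
  # gap exactly 50, relative difference 0.4: extended
  ext <- extend_exonic(exonic, near, 100, 60, cfg)
  expect_equal(ext$start, 1000)
  expect_equal(ext$end, 1800)
  expect_equal(ext$re_class, "Exonic")
  expect_equal(ext$gene_names, "G")
  # relative difference exactly 0.5 fails the strict rule
  near2 <- tibble::tibble(id = "n", chrom = "chr1", start = 1540, end = 1800)
  expect_null(extend_exonic(exonic, near2, 100, 50, cfg))
  # gap 51 fails
  near3 <- tibble::tibble(id = "n", chrom = "chr1", start = 1551, end = 1800)
  expect_null(extend_exonic(exonic, near3, 100, 100, cfg))
  # both depths zero: undefined relative difference, no extension
  expect_null(extend_exonic(exonic, near, 0, 0, cfg))
})

test_that("discovery recovers a planted orphan region in one sample", {
  uni <- make_universe("chr1", 1000, 1300)
  # 60x plateau at 40 kb; mu chosen so the absolute threshold is 5
  track <- make_track("chr1", c(40000, 41000), c(40500, 41010),
                      c(60, 1), 2e6, "s1")
  disc <- discover(list(track), uni, discovery_config(mu = 2.5))
  novel <- disc$elements[disc$elements$re_class != "Exonic", ]
  expect_equal(nrow(novel), 1)
  expect_equal(novel$re_class, "Orphan")
  expect_equal(novel$start, 40000)
  expect_equal(novel$end, 40500)
  expect_equal(disc$thresholds$absolute_depth, 5)
})

test_that("with no expressed bins the output is the exonic REs alone", {
  uni <- make_universe("chr1", 1000, 1300)
  track <- make_track("chr1", 5000, 6000, 2, 2e7, "s1") # threshold 50
  disc <- discover(list(track), uni)
  expect_equal(nrow(disc$elements), 1)
  expect_equal(disc$elements$re_class, "Exonic")
})

test_that("raising mu never creates expressed bins (subset monotonicity)", {
  set.seed(23)
  uni <- make_universe("chr1", 80000, 80300)
  steps <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 19990, by = 10),
    end = seq(10, 20000, by = 10),
    depth = rnbinom(2000, mu = 30, size = 3)
  ) |> dplyr::filter(depth > 0)
  track <- coverage_track(steps, library_size = 1e7, sample_id = "s")
  binned <- bin_coverage(track)
  prev <- NULL
  for (mu in c(1, 2.5, 4, 6)) {
    bins <- call_expressed_bins(binned, rpm_to_depth(mu, 1e7), uni)
    key <- paste(bins$chrom, bins$start)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("novel elements never overlap exonic REs even across short exons", {
  # a 100 bp exon sits inside a high-coverage region; merging must not
  # produce a novel element bridging it
  uni <- make_universe("chr1", 5200, 5300)
  track <- make_track("chr1", 5000, 5500, 100, 1e6, "s") # threshold 2.5
  disc <- discover(list(track), uni, extend = FALSE)
  novel <- disc$elements[disc$elements$re_class != "Exonic", ]
  expect_equal(nrow(novel), 2)
  ov <- oracle_overlap_pairs(novel, uni$exonic_res)
  expect_equal(nrow(ov), 0)
})

test_that("element ids are coordinate-derived", {
  uni <- make_universe("chr1", 1000, 1300)
  track <- make_track("chr1", 40000, 40500, 60, 2e6, "s1")
  disc <- discover(list(track), uni)
  novel <- disc$elements[disc$elements$re_class != "Exonic", ]
  expect_equal(novel$id, "chr1_40000_40500")
})

test_that("glance and tidy summarise a discovery result", {
  scn <- four_sample_scenario()
  disc <- discover(scn$tracks, scn$universe)
  g <- glance(disc)
  expect_equal(g$n_elements, nrow(tidy(disc)))
  expect_equal(g$n_samples, 4)
  expect_equal(g$n_exonic + g$n_intronic + g$n_near_exon + g$n_orphan,
               g$n_elements)
})
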