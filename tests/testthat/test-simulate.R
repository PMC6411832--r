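# The synthetic fixture generator and recovery scoring.

test_that("the same seed reproduces the fixture exactly, on disk too", {
  fx1 <- generate_fixture(fixture_config(seed = 5))
  fx2 <- generate_fixture(fixture_config(seed = 5))
  expect_equal(fx1$truth, fx2$truth)
  expect_equal(fx1$repeats, fx2$repeats)
  expect_equal(
    lapply(fx1$tracks, tibble::as_tibble),
    lapply(fx2$tracks, tibble::as_tibble)
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(fx1, d1)
  p2 <- write_fixture(fx2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_fixture(fixture_config(seed = 5)))
  after <- stats::runif(1)
  expect_equal(before, after)
})

test_that("a fixture with no planted elements discovers only exonic REs", {
  cfg <- fixture_config(
    seed = 3,
    planted_res = tibble::tibble(class = character(), length = integer(),
                                 depth_multiplier = numeric())
  )
  fx <- generate_fixture(cfg)
  disc <- discover(fx$tracks, fx$universe)
  expect_true(all(disc$elements$re_class == "Exonic"))
})

test_that("planted elements are recovered with their planted classes", {
  fx <- generate_fixture(fixture_config(seed = 8))
  disc <- discover(fx$tracks, fx$universe)
  novel_truth <- fx$truth[fx$truth$class != "Exonic", ]
  sc <- score_recovery(disc, fx$truth)
  expect_equal(sum(sc$by_class$n_recovered[sc$by_class$class != "Exonic"]),
               nrow(novel_truth))
  expect_equal(sc$overall$sensitivity, 1)
  expect_equal(sc$overall$precision, 1)
})

test_that("planted classes are self-consistent with the classifier across seeds", {
  for (seed in c(2, 12, 22)) {
    fx <- generate_fixture(fixture_config(seed = seed))
    novel <- fx$truth[fx$truth$class != "Exonic", ]
    expect_equal(classify_re(novel, fx$universe), novel$class)
  }
})

test_that("fixture files round-trip through the package readers", {
  fx <- generate_fixture(fixture_config(seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  exons <- read_gene_annotation(paths[["annotation"]])
  expect_equal(
    exons[c("chrom", "start", "end", "gene_id")],
    fx$exons[c("chrom", "start", "end", "gene_id")]
  )
  reps <- read_repeat_track(paths[["repeats"]])
  expect_equal(reps[c("chrom", "start", "end", "repeat_name")],
               fx$repeats[c("chrom", "start", "end", "repeat_name")])
  s1 <- read_bedgraph(paths[["S1"]],
                      library_size = fx$config$library_size,
                      sample_id = "S1")
  expect_equal(
    tibble::as_tibble(s1)[c("chrom", "start", "end", "depth")],
    tibble::as_tibble(fx$tracks$S1)[c("chrom", "start", "end", "depth")]
  )
})

test_that("background noise stays below the discovery threshold", {
  fx <- generate_fixture(fixture_config(seed = 6, chromosome_length = 50000))
  thr <- rpm_to_depth(2.5, fx$config$library_size)$absolute_depth
  for (track in fx$tracks) {
    tr <- tibble::as_tibble(track)
    in_truth <- rep(FALSE, nrow(tr))
    for (j in seq_len(nrow(fx$truth))) {
      in_truth <- in_truth |
        (tr$chrom == fx$truth$chrom[j] &
           tr$start < fx$truth$end[j] & tr$end > fx$truth$start[j])
    }
    expect_true(all(tr$depth[!in_truth] < thr))
  }
})

test_that("recovery scoring is exact on identity and empty discoveries", {
  truth <- tibble::tibble(
    chrom = "chr1", start = c(1000, 5000), end = c(1400, 5600),
    class = c("Orphan", "Intronic"), depth = 100
  )
  as_elements <- dplyr::mutate(truth, re_class = class,
                               id = paste0("re", 1:2))
  perfect <- score_recovery(as_elements, truth)
  expect_equal(perfect$overall$sensitivity, 1)
  expect_equal(perfect$overall$precision, 1)
  expect_equal(perfect$overall$jaccard, 1)
  none <- score_recovery(as_elements[0, ], truth)
  expect_equal(none$overall$sensitivity, 0)
})

test_that("a coverage hole wider than the merge gap splits a planted element", {
  uni <- make_universe("chr1", 100000, 100300)
  # planted truth [40000, 41000) but coverage has a 200 bp hole
  track <- make_track("chr1", c(40000, 40600), c(40400, 41000), c(60, 60),
                      2e6, "s1")
  truth <- tibble::tibble(chrom = "chr1", start = 40000, end = 41000,
                          class = "Orphan", depth = 60)
  disc <- discover(list(track), uni)
  sc <- score_recovery(disc, truth)
  expect_equal(sum(disc$elements$re_class == "Orphan"), 2)
  expect_lt(sc$overall$jaccard, 1)
  expect_equal(sc$overall$jaccard, 800 / 1000)
})

test_that("fragmentation holes of up to 150 bp do not split planted elements", {
  fx <- generate_fixture(fixture_config(seed = 9, fragmentation = TRUE))
  disc <- discover(fx$tracks, fx$universe)
  sc <- score_recovery(disc, fx$truth)
  expect_equal(sc$overall$sensitivity, 1)
  expect_gte(sc$overall$jaccard, 0.9)
})

test_that("an infeasible layout is rejected with a configuration error", {
  expect_error(
    generate_fixture(fixture_config(seed = 1, chromosome_length = 30000)),
    "chromosome too short"
  )
})
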