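# Fold change, transmission rules, PPV sweep and database intersect.

test_that("fold change follows log2(total/polyA) with pseudocount guards", {
  df <- tibble::tibble(
    re_id = c("a", "b", "c"),
    mean_total = c(40, 7, 0),
    mean_polya = c(10, 7, 0)
  )
  out0 <- fold_change(df, pseudocount = 0)
  expect_equal(out0$log2_fc[1], 2)
  expect_equal(out0$log2_fc[2], 0)
  out1 <- fold_change(df, pseudocount = 1)
  expect_equal(out1$log2_fc[3], 0)
})

test_that("swapping preparations negates the fold change", {
  set.seed(61)
  df <- tibble::tibble(
    re_id = paste0("re", 1:20),
    mean_total = stats::runif(20, 0.1, 100),
    mean_polya = stats::runif(20, 0.1, 100)
  )
  fwd <- fold_change(df, pseudocount = 0)$log2_fc
  rev <- fold_change(
    dplyr::rename(df, mean_total = mean_polya, mean_polya = mean_total),
    pseudocount = 0
  )$log2_fc
  expect_equal(fwd, -rev)
})

test_that("transmission labels apply the printed thresholds strictly", {
  med <- tibble::tibble(
    re_id = paste0("re", 1:4),
    oocyte = c(30, 1, 3, 6),
    sperm = c(1, 30, 30, 30),
    zygote = c(15, 15, 15, 15)
  )
  out <- classify_transmission(med)
  expect_equal(out$label, c("maternal", "paternal_high",
                            "paternal_moderate", "unassigned"))
  # boundaries: all strict
  bd <- classify_transmission(tibble::tibble(
    re_id = paste0("b", 1:4),
    oocyte = c(25, 2, 5, 1),
    sperm = c(1, 30, 30, 25),
    zygote = c(15, 15, 15, 15)
  ))
  expect_equal(bd$label, c("unassigned", "paternal_moderate",
                           "unassigned", "unassigned"))
})

test_that("transmission labels are exclusive and exhaustive over the threshold lattice", {
  lattice <- c(0, 1, 2, 3, 5, 10, 11, 25, 26)
  grid <- tidyr::expand_grid(oocyte = lattice, sperm = lattice,
                             zygote = lattice)
  grid$re_id <- as.character(seq_len(nrow(grid)))
  out <- classify_transmission(grid)
  expect_true(all(out$label %in% c("maternal", "paternal_high",
                                   "paternal_moderate", "unassigned")))
  # independent rule evaluation: each point satisfies exactly the rule of
  # its label, with paternal_high taking precedence over moderate
  maternal <- grid$zygote > 10 & grid$sperm < 2 & grid$oocyte > 25
  pat_hi <- grid$zygote > 10 & grid$sperm > 25 & grid$oocyte < 2
  pat_mod <- grid$zygote > 10 & grid$sperm > 25 & grid$oocyte >= 2 &
    grid$oocyte < 5
  expect_false(any(maternal & (pat_hi | pat_mod)))
  expect_equal(out$label == "maternal", maternal)
  expect_equal(out$label == "paternal_high", pat_hi)
  expect_equal(out$label == "paternal_moderate", pat_mod)
  expect_equal(out$label == "unassigned", !(maternal | pat_hi | pat_mod))
})

test_that("PPV follows the printed formula on known medians", {
  grid <- ppv_sweep(list(`2.5` = c(30, 30, 5, 5)), thresholds = 25)
  expect_equal(grid$ppv, 0.5)
  below <- ppv_sweep(list(`1` = c(50, 60)), thresholds = c(10, 40))
  expect_equal(below$ppv, c(1, 1)) # both thresholds below all medians
  empty <- ppv_sweep(list(`9.5` = numeric()), thresholds = 1:3)
  expect_true(all(is.na(empty$ppv)))
})

test_that("the PPV grid matches a naive recount and is non-increasing in threshold", {
  set.seed(62)
  medians <- list(
    `1` = stats::rexp(200, 1 / 40),
    `2.5` = stats::rexp(120, 1 / 40),
    `5` = stats::rexp(60, 1 / 40)
  )
  grid <- ppv_sweep(medians, thresholds = 1:200)
  for (mu in names(medians)) {
    sub <- grid[grid$mu == as.numeric(mu), ]
    recount <- vapply(1:200, function(t) {
      sum(medians[[mu]] > t) / length(medians[[mu]])
    }, numeric(1))
    expect_equal(sub$ppv, recount)
    expect_true(all(diff(sub$ppv) <= 0))
    expect_true(all(sub$ppv >= 0 & sub$ppv <= 1))
  }
})

test_that("re-running discovery at higher mu yields fewer or equal novel elements", {
  scn <- four_sample_scenario()
  grid <- ppv_sweep_discovery(scn$tracks, scn$universe, mus = c(1, 2.5, 5),
                              thresholds = c(5, 25))
  totals <- grid |>
    dplyr::distinct(mu, n_total) |>
    dplyr::arrange(mu)
  expect_true(all(diff(totals$n_total) <= 0))
})

test_that("database intersect de-duplicates by mean and restricts to shared genes", {
  ref <- tibble::tibble(
    gene = c("A", "A", "B", "C", "D"),
    tpm = c(2, 10, 8, 1, 50) # A averages to 6 > 5
  )
  res <- tibble::tibble(
    gene = c("A", "B", "C", "E"),
    rpkm = c(100, 10, 40, 99) # E is not shared
  )
  out <- expression_intersect(ref, res)
  expect_equal(out$n_shared, 3) # A, B, C
  expect_equal(sort(out$reference_genes[[1]]), c("A", "B"))
  expect_equal(sort(out$re_genes[[1]]), c("A", "C"))
  expect_equal(out$both_genes[[1]], "A")
  expect_equal(out$overlap_fraction, 1 / 2)
})

test_that("identical and disjoint expression sets bound the overlap fraction", {
  ref <- tibble::tibble(gene = c("A", "B"), tpm = c(10, 10))
  same <- expression_intersect(ref, tibble::tibble(gene = c("A", "B"),
                                                   rpkm = c(30, 30)))
  expect_equal(same$overlap_fraction, 1)
  disjoint <- expression_intersect(
    tibble::tibble(gene = c("A", "B"), tpm = c(10, 1)),
    tibble::tibble(gene = c("A", "B"), rpkm = c(1, 30))
  )
  expect_equal(disjoint$overlap_fraction, 0)
})
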