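# Brute-force oracles, deliberately independent of the package's
# GenomicRanges-based implementation paths.

# per-base union of intervals on one chromosome -> run-length intervals
mask_runs <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(mask)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths
  tibble::tibble(start = start_at[r$values], end = stop_at[r$values])
}

# union-merge oracle (gap 0) over a multi-chromosome interval table
oracle_union <- function(df, len = 100000L) {
  out <- lapply(split(df, df$chrom), function(d) {
    runs <- mask_runs(d$start, d$end, len)
    runs$chrom <- d$chrom[1]
    runs
  })
  dplyr::bind_rows(out)[c("chrom", "start", "end")] |>
    dplyr::arrange(chrom, start)
}

# gap-merge oracle: sorted linear scan fusing intervals with gap <= g
oracle_gap_merge <- function(df, gap, len = 100000L) {
  out <- lapply(split(df, df$chrom), function(d) {
    runs <- mask_runs(d$start, d$end, len)
    if (nrow(runs) == 0) return(NULL)
    acc_start <- runs$start[1]
    acc_end <- runs$end[1]
    res <- list()
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - acc_end <= gap) {
        acc_end <- runs$end[i]
      } else {
        res[[length(res) + 1]] <- c(acc_start, acc_end)
        acc_start <- runs$start[i]
        acc_end <- runs$end[i]
      }
    }
    res[[length(res) + 1]] <- c(acc_start, acc_end)
    m <- do.call(rbind, res)
    tibble::tibble(chrom = d$chrom[1], start = m[, 1], end = m[, 2])
  })
  dplyr::bind_rows(out) |> dplyr::arrange(chrom, start)
}

# mean depth per fixed bin from a per-base depth array
oracle_bin_means <- function(steps, bin_size, len) {
  out <- lapply(split(steps, steps$chrom), function(d) {
    depth <- numeric(len)
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) {
        depth[(d$start[i] + 1):d$end[i]] <- d$depth[i]
      }
    }
    n_bins <- ceiling(len / bin_size)
    means <- vapply(seq_len(n_bins) - 1L, function(b) {
      lo <- b * bin_size + 1
      hi <- min((b + 1) * bin_size, len)
      sum(depth[lo:hi]) / bin_size
    }, numeric(1))
    keep <- which(means > 0) - 1L
    tibble::tibble(chrom = d$chrom[1], bin = keep, mean_depth = means[keep + 1L])
  })
  dplyr::bind_rows(out) |> dplyr::arrange(chrom, bin)
}

# covered bases of an interval set, via the mask oracle
union_bp_tbl <- function(df, len = 100000L) {
  u <- oracle_union(df, len = len)
  sum(u$end - u$start)
}

# pairwise half-open overlap test, double loop
oracle_overlap_pairs <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  m <- do.call(rbind, hits)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

# hypergeometric tail probabilities by combinatorial summation
oracle_hyper_tails <- function(k, n, K, N) {
  pmf <- function(j) choose(K, j) * choose(N - K, n - j) / choose(N, n)
  support <- max(0, n - (N - K)):min(n, K)
  list(
    p_enrich = sum(vapply(support[support >= k], pmf, numeric(1))),
    p_deplete = sum(vapply(support[support <= k], pmf, numeric(1))),
    point = if (k %in% support) pmf(k) else 0
  )
}

# full enumeration of draws for tiny N: every subset of size n
oracle_hyper_enumerate <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K) # items 1..K carry the repeat
  list(
    p_enrich = mean(overlap >= k),
    p_deplete = mean(overlap <= k)
  )
}

# minimum half-open gap from an interval to a set of intervals
oracle_min_gap <- function(chrom, start, end, others) {
  o <- others[others$chrom == chrom, , drop = FALSE]
  if (nrow(o) == 0) return(Inf)
  gaps <- pmax(o$start - end, start - o$end)
  max(min(gaps), 0)
}
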