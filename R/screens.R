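# Downstream screens: poly(A+) vs total-RNA fold change, parental
# transmission classification, the PPV parameter sweep, and the
# reference-database expression intersect.

#' Log2 fold change of total-RNA over poly(A+) expression
#'
#' `log2((mean_total + pseudocount) / (mean_polya + pseudocount))` per
#' element; the pseudocount guards zero means.
#'
#' @param expr_means Tibble with `re_id`, `mean_total`, `mean_polya`
#'   (mean RPKM per element in each library preparation).
#' @param pseudocount RPKM added to both means (default 0.5; set 0 for the
#'   bare ratio).
#' @return The input with a `log2_fc` column; positive values indicate
#'   higher abundance in total RNA.
#' @export
#' @examples
#' fold_change(tibble::tibble(re_id = "re1", mean_total = 40,
#'                            mean_polya = 10), pseudocount = 0) # +2
fold_change <- function(expr_means, pseudocount = 0.5) {
  stopifnot(all(c("mean_total", "mean_polya") %in% names(expr_means)))
  if (any(expr_means$mean_total < 0 | expr_means$mean_polya < 0)) {
    abort("means must be >= 0")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  mutate(
    expr_means,
    log2_fc = log2((.data$mean_total + pseudocount) /
                     (.data$mean_polya + pseudocount))
  )
}

# vector core for the transmission rules; strict inequalities as printed
transmission_label <- function(oocyte, sperm, zygote) {
  dplyr::case_when(
    zygote > 10 & sperm > 25 & oocyte < 2 ~ "paternal_high",
    zygote > 10 & sperm > 25 & oocyte < 5 ~ "paternal_moderate",
    zygote > 10 & sperm < 2 & oocyte > 25 ~ "maternal",
    TRUE ~ "unassigned"
  )
}

#' Classify parental transmission of zygotic RNA elements
#'
#' Threshold rules on median RPKM in oocyte, sperm and zygote:
#' \describe{
#'   \item{maternal}{zygote > 10, sperm < 2, oocyte > 25}
#'   \item{paternal_high}{zygote > 10, sperm > 25, oocyte < 2 (greatest
#'     confidence)}
#'   \item{paternal_moderate}{zygote > 10, sperm > 25, oocyte < 5
#'     (moderate confidence)}
#' }
#' The paternal rules nest (oocyte < 2 implies oocyte < 5); the most
#' stringent applicable label is reported. All inequalities are strict.
#' Everything else is `unassigned`.
#'
#' @param medians Tibble with `re_id`, `oocyte`, `sperm`, `zygote`
#'   (median RPKM per cell type).
#' @return The input with a `label` column.
#' @export
#' @examples
#' classify_transmission(tibble::tibble(
#'   re_id = c("a", "b"), oocyte = c(30, 1), sperm = c(1, 30),
#'   zygote = c(15, 15)
#' ))
classify_transmission <- function(medians) {
  stopifnot(all(c("oocyte", "sperm", "zygote") %in% names(medians)))
  if (any(medians$oocyte < 0 | medians$sperm < 0 | medians$zygote < 0)) {
    abort("median RPKM values must be >= 0")
  }
  mutate(
    medians,
    label = transmission_label(.data$oocyte, .data$sperm, .data$zygote)
  )
}

#' Positive-predictive-value sweep over mu and expression thresholds
#'
#' For each discovery stringency mu, given the median RPKM of every novel
#' element discovered at that mu, the PPV at expression threshold `t` is
#' the fraction of novel elements whose median exceeds `t`:
#' `PPV = (# medians > t) / (# medians > t + # medians <= t)`.
#'
#' @param medians_by_mu Named list: names are mu values (RPM), each entry
#'   the numeric vector of median RPKM over the novel elements discovered
#'   at that mu.
#' @param thresholds Expression thresholds in RPKM (default `1:200`).
#' @return A `ppv_grid` tibble: `mu`, `threshold`, `n_total`,
#'   `n_expressed`, `ppv` (NA for a mu with no elements).
#' @export
#' @examples
#' ppv_sweep(list(`2.5` = c(30, 30, 5, 5)), thresholds = 25)
ppv_sweep <- function(medians_by_mu, thresholds = 1:200) {
  stopifnot(!is.null(names(medians_by_mu)))
  out <- purrr::imap_dfr(medians_by_mu, function(med, mu) {
    tibble(
      mu = as.numeric(mu),
      threshold = thresholds,
      n_total = length(med),
      n_expressed = vapply(
        thresholds, function(t) sum(med > t), integer(1)
      )
    )
  }) |>
    mutate(ppv = ifelse(.data$n_total > 0,
                        .data$n_expressed / .data$n_total, NA_real_)) |>
    arrange(.data$mu, .data$threshold)
  class(out) <- c("ppv_grid", class(out))
  out
}

#' PPV sweep by re-running discovery at each mu
#'
#' Re-runs [discover()] at each mu on the same tracks, quantifies the
#' novel elements, takes the median RPKM across samples per element, and
#' delegates to [ppv_sweep()].
#'
#' @param tracks List of `coverage_track` objects.
#' @param universe An `exon_universe`.
#' @param mus Discovery thresholds in RPM (default `seq(1, 10, by = 0.5)`).
#' @param thresholds Expression thresholds in RPKM (default `1:200`).
#' @param config Base [discovery_config()]; its `mu` is overridden.
#' @return A `ppv_grid` tibble, plus attribute `medians_by_mu`.
#' @export
ppv_sweep_discovery <- function(tracks, universe,
                                mus = seq(1, 10, by = 0.5),
                                thresholds = 1:200,
                                config = discovery_config()) {
  medians_by_mu <- lapply(mus, function(mu) {
    cfg <- config
    cfg$mu <- mu
    disc <- discover(tracks, universe, cfg, extend = FALSE)
    novel <- disc$elements |> filter(.data$re_class != "Exonic")
    if (nrow(novel) == 0) return(numeric())
    quantify_res(novel, tracks, read_length = config$read_length) |>
      group_by(.data$re_id) |>
      summarise(med = median(.data$rpkm), .groups = "drop") |>
      pull("med")
  })
  names(medians_by_mu) <- format(mus, trim = TRUE)
  grid <- ppv_sweep(medians_by_mu, thresholds)
  attr(grid, "medians_by_mu") <- medians_by_mu
  grid
}

#' Intersect exonic-element expression with a reference database
#'
#' Compares the gene names called expressed from exonic RNA elements
#' (RPKM above `rpkm_cut`) with those expressed in a reference database
#' such as GTEx (TPM above `tpm_cut`). Duplicated gene names in either
#' table are replaced by the mean of their values; only gene names present
#' in both tables are compared.
#'
#' @param reference Tibble with `gene`, `tpm` (reference median TPM).
#' @param re_genes Tibble with `gene`, `rpkm` (exonic-element RPKM).
#' @param tpm_cut Reference expression cutoff in TPM (default 5, strict).
#' @param rpkm_cut Element expression cutoff in RPKM (default 25, strict).
#' @return One-row tibble: `n_shared`, `n_reference_expressed`,
#'   `n_re_expressed`, `n_both`, `overlap_fraction`
#'   (= n_both / n_re_expressed), with the gene sets in list columns
#'   `reference_genes`, `re_genes`, `both_genes`.
#' @export
expression_intersect <- function(reference, re_genes, tpm_cut = 5,
                                 rpkm_cut = 25) {
  stopifnot(all(c("gene", "tpm") %in% names(reference)),
            all(c("gene", "rpkm") %in% names(re_genes)))
  ref <- reference |>
    group_by(.data$gene) |>
    summarise(tpm = mean(.data$tpm), .groups = "drop")
  res <- re_genes |>
    group_by(.data$gene) |>
    summarise(rpkm = mean(.data$rpkm), .groups = "drop")
  shared <- intersect(ref$gene, res$gene)
  ref <- filter(ref, .data$gene %in% shared)
  res <- filter(res, .data$gene %in% shared)
  a <- sort(ref$gene[ref$tpm > tpm_cut])
  b <- sort(res$gene[res$rpkm > rpkm_cut])
  both <- intersect(a, b)
  tibble(
    n_shared = length(shared),
    n_reference_expressed = length(a),
    n_re_expressed = length(b),
    n_both = length(both),
    overlap_fraction = if (length(b)) length(both) / length(b) else NA_real_,
    reference_genes = list(a),
    re_genes = list(b),
    both_genes = list(both)
  )
}
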