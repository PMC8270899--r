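MEASURES <- c(TRANSCRIPT = "TRANSCRIPT", TE = "TE", POLY80S = "POLY80S")

# numerator / denominator fraction of each measure
.measure_fractions <- function(measure) {
  switch(measure,
         TRANSCRIPT = c(num = "TOTAL_RNA", den = "DNA"),
         TE = c(num = "POLYSOME", den = "TOTAL_RNA"),
         POLY80S = c(num = "POLYSOME", den = "RNA_80S"),
         stop("unknown measure: ", measure))
}

#' Per-barcode log2 ratios between two samples
#'
#' One observation per retained barcode:
#' \code{log2(cpm_numerator) - log2(cpm_denominator)}. Barcodes failing the
#' minimum-CPM filter in either sample are simply absent.
#'
#' @param cm an \code{\link{mpra_counts}} object.
#' @param num_sample,den_sample sample ids of the numerator and denominator
#'   (same replicate and cell line).
#' @param min_cpm inclusive minimum CPM in both samples.
#' @return Data frame \code{(barcode, log2_ratio)}.
#' @export
barcode_log_ratios <- function(cm, num_sample, den_sample, min_cpm = 0.5) {
  keep <- filter_min_cpm(cm, c(num_sample, den_sample), min_cpm)
  data.frame(barcode = keep,
             log2_ratio = log2(cm$cpm[keep, num_sample]) -
               log2(cm$cpm[keep, den_sample]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collect barcode-level ratio observations for one measure
#'
#' For every (cell line, replicate) that has both fractions of the measure,
#' computes per-barcode log2 ratios and attaches the variant each barcode
#' reports on through the EXACT entries of the long-read dictionary.
#' Observations pool barcodes across replicates; replicates are not tested
#' separately.
#'
#' @param cm an \code{\link{mpra_counts}} object.
#' @param dictionary dictionary data frame (only EXACT rows are used).
#' @param measure \code{"TRANSCRIPT"} (mRNA/DNA), \code{"TE"}
#'   (polysome/total mRNA) or \code{"POLY80S"} (polysome/80S).
#' @param min_cpm inclusive minimum CPM in both samples of each ratio.
#' @return Data frame \code{(variant_id, gene, barcode, cell_line, replicate,
#'   log2_ratio)}.
#' @export
ratio_observations <- function(cm, dictionary, measure = "TRANSCRIPT",
                               min_cpm = 0.5) {
  fr <- .measure_fractions(measure)
  s <- cm$samples
  exact <- dictionary[dictionary$status == "EXACT", c("barcode", "variant_id",
                                                      "gene")]
  out <- list()
  groups <- unique(s[c("cell_line", "replicate")])
  for (g in seq_len(nrow(groups))) {
    in_g <- s$cell_line == groups$cell_line[g] &
      s$replicate == groups$replicate[g]
    num <- s$sample_id[in_g & s$fraction == fr[["num"]]]
    den <- s$sample_id[in_g & s$fraction == fr[["den"]]]
    if (length(num) != 1 || length(den) != 1) next
    r <- barcode_log_ratios(cm, num, den, min_cpm)
    if (nrow(r) == 0) next
    r <- merge(r, exact, by = "barcode")
    if (nrow(r) == 0) next
    r$cell_line <- groups$cell_line[g]
    r$replicate <- groups$replicate[g]
    out[[length(out) + 1]] <- r
  }
  if (length(out) == 0)
    return(data.frame(variant_id = character(), gene = character(),
                      barcode = character(), cell_line = character(),
                      replicate = integer(), log2_ratio = numeric()))
  res <- do.call(rbind, out)
  res[c("variant_id", "gene", "barcode", "cell_line", "replicate",
        "log2_ratio")]
}

#' Two-sided Mann-Whitney U test for mutant versus WT barcode ratios
#'
#' The exact null distribution is used when both groups have at most 20
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections applies (mid-ranks for ties).
#'
#' @param mut_obs,wt_obs numeric vectors of barcode log2 ratios.
#' @return \code{list(U, p, exact, low_power)}; \code{U} is the statistic of
#'   the mutant group (\code{0 <= U <= n_mut * n_wt}), \code{low_power} flags
#'   \code{min(n) < 5}.
#' @export
mwu_test <- function(mut_obs, wt_obs) {
  if (length(mut_obs) == 0 || length(wt_obs) == 0)
    stop("both groups must be nonempty")
  ties <- anyDuplicated(c(mut_obs, wt_obs)) > 0
  use_exact <- !ties && length(mut_obs) <= 20 && length(wt_obs) <= 20
  ht <- suppressWarnings(
    wilcox.test(mut_obs, wt_obs, alternative = "two.sided",
                exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p = min(1, ht$p.value), exact = use_exact,
       low_power = min(length(mut_obs), length(wt_obs)) < 5)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment \code{q_(i) = min_{j >= i} p_(j) * m / j}, as
#' implemented by \code{p.adjust(method = "BH")}.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values, in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Mutant-versus-WT construct results for one measure
#'
#' One row per mutant/WT pair: barcode-level observations of the mutant are
#' compared to those of its paired WT by a two-sided Mann-Whitney U test;
#' q-values are BH-adjusted across all pairs of the table (per measure), and
#' significance is called at q < \code{fdr}. The fold change is the
#' difference of group medians of the log2 ratios (the mean difference is
#' also reported).
#'
#' @param obs observation table from \code{\link{ratio_observations}}.
#' @param lib the \code{\link{utr_library}} defining the MUT/WT pairing.
#' @param measure measure label carried into the output.
#' @param fdr significance cutoff on q (default 0.1).
#' @return Data frame \code{(pair_id, gene, measure, n_wt, n_mut, U, p, q,
#'   log2fc_median, log2fc_mean, significant, low_power)}.
#' @export
summarize_pairs <- function(obs, lib, measure = "TRANSCRIPT", fdr = 0.1) {
  muts <- lib[lib$allele == "MUT", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(muts))) {
    wt_id <- muts$paired_variant_id[i]
    if (is.na(wt_id) || !wt_id %in% lib$variant_id)
      stop("mutant ", muts$variant_id[i], " has no paired WT in the library")
    mo <- obs$log2_ratio[obs$variant_id == muts$variant_id[i]]
    wo <- obs$log2_ratio[obs$variant_id == wt_id]
    if (length(mo) == 0 || length(wo) == 0) next
    ht <- mwu_test(mo, wo)
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = paste0(wt_id, "|", muts$variant_id[i]),
      gene = muts$gene[i], measure = measure,
      n_wt = length(wo), n_mut = length(mo),
      U = ht$U, p = ht$p, q = NA_real_,
      log2fc_median = median(mo) - median(wo),
      log2fc_mean = mean(mo) - mean(wo),
      significant = NA, low_power = ht$low_power,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(pair_id = character(), gene = character(),
                      measure = character(), n_wt = integer(),
                      n_mut = integer(), U = numeric(), p = numeric(),
                      q = numeric(), log2fc_median = numeric(),
                      log2fc_mean = numeric(), significant = logical(),
                      low_power = logical()))
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < fdr
  res
}
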