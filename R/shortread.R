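#' Short-read barcode extraction configuration
#'
#' The sequencing design places the barcode completely within read 2, at a
#' fixed offset from its 3' end, bracketed by two constant 4-nt flanks that
#' are checked exactly as a guard against improper barcode length or
#' placement. Neither the offset nor the flanks are properties of the assay
#' itself, so they are run configuration; the defaults are consistent with
#' \code{\link{backbone_fixture}}: the flanks are the 4 nt of the barcode
#' anchors immediately adjacent to the barcode.
#'
#' @param barcode_length 8 (fixed barcodes) or 30 (W/S randomers).
#' @param offset_from_3prime bases between the right flank and the read's 3'
#'   end.
#' @param flank_left,flank_right the two 4-nt constant flanks.
#' @param backbone fixture used to derive the default flanks.
#' @return A list of class \code{"shortread_config"}.
#' @export
shortread_config <- function(barcode_length = 30L, offset_from_3prime = 10L,
                             flank_left = NULL, flank_right = NULL,
                             backbone = backbone_fixture()) {
  if (is.null(flank_left))
    flank_left <- substr(backbone$bc_anchor_left, 17L, 20L)
  if (is.null(flank_right))
    flank_right <- substr(backbone$bc_anchor_right, 1L, 4L)
  stopifnot(nchar(flank_left) == 4L, nchar(flank_right) == 4L,
            offset_from_3prime >= 0L, barcode_length > 0L)
  structure(list(barcode_length = as.integer(barcode_length),
                 offset_from_3prime = as.integer(offset_from_3prime),
                 flank_left = toupper(flank_left),
                 flank_right = toupper(flank_right)),
            class = "shortread_config")
}

#' Extract the barcode from read-2 sequences at a fixed position
#'
#' Position-exact: the barcode substring is taken at the configured offset
#' from the 3' end and returned only if both 4-nt flanks match exactly.
#' There is no quality trimming and no mismatch-tolerant rescue.
#'
#' @param read_seqs character vector of read-2 sequences.
#' @param config a \code{\link{shortread_config}}.
#' @return Character vector of barcodes; \code{NA} where the read is too
#'   short or a flank check fails.
#' @export
extract_barcode <- function(read_seqs, config = shortread_config()) {
  read_seqs <- toupper(read_seqs)
  len <- nchar(read_seqs)
  bc_len <- config$barcode_length
  rf_end <- len - config$offset_from_3prime
  rf_start <- rf_end - 3L
  bc_end <- rf_start - 1L
  bc_start <- bc_end - bc_len + 1L
  lf_start <- bc_start - 4L
  ok <- lf_start >= 1L
  bc <- rep(NA_character_, length(read_seqs))
  if (!any(ok)) return(bc)
  lf <- substr(read_seqs, lf_start, bc_start - 1L)
  rf <- substr(read_seqs, rf_start, rf_end)
  ok <- ok & lf == config$flank_left & rf == config$flank_right
  bc[ok] <- substr(read_seqs[ok], bc_start[ok], bc_end[ok])
  bc
}

#' Tally extracted barcodes against the cataloged dictionary
#'
#' Only barcodes cataloged as \code{EXACT} in the long-read dictionary are
#' counted; extracted-but-uncataloged barcodes appear in the QC as extracted
#' yet unmatched.
#'
#' @param read_seqs read-2 sequences, or \code{NULL} when \code{barcodes} is
#'   supplied directly (pre-extracted).
#' @param dictionary dictionary data frame from \code{\link{build_dictionary}}.
#' @param config a \code{\link{shortread_config}}.
#' @param barcodes optional pre-extracted barcode vector (bypasses
#'   extraction).
#' @return \code{list(counts, qc)}: \code{counts} is an integer vector named
#'   by every EXACT barcode of the dictionary (zeros included); \code{qc}
#'   holds \code{n_reads}, \code{n_barcode_extracted}, \code{n_matched}.
#' @export
tally_barcodes <- function(read_seqs, dictionary,
                           config = shortread_config(), barcodes = NULL) {
  if (nrow(dictionary) == 0) stop("empty barcode dictionary")
  if (is.null(barcodes)) barcodes <- extract_barcode(read_seqs, config)
  cataloged <- dictionary$barcode[dictionary$status == "EXACT"]
  extracted <- barcodes[!is.na(barcodes)]
  counts <- table(factor(extracted, levels = cataloged))
  counts <- setNames(as.integer(counts), cataloged)
  list(counts = counts,
       qc = list(n_reads = length(barcodes),
                 n_barcode_extracted = length(extracted),
                 n_matched = sum(counts)))
}

#' Sample metadata for one sequenced fraction
#'
#' @param sample_id unique sample label.
#' @param fraction \code{"DNA"}, \code{"TOTAL_RNA"}, \code{"POLYSOME"} or
#'   \code{"RNA_80S"}.
#' @param replicate biological replicate number.
#' @param cell_line free-text cell line label.
#' @return One-row data frame.
#' @export
sample_meta <- function(sample_id, fraction, replicate, cell_line = "cellA") {
  stopifnot(all(fraction %in% c("DNA", "TOTAL_RNA", "POLYSOME", "RNA_80S")))
  data.frame(sample_id = sample_id, fraction = fraction,
             replicate = as.integer(replicate), cell_line = cell_line,
             stringsAsFactors = FALSE)
}

#' Assemble a barcode count matrix across samples
#'
#' The container mirrors the layout of expression count objects: a raw count
#' matrix (barcodes x samples), the per-sample metadata, the CPM matrix and
#' per-sample QC. CPM divides each raw count by the sample's matched-read
#' total (in millions), so per-sample CPM sums to 1e6 over counted barcodes.
#'
#' @param count_list list of per-sample count vectors (identically named, as
#'   returned in \code{\link{tally_barcodes}$counts}).
#' @param samples data frame of \code{\link{sample_meta}} rows, one per
#'   element of \code{count_list}, in the same order.
#' @param qc optional list of per-sample QC records.
#' @return A list of class \code{"mpra_counts"} with elements \code{counts},
#'   \code{cpm}, \code{samples}, \code{qc}.
#' @export
mpra_counts <- function(count_list, samples, qc = NULL) {
  stopifnot(length(count_list) == nrow(samples))
  if (anyDuplicated(samples[c("fraction", "replicate", "cell_line")]))
    stop("(fraction, replicate, cell_line) must be unique per experiment")
  bcs <- names(count_list[[1]])
  if (!all(vapply(count_list, function(x) identical(names(x), bcs), TRUE)))
    stop("all count vectors must share the same barcode universe and order")
  counts <- do.call(cbind, count_list)
  colnames(counts) <- samples$sample_id
  cpm <- apply(counts, 2, cpm_normalize)
  structure(list(counts = counts, cpm = cpm, samples = samples, qc = qc),
            class = "mpra_counts")
}

#' @export
print.mpra_counts <- function(x, ...) {
  cat("mpra_counts:", nrow(x$counts), "barcodes x",
      ncol(x$counts), "samples\n")
  cat("fractions:", paste(unique(x$samples$fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Counts-per-million normalization
#'
#' \code{cpm_i = raw_i * 1e6 / n_matched}, where \code{n_matched} is the
#' total number of reads matched to cataloged barcodes in the sample (the
#' sum of the raw counts), not the sample's total read count.
#'
#' @param raw nonnegative count vector.
#' @param n_matched matched-read denominator; defaults to \code{sum(raw)}.
#' @return CPM vector; sums to 1e6 over the counted barcodes.
#' @export
cpm_normalize <- function(raw, n_matched = sum(raw)) {
  if (n_matched <= 0) stop("zero sequencing depth: no matched reads")
  raw * 1e6 / n_matched
}

#' Barcodes passing the minimum-CPM filter in every given sample
#'
#' A barcode enters a ratio computation only if its CPM is at least
#' \code{threshold} (inclusive) in every sample of that ratio. Barcodes with
#' a zero raw count in any of the samples are always excluded, so the log
#' ratios of retained barcodes are finite even at threshold 0.
#'
#' @param cm an \code{\link{mpra_counts}} object.
#' @param sample_ids samples that all must pass.
#' @param threshold minimum CPM (default 0.5).
#' @return Character vector of retained barcodes.
#' @export
filter_min_cpm <- function(cm, sample_ids, threshold = 0.5) {
  sub <- cm$cpm[, sample_ids, drop = FALSE]
  raw <- cm$counts[, sample_ids, drop = FALSE]
  keep <- rowSums(sub >= threshold & raw > 0) == ncol(sub)
  rownames(sub)[keep]
}
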