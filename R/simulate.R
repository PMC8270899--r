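#' Generate a random UTR reporter library with known truth
#'
#' One WT/MUT pair per gene: a random UTR of uniformly drawn length and a
#' single-nucleotide mutant differing at a uniformly drawn offset. Optional
#' motif planting inserts a fixed consensus into the WT sequence of selected
#' genes and records the planted interval (the mutation is then placed inside
#' the planted element so that create/disrupt behaviour is exercised).
#'
#' @param n_genes number of genes (WT/MUT pairs).
#' @param utr_length_range inclusive range of UTR lengths; the default spans
#'   the lengths full-length 5'-UTR libraries realistically cover.
#' @param plant optional \code{list(seq =, genes =)}: plant \code{seq} into
#'   the WT UTRs of gene indices \code{genes} and put each mutant's
#'   substitution inside the planted interval.
#' @param seed optional RNG seed.
#' @return \code{list(library, planted)}: a \code{\link{utr_library}} and a
#'   data frame of planted element intervals (0-based, half-open).
#' @export
simulate_library <- function(n_genes = 10L, utr_length_range = c(42L, 2960L),
                             plant = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  planted <- list()
  rows <- list()
  for (i in seq_len(n_genes)) {
    len <- sample(utr_length_range[1]:utr_length_range[2], 1L)
    wt <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    off_range <- 0:(len - 1L)
    if (!is.null(plant) && i %in% plant$genes) {
      p_seq <- toupper(plant$seq)
      p_len <- nchar(p_seq)
      stopifnot(p_len <= len)
      at <- sample(0:(len - p_len), 1L)
      wt <- paste0(substr(wt, 1, at), p_seq,
                   substr(wt, at + p_len + 1L, len))
      off_range <- at:(at + p_len - 1L)
      planted[[length(planted) + 1]] <- data.frame(
        variant_id = paste0(genes[i], "_WT"), element = "planted",
        start = at, end = at + p_len, stringsAsFactors = FALSE)
    }
    off <- if (length(off_range) == 1) off_range else sample(off_range, 1L)
    ref <- substr(wt, off + 1L, off + 1L)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    wt_id <- paste0(genes[i], "_WT")
    mut_id <- paste0(genes[i], "_MUT")
    rows[[length(rows) + 1]] <- utr_library(
      variant_id = c(wt_id, mut_id), gene = genes[i],
      allele = c("WT", "MUT"),
      sequence = c(wt, apply_mutation(wt, off, ref, alt)),
      utr_offset = c(NA, off), ref = c(NA, ref), alt = c(NA, alt),
      paired_variant_id = c(mut_id, wt_id))
  }
  lib <- do.call(rbind, rows)
  class(lib) <- c("utr_library", "data.frame")
  list(library = lib,
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(variant_id = character(), element = character(),
                    start = integer(), end = integer()))
}

# draw n unique random barcodes of the given mode
random_barcodes <- function(n, mode = c("WS30", "FIXED8")) {
  mode <- match.arg(mode)
  draw <- function(k) {
    if (mode == "FIXED8") {
      vapply(seq_len(k), function(i)
        paste(sample(DNA_BASES, 8, replace = TRUE), collapse = ""), "")
    } else {
      vapply(seq_len(k), function(i)
        paste(rbind(sample(c("A", "T"), 15, replace = TRUE),
                    sample(c("G", "C"), 15, replace = TRUE)),
              collapse = ""), "")
    }
  }
  bcs <- unique(draw(n))
  while (length(bcs) < n) bcs <- unique(c(bcs, draw(n - length(bcs))))
  bcs[seq_len(n)]
}

# substitute bases at rate `rate` (iid per base)
.corrupt <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  at <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  chars[at] <- vapply(chars[at], function(b)
    sample(setdiff(DNA_BASES, b), 1L), "")
  paste(chars, collapse = "")
}

#' Simulate circular-consensus long reads of the plasmid library
#'
#' Every construct receives \code{barcodes_per_construct} unique barcodes. A
#' plasmid is mis-synthesized with probability
#' \code{1 - (1 - synthesis_error_per_base)^utr_length} (one permanent random
#' substitution in its UTR), so longer UTRs are mis-synthesized more often.
#' Reads copy the assembled plasmid with iid per-base substitution errors at
#' \code{ccs_error_rate}; half of the reads are emitted reverse-complemented.
#'
#' @param lib a \code{\link{utr_library}}.
#' @param barcodes_per_construct distinct barcodes per construct (the full
#'   library design averages 236; proof-of-concept designs use 5).
#' @param reads_per_barcode CCS-like reads per barcode.
#' @param barcode_mode \code{"WS30"} or \code{"FIXED8"}.
#' @param ccs_error_rate per-base read error rate.
#' @param synthesis_error_per_base per-base plasmid mis-synthesis rate.
#' @param backbone a \code{\link{backbone_fixture}}.
#' @param seed optional RNG seed.
#' @return \code{list(reads, truth)}: named read vector and the truth table
#'   \code{(barcode, variant_id, corrupted)}.
#' @export
simulate_ccs <- function(lib, barcodes_per_construct = 5L,
                         reads_per_barcode = 10L,
                         barcode_mode = c("WS30", "FIXED8"),
                         ccs_error_rate = 0, synthesis_error_per_base = 0,
                         backbone = backbone_fixture(), seed = NULL) {
  barcode_mode <- match.arg(barcode_mode)
  if (!is.null(seed)) set.seed(seed)
  n_constructs <- nrow(lib)
  bcs <- random_barcodes(n_constructs * barcodes_per_construct, barcode_mode)
  truth <- data.frame(
    barcode = bcs,
    variant_id = rep(lib$variant_id, each = barcodes_per_construct),
    corrupted = FALSE, stringsAsFactors = FALSE)
  reads <- character(0)
  for (i in seq_len(nrow(truth))) {
    utr <- lib$sequence[match(truth$variant_id[i], lib$variant_id)]
    p_bad <- 1 - (1 - synthesis_error_per_base)^nchar(utr)
    if (runif(1) < p_bad) {
      truth$corrupted[i] <- TRUE
      at <- sample.int(nchar(utr), 1L)
      b <- substr(utr, at, at)
      utr <- paste0(substr(utr, 1, at - 1L),
                    sample(setdiff(DNA_BASES, b), 1L),
                    substr(utr, at + 1L, nchar(utr)))
    }
    plasmid <- assemble_construct(utr, truth$barcode[i], backbone,
                                  barcode_mode)
    rd <- vapply(seq_len(reads_per_barcode), function(j)
      .corrupt(plasmid, ccs_error_rate), "")
    flip <- runif(reads_per_barcode) < 0.5
    rd[flip] <- revcomp(rd[flip])
    names(rd) <- sprintf("read_%s_%02d", truth$barcode[i],
                         seq_len(reads_per_barcode))
    reads <- c(reads, rd)
  }
  list(reads = reads, truth = truth)
}

#' Simulate DNA / mRNA / polysome / 80S barcode count matrices
#'
#' Generative model: each barcode's plasmid abundance is lognormal
#' (\code{log2} sd \code{dispersion}); expected mRNA mass is DNA abundance
#' times the construct's transcript factor; expected polysome mass is mRNA
#' mass times the TE factor; 80S mass is mRNA mass divided by the TE factor
#' (mass moves between the single-ribosome and polysome pools). Every sample
#' is an independent multinomial draw of \code{depth} matched reads from its
#' expected mass profile; replicates share the underlying abundances, which
#' is what makes replicate CPM correlations high.
#'
#' @param truth dictionary truth (\code{barcode}, \code{variant_id}), e.g.
#'   from \code{\link{simulate_ccs}}.
#' @param effects data frame \code{(variant_id, transcript_factor,
#'   te_factor)}; factors are 1 for WT and null mutants.
#' @param depth matched reads per sample.
#' @param dispersion log2 sd of the barcode abundance lognormal.
#' @param replicates biological replicates per fraction.
#' @param cell_line sample label.
#' @param fractions fractions to emit.
#' @param seed optional RNG seed.
#' @return An \code{\link{mpra_counts}} object.
#' @export
simulate_counts <- function(truth, effects, depth = 5e6, dispersion = 1,
                            replicates = 3L, cell_line = "cellA",
                            fractions = c("DNA", "TOTAL_RNA", "POLYSOME",
                                          "RNA_80S"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depth > 0, dispersion >= 0)
  i <- match(truth$variant_id, effects$variant_id)
  if (anyNA(i)) stop("effects missing for some variants")
  tf <- effects$transcript_factor[i]
  te <- effects$te_factor[i]
  stopifnot(all(tf > 0), all(te > 0))
  abundance <- rlnorm(nrow(truth), meanlog = 0, sdlog = dispersion * log(2))
  mass <- list(DNA = abundance,
               TOTAL_RNA = abundance * tf,
               POLYSOME = abundance * tf * te,
               RNA_80S = abundance * tf / te)
  count_list <- list()
  samples <- list()
  for (fr in fractions) {
    for (r in seq_len(replicates)) {
      cnt <- as.integer(rmultinom(1, size = depth,
                                  prob = mass[[fr]] / sum(mass[[fr]])))
      count_list[[length(count_list) + 1]] <- setNames(cnt, truth$barcode)
      samples[[length(samples) + 1]] <-
        sample_meta(paste0(fr, "_rep", r, "_", cell_line), fr, r, cell_line)
    }
  }
  mpra_counts(count_list, do.call(rbind, samples))
}

#' Emit short reads reproducing a count vector
#'
#' One read per tallied count: random padding, the left 4-nt flank, the
#' barcode, the right flank, and 3'-end padding matching the configured
#' offset, so that counting the emitted reads reproduces the input counts
#' exactly.
#'
#' @param counts named integer vector (barcode -> count).
#' @param config a \code{\link{shortread_config}}.
#' @param read_length total read length (default 100).
#' @param seed optional RNG seed.
#' @return Named character vector of reads.
#' @export
emit_shortreads <- function(counts, config = shortread_config(),
                            read_length = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total == 0) return(character(0))
  bc <- rep(names(counts), counts)
  tail_len <- config$offset_from_3prime
  lead_len <- read_length - config$barcode_length - 8L - tail_len
  if (lead_len < 0) stop("read_length too short for the barcode layout")
  pad <- function(k, n) vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, k, replace = TRUE), collapse = ""), "")
  reads <- paste0(pad(lead_len, total), config$flank_left, bc,
                  config$flank_right, pad(tail_len, total))
  setNames(reads, sprintf("sr_%07d", seq_len(total)))
}
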