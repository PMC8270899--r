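#' Extract the UTR and barcode fields from a long read
#'
#' Locates the four constant 20-nt anchors inside a circular-consensus read
#' and returns the substrings between the UTR anchors and between the barcode
#' anchors. Anchors are first searched for exactly, then (if
#' \code{max_anchor_edit > 0}) with up to that many mismatches/indels. If the
#' full anchor set is not found on the given strand the reverse complement is
#' searched; a read whose anchors are found on both strands is excluded as
#' chimeric.
#'
#' Exclusion is a return state, not an error: the \code{status} field is
#' \code{"OK"}, \code{"ANCHOR_MISSING"}, \code{"NO_BARCODE"} (the EcoRI site
#' GAATTC still occupies the barcode locus, i.e. no barcode was inserted), or
#' \code{"CHIMERIC"}.
#'
#' @param read_seq read sequence (character scalar).
#' @param backbone a \code{\link{backbone_fixture}}.
#' @param max_anchor_edit maximum edit distance tolerated per anchor.
#' @return \code{list(status, utr_seq, barcode_seq)}.
#' @export
extract_fields <- function(read_seq, backbone = backbone_fixture(),
                           max_anchor_edit = 2L) {
  res <- extract_fields_many(read_seq, backbone, max_anchor_edit)
  list(status = res$status[1], utr_seq = res$utr_seq[1],
       barcode_seq = res$barcode_seq[1])
}

# locate one anchor in one read: exact first, then approximate
.find_anchor <- function(anchor, seq, max_edit) {
  p <- regexpr(anchor, seq, fixed = TRUE)
  if (p > 0) return(c(p, p + nchar(anchor) - 1L))
  if (max_edit > 0) {
    m <- Biostrings::matchPattern(anchor, Biostrings::DNAString(seq),
                                  max.mismatch = max_edit, with.indels = TRUE)
    if (length(m) > 0)
      return(c(IRanges::start(m)[1], IRanges::end(m)[1]))
  }
  NULL
}

# all four anchors on one strand, in order; NULL if incomplete
.locate_anchors <- function(seq, backbone, max_edit) {
  hits <- lapply(c(backbone$utr_anchor_left, backbone$utr_anchor_right,
                   backbone$bc_anchor_left, backbone$bc_anchor_right),
                 .find_anchor, seq = seq, max_edit = max_edit)
  if (any(vapply(hits, is.null, TRUE))) return(NULL)
  pos <- do.call(rbind, hits)
  # ordering uL < uR <= bL < bR along the read
  if (is.unsorted(pos[, 1]) || any(pos[-4, 2] >= pos[-1, 1])) return(NULL)
  pos
}

#' Vectorized field extraction over many reads
#'
#' @param read_seqs character vector of read sequences.
#' @inheritParams extract_fields
#' @return data frame with columns \code{status}, \code{utr_seq},
#'   \code{barcode_seq}, one row per read.
#' @export
extract_fields_many <- function(read_seqs, backbone = backbone_fixture(),
                                max_anchor_edit = 2L) {
  read_seqs <- toupper(read_seqs)
  n <- length(read_seqs)
  out <- data.frame(status = rep("ANCHOR_MISSING", n),
                    utr_seq = NA_character_, barcode_seq = NA_character_,
                    stringsAsFactors = FALSE)
  anchors <- c(backbone$utr_anchor_left, backbone$utr_anchor_right,
               backbone$bc_anchor_left, backbone$bc_anchor_right)
  exact_pos <- function(seqs) {
    sapply(anchors, function(a) as.integer(regexpr(a, seqs, fixed = TRUE)))
  }
  finish <- function(seq, pos) {
    # pos: 4 x 2 matrix of (start, end) for uL, uR, bL, bR
    utr <- substr(seq, pos[1, 2] + 1L, pos[2, 1] - 1L)
    bc <- substr(seq, pos[3, 2] + 1L, pos[4, 1] - 1L)
    if (grepl("GAATTC", bc, fixed = TRUE) || nchar(bc) == 0L)
      return(list(status = "NO_BARCODE", utr_seq = NA_character_,
                  barcode_seq = NA_character_))
    list(status = "OK", utr_seq = utr, barcode_seq = bc)
  }
  fwd <- matrix(exact_pos(read_seqs), nrow = n)
  rc_seqs <- revcomp(read_seqs)
  rev <- matrix(exact_pos(rc_seqs), nrow = n)
  fwd_ok <- rowSums(fwd > 0) == 4L
  rev_ok <- rowSums(rev > 0) == 4L
  for (i in seq_len(n)) {
    pos_f <- if (fwd_ok[i])
      .locate_anchors(read_seqs[i], backbone, 0L) else NULL
    pos_r <- if (rev_ok[i])
      .locate_anchors(rc_seqs[i], backbone, 0L) else NULL
    if (is.null(pos_f) && is.null(pos_r) && max_anchor_edit > 0) {
      pos_f <- .locate_anchors(read_seqs[i], backbone, max_anchor_edit)
      pos_r <- .locate_anchors(rc_seqs[i], backbone, max_anchor_edit)
    }
    if (!is.null(pos_f) && !is.null(pos_r)) {
      out$status[i] <- "CHIMERIC"
    } else if (!is.null(pos_f)) {
      out[i, ] <- finish(read_seqs[i], pos_f)
    } else if (!is.null(pos_r)) {
      out[i, ] <- finish(rc_seqs[i], pos_r)
    }
  }
  out
}

#' Group extracted UTR sequences by their exact barcode
#'
#' Barcodes are exact string keys: sequences differing by a single base are
#' distinct barcodes (no fuzzy merging).
#'
#' @param utr_seqs,barcode_seqs parallel character vectors from
#'   \code{\link{extract_fields_many}} rows with status \code{"OK"}.
#' @return Named list: barcode -> character vector of UTR observations.
#' @export
group_by_barcode <- function(utr_seqs, barcode_seqs) {
  if (length(utr_seqs) != length(barcode_seqs))
    stop("utr_seqs and barcode_seqs must be parallel vectors")
  if (length(utr_seqs) == 0) return(setNames(list(), character()))
  split(utr_seqs, factor(barcode_seqs, levels = sort(unique(barcode_seqs))))
}

#' Column-majority consensus of the reads sharing one barcode
#'
#' Single observations pass through verbatim. For multiple observations the
#' medoid read (minimum total edit distance to the others, ties broken toward
#' the lexicographically smallest sequence) anchors a star alignment: every
#' other read is globally aligned to the medoid and votes per column. The gap
#' is a fifth symbol and is dropped from the consensus when it wins a column;
#' ties are broken toward the lexicographically smallest non-gap symbol, so
#' the result does not depend on input order.
#'
#' @param utr_seqs character vector of UTR observations (nonempty).
#' @return Consensus sequence (character scalar).
#' @export
consensus_sequence <- function(utr_seqs) {
  if (length(utr_seqs) == 0) stop("consensus of an empty read list")
  tab <- table(utr_seqs)
  uniq <- sort(names(tab))                 # order-insensitive by construction
  w <- as.numeric(tab[uniq])
  if (length(uniq) == 1L) return(uniq)
  d <- adist(uniq)
  total <- as.numeric(d %*% w)
  medoid <- uniq[which.min(total)]         # ties -> lexicographically first
  m_len <- nchar(medoid)
  # votes[[key]] accumulates symbol weights; key "i.j" = j-th insertion after
  # medoid position i (j = 0 is the medoid position itself)
  votes <- new.env(parent = emptyenv())
  cast <- function(key, sym, weight) {
    cur <- if (!is.null(votes[[key]])) votes[[key]] else numeric()
    cur[sym] <- (if (sym %in% names(cur)) cur[sym] else 0) + weight
    votes[[key]] <- cur
  }
  w_medoid <- w[uniq == medoid]
  for (i in seq_len(m_len)) cast(paste0(i, ".0"),
                                 substr(medoid, i, i), w_medoid)
  others <- uniq[uniq != medoid]
  ins_weight <- numeric()                  # total weight voting at each key
  for (k in seq_along(others)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(others[k]), Biostrings::DNAString(medoid),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    wk <- w[uniq == others[k]]
    i <- 0L; j <- 0L
    for (c in seq_along(s)) {
      if (s[c] != "-") { i <- i + 1L; j <- 0L } else { j <- j + 1L }
      key <- paste0(i, ".", j)
      cast(key, p[c], wk)
      if (j > 0) ins_weight[key] <-
          (if (key %in% names(ins_weight)) ins_weight[key] else 0) + wk
    }
  }
  total_w <- sum(w)
  # reads that never visited an insertion column implicitly vote gap there
  for (key in names(ins_weight)) cast(key, "-", total_w - ins_weight[key])
  keys <- ls(votes)
  ki <- as.integer(sub("\\..*$", "", keys))
  kj <- as.integer(sub("^.*\\.", "", keys))
  ord <- order(ki, kj)
  res <- vapply(keys[ord], function(key) {
    v <- votes[[key]]
    top <- names(v)[v == max(v)]
    if (length(top) > 1) top <- setdiff(top, "-")  # gap loses ties
    sort(top)[1]                                   # smallest non-gap symbol
  }, "")
  paste(res[res != "-"], collapse = "")
}

#' Annotate a consensus sequence against the expected library
#'
#' Exact string matching is required to assign a variant, because most mutants
#' differ from their WT by a single base. A consensus identical to a sequence
#' shared by more than one variant is \code{AMBIGUOUS} (excluded from
#' quantification); any other non-matching consensus is annotated to the
#' nearest library gene by global edit distance, with equidistant genes
#' resolved to the lexicographically first and flagged \code{tie}.
#'
#' @param consensus_seq consensus UTR sequence.
#' @param lib a \code{\link{utr_library}}.
#' @return \code{list(status, variant_id, gene, edit_distance, tie)} where
#'   \code{status} is \code{"EXACT"}, \code{"AMBIGUOUS"} or
#'   \code{"NEAREST_GENE"}.
#' @export
annotate_consensus <- function(consensus_seq, lib) {
  if (nrow(lib) == 0) stop("empty library")
  hit <- which(lib$sequence == consensus_seq)
  if (length(hit) == 1)
    return(list(status = "EXACT", variant_id = lib$variant_id[hit],
                gene = lib$gene[hit], edit_distance = 0L, tie = FALSE))
  if (length(hit) > 1)
    return(list(status = "AMBIGUOUS", variant_id = NA_character_,
                gene = NA_character_, edit_distance = 0L, tie = FALSE))
  d <- as.integer(adist(consensus_seq, lib$sequence))
  dmin <- min(d)
  genes <- sort(unique(lib$gene[d == dmin]))
  list(status = "NEAREST_GENE", variant_id = NA_character_,
       gene = genes[1], edit_distance = dmin, tie = length(genes) > 1)
}

#' Build the barcode-to-construct dictionary from long reads
#'
#' Composition of \code{\link{extract_fields_many}},
#' \code{\link{group_by_barcode}}, \code{\link{consensus_sequence}} and
#' \code{\link{annotate_consensus}}, with QC tallies. Grouping and consensus
#' are order-insensitive, so the dictionary is a deterministic function of the
#' read multiset.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param lib the expected \code{\link{utr_library}}.
#' @param backbone a \code{\link{backbone_fixture}}.
#' @param max_anchor_edit maximum per-anchor edit distance during extraction.
#' @return \code{list(dictionary, qc)}: \code{dictionary} is a data frame with
#'   one row per distinct barcode (\code{barcode, variant_id, status, gene,
#'   edit_distance, tie, n_reads, consensus_seq, consensus_len}); \code{qc}
#'   tallies reads, exclusions and per-variant barcode support.
#' @export
build_dictionary <- function(reads, lib, backbone = backbone_fixture(),
                             max_anchor_edit = 2L) {
  validate_library(lib)
  ext <- extract_fields_many(reads, backbone, max_anchor_edit)
  ok <- ext$status == "OK"
  groups <- group_by_barcode(ext$utr_seq[ok], ext$barcode_seq[ok])
  rows <- lapply(names(groups), function(bc) {
    cons <- consensus_sequence(groups[[bc]])
    ann <- annotate_consensus(cons, lib)
    data.frame(barcode = bc, variant_id = ann$variant_id,
               status = ann$status, gene = ann$gene,
               edit_distance = ann$edit_distance, tie = ann$tie,
               n_reads = length(groups[[bc]]), consensus_seq = cons,
               consensus_len = nchar(cons), stringsAsFactors = FALSE)
  })
  dict <- if (length(rows)) do.call(rbind, rows) else
    data.frame(barcode = character(), variant_id = character(),
               status = character(), gene = character(),
               edit_distance = integer(), tie = logical(),
               n_reads = integer(), consensus_seq = character(),
               consensus_len = integer(), stringsAsFactors = FALSE)
  exact <- dict[dict$status == "EXACT", , drop = FALSE]
  per_variant <- table(factor(exact$variant_id, levels = lib$variant_id))
  qc <- list(
    n_ccs = length(reads),
    n_extracted = sum(ok),
    n_excluded = as.list(table(ext$status[!ok])),
    n_distinct_barcodes = nrow(dict),
    n_exact = nrow(exact),
    per_variant_barcode_counts = as.list(per_variant),
    mean_barcodes_per_variant = mean(per_variant),
    median_barcodes_per_variant = median(as.numeric(per_variant))
  )
  list(dictionary = dict, qc = qc)
}
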