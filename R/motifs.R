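#' Convert a position-frequency matrix to a log2 position weight matrix
#'
#' Each position's frequencies receive a pseudocount and are renormalized
#' before the standard conversion \code{log2(frequency / 0.25)}, so that zero
#' frequencies map to a finite floor instead of -Inf. A uniform column
#' contributes weight 0; the maximum score is the score of the per-position
#' argmax sequence. RNA motifs are stored in DNA alphabet (U = T) and are
#' scanned on the plus strand only.
#'
#' @param pfm L x 4 matrix of base probabilities, columns in A, C, G, T
#'   order; rows must be nonnegative and sum to about 1.
#' @param name motif name.
#' @param source \code{"DNA"} (scanned on both strands) or \code{"RNA"}
#'   (plus strand only).
#' @param pseudocount added to every frequency before renormalization.
#' @param cutoff_frac default scan cutoff as a fraction of the maximum score.
#' @return A list of class \code{"pwm_motif"} with elements \code{name},
#'   \code{source}, \code{weights}, \code{max_score}, \code{cutoff_frac}.
#' @export
pfm_to_pwm <- function(pfm, name = "motif", source = c("DNA", "RNA"),
                       pseudocount = 1e-3, cutoff_frac = 0.9) {
  source <- match.arg(source)
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4 || any(pfm < 0) || any(abs(rowSums(pfm) - 1) > 0.05))
    stop("pfm must be an L x 4 matrix of probabilities (A, C, G, T columns)")
  colnames(pfm) <- DNA_BASES
  adj <- (pfm + pseudocount) / (1 + 4 * pseudocount)
  w <- log2(adj / 0.25)
  structure(list(name = name, source = source, weights = w,
                 max_score = sum(apply(w, 1, max)),
                 cutoff_frac = cutoff_frac),
            class = "pwm_motif")
}

# integer-encode a sequence (A=1 C=2 G=3 T=4; other letters NA)
.seq_int <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

# scores of all windows of `weights` along an integer-encoded sequence
.window_scores <- function(seq_int, weights) {
  L <- nrow(weights)
  n <- length(seq_int) - L + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + weights[j, seq_int[j:(j + n - 1L)]]
  s
}

# weight matrix that scores the minus strand at plus-strand coordinates:
# W_rc[j, b] = W[L + 1 - j, complement(b)]
.revcomp_weights <- function(weights) {
  w <- weights[rev(seq_len(nrow(weights))), c("T", "G", "C", "A")]
  colnames(w) <- DNA_BASES
  w
}

.empty_hits <- function() {
  data.frame(element = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

.hits_df <- function(element, start, L, strand, score) {
  if (length(start) == 0) return(.empty_hits())
  data.frame(element = element, start = as.integer(start),
             end = as.integer(start + L), strand = strand, score = score,
             stringsAsFactors = FALSE)
}

#' Scan a sequence with a position weight matrix
#'
#' Every window scoring at least \code{cutoff_frac * max_score} is a hit.
#' DNA motifs are scanned on both the forward and reverse strands (minus
#' strand hits are reported at plus-strand coordinates); RNA motifs only on
#' the plus strand. Intervals are 0-based, half-open.
#'
#' @param seq DNA string.
#' @param motif a \code{\link{pfm_to_pwm}} motif.
#' @param cutoff_frac overrides the motif's stored cutoff fraction.
#' @return Hits data frame \code{(element, start, end, strand, score)}.
#' @export
scan_pwm <- function(seq, motif, cutoff_frac = motif$cutoff_frac) {
  si <- .seq_int(seq)
  cutoff <- cutoff_frac * motif$max_score
  L <- nrow(motif$weights)
  sp <- .window_scores(si, motif$weights)
  keep <- which(!is.na(sp) & sp >= cutoff)
  hits <- .hits_df(motif$name, keep - 1L, L, "+", sp[keep])
  if (motif$source == "DNA") {
    sm <- .window_scores(si, .revcomp_weights(motif$weights))
    keep <- which(!is.na(sm) & sm >= cutoff)
    hits <- rbind(hits, .hits_df(motif$name, keep - 1L, L, "-", sm[keep]))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Find upstream AUG codons (and complete upstream ORFs)
#'
#' Reports every ATG trinucleotide in the UTR. When the main ORF is assumed
#' to start right after the UTR (\code{cds_gap} nt downstream of the UTR's
#' 3' end, 0 by default), each uAUG is annotated with whether it is in frame
#' with the main ORF and whether an in-frame stop codon (TAA/TAG/TGA) lies
#' fully within the UTR before the CDS. A uAUG with such a stop is a complete
#' upstream ORF (\code{uorf}); an in-frame uAUG without one reads through
#' into the CDS as an N-terminal extension (\code{in_frame_extension}).
#'
#' @param seq the UTR sequence.
#' @param cds_gap nt between the UTR 3' end and the CDS start codon.
#' @return Hits data frame with columns \code{element = "UAUG"},
#'   \code{start}, \code{end}, \code{strand}, \code{score} (NA),
#'   \code{in_frame}, \code{has_stop}, \code{uorf}, \code{in_frame_extension}.
#' @export
find_uaug <- function(seq, cds_gap = 0L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  m <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) {
    h <- .empty_hits()
    h$in_frame <- logical(); h$has_stop <- logical()
    h$uorf <- logical(); h$in_frame_extension <- logical()
    return(h)
  }
  starts0 <- as.integer(m) - 1L
  in_frame <- (n - starts0 + cds_gap) %% 3L == 0L
  has_stop <- vapply(starts0, function(s) {
    if (s + 6L > n) return(FALSE)
    cs <- seq.int(s + 3L, n - 3L, by = 3L)
    any(substring(seq, cs + 1L, cs + 3L) %in% c("TAA", "TAG", "TGA"))
  }, TRUE)
  h <- .hits_df("UAUG", starts0, 3L, "+", NA_real_)
  h$in_frame <- in_frame
  h$has_stop <- has_stop
  h$uorf <- has_stop
  h$in_frame_extension <- in_frame & !has_stop
  h
}

#' Find G-quadruplex-forming tracts
#'
#' A G-quadruplex is four groups of at least two adjacent guanines separated
#' by loops of 1 to 7 nucleotides. Matching is left-greedy and
#' non-overlapping; scanning is on the plus strand only.
#'
#' @param seq DNA string.
#' @return Hits data frame \code{(element = "G4", start, end, strand,
#'   score)}.
#' @export
find_g4 <- function(seq) {
  seq <- toupper(seq)
  pat <- "G{2,}([ACGT]{1,7}G{2,}){3}"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(.empty_hits())
  starts0 <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(element = "G4", start = starts0, end = starts0 + lens,
             strand = "+", score = NA_real_, stringsAsFactors = FALSE)
}

#' Find a 5'-terminal oligopyrimidine (5'-TOP) tract
#'
#' A 5'-TOP starts at the very first base of the UTR with a cytosine followed
#' by at least four pyrimidines (C/T), extending maximally. Its impact rule
#' is positional: any mutation in the first ten bases (0-based offsets 0-9)
#' of a UTR carrying a 5'-TOP counts as mutating that 5'-TOP.
#'
#' @param seq the UTR sequence.
#' @return Hits data frame with zero or one \code{TOP5} row.
#' @export
find_5top <- function(seq) {
  seq <- toupper(seq)
  if (substr(seq, 1, 1) != "C") return(.empty_hits())
  run <- attr(regexpr("^[CT]*", substr(seq, 2, nchar(seq))), "match.length")
  if (run < 4) return(.empty_hits())
  .hits_df("TOP5", 0L, 1L + run, "+", NA_real_)
}

#' Find pyrimidine-rich translational elements (PRTE)
#'
#' A PWM scan (plus strand, 90%-of-maximum cutoff by default) with two hard
#' constraints from the element's definition: the window base at position 6
#' (1-based within the window) must be the invariant uridine (T in DNA
#' alphabet), and the window must not start at position +1 of the UTR
#' (0-based offset 0). The matrix itself is supplied by the caller; the
#' package bundles a synthetic fixture matrix encoding the verbal definition
#' (see \code{system.file("extdata/motifs", package = "utrmpra")}).
#'
#' @param seq the UTR sequence.
#' @param prte_pwm a \code{\link{pfm_to_pwm}} motif of length >= 6.
#' @param cutoff_frac overrides the motif's stored cutoff fraction.
#' @return Hits data frame \code{(element = "PRTE", ...)}.
#' @export
find_prte <- function(seq, prte_pwm, cutoff_frac = prte_pwm$cutoff_frac) {
  if (nrow(prte_pwm$weights) < 6) stop("PRTE matrix must have length >= 6")
  hits <- scan_pwm(seq, structure(prte_pwm, class = "pwm_motif"),
                   cutoff_frac)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) == 0) return(.empty_hits())
  base6 <- substr(rep(toupper(seq), nrow(hits)),
                  hits$start + 6L, hits$start + 6L)
  hits <- hits[hits$start > 0L & base6 == "T", , drop = FALSE]
  if (nrow(hits) == 0) return(.empty_hits())
  hits$element <- "PRTE"
  hits
}

#' Bundle the element scanners applied to every sequence
#'
#' @param dna_pwms,rna_pwms named lists of \code{\link{pfm_to_pwm}} motifs
#'   (DNA motifs are scanned on both strands, RNA motifs plus-strand only).
#' @param prte_pwm optional PRTE matrix for \code{\link{find_prte}}.
#' @param uaug,uorf,g4,top5 logical switches for the rule-based scanners.
#' @param uorf_catalog optional list mapping a sequence label to 0-based
#'   start offsets of externally predicted uORF start codons; when supplied,
#'   the uORF class counts a mutation only if it lands within one of these
#'   start codons (the de novo uORF scan is bypassed).
#' @param cds_gap passed to \code{\link{find_uaug}}.
#' @return A list of class \code{"scanner_set"}.
#' @export
scanner_set <- function(dna_pwms = list(), rna_pwms = list(),
                        prte_pwm = NULL, uaug = TRUE, uorf = TRUE,
                        g4 = TRUE, top5 = TRUE, uorf_catalog = NULL,
                        cds_gap = 0L) {
  structure(list(dna_pwms = dna_pwms, rna_pwms = rna_pwms,
                 prte_pwm = prte_pwm, uaug = uaug, uorf = uorf, g4 = g4,
                 top5 = top5, uorf_catalog = uorf_catalog,
                 cds_gap = as.integer(cds_gap)),
            class = "scanner_set")
}

#' Class labels produced by a scanner set
#' @param scanners a \code{\link{scanner_set}}.
#' @return Character vector of element class labels.
#' @export
scanner_classes <- function(scanners) {
  prefix <- function(p, l) if (length(l)) paste0(p, names(l)) else character()
  c(prefix("DNA:", scanners$dna_pwms),
    prefix("RNA:", scanners$rna_pwms),
    if (!is.null(scanners$prte_pwm)) "PRTE",
    if (scanners$uaug) "UAUG",
    if (scanners$uorf) "UORF",
    if (scanners$g4) "G4",
    if (scanners$top5) "TOP5")
}

# all hits of one element class on one sequence
.class_hits <- function(seq, class, scanners, seq_label = NULL) {
  if (startsWith(class, "DNA:"))
    return(scan_pwm(seq, scanners$dna_pwms[[substring(class, 5)]]))
  if (startsWith(class, "RNA:"))
    return(scan_pwm(seq, scanners$rna_pwms[[substring(class, 5)]]))
  switch(class,
         PRTE = find_prte(seq, scanners$prte_pwm),
         UAUG = find_uaug(seq, scanners$cds_gap)[, 1:5],
         UORF = {
           if (!is.null(scanners$uorf_catalog)) {
             starts <- scanners$uorf_catalog[[seq_label %||% ""]]
             .hits_df("UORF", as.integer(starts %||% integer()), 3L, "+",
                      NA_real_)
           } else {
             h <- find_uaug(seq, scanners$cds_gap)
             h <- h[h$uorf, 1:5, drop = FALSE]
             if (nrow(h)) h$element <- "UORF"
             h
           }
         },
         G4 = find_g4(seq),
         TOP5 = find_5top(seq),
         stop("unknown element class: ", class))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hits whose [start, end) interval overlaps 0-based offset
.overlapping <- function(hits, offset) {
  hits[hits$start <= offset & hits$end > offset, , drop = FALSE]
}

.hit_keys <- function(hits) paste(hits$start, hits$end, hits$strand)

#' Call the impact of a single-nucleotide mutation on each element class
#'
#' For every element class the hit sets of the WT and mutant sequences are
#' compared at intervals overlapping the mutation: a WT hit missing from the
#' mutant is \code{DISRUPTS_EXISTING}, a mutant hit missing from the WT is
#' \code{CREATES_NEW}; when a mutation does both (possible when a window
#' remains a hit while another is lost), both calls are emitted. The 5'-TOP
#' class uses its positional rule instead: any mutation at offsets 0-9 of a
#' UTR whose WT (mutant) carries a 5'-TOP disrupts (creates) it.
#'
#' @param wt_utr,mut_utr WT and mutant sequences (equal length, differing
#'   only at \code{utr_offset}).
#' @param utr_offset 0-based offset of the substitution.
#' @param scanners a \code{\link{scanner_set}}.
#' @param seq_label label used to look up \code{uorf_catalog} entries.
#' @return Data frame \code{(element_class, verdict)} with one \code{NONE}
#'   row per unaffected class and one row per \code{DISRUPTS_EXISTING} /
#'   \code{CREATES_NEW} call.
#' @export
mutation_impact <- function(wt_utr, mut_utr, utr_offset, scanners,
                            seq_label = NULL) {
  wt_utr <- toupper(wt_utr); mut_utr <- toupper(mut_utr)
  if (nchar(wt_utr) != nchar(mut_utr))
    stop("WT and mutant sequences must have equal length")
  diffs <- which(strsplit(wt_utr, "")[[1]] != strsplit(mut_utr, "")[[1]])
  if (!identical(diffs, as.integer(utr_offset) + 1L))
    stop("sequences must differ exactly at utr_offset")
  rows <- list()
  for (class in scanner_classes(scanners)) {
    if (class == "TOP5") {
      wt_top <- nrow(find_5top(wt_utr)) > 0
      mut_top <- nrow(find_5top(mut_utr)) > 0
      v <- if (utr_offset >= 10L || (!wt_top && !mut_top)) "NONE"
      else if (wt_top) "DISRUPTS_EXISTING" else "CREATES_NEW"
      rows[[length(rows) + 1]] <- data.frame(element_class = class,
                                             verdict = v,
                                             stringsAsFactors = FALSE)
      next
    }
    if (class == "UORF" && !is.null(scanners$uorf_catalog)) {
      # external catalog: a mutation counts iff it lands within the start
      # codon of a predicted uORF of this sequence
      starts <- scanners$uorf_catalog[[seq_label %||% ""]] %||% integer()
      v <- if (any(utr_offset >= starts & utr_offset < starts + 3L))
        "DISRUPTS_EXISTING" else "NONE"
      rows[[length(rows) + 1]] <- data.frame(element_class = class,
                                             verdict = v,
                                             stringsAsFactors = FALSE)
      next
    }
    wt_hits <- .overlapping(.class_hits(wt_utr, class, scanners, seq_label),
                            utr_offset)
    mut_hits <- .overlapping(.class_hits(mut_utr, class, scanners,
                                         seq_label), utr_offset)
    lost <- setdiff(.hit_keys(wt_hits), .hit_keys(mut_hits))
    gained <- setdiff(.hit_keys(mut_hits), .hit_keys(wt_hits))
    v <- c(if (length(lost)) "DISRUPTS_EXISTING",
           if (length(gained)) "CREATES_NEW")
    if (length(v) == 0) v <- "NONE"
    rows[[length(rows) + 1]] <- data.frame(element_class = class,
                                           verdict = v,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' The bundled synthetic PRTE fixture matrix
#'
#' The published PRTE matrix is not redistributable here, so the package
#' ships a synthetic stand-in that encodes the element's verbal definition:
#' a 10-position pyrimidine-rich matrix with an invariant T (uridine) at
#' position 6. Results obtained with it are fixture-derived, not
#' reproductions of the published matrix.
#'
#' @param pseudocount,cutoff_frac passed to \code{\link{pfm_to_pwm}}.
#' @return A \code{"pwm_motif"} for \code{\link{find_prte}}.
#' @export
prte_fixture_pwm <- function(pseudocount = 1e-3, cutoff_frac = 0.9) {
  path <- system.file("extdata/motifs/prte_synthetic.motif",
                      package = "utrmpra")
  read_homer_motifs(path, source = "RNA", pseudocount = pseudocount)[[1]]
}
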