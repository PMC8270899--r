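#' The reporter-library model
#'
#' A UTR reporter library is represented as a data frame with one row per
#' variant (class \code{"utr_library"}). Wild-type (WT) rows carry no mutation
#' record; mutant (MUT) rows carry a single-nucleotide substitution relative to
#' their paired WT sequence, described both in UTR coordinates (0-based
#' \code{utr_offset}) and, optionally, genomic coordinates (1-based
#' \code{genomic_pos}).
#'
#' @param variant_id unique variant identifier.
#' @param gene gene symbol.
#' @param allele \code{"WT"} or \code{"MUT"}.
#' @param sequence mRNA-sense 5'-UTR sequence over \code{A,C,G,T}.
#' @param utr_offset 0-based offset of the mutated base (MUT rows), else NA.
#' @param ref,alt reference and alternate base (MUT rows), else NA.
#' @param chrom,genomic_pos optional genomic coordinates of the mutation
#'   (1-based position as conventionally printed, e.g. chr8:38965236).
#' @param paired_variant_id the WT partner of a MUT row (and vice versa).
#'
#' @return A \code{utr_library} data frame.
#' @export
utr_library <- function(variant_id, gene, allele, sequence,
                        utr_offset = NA_integer_, ref = NA_character_,
                        alt = NA_character_, chrom = NA_character_,
                        genomic_pos = NA_integer_,
                        paired_variant_id = NA_character_) {
  lib <- data.frame(
    variant_id = as.character(variant_id),
    gene = as.character(gene),
    allele = as.character(allele),
    sequence = toupper(as.character(sequence)),
    utr_offset = as.integer(utr_offset),
    ref = as.character(ref),
    alt = as.character(alt),
    chrom = as.character(chrom),
    genomic_pos = as.integer(genomic_pos),
    paired_variant_id = as.character(paired_variant_id),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("utr_library", "data.frame")
  validate_library(lib)
  lib
}

#' Validate the structural rules of a reporter library
#'
#' Checks that sequences are nonempty DNA, variant ids are unique, alleles are
#' WT/MUT, WT rows carry no mutation record, and that every MUT row with a SNV
#' record differs from its paired WT at exactly \code{utr_offset}, where the WT
#' holds \code{ref} and the mutant holds \code{alt}.
#'
#' @param lib a \code{utr_library} data frame.
#' @return \code{lib}, invisibly, or an error describing the violation.
#' @export
validate_library <- function(lib) {
  stopifnot(is.data.frame(lib))
  if (anyDuplicated(lib$variant_id))
    stop("variant_id values must be unique")
  if (!all(lib$allele %in% c("WT", "MUT")))
    stop("allele must be 'WT' or 'MUT'")
  if (any(nchar(lib$sequence) == 0) || !is_dna(lib$sequence))
    stop("sequences must be nonempty strings over {A,C,G,T}")
  wt_bad <- lib$allele == "WT" & !is.na(lib$utr_offset)
  if (any(wt_bad))
    stop("WT variants must not carry a mutation record: ",
         paste(lib$variant_id[wt_bad], collapse = ", "))
  muts <- lib[lib$allele == "MUT" & !is.na(lib$utr_offset), , drop = FALSE]
  for (i in seq_len(nrow(muts))) {
    wt <- lib[match(muts$paired_variant_id[i], lib$variant_id), ]
    if (is.na(wt$variant_id[1]))
      stop("MUT variant ", muts$variant_id[i], " has no paired WT")
    expect <- apply_mutation(wt$sequence, muts$utr_offset[i],
                             muts$ref[i], muts$alt[i])
    if (!identical(expect, muts$sequence[i]))
      stop("MUT variant ", muts$variant_id[i],
           " does not equal its WT with the recorded substitution applied")
  }
  invisible(lib)
}

#' Apply a single-nucleotide substitution to a UTR sequence
#'
#' @param wt_seq DNA string.
#' @param utr_offset 0-based position of the substitution.
#' @param ref expected reference base at \code{utr_offset}.
#' @param alt replacement base.
#'
#' @return The mutated sequence; same length as \code{wt_seq}.
#'
#' @examples
#' apply_mutation("CACGCG", 4, "C", "T")  # creates the E-box CACGTG
#' @export
apply_mutation <- function(wt_seq, utr_offset, ref, alt) {
  wt_seq <- toupper(wt_seq)
  if (utr_offset < 0 || utr_offset >= nchar(wt_seq))
    stop("utr_offset ", utr_offset, " out of range for a ",
         nchar(wt_seq), "-nt sequence")
  if (ref == alt) stop("ref and alt must differ")
  at <- substr(wt_seq, utr_offset + 1, utr_offset + 1)
  if (at != ref)
    stop("reference mismatch at offset ", utr_offset, ": sequence has ", at,
         ", mutation table says ", ref)
  paste0(substr(wt_seq, 1, utr_offset), alt,
         substr(wt_seq, utr_offset + 2, nchar(wt_seq)))
}

#' Validate a barcode against its design mode
#'
#' \code{FIXED8} barcodes are any 8-mer over \code{A,C,G,T}. \code{WS30}
#' barcodes are 30-mers of 15 W/S dinucleotide repeats: odd positions
#' (1, 3, 5, ...) are W = A/T and even positions are S = G/C.
#'
#' @param seq barcode sequence.
#' @param mode \code{"FIXED8"} or \code{"WS30"}.
#' @return \code{TRUE} or \code{FALSE} (pure predicate, vectorized over
#'   \code{seq}).
#' @export
validate_barcode <- function(seq, mode = c("WS30", "FIXED8")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  if (mode == "FIXED8") {
    return(nchar(seq) == 8L & grepl("^[ACGT]{8}$", seq))
  }
  nchar(seq) == 30L & grepl("^([AT][GC]){15}$", seq)
}

#' The constant backbone fixture of the reporter plasmid
#'
#' Encapsulates the constant sequence context of every construct: the 202-nt
#' XbaI spacer fragment carrying the EcoRI site (GAATTC) that occupies the
#' barcode locus in unbarcoded plasmids, the two 36-nt Gibson homology arms
#' that flank every synthesized UTR, and the four 20-nt constant anchors used
#' to locate the UTR and the barcode inside long reads. The anchors are not
#' dictated by the plasmid itself, so they are configurable; the defaults are
#' mutually distinct and absent from the spacer fragment.
#'
#' @param utr_anchor_left,utr_anchor_right 20-nt constants flanking the UTR.
#' @param bc_anchor_left,bc_anchor_right 20-nt constants flanking the barcode.
#' @return A list of class \code{"backbone_fixture"}.
#' @export
backbone_fixture <- function(utr_anchor_left = "ACGTGCTTGACCTGGATCCA",
                             utr_anchor_right = "TGGTCAAGCTGACCGGTACT",
                             bc_anchor_left = "CCATGGTACGTCAGCTTGAC",
                             bc_anchor_right = "GATCCTGAGCTAGCTAGGTC") {
  insert <- paste0(
    "AAGTACCGAAAGGTCTTACCGGAAAACTCGACGCAAGAAAAATCAGAGAGATCCTCATAAAGGCC",
    "AAGAAGGGCGGAAAGATCGCCGTGTAATTCTAGAGAATTCTCATGTAATTAGTTATGTCACGCAG",
    "ATCGGAAGAGCGTCGGGGCGGCCGGCCGCTTCGAGCAGACATGATAAGATACATTGATGAGTTTG",
    "GACAAAC")
  anchors <- c(utr_anchor_left, utr_anchor_right,
               bc_anchor_left, bc_anchor_right)
  if (any(nchar(anchors) != 20L) || !is_dna(anchors))
    stop("all four anchors must be 20-nt DNA strings")
  if (anyDuplicated(anchors))
    stop("the four anchors must be mutually distinct")
  if (any(vapply(anchors, function(a) grepl(a, insert, fixed = TRUE), TRUE)))
    stop("anchors must be absent from the backbone spacer fragment")
  structure(list(
    insert_seq = insert,
    arm5 = "GAGGAGGCTTTTTTGGAGGCCTAGGCTTTTGCAAAA",
    arm3 = "CATGGAAGACGCCAAAAACATAAAGAAAGGCCCGGC",
    utr_anchor_left = utr_anchor_left,
    utr_anchor_right = utr_anchor_right,
    bc_anchor_left = bc_anchor_left,
    bc_anchor_right = bc_anchor_right
  ), class = "backbone_fixture")
}

#' Assemble an in-silico reporter construct
#'
#' Builds the plasmid sequence read by long-read sequencing: the UTR sits
#' between its homology arms and constant anchors, and the barcode locus holds
#' either the barcode (between its two anchors) or, for an unbarcoded
#' construct, the EcoRI-containing segment of the backbone spacer, so that
#' GAATTC remains at the barcode locus exactly when no barcode was inserted.
#'
#' @param utr_seq the UTR sequence of the variant.
#' @param barcode barcode sequence, or \code{NULL} for an unbarcoded plasmid.
#' @param backbone a \code{\link{backbone_fixture}}.
#' @param barcode_mode barcode design used to validate \code{barcode}.
#' @return The plasmid sequence (character scalar).
#' @export
assemble_construct <- function(utr_seq, barcode, backbone = backbone_fixture(),
                               barcode_mode = c("WS30", "FIXED8")) {
  barcode_mode <- match.arg(barcode_mode)
  utr_seq <- toupper(utr_seq)
  if (!is_dna(utr_seq)) stop("utr_seq must be DNA over {A,C,G,T}")
  if (is.null(barcode)) {
    # retain the EcoRI-bearing stretch of the spacer at the barcode locus
    at <- regexpr("GAATTC", backbone$insert_seq, fixed = TRUE)
    locus <- substr(backbone$insert_seq, max(1L, at - 12L), at + 17L)
  } else {
    barcode <- toupper(barcode)
    if (!validate_barcode(barcode, barcode_mode))
      stop("invalid ", barcode_mode, " barcode: ", barcode)
    locus <- barcode
  }
  paste0(backbone$arm5,
         backbone$utr_anchor_left, utr_seq, backbone$utr_anchor_right,
         backbone$arm3,
         "TTCGAAGTATTCCGCGTACG",  # stand-in for the reporter CDS spacer
         backbone$bc_anchor_left, locus, backbone$bc_anchor_right,
         "CTAGAGTCGGGGCGGCCGGC")
}
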