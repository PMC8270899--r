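#' Read and write the reporter library as FASTA
#'
#' The library travels as FASTA with structured headers of the form
#' \preformatted{>variant_id|gene=G|allele=WT
#' >variant_id|gene=G|allele=MUT|mut=chr1:1234:C:T|offset=17|pair=G_WT}
#' \code{mut} holds \code{chrom:pos(1-based):ref:alt}; \code{offset} is the
#' 0-based UTR offset of the substitution; \code{pair} links MUT and WT rows.
#'
#' @param path file path.
#' @param lib a \code{\link{utr_library}} data frame.
#' @return \code{read_library_fasta} returns a validated \code{utr_library};
#'   \code{write_library_fasta} returns \code{path} invisibly.
#' @export
read_library_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  parse_kv <- function(p) {
    kv <- p[-1]
    eq <- regexpr("=", kv, fixed = TRUE)
    if (any(eq < 0)) stop("malformed library header field: ",
                          paste(kv[eq < 0], collapse = ", "))
    setNames(substring(kv, eq + 1L), substring(kv, 1L, eq - 1L))
  }
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    kv <- parse_kv(p)
    if (!all(c("gene", "allele") %in% names(kv)))
      stop("library header missing gene= or allele=: ", headers[i])
    mut <- rep(NA_character_, 4)
    if ("mut" %in% names(kv)) {
      mut <- strsplit(kv[["mut"]], ":", fixed = TRUE)[[1]]
      if (length(mut) != 4) stop("malformed mut= field: ", kv[["mut"]])
      if (mut[1] == ".") mut[1] <- NA_character_
      if (mut[2] %in% c("0", ".")) mut[2] <- NA_character_
    }
    data.frame(
      variant_id = p[1], gene = kv[["gene"]], allele = kv[["allele"]],
      sequence = as.character(seqs[[i]]),
      utr_offset = if ("offset" %in% names(kv))
        as.integer(kv[["offset"]]) else NA_integer_,
      ref = mut[3], alt = mut[4], chrom = mut[1],
      genomic_pos = as.integer(mut[2]),
      paired_variant_id = if ("pair" %in% names(kv))
        kv[["pair"]] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  lib <- do.call(rbind, rows)
  class(lib) <- c("utr_library", "data.frame")
  validate_library(lib)
  lib
}

#' @rdname read_library_fasta
#' @export
write_library_fasta <- function(lib, path) {
  validate_library(lib)
  hdr <- paste0(lib$variant_id, "|gene=", lib$gene, "|allele=", lib$allele)
  has_mut <- !is.na(lib$utr_offset)
  hdr[has_mut] <- paste0(
    hdr[has_mut],
    "|mut=", ifelse(is.na(lib$chrom[has_mut]), ".", lib$chrom[has_mut]),
    ":", ifelse(is.na(lib$genomic_pos[has_mut]), 0, lib$genomic_pos[has_mut]),
    ":", lib$ref[has_mut], ":", lib$alt[has_mut],
    "|offset=", lib$utr_offset[has_mut])
  has_pair <- !is.na(lib$paired_variant_id)
  hdr[has_pair] <- paste0(hdr[has_pair], "|pair=",
                          lib$paired_variant_id[has_pair])
  ss <- Biostrings::DNAStringSet(lib$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Thin wrapper around \code{Biostrings} readers; gzip is handled
#' transparently. Returns a named character vector (read id -> sequence).
#'
#' @param path FASTA/FASTQ path (optionally gzipped).
#' @param format \code{"auto"} infers from the extension.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTQ (constant Phred 40 qualities)
#'
#' @param reads named character vector (read id -> sequence).
#' @param path output path; \code{.gz} suffix compresses.
#' @return \code{path}, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  names(ss) <- names(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), ""))
  qss <- Biostrings::QualityScaledDNAStringSet(ss, q)
  Biostrings::writeQualityScaledXStringSet(qss, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read position-frequency matrices in HOMER motif format
#'
#' Each block starts with a header line \code{>consensus<TAB>name<TAB>score}
#' followed by one line per motif position holding four base probabilities in
#' A, C, G, T order. Rows whose probabilities do not sum to 1 within 0.01 are
#' renormalized with a warning.
#'
#' @param path a \code{.motif} file (may hold several blocks).
#' @param source whether the motifs describe DNA elements (scanned on both
#'   strands) or RNA elements (plus strand only); see \code{\link{scan_pwm}}.
#' @param pseudocount passed to \code{\link{pfm_to_pwm}}.
#' @return A named list of \code{\link{pfm_to_pwm}} motifs.
#' @export
read_homer_motifs <- function(path, source = c("DNA", "RNA"),
                              pseudocount = 1e-3) {
  source <- match.arg(source)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif blocks ('>' headers) in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(seq_along(body), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(body[j]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v) || any(v < 0))
        stop("malformed motif row ", j, " in block '", name, "' of ", path)
      v
    })
    pfm <- do.call(rbind, rows)
    colnames(pfm) <- DNA_BASES
    bad <- abs(rowSums(pfm) - 1) > 0.01
    if (any(bad)) {
      warning("motif '", name, "': ", sum(bad),
              " row(s) do not sum to 1; renormalizing")
    }
    pfm <- pfm / rowSums(pfm)
    motifs[[name]] <- pfm_to_pwm(pfm, name = name, source = source,
                                 pseudocount = pseudocount)
  }
  motifs
}

#' Write position-frequency matrices in HOMER motif format
#'
#' @param pfms named list of L x 4 probability matrices (A, C, G, T columns).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_homer_motifs <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pfms)) {
    pfm <- pfms[[name]]
    consensus <- paste(DNA_BASES[max.col(pfm)], collapse = "")
    writeLines(paste(paste0(">", consensus), name, "0", sep = "\t"), con)
    writeLines(apply(pfm, 1, function(r)
      paste(formatC(r, digits = 3, format = "f"), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read and write barcode dictionaries as TSV
#'
#' Columns: \code{barcode, variant_id, status, gene, edit_distance, n_reads,
#' consensus_len}. Only rows with status \code{EXACT} carry a variant_id
#' usable for quantification.
#'
#' @param dict a dictionary data frame from \code{\link{build_dictionary}}.
#' @param path file path.
#' @return \code{read_dictionary_tsv} returns the dictionary data frame.
#' @export
write_dictionary_tsv <- function(dict, path) {
  write.table(dict, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary_tsv
#' @export
read_dictionary_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
             colClasses = c(barcode = "character"))
}
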