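#' Trinucleotide context of a UTR position
#'
#' Interior positions yield the 3-mer centered on the position; the first and
#' last position of a sequence yield edge forms with a \code{"."} in place of
#' the absent neighbor (e.g. \code{".AC"}, \code{"GT."}). Together with the
#' three possible substitutions of the middle base this scheme defines 288
#' mutation classes: 64 full trinucleotides plus 32 edge contexts, times 3.
#'
#' @param utr_seq the UTR sequence.
#' @param offset 0-based position.
#' @return Context string of length 3.
#' @export
trinucleotide_context <- function(utr_seq, offset) {
  utr_seq <- toupper(utr_seq)
  n <- nchar(utr_seq)
  if (offset < 0 || offset >= n)
    stop("offset ", offset, " out of range for a ", n, "-nt sequence")
  p <- if (offset == 0) "." else substr(utr_seq, offset, offset)
  m <- substr(utr_seq, offset + 1, offset + 1)
  s <- if (offset == n - 1) "." else substr(utr_seq, offset + 2, offset + 2)
  paste0(p, m, s)
}

#' Enumerate all 288 context-preserving mutation classes
#'
#' @return Character vector \code{"<context>><alt>"}, e.g. \code{"ACG>T"},
#'   \code{".AC>G"}; length 288.
#' @export
enumerate_mutation_classes <- function() {
  ctx <- c(
    as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                    DNA_BASES, paste0)),                       # 64 interior
    as.vector(outer(paste0(".", DNA_BASES), DNA_BASES, paste0)),  # 16 no-5'
    as.vector(outer(DNA_BASES, paste0(DNA_BASES, "."),
                    function(a, b) paste0(a, b))))                # 16 no-3'
  classes <- unlist(lapply(ctx, function(c3) {
    mid <- substr(c3, 2, 2)
    paste0(c3, ">", setdiff(DNA_BASES, mid))
  }))
  sort(classes)
}

#' Index every UTR-ome position by its trinucleotide context
#'
#' @param utrome named character vector of UTR sequences (one per gene).
#' @return List with \code{positions} (data frame \code{utr_id, pos, ref,
#'   context}), \code{buckets} (context -> row indices into
#'   \code{positions}) and \code{n_excluded} (positions with non-ACGT base
#'   in their context, which are left out of the index).
#' @export
build_context_index <- function(utrome) {
  if (length(utrome) == 0) stop("empty UTR-ome")
  if (is.null(names(utrome)) || anyDuplicated(names(utrome)))
    stop("utrome must be a uniquely named character vector")
  rows <- lapply(names(utrome), function(id) {
    chars <- strsplit(toupper(utrome[[id]]), "")[[1]]
    n <- length(chars)
    prev <- c(".", chars[-n])
    nxt <- c(chars[-1], ".")
    data.frame(utr_id = id, pos = seq_len(n) - 1L, ref = chars,
               context = paste0(prev, chars, nxt), stringsAsFactors = FALSE)
  })
  positions <- do.call(rbind, rows)
  valid <- grepl("^[ACGT.][ACGT][ACGT.]$", positions$context)
  n_excluded <- sum(!valid)
  positions <- positions[valid, , drop = FALSE]
  rownames(positions) <- NULL
  list(positions = positions,
       buckets = split(seq_len(nrow(positions)), positions$context),
       n_excluded = n_excluded)
}

# annotate a mutation table with context and class; checks ref bases
.classify_mutations <- function(mutations, utrome) {
  stopifnot(all(c("utr_id", "utr_offset", "alt") %in% names(mutations)))
  if (!all(mutations$utr_id %in% names(utrome)))
    stop("mutations refer to UTRs absent from the UTR-ome")
  mutations$context <- mapply(function(id, off)
    trinucleotide_context(utrome[[id]], off),
    mutations$utr_id, mutations$utr_offset, USE.NAMES = FALSE)
  mutations$ref <- substr(mutations$context, 2, 2)
  if (any(mutations$ref == mutations$alt))
    stop("alt base equals the reference base for some mutations")
  mutations$class <- paste0(mutations$context, ">", mutations$alt)
  mutations
}

# one context-preserving random placement of the observed mutation set;
# returns row indices into index$positions plus the alt carried by each
.permute_once <- function(by_context, index) {
  picks <- lapply(names(by_context), function(ctx) {
    alts <- by_context[[ctx]]
    bucket <- index$buckets[[ctx]]
    if (is.null(bucket))
      stop("no UTR-ome position carries context ", ctx)
    k <- length(alts)
    idx <- if (length(bucket) >= k) {
      bucket[sample.int(length(bucket), k)]
    } else {
      warning("context bucket ", ctx, " smaller than its mutation count; ",
              "sampling with replacement")
      bucket[sample.int(length(bucket), k, replace = TRUE)]
    }
    data.frame(row = idx, alt = alts, stringsAsFactors = FALSE)
  })
  do.call(rbind, picks)
}

#' Context-preserving permutations of an observed mutation set
#'
#' Each permuted set preserves the observed counts of every mutation class
#' exactly: positions are drawn uniformly without replacement from the
#' UTR-ome positions sharing each mutation's trinucleotide context (with
#' replacement, plus a warning, when a bucket is smaller than its class
#' count), and the alternate base travels with its class.
#'
#' @param mutations data frame with \code{utr_id}, \code{utr_offset} (0-based)
#'   and \code{alt}.
#' @param utrome named character vector of UTR sequences.
#' @param n_perm number of permuted sets.
#' @param index optional precomputed \code{\link{build_context_index}}.
#' @return List of \code{n_perm} data frames \code{(utr_id, utr_offset, ref,
#'   alt, class)}.
#' @export
permute_mutations <- function(mutations, utrome, n_perm = 10000L,
                              index = build_context_index(utrome)) {
  mutations <- .classify_mutations(mutations, utrome)
  by_context <- split(mutations$alt, mutations$context)
  lapply(seq_len(n_perm), function(b) {
    pk <- .permute_once(by_context, index)
    pos <- index$positions[pk$row, , drop = FALSE]
    data.frame(utr_id = pos$utr_id, utr_offset = pos$pos, ref = pos$ref,
               alt = pk$alt, class = paste0(pos$context, ">", pk$alt),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Monte Carlo p-values from a permutation null
#'
#' Add-one estimators, never zero:
#' \code{p_enrich = (1 + #\{perm >= observed\}) / (1 + N)} and the analogous
#' lower tail for depletion.
#'
#' @param observed_count observed impact count.
#' @param perm_counts integer vector of permuted impact counts.
#' @return \code{list(p_enrich, p_deplete)}.
#' @export
monte_carlo_p <- function(observed_count, perm_counts) {
  if (length(perm_counts) == 0) stop("perm_counts must be nonempty")
  n <- length(perm_counts)
  list(p_enrich = (1 + sum(perm_counts >= observed_count)) / (1 + n),
       p_deplete = (1 + sum(perm_counts <= observed_count)) / (1 + n))
}

#' Fraction of recurrently mutated genes with tightly clustered mutations
#'
#' Among genes mutated in two or more patients (or carrying two or more
#' mutations when no patient labels are given), the fraction whose minimum
#' pairwise absolute genomic distance is strictly less than \code{window}.
#'
#' @param mutations data frame with \code{gene}, \code{genomic_pos}
#'   (1-based) and optionally \code{patient_id}.
#' @param window distance threshold in bp (default 50; strict inequality).
#' @return Fraction in [0, 1].
#' @export
recurrent_distance_fraction <- function(mutations, window = 50L) {
  stopifnot(all(c("gene", "genomic_pos") %in% names(mutations)))
  by_gene <- split(mutations, mutations$gene)
  recurrent <- Filter(function(g) {
    if ("patient_id" %in% names(g)) length(unique(g$patient_id)) >= 2
    else nrow(g) >= 2
  }, by_gene)
  recurrent <- Filter(function(g) nrow(g) >= 2, recurrent)
  if (length(recurrent) == 0)
    stop("no recurrently mutated gene in the input")
  close_by <- vapply(recurrent, function(g) {
    min(dist(g$genomic_pos)) < window
  }, TRUE)
  mean(close_by)
}
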