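#' Precompute per-UTR scanner state for fast impact evaluation
#'
#' Permutation enrichment evaluates hundreds of thousands of candidate
#' mutations, so the WT side of every comparison is computed once per UTR:
#' integer-encoded sequence, all PWM window scores on both strands, the G4
#' hit set and the 5'-TOP flag. Single-nucleotide impact calls then only
#' rescore the windows overlapping the mutated base (a one-weight delta per
#' window), which is exactly equivalent to a full rescan because windows not
#' overlapping the substitution are unchanged.
#'
#' @param utrome named character vector of UTR sequences.
#' @param scanners a \code{\link{scanner_set}}.
#' @return A list of class \code{"utrome_prep"}.
#' @export
prepare_utrome <- function(utrome, scanners) {
  pwm_entries <- c(
    lapply(names(scanners$dna_pwms), function(nm) {
      m <- scanners$dna_pwms[[nm]]
      list(class = paste0("DNA:", nm), w = m$weights,
           w_rc = .revcomp_weights(m$weights),
           cutoff = m$cutoff_frac * m$max_score, L = nrow(m$weights))
    }),
    lapply(names(scanners$rna_pwms), function(nm) {
      m <- scanners$rna_pwms[[nm]]
      list(class = paste0("RNA:", nm), w = m$weights, w_rc = NULL,
           cutoff = m$cutoff_frac * m$max_score, L = nrow(m$weights))
    }))
  if (!is.null(scanners$prte_pwm)) {
    m <- scanners$prte_pwm
    pwm_entries <- c(pwm_entries, list(list(
      class = "PRTE", w = m$weights, w_rc = NULL,
      cutoff = m$cutoff_frac * m$max_score, L = nrow(m$weights),
      prte = TRUE)))
  }
  per_utr <- lapply(names(utrome), function(id) {
    seq <- toupper(utrome[[id]])
    si <- .seq_int(seq)
    scores <- lapply(pwm_entries, function(e) {
      list(plus = .window_scores(si, e$w),
           minus = if (!is.null(e$w_rc)) .window_scores(si, e$w_rc))
    })
    list(seq = seq, n = nchar(seq), si = si, scores = scores,
         g4 = find_g4(seq), top5 = nrow(find_5top(seq)) > 0)
  })
  names(per_utr) <- names(utrome)
  structure(list(utrs = per_utr, pwm_entries = pwm_entries,
                 scanners = scanners,
                 classes = scanner_classes(scanners)),
            class = "utrome_prep")
}

# does the substitution (pos0, alt) change any PWM hit overlapping it?
.pwm_impacted <- function(entry, sc, si, pos0, alt_i) {
  L <- entry$L
  n <- length(si)
  lo <- max(0L, pos0 - L + 1L)
  hi <- min(pos0, n - L)
  if (hi < lo) return(FALSE)
  win <- lo:hi                      # 0-based window starts overlapping pos0
  k <- pos0 - win + 1L              # 1-based motif position of the mutation
  ref_i <- si[pos0 + 1L]
  d_plus <- entry$w[cbind(k, alt_i)] - entry$w[cbind(k, ref_i)]
  wt <- sc$plus[win + 1L] >= entry$cutoff
  mut <- sc$plus[win + 1L] + d_plus >= entry$cutoff
  if (isTRUE(entry$prte)) {
    # hard constraints are evaluated per sequence: start > 0 and T at
    # window position 6 (the mutation may be that very base)
    ok_start <- win > 0L
    base6 <- si[win + 6L]
    base6_mut <- ifelse(win + 5L == pos0, alt_i, base6)
    wt <- wt & ok_start & !is.na(base6) & base6 == 4L
    mut <- mut & ok_start & !is.na(base6_mut) & base6_mut == 4L
  }
  wt[is.na(wt)] <- FALSE; mut[is.na(mut)] <- FALSE
  if (any(wt != mut)) return(TRUE)
  if (!is.null(sc$minus)) {
    d_minus <- entry$w_rc[cbind(k, alt_i)] - entry$w_rc[cbind(k, ref_i)]
    wt <- sc$minus[win + 1L] >= entry$cutoff
    mut <- sc$minus[win + 1L] + d_minus >= entry$cutoff
    wt[is.na(wt)] <- FALSE; mut[is.na(mut)] <- FALSE
    if (any(wt != mut)) return(TRUE)
  }
  FALSE
}

# logical vector over prep$classes: is each class impacted by (utr, pos, alt)?
.impact_flags <- function(prep, utr_id, pos0, alt) {
  u <- prep$utrs[[utr_id]]
  sc <- prep$scanners
  alt_i <- match(alt, DNA_BASES)
  flags <- setNames(logical(length(prep$classes)), prep$classes)
  for (e in seq_along(prep$pwm_entries)) {
    entry <- prep$pwm_entries[[e]]
    flags[entry$class] <- .pwm_impacted(entry, u$scores[[e]], u$si,
                                        pos0, alt_i)
  }
  mut_seq <- NULL
  get_mut <- function() {
    if (is.null(mut_seq))
      mut_seq <<- paste0(substr(u$seq, 1, pos0), alt,
                         substr(u$seq, pos0 + 2, u$n))
    mut_seq
  }
  if (sc$uaug || (sc$uorf && is.null(sc$uorf_catalog))) {
    cand <- max(0L, pos0 - 2L):pos0
    cand <- cand[cand + 3L <= u$n]
    wt_atg <- substring(u$seq, cand + 1L, cand + 3L) == "ATG"
    mut_atg <- substring(get_mut(), cand + 1L, cand + 3L) == "ATG"
    if (sc$uaug) flags["UAUG"] <- any(wt_atg != mut_atg)
    if (sc$uorf && is.null(sc$uorf_catalog)) {
      # the stop-codon search region of an ATG overlapping the mutation
      # lies strictly downstream of it, so stop status is shared
      stop_ok <- vapply(cand, function(s) {
        if (s + 6L > u$n) return(FALSE)
        cs <- seq.int(s + 3L, u$n - 3L, by = 3L)
        any(substring(u$seq, cs + 1L, cs + 3L) %in% c("TAA", "TAG", "TGA"))
      }, TRUE)
      flags["UORF"] <- any((wt_atg & stop_ok) != (mut_atg & stop_ok))
    }
  }
  if (sc$uorf && !is.null(sc$uorf_catalog)) {
    starts <- sc$uorf_catalog[[utr_id]] %||% integer()
    flags["UORF"] <- any(pos0 >= starts & pos0 < starts + 3L)
  }
  if (sc$g4) {
    wt_g4 <- .overlapping(u$g4, pos0)
    mut_g4 <- .overlapping(find_g4(get_mut()), pos0)
    flags["G4"] <- !setequal(.hit_keys(wt_g4), .hit_keys(mut_g4))
  }
  if (sc$top5) {
    flags["TOP5"] <- pos0 < 10L &&
      (u$top5 || nrow(find_5top(get_mut())) > 0)
  }
  flags
}

#' Count mutations impacting each element class
#'
#' A mutation counts toward a class when its impact verdict for that class is
#' not \code{NONE} (it creates a new element or disrupts an existing one); a
#' single mutation may count toward several classes but at most once per
#' class.
#'
#' @param mutations data frame with \code{utr_id}, \code{utr_offset},
#'   \code{alt}.
#' @param prep a \code{\link{prepare_utrome}} object (or a named character
#'   vector, prepared on the fly with \code{scanners}).
#' @param scanners required when \code{prep} is a plain UTR-ome.
#' @param collapse_pwm collapse individual PWM classes into \code{DNA_PWM}
#'   and \code{RNA_PWM} database-level classes.
#' @return Named integer vector of per-class impact counts.
#' @export
count_impacts <- function(mutations, prep, scanners = NULL,
                          collapse_pwm = TRUE) {
  if (!inherits(prep, "utrome_prep")) {
    if (is.null(scanners)) stop("scanners required to prepare the UTR-ome")
    prep <- prepare_utrome(prep, scanners)
  }
  grp <- .class_groups(prep$classes, collapse_pwm)
  out_classes <- unique(grp)
  counts <- setNames(integer(length(out_classes)), out_classes)
  for (i in seq_len(nrow(mutations))) {
    fl <- .impact_flags(prep, mutations$utr_id[i], mutations$utr_offset[i],
                        mutations$alt[i])
    hit <- unique(grp[fl])
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# map scanner class labels to reported (possibly database-level) classes
.class_groups <- function(classes, collapse_pwm) {
  if (!collapse_pwm) return(setNames(classes, classes))
  out <- classes
  out[startsWith(out, "DNA:")] <- "DNA_PWM"
  out[startsWith(out, "RNA:")] <- "RNA_PWM"
  setNames(out, classes)
}

#' Element-class enrichment of observed mutations under a
#' context-preserving permutation null
#'
#' The observed per-class impact counts are compared to the counts obtained
#' by repeatedly placing the same mutation set (exactly preserving every
#' trinucleotide-context x substitution class) uniformly at random across
#' the UTR-ome. Monte Carlo p-values use the add-one estimator; classes with
#' \code{p < alpha} on the enrichment (depletion) tail are flagged.
#'
#' @param mutations data frame with \code{utr_id}, \code{utr_offset}
#'   (0-based) and \code{alt}; \code{ref} is derived from the UTR-ome and
#'   checked.
#' @param utrome named character vector of UTR sequences (WT).
#' @param scanners a \code{\link{scanner_set}}.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed for a reproducible permutation stream.
#' @param collapse_pwm report PWM databases as single classes.
#' @param alpha Monte Carlo significance cutoff (default 0.025 per tail).
#' @return Data frame \code{(element_class, observed, perm_mean, perm_sd,
#'   p_enrich, p_deplete, enriched, depleted)} with the permutation count
#'   matrix attached as attribute \code{"perm_counts"}.
#' @export
enrich_elements <- function(mutations, utrome, scanners, n_perm = 10000L,
                            seed = NULL, collapse_pwm = TRUE,
                            alpha = 0.025) {
  if (!is.null(seed)) set.seed(seed)
  index <- build_context_index(utrome)
  mutations <- .classify_mutations(mutations, utrome)
  prep <- prepare_utrome(utrome, scanners)
  observed <- count_impacts(mutations, prep, collapse_pwm = collapse_pwm)
  by_context <- split(mutations$alt, mutations$context)
  perm <- matrix(0L, nrow = n_perm, ncol = length(observed),
                 dimnames = list(NULL, names(observed)))
  for (b in seq_len(n_perm)) {
    pk <- .permute_once(by_context, index)
    pos <- index$positions[pk$row, , drop = FALSE]
    pset <- data.frame(utr_id = pos$utr_id, utr_offset = pos$pos,
                       alt = pk$alt, stringsAsFactors = FALSE)
    perm[b, ] <- count_impacts(pset, prep, collapse_pwm = collapse_pwm)
  }
  res <- data.frame(
    element_class = names(observed), observed = as.integer(observed),
    perm_mean = colMeans(perm), perm_sd = apply(perm, 2, sd),
    p_enrich = NA_real_, p_deplete = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(observed)) {
    mc <- monte_carlo_p(observed[j], perm[, j])
    res$p_enrich[j] <- mc$p_enrich
    res$p_deplete[j] <- mc$p_deplete
  }
  res$enriched <- res$p_enrich < alpha
  res$depleted <- res$p_deplete < alpha
  attr(res, "perm_counts") <- perm
  res
}
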