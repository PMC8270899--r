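# Independent brute-force oracles; each recomputes a quantity by the most
# direct enumeration available, with no code shared with the implementation.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# PWM scan by explicit per-window scoring on both strands
naive_scan_pwm <- function(seq, motif, cutoff_frac = motif$cutoff_frac) {
  L <- nrow(motif$weights)
  n <- nchar(seq)
  cutoff <- cutoff_frac * motif$max_score
  hits <- list()
  score_of <- function(win) {
    chars <- strsplit(win, "")[[1]]
    sum(vapply(seq_len(L), function(j) motif$weights[j, chars[j]], 0))
  }
  for (s in 0:(n - L)) {
    win <- substr(seq, s + 1, s + L)
    sc <- score_of(win)
    if (sc >= cutoff)
      hits[[length(hits) + 1]] <- data.frame(start = s, end = s + L,
                                             strand = "+", score = sc)
    if (motif$source == "DNA") {
      sc <- score_of(revcomp_chr(win))
      if (sc >= cutoff)
        hits[[length(hits) + 1]] <- data.frame(start = s, end = s + L,
                                               strand = "-", score = sc)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  do.call(rbind, hits)
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
naive_mwu <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(rk[idx]) - nx * (nx + 1) / 2)
  mid <- nx * ny / 2
  p <- if (u_obs > mid) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(U = u_obs, p = min(1, p))
}

# BH step-up from the defining formula
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(vapply(rank_i:m, function(j) p[ord[j]] * m / j, 0), 1)
  }
  q
}

# does a string fully match the G-quadruplex pattern?
full_g4_match <- function(x) grepl("^G{2,}([ACGT]{1,7}G{2,}){3}$", x,
                                   perl = TRUE)

# is there any substring of seq that fully matches the G4 pattern?
any_g4_window <- function(seq) {
  n <- nchar(seq)
  for (s in 1:n) for (e in s:n)
    if (e - s + 1 >= 11 && full_g4_match(substr(seq, s, e))) return(TRUE)
  FALSE
}

# a small sharp DNA PWM from a consensus string (1/0 frequencies)
consensus_pwm <- function(consensus, name = consensus, source = "DNA",
                          pseudocount = 1e-3) {
  chars <- strsplit(consensus, "")[[1]]
  pfm <- t(vapply(chars, function(b) as.numeric(BASES == b),
                  numeric(4)))
  colnames(pfm) <- BASES
  pfm_to_pwm(pfm, name = name, source = source, pseudocount = pseudocount)
}

# a tiny 3-gene WT/MUT library with short UTRs, built by hand
tiny_library <- function() {
  wt <- c(A = "CACGCGTTACGTAGGCTTAA",
          B = "TTGACCATGGACCGTTAGCA",
          C = "GGGCATTCAGACTTGGCAAT")
  off <- c(A = 4L, B = 9L, C = 11L)
  rows <- lapply(names(wt), function(g) {
    ref <- substr(wt[[g]], off[[g]] + 1, off[[g]] + 1)
    alt <- setdiff(BASES, ref)[1]
    utr_library(
      variant_id = paste0(g, c("_WT", "_MUT")), gene = g,
      allele = c("WT", "MUT"),
      sequence = c(wt[[g]], apply_mutation(wt[[g]], off[[g]], ref, alt)),
      utr_offset = c(NA, off[[g]]), ref = c(NA, ref), alt = c(NA, alt),
      paired_variant_id = paste0(g, c("_MUT", "_WT")))
  })
  lib <- do.call(rbind, rows)
  class(lib) <- c("utr_library", "data.frame")
  lib
}
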