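ebox <- consensus_pwm("CACGTG", "Ebox")

test_that("PFM to PWM conversion follows log2(f/0.25) with pseudocount", {
  uni <- matrix(0.25, nrow = 3, ncol = 4)
  pwm <- pfm_to_pwm(uni)
  expect_equal(unname(pwm$weights), matrix(0, 3, 4), tolerance = 1e-12)
  expect_equal(pwm$max_score, 0, tolerance = 1e-12)
  # a degenerate column tends to weight 2 as the pseudocount vanishes
  sharp <- matrix(c(1, 0, 0, 0), nrow = 1)
  expect_equal(unname(pfm_to_pwm(sharp, pseudocount = 1e-9)$weights[1, "A"]),
               2, tolerance = 1e-6)
  # max_score always equals the score of the argmax sequence
  set.seed(71)
  for (i in 1:10) {
    L <- sample(4:12, 1)
    pfm <- matrix(rexp(4 * L), ncol = 4)
    pfm <- pfm / rowSums(pfm)
    pwm <- pfm_to_pwm(pfm)
    argmax <- apply(pwm$weights, 1, max)
    expect_equal(pwm$max_score, sum(argmax))
  }
  expect_error(pfm_to_pwm(matrix(1, 2, 3)), "L x 4")
})

test_that("pseudocount continuity: clean-window scores converge", {
  s <- "CACGTG"
  scores <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(pc) {
    m <- consensus_pwm("CACGTG", pseudocount = pc)
    scan_pwm(s, m, cutoff_frac = 0)$score[1]
  }, 0)
  expect_true(all(diff(abs(scores - 12)) < 0))
  expect_equal(scores[4], 12, tolerance = 1e-6)
})

test_that("PWM scanning hits at 90% of maximum on the right strands", {
  h <- scan_pwm("CACGTG", ebox)
  plus <- h[h$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$start, 0L)
  expect_identical(plus$end, 6L)
  expect_equal(plus$score, ebox$max_score)
  # one mismatch against a sharp consensus falls below the 90% cutoff
  expect_identical(nrow(scan_pwm("CACGCG", ebox)), 0L)
  # non-palindromic motif: minus-strand hit on the reverse complement
  tata <- consensus_pwm("TATAAA", "TATAAA")
  h <- scan_pwm("TTTATA", tata)
  expect_identical(h$strand, "-")
  expect_identical(c(h$start, h$end), c(0L, 6L))
  tata_rna <- consensus_pwm("TATAAA", "TATAAA", source = "RNA")
  expect_identical(nrow(scan_pwm("TTTATA", tata_rna)), 0L)
})

test_that("scanners agree with brute-force window enumeration", {
  set.seed(73)
  motifs <- list(consensus_pwm("CACGTG"), consensus_pwm("TATAAA"),
                 consensus_pwm("AGGACA", source = "RNA"))
  soft <- pfm_to_pwm(matrix(c(.7, .1, .1, .1, .1, .7, .1, .1,
                              .25, .25, .25, .25, .1, .1, .4, .4),
                            ncol = 4, byrow = TRUE), "soft")
  motifs <- c(motifs, list(soft))
  for (i in 1:15) {
    seq <- random_dna(sample(20:200, 1))
    # seed motif-like content so hits actually occur
    seq <- paste0(seq, "CACGTGTTTATAAAAGGACA")
    for (m in motifs) {
      got <- scan_pwm(seq, m)
      want <- naive_scan_pwm(seq, m)
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("DNA strand symmetry: hits mirror on the reverse complement", {
  set.seed(79)
  tata <- consensus_pwm("TATAAA")
  for (i in 1:10) {
    seq <- paste0(random_dna(60), "TATAAA", random_dna(10))
    fwd <- scan_pwm(seq, tata)
    rev <- scan_pwm(revcomp_chr(seq), tata)
    n <- nchar(seq)
    mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                           strand = ifelse(rev$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    fwd_cmp <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand")]
    expect_equal(fwd_cmp$start, mirrored$start)
    expect_equal(fwd_cmp$strand, mirrored$strand)
  }
})

test_that("uAUG detection reports frames and read-through extensions", {
  h <- find_uaug("AAATGAA")
  expect_identical(c(h$start, h$end), c(2L, 5L))
  # C -> T gain of a uAUG
  expect_identical(nrow(find_uaug("AAACGAA")), 0L)
  expect_identical(nrow(find_uaug("AAATGAA")), 1L)
  # ATG 6 nt upstream of the CDS with no stop: in-frame N-terminal extension
  h <- find_uaug("ATGCCCAAA")                 # distance 9 from UTR end? no:
  # start 0, length 9, distance to CDS = 9, 9 %% 3 == 0 -> in frame
  expect_true(h$in_frame[1])
  expect_false(h$has_stop[1])
  expect_true(h$in_frame_extension[1])
  # an in-frame stop inside the UTR makes it a complete uORF instead
  h <- find_uaug("ATGTAAACC")
  expect_true(h$has_stop[1])
  expect_true(h$uorf[1])
  expect_false(h$in_frame_extension[1])
  # out-of-frame uAUG
  h <- find_uaug("AATGCCCC")                  # start 1, distance 7
  expect_false(h$in_frame[1])
})

test_that("G-quadruplex matching follows the four-run loop rule", {
  h <- find_g4("GGAGGAGGAGG")
  expect_identical(c(h$start, h$end), c(0L, 11L))
  expect_identical(nrow(find_g4("GGAGGAGG")), 0L)
  expect_identical(nrow(find_g4(paste0("GG", strrep("A", 8), "GGAGGAGG"))),
                   0L)
  # every reported hit is a genuine full match and hits never overlap
  set.seed(83)
  for (i in 1:40) {
    seq <- paste(sample(c("G", "G", "A", "C", "T"), sample(20:150, 1),
                        replace = TRUE), collapse = "")
    h <- find_g4(seq)
    if (nrow(h) == 0) {
      expect_false(any_g4_window(seq))
    } else {
      for (j in seq_len(nrow(h)))
        expect_true(full_g4_match(substr(seq, h$start[j] + 1, h$end[j])))
      if (nrow(h) > 1)
        expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
      # leftmost hit starts at the first matchable position
      firsts <- which(vapply(0:(nchar(seq) - 11), function(s) {
        any(vapply((s + 11):nchar(seq), function(e)
          full_g4_match(substr(seq, s + 1, e)), TRUE))
      }, TRUE)) - 1L
      expect_identical(h$start[1], firsts[1])
    }
  }
})

test_that("5'-TOP tracts start with C plus four or more pyrimidines", {
  h <- find_5top("CTTTCAGG")
  expect_identical(c(h$start, h$end), c(0L, 5L))
  expect_identical(nrow(find_5top("ACTTTT")), 0L)
  expect_identical(nrow(find_5top("CTTAGG")), 0L)    # only 2 pyrimidines
  expect_identical(find_5top("CTTTTTTAGG")$end, 7L)  # maximal extension
})

test_that("PRTE calls require the invariant uridine and internal start", {
  prte <- prte_fixture_pwm()
  seq <- paste0("A", "CTTTTTTTCC", strrep("A", 10))
  h <- find_prte(seq, prte)
  expect_true(nrow(h) >= 1)
  expect_true(all(h$start > 0))
  expect_true(all(substr(rep(seq, nrow(h)), h$start + 6, h$start + 6) == "T"))
  # the same window at offset 0 is rejected regardless of score
  seq0 <- paste0("CTTTTTTTCC", strrep("A", 11))
  h0 <- find_prte(seq0, prte)
  expect_false(any(h0$start == 0))
  # an A at window position 6 is rejected
  seqA <- paste0("A", "CTTTTATTCC", strrep("A", 10))
  h <- find_prte(seqA, prte)
  expect_false(any(substr(rep(seqA, nrow(h)), h$start + 6,
                          h$start + 6) != "T"))
})

test_that("mutation impact reproduces the worked create/disrupt cases", {
  # E-box creation: CACGCG -> CACGTG
  sc <- scanner_set(dna_pwms = list(Ebox = ebox))
  wt <- "TTACGCACGCGTTAGGCCTT"
  mut <- apply_mutation(wt, 9, "C", "T")
  calls <- mutation_impact(wt, mut, 9, sc)
  expect_identical(calls$verdict[calls$element_class == "DNA:Ebox"],
                   "CREATES_NEW")
  # ablation of an existing RNA-binding motif
  srsf <- consensus_pwm("AGGACA", "SRSF9like", source = "RNA")
  sc2 <- scanner_set(rna_pwms = list(SRSF9like = srsf))
  wt2 <- "TTTAGGACATTTTTTTTTTT"
  mut2 <- apply_mutation(wt2, 5, "G", "T")
  calls2 <- mutation_impact(wt2, mut2, 5, sc2)
  expect_identical(calls2$verdict[calls2$element_class == "RNA:SRSF9like"],
                   "DISRUPTS_EXISTING")
  # a C -> T mutation creating an in-frame upstream start codon
  wt3 <- "GGGACGGGGCCCAAACCCAAA"     # ACG at offsets 3..5
  mut3 <- apply_mutation(wt3, 4, "C", "T")
  calls3 <- mutation_impact(wt3, mut3, 4, scanner_set())
  expect_identical(calls3$verdict[calls3$element_class == "UAUG"],
                   "CREATES_NEW")
  expect_true(find_uaug(mut3)$in_frame[1])
  # far from everything: all NONE
  wt4 <- strrep("A", 30)
  mut4 <- apply_mutation(wt4, 15, "A", "C")
  calls4 <- mutation_impact(wt4, mut4, 15, scanner_set(
    dna_pwms = list(Ebox = ebox)))
  expect_true(all(calls4$verdict == "NONE"))
})

test_that("the 5'-TOP positional rule is a strict first-ten-bases window", {
  sc <- scanner_set(uaug = FALSE, uorf = FALSE, g4 = FALSE)
  top_utr <- paste0("CTTTTT", strrep("A", 20))
  for (off in c(9L, 10L)) {
    ref <- substr(top_utr, off + 1, off + 1)
    mut <- apply_mutation(top_utr, off, ref, "G")
    call <- mutation_impact(top_utr, mut, off, sc)
    v <- call$verdict[call$element_class == "TOP5"]
    if (off < 10) expect_identical(v, "DISRUPTS_EXISTING")
    else expect_identical(v, "NONE")
  }
  # a UTR without a 5'-TOP is untouched by the rule
  plain <- paste0("GTTTTT", strrep("A", 20))
  mut <- apply_mutation(plain, 3, "T", "A")
  call <- mutation_impact(plain, mut, 3, sc)
  expect_identical(call$verdict[call$element_class == "TOP5"], "NONE")
})

test_that("an external uORF catalog restricts uORF calls to start codons", {
  sc <- scanner_set(uaug = FALSE, g4 = FALSE, top5 = FALSE,
                    uorf_catalog = list(u1 = c(4L)))
  wt <- "AAAAATGCCCTAAGGG"
  for (off in c(5L, 8L)) {
    ref <- substr(wt, off + 1, off + 1)
    mut <- apply_mutation(wt, off, ref, setdiff(BASES, ref)[1])
    call <- mutation_impact(wt, mut, off, sc, seq_label = "u1")
    v <- call$verdict[call$element_class == "UORF"]
    if (off >= 4 && off < 7) expect_identical(v, "DISRUPTS_EXISTING")
    else expect_identical(v, "NONE")
  }
})

test_that("swapping WT and mutant swaps creates and disrupts", {
  set.seed(89)
  sc <- scanner_set(dna_pwms = list(Ebox = ebox),
                    rna_pwms = list(M = consensus_pwm("AGGACA", "M",
                                                      source = "RNA")),
                    top5 = FALSE)
  for (i in 1:30) {
    wt <- paste0(random_dna(20), sample(c("CACGTG", "AGGACA", "ATGTAA",
                                          "GGAGGAGGAGG", ""), 1),
                 random_dna(20))
    off <- sample(0:(nchar(wt) - 1), 1)
    ref <- substr(wt, off + 1, off + 1)
    mut <- apply_mutation(wt, off, ref, sample(setdiff(BASES, ref), 1))
    fwd <- mutation_impact(wt, mut, off, sc)
    bwd <- mutation_impact(mut, wt, off, sc)
    swap <- c(DISRUPTS_EXISTING = "CREATES_NEW",
              CREATES_NEW = "DISRUPTS_EXISTING", NONE = "NONE")
    for (cl in unique(fwd$element_class)) {
      a <- sort(unname(swap[fwd$verdict[fwd$element_class == cl]]))
      b <- sort(bwd$verdict[bwd$element_class == cl])
      expect_identical(a, b)
    }
  }
})

test_that("the HOMER reader parses fixtures and flags bad rows", {
  path <- system.file("extdata/motifs/ebox.motif", package = "utrmpra")
  m <- read_homer_motifs(path)
  expect_identical(length(m), 1L)
  expect_identical(nrow(m[[1]]$weights), 6L)
  # two-block files give two motifs; unnormalized rows warn and renormalize
  two <- tempfile(fileext = ".motif")
  writeLines(c(">AC\tmot1\t0", "0.5\t0.5\t0\t0", "1\t0\t0\t0",
               ">GT\tmot2\t0", "0\t0\t2\t2"), two)
  expect_warning(res <- read_homer_motifs(two), "renormaliz")
  expect_identical(names(res), c("mot1", "mot2"))
  expect_equal(unname(res$mot2$weights[1, "G"]),
               unname(res$mot2$weights[1, "T"]))
  writeLines(c(">AC\tbad\t0", "0.5\t0.5\t0"), two)
  expect_error(read_homer_motifs(two), "malformed")
  # write -> read round trip
  pfms <- list(m1 = matrix(c(.7, .1, .1, .1, .1, .1, .1, .7), ncol = 4,
                           byrow = TRUE))
  colnames(pfms$m1) <- BASES
  out <- tempfile(fileext = ".motif")
  write_homer_motifs(pfms, out)
  back <- read_homer_motifs(out)
  expect_equal(back$m1$weights, pfm_to_pwm(pfms$m1)$weights,
               tolerance = 1e-6)
})
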