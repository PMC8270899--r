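# utrmpra

Barcode-resolved analysis of massively parallel reporter assays (MPRAs)
that test **full-length 5'-UTR variants**.

Somatic single-nucleotide mutations in 5'-UTRs can rewire gene expression
twice over: at the DNA level, by creating or destroying transcription
factor binding sites, and at the RNA level, by altering translational
cis-elements (upstream AUGs and ORFs, pyrimidine-rich elements,
G-quadruplexes, 5'-TOP tracts, RNA-binding protein motifs). Testing such
mutations at scale requires reporter libraries in which each wild-type
(WT) or mutant (MUT) UTR is linked to many short barcodes, long reads to
learn which barcode belongs to which construct, and short reads to count
barcodes across DNA, total mRNA, polysome-bound and 80S-bound fractions.
`utrmpra` is the complete computational side of such an assay, for
bioinformaticians and genomicists running or reanalyzing barcoded UTR
reporter screens.

## What the package computes

- **Barcode–construct dictionary** from CCS-like long reads: constant
  20-nt anchors locate the UTR and barcode within each read; reads sharing
  a barcode are collapsed to a medoid-star, column-majority consensus;
  consensus sequences must match the expected library **exactly** to be
  quantified (most mutants sit one base from their WT), with non-matching
  consensus annotated to the nearest gene by edit distance.
- **Counts and normalization**: position-exact barcode extraction from
  read 2 with 4-nt flank checks; counts-per-million over matched reads
  (`CPM_i = c_i · 10^6 / Σc`); a 0.5-CPM minimum (inclusive) in *both*
  samples of any ratio.
- **Barcode-level statistics** per MUT/WT pair and measure
  (transcript = mRNA/DNA, TE = polysome/mRNA, polysome/80S): per-barcode,
  per-replicate log2 CPM ratios pooled into a two-sided Mann–Whitney U
  test, Benjamini–Hochberg FDR across pairs, significance at q < 0.1,
  fold change as the difference of group medians.
- **Element scanning**: PWMs converted as log2(f/0.25) with pseudocount,
  hits at ≥ 90% of the maximum score, DNA motifs on both strands and RNA
  motifs on the plus strand; rule-based uAUG/uORF (with frame and
  read-through annotation), G-quadruplex `G≥2(N1–7 G≥2)×3`, 5'-TOP, and
  PRTE scanners; per-mutation verdicts `CREATES_NEW` / `DISRUPTS_EXISTING`.
- **Permutation enrichment**: the observed mutation set is re-placed
  across the UTR-ome ~10,000 times preserving each mutation's
  trinucleotide context and substitution (288 classes = 96 contexts × 3
  alts); Monte Carlo p-values `p = (1 + #{perm ≥ obs}) / (1 + N)`,
  significance at p < 0.025 per tail; plus the recurrence statistic
  (fraction of recurrently mutated genes with mutations < 50 bp apart).
- **Simulator** for all of the above, with ground-truth dictionaries,
  planted motifs and injected transcript/TE effects.

## Worked example

```r
library(utrmpra)

# 1. a small library: 3 genes, WT + single-SNV mutant each
sim <- simulate_library(n_genes = 3, utr_length_range = c(100, 300), seed = 1)

# 2. long reads link five 8-bp barcodes to each construct
cc <- simulate_ccs(sim$library, barcodes_per_construct = 5,
                   reads_per_barcode = 20, barcode_mode = "FIXED8", seed = 1)
bd <- build_dictionary(cc$reads, sim$library)
table(bd$dictionary$status)
#> EXACT
#>    30

# 3. short-read counts: GENE001's mutant gets a 2-fold TE boost
eff <- data.frame(variant_id = sim$library$variant_id,
                  transcript_factor = 1, te_factor = 1)
eff$te_factor[eff$variant_id == "GENE001_MUT"] <- 2
cm <- simulate_counts(cc$truth, eff, depth = 1e6, replicates = 3, seed = 1)

# 4. barcode-level TE statistics per mutant/WT pair
obs <- ratio_observations(cm, bd$dictionary, measure = "TE")
res <- summarize_pairs(obs, sim$library, measure = "TE")
res[, c("pair_id", "n_wt", "n_mut", "U", "p", "q", "log2fc_median",
        "significant")]
#>                  pair_id n_wt n_mut   U            p            q log2fc_median
#> 1 GENE001_WT|GENE001_MUT   15    15 225 1.289345e-08 3.868035e-08   1.002419718
#> 2 GENE002_WT|GENE002_MUT   15    15 119 8.063338e-01 8.063338e-01   0.001216417
#> 3 GENE003_WT|GENE003_MUT   15    15 123 6.826738e-01 8.063338e-01   0.005228368
#>   significant
#> 1        TRUE
#> 2       FALSE
#> 3       FALSE

# 5. does a mutation create or destroy a regulatory element?
ebox <- read_homer_motifs(system.file("extdata/motifs/ebox.motif",
                                      package = "utrmpra"))[[1]]
sc <- scanner_set(dna_pwms = list(Ebox = ebox))
mutation_impact("TTCACGCGTT", "TTCACGTGTT", utr_offset = 6, sc)
#>   element_class     verdict
#> 1      DNA:Ebox CREATES_NEW
#> 2          UAUG        NONE
#> 3          UORF        NONE
#> 4            G4        NONE
#> 5          TOP5        NONE
```

Reading the output: all 30 simulated barcode–construct links are recovered
`EXACT` by the long-read stage; the injected 2-fold TE effect on GENE001 is
detected (median log2 fold change ≈ 1.0, i.e. 2-fold, at q ≈ 4e-8) with
each of the 15 barcode×replicate observations per group acting as an
independent reporter, while the two null genes stay non-significant; and
the C→T substitution that turns `CACGCG` into `CACGTG` is called as
creating a new E-box element.

A thin command-line interface over the same functions lives at
`inst/cli/utrmpra.R` (subcommands `simulate`, `link`, `count`, `test`,
`scan`, `enrich`). The methods vignette
(`vignettes/utr-mpra-methods.Rmd`) documents every model, parameter and
numerical choice.

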