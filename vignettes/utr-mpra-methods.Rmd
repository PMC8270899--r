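---
title: "Models and methods behind utrmpra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind utrmpra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrmpra)
```

`utrmpra` analyzes massively parallel reporter assays (MPRAs) in which
full-length 5'-UTR variants — wild-type (WT) and single-nucleotide mutant
(MUT) pairs — drive a reporter gene, and each plasmid carries a short
barcode downstream of the reporter CDS. Long reads establish which barcode
belongs to which UTR; short reads count barcodes in DNA, total mRNA,
polysome-bound and 80S-bound fractions; barcode-level statistics decide
whether a mutation changes transcript abundance or translation efficiency
(TE); and a permutation framework asks whether a cohort's mutations hit
cis-regulatory elements more often than chance allows. This vignette
explains each model, its assumptions, and the numerical choices the
implementation makes.

## The library model

A library is a data frame of `UTRVariant` rows (`utr_library()`), with WT
and MUT sequences linked by `paired_variant_id`. The structural contract
(`validate_library()`) is strict: a MUT sequence must equal its WT with
exactly the recorded substitution applied at the recorded 0-based offset.
UTR offsets are 0-based with half-open intervals throughout; genomic
positions are 1-based, as conventionally printed. Sequences are stored in
DNA alphabet; RNA elements are matched with U = T, one alphabet end to end.

Two barcode designs exist: free 8-mers (`FIXED8`, used in small
proof-of-concept pools) and 30-mers of fifteen W/S dinucleotide repeats
(`WS30`; odd positions A/T, even positions G/C), the design of the
full-scale library.

`backbone_fixture()` holds the constant context every construct shares: the
202-nt spacer fragment whose EcoRI site (GAATTC) occupies the barcode locus
until a barcode is inserted, the two 36-nt Gibson homology arms flanking
every synthesized UTR, and four 20-nt anchors used to locate the UTR and
barcode inside long reads. The anchor sequences are not identifiable from
the published construct, so they are configuration with fixed defaults
(mutually distinct, absent from the spacer); every function that touches
reads takes the fixture as an argument.

## Long-read dictionary construction

`build_dictionary()` composes four steps:

1. **Field extraction** (`extract_fields()`): the UTR is the substring
   between the UTR anchors, the barcode the substring between the barcode
   anchors. Reads missing an anchor are excluded (`ANCHOR_MISSING`), reads
   whose barcode locus still holds GAATTC are excluded (`NO_BARCODE`), and
   reads found intact on both strands are excluded as chimeras. Anchors are
   searched exactly first and then with up to `max_anchor_edit` (default 2)
   mismatches/indels; the default exists because at a 1% per-base read
   error, a 20-nt anchor is intact in only `0.99^20 = 82%` of reads, and
   requiring four exact anchors would discard most of an ordinary run. The
   reverse complement is searched before a read is given up.
2. **Grouping** (`group_by_barcode()`): exact string keys; barcodes one
   base apart are different barcodes. There is no fuzzy merging, because a
   mis-read barcode cannot be distinguished from a genuinely different one
   at this stage; mis-read barcodes form small spurious groups instead.
3. **Consensus** (`consensus_sequence()`): singleton groups pass through
   verbatim. Larger groups use a star alignment centered on the medoid (the
   read minimizing total edit distance to the rest, distance by
   `utils::adist`, alignment by `Biostrings::pairwiseAlignment`), followed
   by a per-column majority vote in which the gap is a fifth symbol.
   Tie-breaks are deterministic and order-free: the medoid prefers the
   lexicographically smallest sequence, a tied column resolves to the
   lexicographically smallest non-gap base, and a gap only wins a column on
   strict majority (it is then dropped). Unique sequences are sorted before
   any decision, so the consensus is a function of the read multiset.
4. **Annotation** (`annotate_consensus()`): exact string matching against
   the library assigns `EXACT` status — required because most mutants
   differ from their WT by one base, so any tolerance would collapse
   alleles. A consensus identical to a sequence shared by several variants
   is `AMBIGUOUS` and never quantified. Any other consensus is annotated to
   the nearest gene by global edit distance (`NEAREST_GENE`), ties going to
   the lexicographically first gene with a flag.

QC tallies (reads in, extracted, distinct barcodes, EXACT barcodes, barcode
support per variant) ride along in the returned object.

## Short-read quantification

Read 2 carries the barcode at a fixed offset from its 3' end, bracketed by
two constant 4-nt flanks. `extract_barcode()` is deliberately rigid: the
substring is taken at the configured position and kept only when both
flanks match exactly — a positional checksum against indels and mispriming.
There is no quality trimming and no mismatch rescue; the information lost
is small and the protection against misassignment is worth it. The offset
and flank sequences are run configuration (`shortread_config()`), defaults
consistent with the bundled backbone fixture.

Counting (`tally_barcodes()`) only credits barcodes cataloged `EXACT` in
the dictionary. CPM normalization divides by the sample's matched-read
total — not its raw read total — so per-sample CPM sums to 1e6 over counted
barcodes. A barcode enters a ratio only if it has at least 0.5 CPM
(inclusive) in **both** samples of that ratio; barcodes with a zero raw
count anywhere are always dropped so every retained log ratio is finite.

## Differential statistics

For each biological replicate, `ratio_observations()` computes per-barcode
`log2(numerator CPM) - log2(denominator CPM)` for one of three measures:
transcript level (total mRNA / DNA), TE (polysome / total mRNA) and the
polysome/80S ratio. Observations pool barcodes across replicates into one
test per MUT/WT pair — each barcode is an independent reporter of the same
construct, and pooling is what gives the assay its power; replicates are
not tested separately.

`mwu_test()` is a two-sided Mann-Whitney U test (`stats::wilcox.test`):
the exact null distribution when both groups have at most 20 tie-free
observations, otherwise the normal approximation with mid-ranks, tie
correction and continuity correction. Pairs with fewer than five
observations on a side are flagged `low_power` rather than suppressed.
`summarize_pairs()` adjusts p-values with Benjamini-Hochberg across all
pairs of one measure (measures are separate families) and calls
significance at q < 0.1. The fold change is the difference of group
medians of the log2 ratios — the median is robust to the occasional wild
barcode — with the mean difference also reported.

## Element scanners

**PWMs.** Position frequency matrices (HOMER `.motif` dialect,
`read_homer_motifs()`) become log2(f/0.25) weight matrices. A pseudocount
(default 1e-3) is added and each position renormalized before the log,
because the bare conversion sends zero frequencies to minus infinity; the
cutoff is computed on the same adjusted matrix. A window is a hit when its
score reaches 90% of the matrix's maximum. DNA motifs are scanned on both
strands (minus-strand hits reported in plus coordinates); RNA motifs only
on the plus strand, since mRNA is single-stranded. With the default
pseudocount, a single mismatch against a sharp consensus matrix falls well
below the 90% cutoff, which is what makes single-nucleotide create/disrupt
calls crisp.

**uAUG / uORF** (`find_uaug()`): every ATG in the UTR, annotated with its
frame relative to the main ORF (assumed to start `cds_gap` nt after the
UTR, default 0) and with whether an in-frame stop lies wholly inside the
UTR. ATG-with-stop is a complete upstream ORF; an in-frame ATG without one
is an N-terminal extension that reads through into the CDS. When an
external catalog of predicted uORF start codons is supplied, the uORF class
counts a mutation only if it lands inside a cataloged start codon.

**G-quadruplex** (`find_g4()`): four runs of at least two guanines
separated by loops of 1-7 nt, matched left-greedy and non-overlapping (the
overlap policy is a deliberate choice; overlapping parses of the same G-rich
tract are one element, not several).

**5'-TOP** (`find_5top()`): a cytosine at the very first base followed by
at least four pyrimidines, extended maximally. Its mutation rule is
positional: any substitution at offsets 0-9 of a TOP-bearing UTR counts as
mutating the TOP.

**PRTE** (`find_prte()`): a plus-strand PWM scan constrained to an
invariant T at window position 6 and a window start after the cap (offset
0 excluded, reading "position +1" as the transcription start base). The
published PRTE matrix is not redistributable, so the package bundles a
synthetic fixture matrix encoding the verbal definition
(`inst/extdata/motifs/prte_synthetic.motif`); PRTE results are
fixture-derived and labeled as such.

**Impact calls** (`mutation_impact()`): for each class, hits of WT and MUT
overlapping the mutated base are compared; a WT hit missing from MUT is
`DISRUPTS_EXISTING`, a MUT hit missing from WT is `CREATES_NEW`, and a
mutation may do both (both calls are emitted). Swapping WT and MUT swaps
the two verdicts for every class except the 5'-TOP positional rule, which
is direction-free when both alleles carry a TOP — the one documented
exception to impact antisymmetry.

## Permutation enrichment

The null model asks: if the cohort's mutations were dropped uniformly at
random across the analyzed UTR-ome while preserving each mutation's
trinucleotide context and substitution, how often would as many mutations
hit each element class? Contexts comprise 64 interior trinucleotides plus
32 edge forms (first or last base of a UTR), each with 3 substitutions of
the middle base: 288 classes in all. `enrich_elements()`:

- indexes every UTR-ome position by context (`build_context_index()`);
- places the observed multiset of classes uniformly at random, sampling
  positions without replacement within a permuted set (two mutations never
  share a position; a bucket smaller than its class count falls back to
  replacement with a warning), the alternate base traveling with its class;
- counts, per permuted set, how many mutations impact each class (a
  mutation counts once per class, may count in several classes), with PWM
  databases optionally collapsed to DNA/RNA database-level classes;
- reports Monte Carlo p-values with the add-one estimator
  `p = (1 + #{perm >= obs}) / (1 + N)` for enrichment and its mirror for
  depletion, flagged at p < 0.025 per tail.

Impact counting is the hot loop, so the WT side of every comparison is
precomputed per UTR (`prepare_utrome()`), and a single-nucleotide candidate
only rescores the PWM windows overlapping it — a one-weight delta per
window, exactly equivalent to a full rescan because windows elsewhere are
untouched. The test suite pins this equivalence against per-mutation full
rescans.

Two numerical caveats are deliberate. The add-one estimator never returns
zero and is slightly conservative. And when impact counts take only a few
integer values (small cohorts, small UTR-omes), the p-value distribution
under the null is discrete: it is *calibrated* (the rejection rate at any
level never exceeds that level) but not exactly uniform. The tests
therefore assert one-sided calibration rather than a distributional
identity; with cohort-scale inputs (thousands of mutations) the counts are
large and the distribution approaches uniformity.

`recurrent_distance_fraction()` computes the companion recurrence
statistic: among genes mutated in two or more patients, the fraction whose
closest pair of mutations lies strictly within a 50-bp window (minimum
pairwise distance; the window and the strict inequality follow the
statistic's definition).

## The simulator

The simulator exists so every stage is testable offline with known truth.

- `simulate_library()` draws random UTRs (default lengths span 42-2960 nt,
  the realistic range of full-length 5'-UTRs) and one single-SNV mutant per
  gene, optionally planting a motif and placing the mutation inside it.
- `simulate_ccs()` assigns unique barcodes per construct (the full-scale
  design averaged ~236 per UTR; proof-of-concept designs use 5), corrupts a
  plasmid permanently with probability `1-(1-e)^L` (one random UTR
  substitution) so longer UTRs are mis-synthesized more often — the
  mechanism behind the observed length dependence of synthesis quality —
  and emits reads with iid per-base substitution errors, half of them
  reverse-complemented.
- `simulate_counts()` models barcode abundance as lognormal (log2 sd 1 by
  default), expected mRNA mass as abundance times a per-construct
  transcript factor, polysome mass as mRNA times a TE factor, and 80S mass
  as mRNA divided by the TE factor (mass conservation between the
  single-ribosome and polysome pools — a modeling choice that makes the
  TE/poly-80S concordance testable). Every sample is an independent
  multinomial of the configured depth; replicates share the underlying
  abundances, which is what produces the high replicate CPM correlations
  the assay exhibits.
- `emit_shortreads()` writes one read per count with the barcode at the
  configured offset, so counting emitted reads reproduces the count matrix
  exactly.

What the simulator does **not** emulate: PCR jackpotting and chimeras,
pass-number-dependent CCS error profiles, adapter/index chemistry, UMI
logic (the design has none), or cell-line-specific trans effects. Passing
tests therefore demonstrate correctness of the computational contracts,
not robustness to every artifact of real libraries.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed (or inherits the session
RNG), and identical seeds give bit-identical outputs, including the
permutation stream. The test suite runs its stochastic properties at sizes
chosen to finish within a normal check run while keeping comfortable
statistical margins: dictionary-recovery properties use libraries of up to
~6 genes with 300-nt UTRs; the noisy-linkage property uses 72 barcodes at
ten reads each and a 1% error rate; FDR calibration uses 20 seeds of 100
null pairs at 20 barcodes per construct and 2e6 reads per sample; the
enrichment power suite uses 8 seeded runs of 40 planted UTRs, 100
mutations and 199 permutations; the acceptance-grade replicate concordance
uses 10,000 barcodes at 5e6 reads. Default function parameters, by
contrast, reflect the full-scale assay (10,000 permutations, 0.5 CPM,
q < 0.1, 90% PWM cutoff, p < 0.025).

## Known limitations

- The consensus step targets low-error long reads; at error rates well
  above a few percent, two-read groups resolve ties arbitrarily (toward
  the lexicographically smallest base) and accuracy degrades.
- Nearest-gene annotation is exhaustive edit distance against the library;
  it is exact but quadratic, fine for library-sized references and not
  meant for genome-scale search.
- The PRTE matrix is a synthetic stand-in; absolute PRTE hit counts are
  not comparable to analyses run with the published matrix.
- Enrichment conditions only on trinucleotide context; regional covariates
  (GC content, expression, replication timing) are out of scope.
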