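Package: utrmpra
Title: Barcode-Resolved Analysis of Full-Length 5'-UTR Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for massively parallel reporter assays (MPRAs) that test
    full-length 5'-UTR variants through linked barcodes. Builds the
    barcode-to-construct dictionary from long circular-consensus reads
    (anchor-based field extraction, per-barcode consensus, exact library
    matching with nearest-gene annotation of mismatches), quantifies
    barcodes in DNA, total mRNA, polysome and 80S short-read samples with
    counts-per-million normalization and a minimum-abundance filter,
    tests mutant versus wild-type barcode log2 ratios (transcript level,
    translation efficiency, polysome/80S) with Mann-Whitney U tests under
    Benjamini-Hochberg FDR control, scans 5'-UTRs for cis-regulatory
    elements (position weight matrices on DNA and RNA, upstream AUGs and
    ORFs, pyrimidine-rich translational elements, G-quadruplexes, 5'-TOP
    tracts), and assesses mutation enrichment in each element class
    against a trinucleotide-context-preserving permutation null with
    Monte Carlo p-values. A self-contained simulator generates synthetic
    libraries, long reads and count matrices with known ground truth so
    that every stage can be exercised offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
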