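Package: ampliclone
Title: Dual-Index Amplicon Planning, Clonal Genotyping and TFBS Collation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for deep-sequencing workflows that genotype
    large panels of Cas9-edited clonal isolates at targeted loci.  Plans
    dual-indexed (i7 x i5) amplicon libraries of up to 9,216 samples and writes
    the corresponding Illumina-style Sample Sheet from a short plate:barcode
    specification; demultiplexes and merges paired-end reads, ranks distinct
    merged sequences by abundance, and infers per-clone genotypes from
    frequency-filtered allele definitions; reconstitutes alleles carrying long
    indels by chaining colinear local-alignment fragments against a reference;
    and scans reference and allele sequences with position weight matrices
    under a Markov background (exact p-values by dynamic programming) to
    collate transcription-factor binding sites lost and gained in each allele.
    A bundled simulator generates reference loci, Cas9 edit alleles, barcoded
    reads and truth tables so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
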