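---
title: "Methods: allele calling and TFBS collation in ampliclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele calling and TFBS collation in ampliclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

## Overview

`ampliclone` supports a workflow in which up to 9,216 clonal isolates from a
nuclease-treated cell population are genotyped at targeted loci from one
dual-indexed sequencing run, and each inferred allele is annotated for
transcription-factor binding sites (TFBSs) lost or gained relative to the
reference sequence. The package covers three stages:

1. **Library planning** — a 96 i7 x 96 i5 barcode design, expanded from a
   short plate specification into an Illumina-style Sample Sheet.
2. **Allele definition and genotype inference** — merging of paired-end
   reads, abundance ranking of distinct merged sequences, local alignment
   to reference loci (with chaining for long indels), mutation
   classification and per-clone genotype cohorts.
3. **TFBS collation** — position-weight-matrix scanning of reference and
   allele sequences under a Markov background with exact p-values, and a
   gap-aware diff of the hit sets.

A bundled simulator generates every input (references, edit alleles,
barcoded reads with errors, motif and background files) together with truth
tables, so the full pipeline is exercised without external data.

## Dual-index planning

Each well of a 96-well plate is identified by one of 96 i7 barcodes (well
ids, row-major: i7-01 is A01, i7-13 is B01, i7-96 is H12) and each plate by
one of 96 i5 barcodes, so one line of text per plate (`name,i7range,i5`)
expands to up to 96 sample rows and 96 lines expand to 9,216. Barcodes are
8-nt sequences drawn by seeded greedy search under a pairwise Hamming
distance of at least 3 within each role, so a single sequencing error in an
index cannot convert one barcode into another; the search enumerates a
seeded permutation of all 4^8 words and fails loudly when a constraint is
infeasible (pairwise distance 8 admits at most four 8-mers, for example).
Index-2 chemistry differs between Illumina instrument families, so the
sheet records a workflow flag: workflow A writes i5 barcodes as entered and
workflow B writes their reverse complements. The flag is a regular
`[Header]` key so that serialize–parse–serialize is byte-identical.

The bundled demultiplexer (used to exercise sheets end to end on synthetic
pools) assigns a read pair when exactly one sheet row matches both observed
indices within `max_mismatch` (default 1) substitutions; pairs matching
zero or several rows go to the unassigned bin, and counts are conserved.

## Read merging and the four abundance renditions

R1 and R2 are merged at the maximal-length 3' overlap with mismatch rate at
most 10% and length at least 10 nt; at overlap disagreements the
higher-quality base wins. Unmergeable pairs are counted and excluded from
allele calling. Distinct merged sequences are tallied exactly and the top
10 (ties broken lexicographically, for determinism) are reported with four
abundance renditions: raw % of all merged reads; % of the top-10 mass; %
after excluding sequences at <= 1% raw frequency; and % after excluding
sequences at <= 10% raw frequency. The two filtered renditions renormalize
to 100% over the retained sequences, reflecting that reads below ~1%
frequency in clonal material are dominated by PCR/sequencing artefacts.
Ranked sequences whose adjusted (>1%) frequency is below 10% are flagged
scarce and set off in reports by a literal divider line, since they are
unlikely to represent true alleles of a clonal isolate.

## Local alignment, fragment chaining, and long indels

Candidate alleles are aligned to every reference locus on both strands with
an affine-gap local aligner (match +2, mismatch −3, gap open −5, gap extend
−2; a gap of length *g* costs 5 + 2*g*). Two behaviours reproduce what
short-read alignment tools do with nuclease-induced indels:

* **Gap-run cap.** A single alignment fragment (HSP) may contain indels of
  at most `max_gap` = 60 bp. The cap is enforced inside the dynamic
  program (gap extension stops at the cap and a new gap may not open
  immediately after a gap on the same side), so a longer indel *cannot* be
  absorbed into one fragment and instead splits the alignment.
* **Fragment recovery by masking.** After the best fragment is found, its
  query span is masked and the alignment repeated (up to 4 fragments), so
  both flanks of a long indel are recovered as separate HSPs.

HSPs on one locus and strand are **chained** when colinear and
non-overlapping in both query and subject and when the combined subject
span is at most 1 kb; otherwise a deprecation value records the reason
(`overlap`, `span_exceeded`, `discordant`). Chains are **reconstituted**
into one contiguous alignment by fetching the bridged reference span and
rendering it as deletion columns (unaligned query bases between fragments
become insertion columns).

Two numerical details matter for exact indel sizes. First, gap runs within
10 columns of a fragment end are trimmed: a micro-extension that jumps a
gap just before the end of a local alignment is more plausibly part of the
adjacent indel than an independent event. Second, chained junctions are
refined: a fragment can "steal" a few bases of its neighbour's flank via a
net-positive extension across the indel boundary (e.g. two matches and a
mismatch), which would shift the junction and mis-size the indel by a few
bases; refinement trims non-match columns within 10 columns of the
inner-facing ends and re-extends the neighbouring fragment diagonally over
exact matches. With both in place, simulated clean deletions are recovered
at exact size across 1–60 bp (one fragment) and 61–900 bp (chaining); the
single-fragment optimum is checked against an independent affine-gap
dynamic-programming oracle in the test suite. A consequence of trimming is
that edits within ~10 bp of an amplicon end are outside the trustworthy
window; cut sites are amplicon-internal by design, so this does not
constrain intended use.

## Allele classification and genotype inference

Relative to its reference hit, an allele is wild-type (no gaps, no
mismatches), a deletion (gaps only in the query), an insertion (gaps only
in the subject), a substitution (mismatches only) or a complex indel
(anything mixed), with `size_bp` the total number of bases inserted,
deleted or substituted — reported in the familiar phrasing, e.g. "likely
deletion 8 bp". Alignments covering less than 90% of the query, queries
with no credible hit, near-tied hits on two loci (second locus within 10%
of the best score) and chains violating the rules above are deprecated
rather than classified, and tallied in the population summary's
reads-lost synopsis.

Genotypes are inferred from **prominent** alleles: ranked sequences whose
adjusted (>1% rendition) frequency is at least 10% (tunable;
`--prominence`). One prominent allele yields a homozygous cohort of its
class — amplicon data cannot distinguish a true homozygote from two
identical alleles, and the report says so. Two yield a heterozygous cohort
(wt+mutant or mutant+mutant); more than two yield "unclear/multi-allelic"
with a multiploid note; none yields "unclear/multi-allelic" for
insufficient representation. Reports group samples by cohort in a fixed
order (deletions, insertions, substitutions, complex, heterozygous,
wild-type, unclear) regardless of input order.

## Motif scanning with exact p-values

MEME-minimal motif files are parsed into position probability matrices
(columns must sum to 1 within 1e-6). The Markov background is estimated
from user sequences by counting (k+1)-mers over both strands with a
pseudocount of 0.1 per cell; the order-0 marginal is always computed
alongside, because scores and the exact p-value table are defined under an
order-0 null (higher-order conditionals are estimated and retained, but
the exact-table machinery is order-0 — a documented limitation shared with
the tool family this emulates).

Log-odds are `log2(((p + 0.1 * bg) / 1.1) / bg)` per cell, discretized per
column onto a shared 1000-bin integer scale. The null distribution of the
total integer score of a random w-mer under the background is computed
exactly by dynamic programming (per-column convolution), giving
`P(S >= t)` for every achievable score; scanning computes each window's
integer score on both strands and reports hits at p <= 1e-4 by default
(adjustable; hit sets nest monotonically in the threshold). For motifs of
width <= 8 the test suite checks the DP against exhaustive enumeration of
all 4^w words under uniform and skewed backgrounds; agreement is exact to
floating-point rounding because both sides share the discretization.

## Collating TFBS losses and gains

For each candidate allele (top 5 merged read types per sample, the
configurable default of the collation stage) the allele and its reference
locus are scanned separately and the hit sets diffed through the
allele-to-reference coordinate map of the alignment. A hit present with
identical (motif, strand, mapped start) on both sides is unchanged and
suppressed — this makes sites downstream of an indel, whose raw
coordinates shift, cancel exactly. Hits whose window *touches* an
alignment gap (contains inserted or deleted columns, or directly abuts
one) cannot be placed exactly: they carry an approximate-position flag,
are annotated in reports with the literal note "note, approx. position"
beside the p-value, and are never cancelled against the other side.

The no-cancellation rule for gap-touching hits is a deliberate design
choice. A positional-slack match would silently cancel a site that an
insertion interrupted and a nearby sequence change recreated — precisely
the biologically interesting event (a binding sequence ablated on one
frame and reconstituted on another), which should be surfaced as a
lost/gained pair for the analyst to judge. Making the touch rule identical
on both alignment sides also keeps the diff antisymmetric: swapping the
roles of reference and allele swaps the lost and gained sets exactly,
which the test suite asserts.

When a TF of interest is supplied, alleles that lost a site for that TF
are partitioned into three views: lost without regain; lost with regain of
an alternative site for the same TF; and lost with gain of a site for a
distinct TF (the last is independent of the first two). The text report
renders gained sites above the allele-versus-reference alignment and lost
sites below it; the workbook is a directory of at most eight tab-separated
worksheets (all hits, lost, gained, lost+gained, the three TF views, and a
summary) — a plain-text workbook format that any spreadsheet tool imports.

## The simulator and what passing tests do (and do not) show

`simulate_clonal_plate()` emulates a 96-well plate of clonal isolates. The
default study conditions: a 170-nt standard locus carrying a 20-nt
protospacer (blunt cut between protospacer positions 17 and 18, the
standard Cas9 convention); 30 read pairs per clone; 2 x 130 nt reads;
substitution-only sequencing errors whose rate is a parameter (0 and 0.5%
are the conditions the recovery properties are stated at). Erroneous bases
carry Phred 2 and correct bases Phred 40, so overlap consensus can repair
overlap errors the way quality-aware mergers do on real data. The clone
plan spans every cohort: 14 wild-type, 16 deletions (1–40 bp), 10
insertions (1–10 bp), 8 substitutions, 8 complex indels, 20 heterozygous
wt+mutant, 10 heterozygous mutant+mutant, 4 homozygous long deletions
(100/200/500/900 bp) and 6 multi-allelic clones. Long-deletion clones live
on their own loci, sized so that the edited amplicon remains mergeable at
the capped read length and the chained subject span stays within 1 kb —
mirroring how such amplicons are designed in practice. Complex-indel
truth is guaranteed irreducible: inserted bases are chosen so the allele
is not a subsequence of the reference or vice versa (checked by an
independent string oracle), because a del+ins whose insert re-embeds in
the deleted context genuinely *is* a pure indel and would make the truth
label wrong, not the caller.

Under these conditions cohort recovery is 100% at zero error and >= 95%
(typically ~99%) at 0.5% per-base error. What this shows: the ranking,
filtering, alignment, chaining and inference rules are internally
consistent and robust to substitution noise at 30x depth. What it does not
show: robustness to simulated indel sequencing errors (excluded so truth
indels stay unambiguous), PCR chimeras, index hopping, coverage dropout,
or copy-number variation — real-data phenomena outside the generator's
model.

The motif use case is a fixed engineered fixture, not a random draw: a
200-nt locus with one planted GBS instance (`ACCACAGGGTGTTCT`; matched by
a 15-wide matrix with a free 3-bp spacer, half-sites deliberately
asymmetric so the palindromic both-strand match of a canonical GRE does
not complicate hit counts), plus a +1 insertion allele that destroys the
planted site while creating a shifted GBS match and a novel synthetic
SOX-like match (`AACCACAG`), and a 5-bp deletion allele that simply
ablates the site. The flanks were verified free of spurious motif matches
and then frozen; the 2-kb background sequence is exactly
composition-balanced so the order-0 marginal is uniform.

## Problem sizes and defaults

| Parameter | Default | Where |
|---|---|---|
| Barcode length / min Hamming | 8 nt / 3 | `generate_barcode_library()` |
| Merge min overlap / mismatch rate | 10 nt / 0.10 | `merge_read_pair()` |
| Ranked alleles / motif candidates | 10 / 5 | `rank_and_filter()`, `collate_run()` |
| Abundance filters | >1%, >10% raw | `rank_and_filter()` |
| Prominence threshold | 10% adjusted | `infer_genotype()` |
| Align scores (m/mm/go/ge) | +2/−3/−5/−2 | `align_params()` |
| Max gap per fragment / chain span | 60 bp / 1000 bp | `align_params()`, `chain_hsps()` |
| Min query coverage | 90% | `classify_allele()` |
| Multiple-hit ratio | 0.9 | `align_params()` |
| End/junction trim window | 10 columns | alignment internals |
| Motif pseudocount / bins / p | 0.1 / 1000 / 1e-4 | `build_log_odds()`, `scan_sequence()` |
| Simulated plate | 96 clones, 30x, 2x130 nt | `simulate_clonal_plate()` |

The test suite and the acceptance script run the full 96-clone plate at
both error rates, the indel-size sweeps at a representative subset of
sizes (seven in 1–60, four to five in 61–900), and the enumeration oracle
at widths 2–8; these sizes keep a complete run in the order of one to two
minutes on a single CPU while exercising every code path.

## Known limitations

* Exact p-values are order-0; order-k backgrounds affect only score
  normalization through their marginal.
* Homozygosity is reported from a single prominent sequence and cannot be
  distinguished from identical biallelic alleles; copy number is not
  modelled.
* Edits within ~10 bp of an amplicon end fall inside the trim window and
  may be missed or mis-sized; design amplicons with internal cut sites.
* The demultiplexer reads index pairs from deflines (the simulator's
  convention); instrument BCL/undetermined handling is out of scope.
* Insertions longer than the read overlap cannot be observed in merged
  reads at all — a sequencing-design constraint, not a software one.
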