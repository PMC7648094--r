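---
title: "Detecting and sequestering oral-microbiome contamination in human WGS alignments"
author: "SalivaDecoy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and sequestering oral-microbiome contamination in human WGS alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SalivaDecoy)
```

## The problem

DNA extracted from saliva carries DNA from the oral microbiome alongside the
donor's own. When such libraries are aligned to the human reference with
standard short-read aligners, a fraction of the bacterial read pairs attach
to the reference through nothing more than a short chance identity: both
mates of a pair align over the same 19--25 bp reference k-mer, the rest of
each read is soft-clipped, and the recorded template span (leftmost to
rightmost mapped base) is at most 30 bp -- far below any real library
insert. We call these *atypical read pairs*. They pile up at their anchor
k-mer, inflate local depth, and, because every one of them carries the
reference base across the anchor, they systematically pull genotype calls at
overlapping variant sites from homozygous-alternate (1/1) to heterozygous
(0/1).

SalivaDecoy implements the full mitigation workflow around that signature:

1. **`detectAtypicalPairs()`** finds atypical pairs in SAM/BAM input,
   recomputing the span from mapped coordinates rather than trusting the
   TLEN field, and records the per-mate identity cores and soft-clip
   geometry parsed from the CIGARs.
2. **`filterByTlen()`** removes or tags those pairs record-by-record -- the
   cheap mitigation that needs no realignment.
3. **`filterHits()` / `assignQueries()` / `tallyTaxa()`** profile the
   taxonomic origin of read sets from BLAST tabular output, and
   `selectDecoyGenera()` / `selectAdditionalSpecies()` choose the decoy
   content by frequency thresholds.
4. **`concatenateDecoy()`** and the three mask finders build a single decoy
   contig that, appended to the reference, gives contaminant reads a better
   home than the human chromosomes.
5. **`compareVcfs()` and friends** quantify the effect on alignment counts
   and genotype calls.
6. A seeded simulator (`simConfig()`, `simulateAlignments()`,
   `makeBlastTable()`, `makeVcfPair()`) generates every input with a full
   truth table, so the entire pipeline is testable offline.

## Detection model and conventions

A pair is *eligible* when both mates are mapped to the same reference in
primary, non-duplicate records (duplicate-marked and
secondary/supplementary records are excluded, matching a best-practice
calling pipeline in which duplicates are marked before genotyping). For an
eligible pair the template span is

$$\mathrm{span} = \max(e_1, e_2) - \min(s_1, s_2) + 1,$$

with $s_i, e_i$ the 1-based inclusive reference start/end of mate $i$'s
reference-consuming CIGAR extent. A pair is atypical when
$1 \le \mathrm{span} \le 30$. Published descriptions of this phenomenon
state the rule both as a coordinate distance and as an absolute template
length between 1 and 30; the two can disagree by one under some aligner
conventions, so the span is always recomputed from coordinates
(aligner-independent) and a warning is raised when `|TLEN|` disagrees.

Other conventions, chosen once:

* Coordinates are 1-based inclusive internally (SAM convention); all BED
  output is 0-based half-open.
* Strand is ignored throughout: the anchoring phenomenon is symmetric in
  strand.
* `minMapq` applies to the *better* mate of the pair; the default is 0 for
  census work, while impact assessment conventionally uses 10, the floor
  below which variant callers discard alignments. `mapqProfile()` reports
  the MAPQ partition under both the per-mate and the per-pair convention,
  because summary percentages in the literature do not say which was
  counted.
* Clusters are single-linkage merges of union core intervals with a default
  `mergeGap` of 20 bp, mirroring the observed spacing of anomalous variant
  clusters; every pair belongs to exactly one cluster.
* `filterByTlen()` preserves all untouched records byte-identically, appends
  a `@PG` header line, tags with `ZA:i:<span>`, and never removes an orphan
  record (mate flagged mapped but absent), annotating it instead.

## Taxonomic profiling

BLAST tabular hits (standard 12-column dialect, optional 13th `qlen`
column) are filtered to *positive* results: query coverage
$\ge 0.80$ and e-value $\le 1$. Each query is assigned the species of its
best surviving hit -- highest bitscore, ties broken by lowest e-value, then
lexicographically smallest subject id, so assignment is deterministic and
order-invariant. Queries with no surviving hit are `No-hit`; subjects
missing from the user-supplied taxonomy table are reported separately as
`Unmapped-subject` rather than silently dropped or miscategorised.

Category fractions are reported over two denominators (all queries, and
assigned queries only) because published per-category tables are ambiguous
about which they use; both are carried in every `TaxonTally`.

Decoy content selection uses two different denominators by design:

* **Genera**: assigned-read count / total unaligned-read count
  $\ge 10^{-5}$ (0.001%). Unaligned reads sample the specimen's full
  microbial diversity; atypical pairs alone are too few.
* **Additional species**: fraction of *positive* results from the
  atypical-read query set $\ge 0.02$, skipping species whose genus is
  already selected.

## Decoy construction and masking

Selected genome sequences are concatenated with 1000-N spacers (no read can
align across a junction), uppercased, ambiguity codes collapsed to N, and
the component index kept so any decoy coordinate maps back to its source
base (`decoyToSource()`). Three independent mask passes then protect the
human alignment:

* **Human-similar regions** (`findHumanSimilarRegions()`): fixed windows
  (100 bp every 50 bp) are seeded against a k-mer index of the human
  reference (k = 12, seeds sampled every 4 bp of the window) and candidate
  regions are locally aligned with a +1/−1 match/mismatch score (gap open
  2, extend 1). A window is masked when an alignment reaches 65% identity
  over at least half the window. The +1/−1 scoring matters: it stops local
  alignments from drifting through low-identity sequence, so "identity over
  aligned columns" means what the threshold intends. No method, window or
  aligner is prescribed in the literature for this screen beyond the 65%
  figure; the windowed seed-and-extend here is deterministic and desk-scale,
  and every parameter is exposed.
* **Polynucleotide repeats** (`findPolynucleotideRepeats()`): interpreted
  as short-unit tandem repeats -- a unit of 1--6 bp repeated contiguously
  over at least 20 bp. Runs consisting solely of N (the spacers, already
  masked) are not reported. This interpretation is the package's own; the
  term is not defined more precisely in the source literature.
* **Internal duplicates** (`findInternalDuplicates()`): shared-21-mer
  chaining marks every occurrence after the first; merged marked intervals
  of at least 100 bp are masked. The first copy is kept -- masking every
  copy would delete legitimate decoy content.

Masking replaces bases with N, preserves length, is idempotent, and the
three passes commute (all verified property-style in the test suite).
`appendDecoyToReference()` refuses contig-name collisions and writes
60-column FASTA that a standard indexer accepts.

## Impact assessment

Pre/post-decoy VCFs are matched on (chrom, pos, ref, alt) after
multi-allelic decomposition, *without* left-normalisation by default (both
calls are assumed to come from the same caller pipeline; cross-pipeline use
should normalise upstream). Genotypes are recoded per alternate allele.
Classes: `lost`, `new`, `restored_hom_alt` (0/1 → 1/1, the signature
correction), `unchanged`, `other`; the classification is a partition and
conserves totals. The median QUAL of lost variants uses the lower median,
so the reported value is always an observed quality.

Variant-to-cluster distance is the positional difference between the VCF
POS and the nearest cluster base, indels anchored at POS; a variant 100 bp
from a cluster is in, 101 bp is out. The attributable-variant fraction is
lost-variants-near-clusters over all pre-decoy variants, in percent, with
an optional coding-interval subset. Percent reductions are
$100(1 - \mathrm{post}/\mathrm{pre})$, undefined (never 0) for a zero
pre-count, and negative (never clamped) when a count grows.

## What the simulator emulates -- and what it does not

`simConfig()` defaults encode the study conditions the package targets:
151 bp paired-end reads, identity cores uniform over 19--25 bp, per-mate
MAPQ drawn from the (0.4541, 0.1219, 0.4240) mixture over the
$\le 10$ / 11--39 / $\ge 40$ bins, a 32.86% no-hit fraction among
atypical-read BLAST queries, a contaminant table dominated by oral
bacteria (~95% of assigned weight), and 5000 typical + 50 atypical pairs
per alignment file at insert 400 ± 50 bp. Planted atypical mates share the
core's reference start with symmetric `xS cM yS` geometry -- an idealised
version of the overlapping alignments seen in real data; flanks are
rejection-sampled so the core k-mer occurs exactly once per read.

Deliberate non-goals: no sequencing-error or quality model, no aligner
emulation beyond CIGAR/TLEN geometry (MAPQs are assigned, not computed),
contaminant flanks are random rather than real bacterial sequence, and
simulated inserts are truncated above the read length so typical pairs can
never be span-atypical. Passing tests therefore demonstrate the
correctness of the detection, selection, masking and comparison logic under
the stated geometry -- not the behaviour of any particular aligner or
caller on real saliva libraries, where soft-clip geometry is noisier and
MAPQ reflects the aligner's own model.

Problem sizes used in the checked examples (chosen to keep every
property readable and quick while leaving no boundary untested): oracle
equivalence on 100 seeded instances of 60--300 records per operation,
planted-read recovery at 5000 + 50 pairs, 50 random decoy constructions,
100 seeded genotype-comparison trials.

## Numerical and degenerate-input choices

* Empty MAPQ profiles report `NA` fractions ("undefined"), not 0; the same
  for reductions with a zero pre-count and attributable fractions with an
  empty pre-VCF.
* Assignment tie-breaks are total (bitscore, e-value, subject id), so
  results are independent of input order.
* `selectDecoyGenera(minFreq = 0)` returns every genus with at least one
  assigned read; a zero read-count denominator is a hard error.
* Malformed CIGARs and malformed BLAST rows are skipped with warnings and
  counted, never silently dropped.
* Cross-reference pairs and unmapped mates make the span *undefined* (an
  error in `templateSpan()`), not infinite.

## Known limitations

* The human-similarity screen is windowed and seeded; a diverged region
  with no shared 12-mer in any sampled seed position can escape the mask.
  Lowering `seedK` or `step` tightens the screen at linear cost.
* `readPairAlignments()` holds the name-indexed pair table in memory; it is
  meant for chromosome- or sample-scale scans, not streaming petabyte
  archives.
* Best-hit assignment gives one taxon per query; fractional or
  lowest-common-ancestor assignment is out of scope.
* The package consumes aligner/caller/BLAST outputs; it never runs those
  tools.
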