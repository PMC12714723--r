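---
title: "Methods: CRISPR adaptation assays, protospacer mapping, and mobile-element detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR adaptation assays, protospacer mapping, and mobile-element detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crispracq)
```

# Scope and model

`crispracq` analyses a CRISPR adaptation assay of the kind used to study a
chronically infecting provirus in a halophilic archaeon. Four questions are
addressed computationally:

1. Does the host acquire new CRISPR spacers, and at what rate relative to
   mere duplications of existing spacers?
2. Where in the genome do new spacers come from, and do they carry a
   protospacer-adjacent motif (PAM)?
3. Is a suspect genomic region a replicating element — at elevated copy
   number, and present as a circular episome, an integrated provirus,
   or both?
4. Are antiviral defense genes transcriptionally suppressed in the infected
   strain, measured as RPKM fold changes?

Every analysis function consumes plain R objects (named character vectors of
sequences, data frames of alignments or hits); FASTA/FASTQ/SAM I/O is
provided for interoperability. All genomic coordinates are 0-based
half-open.

# Spacer extraction

The adaptation assay amplifies the region between the array leader and the
third spacer, so a baseline (no-insertion) amplicon carries three repeats.
A newly inserted spacer+repeat unit at the leader end lengthens the amplicon
by roughly 70 bp, which is why the assay keeps only merged reads *longer
than* 300 bp (strict inequality) before parsing: under the default array
geometry (60 bp leader, 30 bp repeat, 37 bp spacers) the baseline amplicon
is 261 bp and any expanded amplicon exceeds 320 bp.

Parsing proceeds per read:

* **Orientation.** Amplicons are sequenced from both strands; the read is
  re-oriented so the leader is 5', decided by the best substitution-tolerant
  match of a 20 bp leader suffix on either strand (up to 5 mismatches).
  Ties and non-matches become `ambiguous_orientation` and are excluded —
  a status, not an error.
* **Repeat counting.** All occurrences of the repeat with at most 2
  substitutions (no indels), selected greedily left-to-right without
  overlap, leftmost start winning ties. The tolerance of 2 in a 30 bp
  repeat accepts typical post-quality-filter sequencing error without
  letting ~37 bp spacers absorb spurious matches; it is exposed as a
  parameter because the original analysis does not state its value.
* **Extraction and length filter.** Reads with more repeats than baseline
  are expanded; the sequence strictly between the two leader-proximal
  repeats is the candidate spacer, and fragments shorter than 10 bp or
  longer than 45 bp are excluded as aberrant. Reads with more than one
  extra repeat still yield only the leader-proximal insert (single
  insertions dominate the assay; multi-insertions are flagged by their
  repeat count).

The pipeline function `extract_spacers()` vectorizes these steps
(`Biostrings::vcountPattern`/`vmatchPattern` do the matching in C); a
property test asserts it is read-for-read identical to the scalar
`orient_read()` / `find_repeat_occurrences()` /
`extract_leader_proximal_spacer()` path.

# Duplicate versus new classification

Each kept spacer is screened against every spacer of every supplied array,
on both strands; a minimum distance of at most 10 labels it a duplication of
an existing spacer, anything farther is a new acquisition. Two distance
conventions are implemented because extracted spacers can differ in length
from array spacers: the default "mixed" metric uses Hamming distance for
equal lengths and unit-cost edit distance (substitutions + indels, via
`utils::adist`) otherwise; a pure edit or pure Hamming metric can be chosen
by flag, since the original ten-mismatch screen does not state whether
indels were allowed. Ties are resolved to the first (array order, spacer
index) pair, deterministically.

Per-array statistics report the new:duplicate ratio — the adaptation
activity measure, undefined (`NA`) rather than infinite when no duplicates
exist — and the mutation spectrum of duplicates, including the fraction
with two or more mutations. The default generator plants mutation counts
with distribution {0: 0.90, 1: 0.04, 2: 0.03, 3: 0.03}, i.e. 6 %
multi-mutated duplicates, matching the upper end reported for the real
assay.

# Protospacer mapping

New spacers (duplicates are never mapped) are aligned by a short-query
seed-and-extend local search: exact 7-mer seeds on both strands, grouped by
diagonal, extended to the best ungapped local alignment per diagonal by a
maximum-scoring-subarray scan, with a gapped `pairwiseAlignment` extension
engaged only where seeds fall on shifted diagonals (indel evidence).
Scoring is match +1, mismatch −3, gap open −5, gap extend −2 (under
Biostrings conventions a gap of length L costs 5 + 2L); hits within 90 % of
the best raw score are retained. A cheap prescreen skips diagonal groups
whose ungapped score falls more than 12 below the best — a bound chosen so
that any hit able to reach 90 % of the best score (possibly via one gap,
which costs at least 7) still has a qualifying seed diagonal.

Hits then face four strict filters, all inequalities strict: percent
identity > 95, mismatches < 4, alignment/query length ratio > 0.9, and
absolute alignment-vs-query length difference < 3. For a 37-mer this makes
the identity filter binding at two substitutions (35/37 = 94.6 %). The
alignment length is measured on the query span; whether the original
filters measured it with or without gaps is unstated, and for the
substitution-dominated data here the two coincide. Among passing hits the
unique top raw score is the best location; an exact score tie excludes the
spacer from location and PAM summaries; raw rather than bit-converted
scores are ranked, which is order-equivalent for fixed scoring parameters.

E-values are deliberately not modelled: without the original program's
exact parameterisation they are not reproducible, and the filters above do
the work.

**PAM.** The PAM is read from the reference as the 3 bases immediately 5'
of the protospacer on the protospacer strand (reverse-complemented slice of
the 3' flank for minus-strand hits), `NA` when the window runs off a
replicon end; length and side are flags. Note the consequence: the reported
PAM is a function of the hit's (locus, strand), so mapping the reverse
complement of a spacer reports the same locus with flipped strand and the
opposite flank. In the pipeline this never matters — spacers are always
mapped in their extracted leader orientation, which is the orientation in
which they were inserted, so the hit strand equals the protospacer strand
and planted PAMs round-trip exactly.

`pam_summary()` reports motif counts against the expected trinucleotide
background of the reference (both strands), and `locus_distribution()` bins
best-hit positions to expose locus skew — the signature of acquisition
focused on one genomic element.

# Coverage, element calling, topology

Reads are placed by their first exact 21-mer (either orientation) when that
k-mer is unique in the reference, then verified ungapped with at most 3
substitutions over the full read; reads with multiple candidate placements
are dropped. This is intentionally conservative: multi-copy sequence is
excluded rather than randomly assigned, and alignments can instead be
supplied as SAM text (`read_sam()`).

Depth is summarised in 500 bp windows (configurable; the choice trades
resolution against window-depth variance). Enrichment divides window depth
by a robust genome baseline: a two-pass median of window depths in which
windows above twice the first-pass median are excluded and the median
recomputed. A plain median is already robust to a multi-copy element in a
megabase genome, but in the scaled-down simulated genomes used here (10 kb
element in a 50–100 kb host) the element occupies enough windows to shift
the plain median by ~2 %, which matters precisely at the 2.5-fold calling
threshold; the two-pass median removes that bias and reduces to the plain
median when no element is present. An arithmetic mean would be inflated by
the element itself, which is why the "fold over genome average" the
headline numbers refer to is implemented as fold over this robust baseline.

Element calls are maximal runs of at least 2 consecutive windows at or
above the enrichment threshold (default 2.5, the lower end of the
secondary-element range; the provirus-like element sits around 20).
`median_enrichment` of a call is the robust copy-number estimate — edge
windows only partially covered by the element dilute the mean, not the
median.

**Topology.** The wet-lab logic — outward-facing primers amplify only a
circularized element; host+element primer pairs amplify only an integrated
one — is translated to read evidence:

* *Circular:* split reads whose leading end k-mer anchors near the element
  end and whose trailing end k-mer anchors near the element start, in
  wrapped order. These reads fail linear mapping by construction, so they
  are sought directly in the raw reads. A fixed probe across the junction
  was considered and rejected: calls are window-quantized, so the true
  junction can sit hundreds of bases from the call edge, and a centered
  30-mer probe needs the edge to base precision. The split-read test needs
  no exact edges; an `edge_slack` parameter (default 600 bp) absorbs the
  quantization.
* *Integrated:* reads whose alignment spans a call edge — continuity
  between element and host flank. When a call abuts a replicon end (an
  excised element resolved as its own replicon has no host flank at all),
  integration evidence is reported as not assessable (`NA`) rather
  than zero.

At least 3 junction reads (configurable) of a kind asserts that form;
the four outcomes are `circular`, `integrated`, `both`, `undetermined`.

# Expression

`rpkm()` is the standard reads-per-kilobase-per-million normalisation; the
library size column is an explicit input because "total mapped reads" can
legitimately mean genome-wide or coding-sequence-only totals, and the
bundled table does not disclose which was used. Fold change (cured over
infected) is rounded half away from zero to two decimals, the dominant
convention of the bundled defense-gene table; three of its nine printed
folds (Cas5, CBASS_2 cyclase, Hachiman A) are not reproducible from their
printed RPKM pairs under either half-up rounding or truncation and are
flagged `printed_consistent = FALSE` rather than chased. Differential
expression testing is out of scope — this module reproduces the
descriptive report only.

# The synthetic-data generator

`sim_config()` fixes the study conditions; the notable defaults and the
reasoning:

| Parameter | Default | Why |
|---|---|---|
| `gc_fraction` | 0.6 | GC-rich haloarchaeal genome |
| `genome_lengths` | 50 kb | scaled-down host; large enough for a stable window-depth baseline and effectively unique 21-mers |
| `element_length` | 10 kb | scaled-down provirus (real elements 16–24 kb); ≥ 19 interior windows make low-copy detection statistically stable |
| `element_copy_number` / `element_mode` | 20 / `both` | the provirus-like condition: ~20-fold coverage, circular and integrated forms |
| `n_amplicon_reads` | 2000 | extraction-scale assay; acceptance runs use up to 50,000 |
| `acquisition_rate` / `duplication_rate` | 0.005 / 0.10 | plants the published new:duplicate ratio of 5 %; the low extreme (0.06 %) uses `acquisition_rate = 6e-5` |
| `duplication_mutation_distribution` | {0:.90, 1:.04, 2:.03, 3:.03} | 6 % multi-mutated duplicates, the published upper bound |
| `pam_motif` | `TTC` | the observed acquisition motif in this clade |
| `per_base_error_rate` | 0.001 | post-quality-filter substitution error; substitutions only, since merged amplicon data are indel-poor and the duplicate screen is mismatch-based (an indel mode is a non-goal) |
| `read_length` / `wgs_depth` | 100 bp / 30× | short-read resequencing scale |

Half of all reads are emitted reverse-complemented (forcing orientation
handling); quality strings are a constant Q30 placeholder because quality
filtering is modelled as already applied upstream. Acquisition spacers are
sourced from PAM-anchored genomic windows (optionally restricted to the
element, the locus-skew scenario); every planted event is logged with
0-based half-open coordinates, and a planted-PAM invariant (the 3 bases 5'
of every planted protospacer on its strand equal the motif) is asserted in
tests.

What the generator does **not** emulate: PCR chimeras and size-selection
bias, platform-specific error profiles, indel errors (by default), multiple
simultaneous insertions per read, and RNA-seq reads. Passing tests
therefore demonstrate correctness of the algorithms under an idealised
error model, not robustness to every artefact of real libraries.

In mode `"both"` the genome generator embeds the element in the host
chromosome and also returns the standalone circular sequence separately
(`element_seq`) rather than as a second mapping replicon — otherwise every
element read would be discarded as multi-mapping. In mode `"circular"` the
element is its own replicon, mirroring how an excised form is resolved as a
standalone contig so its depth can be reported apart from the chromosome.

# Numerical and testing choices

* Determinism: all generators derive their RNG streams from the config
  seed; identical configs give byte-identical outputs.
* The mapping test oracle is an exhaustive every-offset, both-strand scan
  computing the best ungapped local alignment per diagonal (vectorized
  Kadane) — independent of the seed-and-extend code path. Planted mutations
  are substitutions, for which the ungapped oracle is exact (one gap costs
  at least 7 versus 3 per mismatch).
* Problem sizes in the acceptance checks: 2,000 amplicons for the
  extraction round-trip, 100 spacers over ten 50 kb references for the
  mapping oracle, ~500 planted acquisitions for PAM recovery, 20 seeds per
  copy number (20, 2.5, 3.5, and a no-element null) at 30× depth for
  coverage recovery, and 50,000 amplicons per planted ratio for
  acquisition-ratio recovery — chosen so each statistic's Monte-Carlo error
  is small against its tolerance.
* Degenerate inputs are statuses, not crashes: empty read sets warn and
  return empty frames; a zero-duplicate ratio is `NA`; a PAM window off the
  replicon end is `NA`; zero best hits warn and return empty summaries.

# Known limitations

* The coverage mapper requires a unique exact end k-mer; heavily repetitive
  references lose reads near repeats (conservative for enrichment claims).
* Junction typing assumes one element per call and reports evidence counts,
  not breakpoint coordinates.
* The two-pass median baseline assumes multi-copy windows are a minority of
  the genome; a genome mostly covered by high-copy elements would need an
  external baseline.
* Edit-distance classification treats a length-k indel as k mutations
  of cost 1 each; biological interpretation of "mismatch" counts for
  length-shifted duplicates is inherently convention-dependent.
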