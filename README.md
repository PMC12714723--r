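# crispracq

Analysis toolkit for CRISPR adaptation (spacer acquisition) assays in
prokaryotes, built around the kind of question posed by a chronically
infecting provirus in a halophilic archaeon: is the host acquiring CRISPR
spacers, where do the new spacers come from, is the suspect genetic element
replicating, and are the host's defense genes transcriptionally suppressed?

The package implements the full computational chain as reusable, tested R
functions, plus a synthetic-data generator that produces every input with
machine-readable ground truth, so the whole pipeline can be validated
end-to-end without any external download.

## What it computes

1. **Spacer extraction from amplicon reads.** Merged amplicon reads covering
   the leader-proximal end of a CRISPR array are length-filtered (kept if
   longer than 300 bp), oriented by a leader anchor, and scanned for repeat
   occurrences (substitution-tolerant, greedy non-overlapping). Reads with
   more repeats than the baseline amplicon carry an insertion; the sequence
   between the two repeats closest to the leader is extracted and fragments
   of aberrant length (< 10 bp or > 45 bp) are excluded.
2. **Duplicate vs new classification.** Each extracted spacer is screened
   against all existing array spacers on both strands, allowing up to ten
   mismatches (Hamming for equal lengths, unit-cost edit distance
   otherwise). Spacers within the threshold are duplications/rearrangements
   of existing spacers; the rest are new acquisitions. Per-array statistics
   include the new:duplicate ratio and the mutation spectrum of duplicates.
3. **Protospacer mapping and PAM.** New spacers are aligned to reference
   replicons by short-query seed-and-extend local alignment (exact word
   size 7, match +1 / mismatch −3 / gap open −5 / extend −2) and filtered
   with strict criteria — identity > 95 %, mismatches < 4, alignment/query
   length ratio > 0.9, |alignment − query length| < 3 (all strict). Among
   passing hits the highest raw score wins; score ties are excluded from
   downstream summaries. The PAM is the trinucleotide immediately 5' of the
   protospacer on the protospacer strand; summaries report the motif
   spectrum against the reference background and the binned protospacer
   location distribution (locus skew).
4. **Replicating-element detection and topology.** WGS reads are placed by
   unique exact 21-mer seed with ungapped verification, windowed depth is
   normalised by a robust (two-pass median) genome baseline, and maximal
   runs of windows at or above a fold-enrichment threshold (default 2.5)
   become element calls. Junction evidence — split reads wrapping from the
   element end back to its start (circular form) and reads spanning the
   host–element edges (integrated form) — types each call as circular,
   integrated, both, or undetermined.
5. **Expression fold changes.** `RPKM = count / ((length/1000) ×
   (library/10^6))` and cured-vs-infected fold change rounded half-up to
   two decimals, reproducing the bundled defense-gene report
   (CRISPR-Cas adaptation genes, two CBASS systems, Hachiman).

## Worked example

```r
library(crispracq)

cfg <- sim_config(seed = 7, n_amplicon_reads = 2000,
                  acquisition_rate = 0.05, duplication_rate = 0.10,
                  per_base_error_rate = 0)
genome <- gen_genome(cfg)
array  <- gen_array(seed = 7)

sim   <- simulate_acquisition_reads(array, genome, cfg)
reads <- filter_reads(sim$reads)   # 1699 read(s) of 2000 discarded at length <= 300
ex    <- extract_spacers(reads, array)
table(ex$status)
#> kept
#>  301

cl <- classify_spacers(ex, list(array))
acquisition_stats(cl)
#>   array_id n_new n_duplicate new_to_duplicate_ratio fraction_multi_mutated
#> 1   arrayA    89         212              0.4198113             0.06132075

new_spacers <- cl[cl$label == "new", c("read_id", "sequence")]
hits <- map_spacers(new_spacers, genome$replicons)
pam_summary(hits, genome$replicons)$top_motif
#> [1] "TTC"
```

All 301 reads that survive the length filter yield a kept spacer; 212 are
duplications of existing array spacers (of which ~6 % carry two or more
mutations, matching the generator's mutation distribution), 89 are new
acquisitions, and every mapped new spacer reports the planted 5'-TTC PAM.
(The simulated per-read acquisition rate of 5 % is deliberately far above
the published assay's — the length filter enriches expanded amplicons, so
the post-filter new:duplicate ratio reflects the planted 0.05/0.10 rates.)

On the WGS side:

```r
wcfg  <- sim_config(seed = 7, element_copy_number = 20, element_mode = "both")
wg    <- gen_genome(wcfg)
wreads <- simulate_wgs(wg, wcfg)
al    <- map_reads(wreads, wg$replicons)
calls <- call_elements(depth_profile(al, wg$replicons), threshold = 2.5)
junction_typing(wreads, calls[1, ], wg$replicons, alignments = al)
#>   replicon start   end mean_enrichment median_enrichment n_windows
#> 1     chr1  6500 16500        19.82272          19.95911        20
#>   n_circular_junction_reads n_integration_junction_reads topology
#> 1                       339                          455     both
```

The planted 10 kb element at copy number 20 is recovered as a single call
with a median window enrichment of ~20-fold over the genome baseline and
junction-read support for both the circular and the integrated form.

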