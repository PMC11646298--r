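---
title: "Benchmarking long-read mitogenome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking long-read mitogenome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mitobench)
```

## The problem

Mitochondrial genomes are small (~16.5 kb in teleost fish), circular, and
present in high copy number, which makes them recoverable even from
low-coverage whole-genome sequencing. Long-read (nanopore) de novo
assemblies of mitogenomes are attractive — one contig, circularized, cheap —
but nanopore base calling has a characteristic error mode: insertions and
deletions at homopolymer runs. The question this package addresses is *how
accurate is a long-read assembly*, measured against a short-read (Illumina)
assembly of the same individual treated as a gold standard.

Accuracy is reported the way assembly benchmarking studies report it:
number of contigs, total length, mean coverage (pass-through metadata),
p-distance to the reference, completeness, and a per-category tally of
every discrepancy.

## The comparison procedure

`benchmark(ref, qry)` runs four stages:

1. **Orientation normalization** (`normalize_orientation`). Circular
   assemblies have an arbitrary origin and strand. The query is
   reverse-complemented if needed and rotated so it starts at the position
   matching the reference start. The anchor is the reference's first
   21-mer, located by exact match in the query or its reverse complement
   (searched on the doubled query string so the anchor may straddle the
   origin); on failure the anchor shrinks by 2 down to k = 11, below which
   the function asks the caller to fall back to aligning both strands
   directly. An exact anchor is appropriate here because query and
   reference are two assemblies of the same molecule: a 21-mer at the
   reference start is overwhelmingly likely to be intact in the query.

2. **Global alignment** (`global_align`). End-to-end Needleman–Wunsch
   under affine gap penalties, implemented in C++ (a 16.5 kb × 16.5 kb
   problem runs in about two seconds). Defaults: match +2, mismatch −3,
   gap open −5, gap extend −2, so a length-L gap costs 5 + 2L. A
   two-sequence run of a multiple aligner is effectively pairwise global
   alignment, so reimplementing it removes an external dependency without
   changing the metric. Tie-breaking is deterministic — diagonal moves are
   preferred over gaps, gaps in the query over gaps in the reference, and
   gap runs are kept maximal.

3. **Metrics.** `p_distance` is the proportion of differing sites among
   columns where both sequences have a base (pairwise deletion: gap
   columns excluded). This matches the convention under which indel-only
   discrepancies yield distances of zero. `completeness` is the fraction
   of reference positions aligned to a query base, so an 11,629-bp partial
   assembly of a 16,502-bp reference scores 11,629/16,502 ≈ 0.7047.

4. **Error taxonomy** (`extract_events`, `classify_events`,
   `summarize_events`). Maximal runs of gap columns on one side become one
   indel event; each mismatch column is one *simple substitution* (there
   is no multi-base substitution category, so a run of k mismatch columns
   is k events). Indels are then left-normalized (VCF-style: shifted to
   their leftmost equivalent placement) so that events inside homopolymers
   and repeats get deterministic coordinates regardless of where the
   aligner placed the gap. Classification rules:

   * an indel whose bases are all one base X, adjacent on either reference
     flank to a run of X of length ≥ `min_run` (default 2), is a
     *homopolymer insertion/deletion*; its size maps to a multiplicity
     label (1 → single … 7 → septuple, larger → `gt7`, kept as its own
     label rather than forced into the short-indel bins);
   * mixed-base indels are never homopolymer events, even next to a run;
   * remaining indels are *single* (size 1) or *short* (size ≥ 2)
     insertions/deletions;
   * an insertion equal to the reference substring of the same length on
     either flank is flagged `tandem_duplication`. The flag is advisory:
     the event still counts once, in its size-based category. Either
     flank is tested because left-normalization slides a duplicated copy
     to just *before* its template, where the matching substring is the
     following one.

   Where two flanking runs could both claim an event the longer run (then
   the 5′ one) supplies the homopolymer base; this only matters when both
   flanks carry runs of the event's base.

### The circular seam

After rotation the molecule is cut at the reference origin and aligned
linearly, so an event that truly spans the origin would be split or
misplaced. If any event falls within `junction_slack` (default 100 bp) of
either end, the reference is re-rotated through the middle of the largest
event-free arc, the query is re-normalized against it, and the alignment
is repeated; the better-scoring event set (ties broken toward fewer
events) is kept, with coordinates mapped back to the original frame. This
suppresses spurious end gaps without ever inventing events.

## Read-pipeline conventions

* Read-level quality is the Phred score of the *mean error probability*
  (−10·log₁₀ of the mean of 10^(−q/10))), the convention of ONT tooling
  and fastp — not the arithmetic mean of Phred values, which would
  overstate quality on reads with a few very bad bases. The default
  threshold is Q ≥ 6, and the length window (default off; the study
  setting is 5,000–20,000 bp) is inclusive at both ends.
* Subsampling to a target depth uses shuffle-then-accumulate semantics
  (as in Rasusa): reads are shuffled by a seeded RNG and taken until
  cumulative bases reach `target_depth × genome_size`. The default
  `genome_size` of 1 Gb reflects the convention of quoting nanopore run
  depth against an assumed fish nuclear genome; for desk-scale work one
  passes the mitogenome length instead. Same seed, same selection —
  removing the last selected read always drops the total below target.

## Descriptive statistics

* `nucleotide_usage` reports A/T/C/G percentages over non-N positions
  (assemblies here are N-free, but raw reads need not be) with
  `at_pct = a_pct + t_pct`, the arithmetic of published usage tables.
* `count_codons`/`rscu` use the vertebrate mitochondrial code
  (translation table 2) for synonymous families, with stop codons
  excluded from families by default. RSCU for codon i in family F is
  `count_i × |F| / Σ_F counts`, so family sums equal family sizes exactly
  whenever the family is used at all. Note that published tables
  occasionally label AGA/AGG as serine codons; under table 2 they are
  terminators and therefore sit outside the RSCU families unless
  `exclude_stop = FALSE`.
* `find_microsatellites` reports maximal *perfect* tandem arrays of motif
  length 1–6 with ≥ 3 copies (the lower end of what control-region
  dinucleotide microsatellites typically show), suppressing non-primitive
  motifs so a homopolymer is never double-reported as a dinucleotide.
* `find_tandem_repeats` is a deliberately simplified tandem repeat
  finder: candidate periods 7–30 are scanned by lagged self-comparison,
  arrays are extended while the mismatch fraction stays ≤ 0.2, and the
  consensus is the per-column majority across copies, with copy number
  span/period to one decimal. Only consensus length and copy number are
  consumed downstream, which is why the full probabilistic treatment of a
  dedicated repeat finder is not needed. Two guards keep chance hits out:
  segments must anchor on ≥ 5 consecutive lag-matches at both ends, and
  the matched self-alignment must be ≥ 20 bp (on 100 random 800-bp
  sequences this yields hits in fewer than 5). One consequence of
  seed–extend detection is that the reported array phase — hence the
  consensus string — is determined only up to cyclic rotation when
  flanking bases happen to continue the pattern.
* `annotation_summary` accepts GFF3 or a minimal TSV and handles genes
  wrapping the circular origin by modular arithmetic. The canonical
  vertebrate gene order (13 PCGs, 22 tRNAs, 2 rRNAs, control region
  between tRNA-Pro and tRNA-Phe; nad6 plus 8 tRNAs on the negative
  strand) ships as a synthetic fixture with typical teleost gene lengths
  laid end-to-end (`standard_gene_order()`), for testing summaries
  without a real annotation.

## The synthetic-data generator

`make_genome` emulates the features of a teleost mitogenome that matter
to this pipeline: ~16.5 kb circular, A+T ≈ 55% (realized within ±1% by
nudging background bases), planted homopolymer runs (by default an 11-bp
T run and a 5-bp A run, the contexts in which single indels were the
residual errors of low-depth assemblies), and an ~850-bp control-region
segment carrying AT-rich dinucleotide microsatellites (3–5 copies) and
two longer tandem repeats (17-mer × 5.4, 20-mer × 4.7). Planted arrays
are flanked by bases chosen to break the repeat so planted period and
copy numbers are exact; the first 30 bases stay feature-free so the
orientation anchor is unambiguous. Everything is reproducible bit-for-bit
from (spec, seed).

`inject_errors` plants an exact per-category error profile and returns
the truth in canonical (left-normalized) coordinates. Placement rules
make the round trip a fair test rather than a tautology: events sit ≥ 15
bp apart (comfortably above the 2-bp minimum needed for unambiguous
classification), outside repeat arrays and the CR, away from the seam
and the anchor; substitution and indel bases are chosen so no planted
event can be reinterpreted as a different category (e.g. an inserted
single base differs from both neighbours; a short deletion's segment is
mixed-base and differs from both adjacent same-length substrings).
Homopolymer deletions of multiplicity m use runs of length ≥ m + 2 so
homopolymer context survives the deletion.

`simulate_reads` draws read lengths from a clipped lognormal
(default body around 8 kb within 1–20 kb), start positions uniformly on
the circle (reads wrap the origin), i.i.d. per-base
substitution/insertion/deletion errors, and Gaussian-jittered Phred
qualities. Depth is specified directly against the template being
simulated: the nuclear-genome convention (1 Gb) used when quoting run
depth would require simulating gigabases, so the simulator documents the
convention and exposes mitogenome-relative depth instead.

What the generator does *not* emulate: signal-level nanopore error
structure (error clustering, strand bias, quality–error correlation),
nuclear DNA, heteroplasmy, or chimeric reads. Passing round-trip tests
therefore demonstrates that the comparison machinery is exact on isolated
events of every category — not that any particular real assembly reaches
a given accuracy.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open only inside the alignment
  kernel; all reported coordinates are 1-based inclusive (an insertion's
  `ref_pos` is the reference base 5′ of the inserted material, 0 at the
  start).
* Composition tables tolerate a summation slack of 0.02 so tables rounded
  to two decimals remain valid.
* Degenerate inputs error early and specifically: empty FASTA records,
  all-N sequences, rotating a linear sequence, empty read sets,
  zero-comparable-column alignments, unsatisfiable injection profiles
  (the error lists the unmet categories).
* Ambiguity codes other than N are normalized to N at ingestion;
  characters outside the IUPAC set error with the offending record named.

## Problem sizes

The test suite exercises full 16.5-kb comparisons where the arithmetic
depends on it (the 14-bp duplication case, the 11,629-bp partial, identity
after rotation) and 2–4.5-kb genomes for the property suites — 100 random
profile round trips, 20 rotation/strand replicates, 50 p-distance oracle
pairs — which keeps the whole suite under a few minutes while covering
every category combination. These sizes are the package's own choice of
desk scale; nothing in the method depends on them.

## Known limitations

* The benchmark assumes one query contig per comparison (multi-contig
  FASTA inputs are reported per contig); fragmented assemblies are not
  scaffolded or merged.
* Exact-anchor orientation normalization fails if the reference start
  region is mutated in the query; the benchmark then warns and aligns the
  query as given.
* The tandem repeat finder is seed–extend with a majority consensus, not
  a probabilistic model; arrays more diverged than ~20% per copy, or with
  periods outside 7–30 bp, are out of its envelope, and array phase is
  reported up to rotation.
* p-distance uses pairwise deletion only; no substitution-model
  correction is applied (appropriate for same-individual comparisons
  where distances are near zero).
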