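---
title: "Methods and design of selexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of selexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexr)
```

`selexr` analyzes multi-round sequencing data from in vitro
selection/evolution experiments. This vignette explains the procedures
the package implements, the parameters that matter, the design
decisions that were genuinely open, and what the synthetic-data tests
do and do not demonstrate.

## Pre-processing model

Each selection round arrives as one FASTQ file of single-end reads
(Sanger encoding: Q = ASCII − 33). As most combinatorial libraries are
shorter than 100 nt, single-end coverage of the randomized region is
assumed; paired-end merging is out of scope. Pre-processing runs in a
fixed order:

1. **Ingestion.** The first `max_reads` raw records are taken, before
   any filtering. Analyzing a prefix subset (e.g. 10,000 or 100,000
   reads) preserves the identities and approximate relative abundances
   of the abundant sequences while bounding run time; statistics are
   then statements about the analyzed subset. gzip is detected by magic
   bytes; a zip container must hold exactly one member, since one
   archive corresponds to one round.
2. **Quality filter.** A read is retained iff the fraction of its
   bases with Q ≥ `q_threshold` is at least `quality_cutoff`/100.
   Defaults `q_threshold = 20` (1% base-call error) and
   `quality_cutoff = 98` implement the common rule that a read with
   more than 2% sub-Q20 bases is discarded. The filter is whole-read:
   no end-trimming by quality, because downstream counting requires
   the full region of interest. Retention is monotone in the cutoff.
3. **Trimming.** Either by coordinates (1-based, inclusive; a read
   shorter than `trim_end` is dropped, not truncated, because a
   partial region cannot be counted as a library member) or by
   flanking constant sequences (the insert strictly between the first
   occurrence of the left flank and the first occurrence of the right
   flank starting after it; missing flanks or empty inserts drop the
   read). Flank matching is exact by default; a `max_mismatch` option
   tolerates sequencing errors in the constant regions but stays 0
   unless the user opts in, so counts are never inflated by fuzzy
   matches silently.
4. **Orientation.** Reads from reverse sequencing runs are batch
   reverse-complemented (after trimming, so the trim window refers to
   the read as sequenced).
5. **Dereplication.** Identical post-trim, orientation-corrected
   sequences collapse into unique sequences with read counts, ranked
   by count. Dereplicating *after* trimming re-aggregates reads that
   differ only in the discarded constant regions — the counts refer to
   the library region, which is what enrichment statements are about.

Reads dropped at trimming are excluded from the high-quality total
`hq_reads`, so the invariant `sum(reads) == hq_reads` holds for every
round table and every downstream fraction has a well-defined
denominator. This accounting choice (rather than counting
quality-passing reads that failed trimming) keeps read-count
conservation testable end to end.

Ranks are made deterministic by breaking count ties lexicographically
in the C locale. Any fixed rule works; determinism matters because
cluster seeding and top-N lists must be reproducible across platforms
and locales.

## Sequence-level analyses

**Selection statistics.** For each round: total reads ingested,
high-quality reads, unique sequences, and
`fraction_unique = unique_count / hq_reads`. A decline across rounds is
the standard signature of sequence enrichment. A round with
`hq_reads = 0` reports `NA` with a warning rather than an error, so one
failed round does not abort a series.

**Top sequences and tracking.** Fractional abundance of sequence *s*
in round *r* is reads(s, r) / hq\_reads(r), 0 when absent. The
high-quality total is used as the denominator (not the raw total):
every analysis operates on the filtered population, so fractions over
the complete entry set sum to 1.

**Motif search.** Patterns use IUPAC codes; the full 15-code alphabet
is accepted (the common cases being A/C/G/T/U, R, Y, N), with U treated
as T. Matching is position-wise over contiguous windows. An `N` in a
*read* is an ambiguous base call, not evidence for any concrete base,
so it satisfies only the pattern code `N`. This is the conservative
choice: motif counts never include reads whose match depends on an
uncalled base. The implementation encodes bases as bit masks and scans
windows; the test suite checks it against an independently constructed
character-class regular expression on thousands of random
sequence/pattern pairs.

**Mutational intermediates.** Given equal-length `source` and
`target`, an observed sequence is an intermediate iff it agrees with
both wherever they agree and carries the source or the target base at
each differing position. This is the Hamming-hypercube notion of
"between": every intermediate satisfies
`hamming(m, src) + hamming(m, tgt) == hamming(src, tgt)`. Sequences
carrying additional mutations outside the differing positions are
excluded by default; a `max_extra_mutations` option reports them
flagged `strict = FALSE` as an explicitly labelled extension, and they
never participate in path search. Neutral paths are Hamming-1 chains
from source to target whose interior vertices were all observed; the
betweenness constraint layers the graph by distance from the source, so
a backward reachability sweep followed by forward enumeration yields
only completable paths, all of minimal length, capped at `max_paths`
(default 100) to bound output. The cap cannot hide the existence of a
path because unreachable vertices are pruned before enumeration.

## Cluster-level analyses

**Clustering algorithm.** Greedy abundance-seeded single-pass
clustering: take the most abundant unassigned sequence as a seed
(peak), assign every unassigned sequence within `max_edit_distance`
(Levenshtein, via `utils::adist`) of the seed, repeat up to `k ≤ 50`
times. Levenshtein rather than Hamming tolerates indel sequencing
errors; a Hamming mode exists for equal-length data. The method is
deterministic, fast at desk scale, and guarantees by construction that
each peak is its cluster's most abundant member and that every member
lies within the radius of its peak. It is a local, radius-based
partition — not a multiple alignment or an iterative optimizer — so
families wider than the radius can split, and two founders closer than
the radius can merge.

The default radius of 7 for a 40-nt region reflects the mutational
load typical of an enriched family (a mutant cloud a few substitutions
deep plus occasional indels); it is a required-review parameter in the
CLI because the right value depends on library length and error rate.

**Cluster numbering and rank.** Clusters are numbered from 0 in seed
order, so cluster 0's peak is always the globally most abundant
sequence and peak read counts are non-increasing in cluster id. A
later seed can nevertheless accumulate a larger *total* of member
reads, and "the most abundant cluster" for conservation analysis is
most naturally read as cluster mass. The two orderings usually
coincide on enriched data but can differ, so both are exposed:
`cluster_id` (seed order) and `mass_rank` (total member reads,
descending, ties by peak reads then peak sequence). Cluster rank R — as
in "analyze the most abundant cluster, R = 1" — refers to `mass_rank`.

**Conservation.** For one cluster of equal-length members, the L × 4
frequency matrix weights each member by its read count by default:
reads carry the selection signal, and the question posed is about the
selected population. The unweighted mode (one vote per unique
sequence) is exposed because read counts also encode amplification
bias. `N` bases are excluded from both numerator and denominator at
their position, so rows remain stochastic over called bases; rows sum
to 1 within 1e-9. The consensus takes the per-row argmax, with ties
mapped to the IUPAC code of the tied set — deterministic and
information-preserving, instead of an arbitrary pick. Information
content is raw Shannon information, `2 + Σ_b f_b log2 f_b` bits with
`0·log 0 = 0`; no small-sample correction is applied, so logos from
very few sequences overstate conservation — the matrix carries
`n_sequences` so users can judge. Letter heights are frequency ×
information, and each row's heights sum to its information content.

## The synthetic-data generator

`simulate_selection()` emulates the data a multi-round selection
produces, with exact ground truth:

* a 40-nt randomized region embedded between constant flanks so that
  it occupies read positions 32–71 — the geometry of a typical
  selection amplicon;
* five founder sequences whose per-round fractions follow programmed
  trajectories (top founder 0.01 → 0.05 → 0.25 → 0.40 over four
  rounds, enrichment becoming evident in round 3), the remainder being
  uniform random background;
* multinomial read assignment per round (10,000 reads by default);
* substitution-only mutation of founder reads at 0.005/base by
  default, producing the mutant clouds clustering must handle while
  keeping Hamming-based oracles exact;
* a two-state quality model: 5% of reads are entirely low quality
  (Q = 12) and fail the 98%/Q20 filter, the rest entirely good
  (Q = 37) and pass. A whole-read model suffices because the only
  quality computation in scope is the whole-read fraction rule;
* optional reverse orientation, emitting each read as the reverse
  complement of flank + region + flank.

The generator is deterministic given its config (seed included), and
returns every read's origin, emitted region and quality state, so
tests can assert exact equality between pipeline output and ground
truth — not just statistical agreement.

What it does **not** emulate: realistic Illumina error spectra
(position- and context-dependent errors, quality-score gradients),
PCR amplification bias, chimeras, or paired-end artifacts. Passing the
synthetic suite therefore demonstrates algorithmic correctness of the
pipeline — counting, filtering semantics, clustering geometry,
conservation arithmetic, determinism — not robustness to every failure
mode of real sequencers.

## Numerical and degenerate-input choices

* Quality encoding is fixed to Phred+33; Phred+64 data must be
  converted upstream. Characters below ASCII 33 raise an error.
* Coordinates are 1-based inclusive throughout (positions 32–71 of a
  read denote a 40-nt window).
* Empty rounds, empty tables, zero-length reads, and patterns longer
  than the sequence all return well-defined empty/false results or
  logged skips rather than errors, except where the input is
  structurally invalid (malformed FASTQ records error with the record
  index; unequal lengths error in Hamming and conservation contexts).
* Conservation row-sum tolerance is 1e-9 (pure floating-point
  accumulation over at most a few thousand members).
* All orderings (dereplication ranks, cluster order, mass ranks,
  intermediate tables) use explicit deterministic tie-breaks, so
  reruns and permuted inputs yield byte-identical CSVs.

## Problem sizes in the test suite

The suite validates invariants at sizes chosen to exercise the
algorithms well beyond the toy regime while keeping a full run around
half a minute on one core: dereplication against a naive counting
oracle at 2 × 10^4 reads, quality filtering and motif matching against
brute-force/regex oracles at 10^4 random cases, intermediates against
exhaustive hypercube enumeration up to d = 10 differing positions, and
enrichment recovery on the default 4 × 10,000-read simulation, where
recovered founder fractions are required to sit within three binomial
standard deviations of the programmed values (with the substitution
rate set to zero in that fixture, so sampling error is the only noise
source).

## Known limitations

* The read cap takes the *first* N records; if the sequencer output is
  order-biased, the subset is too.
* Greedy clustering is order-dependent by design (abundance order);
  it does not optimize any global objective and has no notion of
  cluster merging.
* Motif search is sequence-level only; structural motifs formed by
  divergent sequences (stem-loops, pseudoknots) are out of scope.
* Enrichment is descriptive (fractions across rounds); no significance
  testing is attempted.
* Neutral-path search is restricted to strict betweenness
  intermediates; paths that detour outside the source/target hypercube
  are not found.
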