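---
title: "Detecting internal tandem duplications from unmapped and soft-clipped reads"
author: "itdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal tandem duplications from unmapped and soft-clipped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model and rationale

An internal tandem duplication (ITD) of length $L$ copies a reference
segment and inserts the copy immediately after the original. Reads that
contain or span the junction between the two copies fail standard
alignment: they are flagged unmapped or survive only as soft-clipped
fragments. `itdscan` therefore works exclusively on that residue of the
alignment, which makes it sensitive to events other callers discard, and
independent of mate-pair information.

Two structural facts drive the method. First, a read containing both
copies of any $k$-mer of the duplicated segment carries that $k$-mer
twice, exactly $L$ positions apart; a read's *repeat-distance* set (the
distances between consecutive occurrences of each duplicated
`p_kmer`-mer) is thus a cheap, alignment-free signature of the event and
of its length. Second, in a De Bruijn graph built from reads of one
repeat-distance bin, a genuine duplication of length $i$ induces a closed
walk of exactly $i$ edges, while coincidental repeats scattered across
unrelated reads do not survive the vertex-coverage cutoff. Membership of
a vertex in some length-$i$ closed walk is read off the diagonal of the
$i$-th power of the boolean adjacency matrix, computed by
exponentiation-by-squaring over the boolean semiring — $O(\log i)$ matrix
products, no overflow by construction.

Assembly is deliberately *not* De Bruijn-based: kmer graphs collapse
tandem copies. Each bin's surviving reads are assembled by a greedy
overlap-layout-consensus procedure, which preserves both copies, and each
contig is then reduced to reference coordinates by deleting the region
between its duplicated `d_kmer` pair and locally aligning the collapsed
contig to the reference.

### Closed walks, not simple cycles

Powering the adjacency matrix detects closed *walks* of length $i$, a
superset of simple cycles. Fixed-length simple-cycle detection is
NP-hard in general; the walk relaxation is exactly what the matrix
power computes and is the quantity our detection claim needs (a tandem
duplication induces a genuine cycle, which is in particular a closed
walk). The cost is that a bin whose graph contains, e.g., both a 3-cycle
and unrelated structure could allow a length-6 walk; such bins are still
disciplined by the subsequent assembly and collapse/alignment checks,
which must reproduce a duplication of the bin length from actual reads.

### Vertex coverage

Vertex coverage counts kmer *occurrences* across the bin (a kmer seen
twice in one read counts 2), consistent with a worked three-read example
whose printed vertex coverages exceed the read count. Cutoffs apply to
vertices only; edges are unweighted.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `p_kmer` | 10 bp | partial-duplication kmer; events duplicating less than `p_kmer` of the unit are invisible |
| `d_kmer` | `p_kmer` | De Bruijn kmer; must be ≥ `p_kmer`; larger values shrink the graph but raise the partial-detection floor |
| `r_min`, `r_max` | 15, 61 bp | bin range = detectable duplication lengths; `r_max` is capped at read length − `p_kmer` at run time |
| `cov_cutoff_min/max` | 2, 10000 | kmer-coverage window for graph vertices; the floor drops singleton (error) kmers, the ceiling guards against low-complexity blowup |
| `max_n` | 50 | absolute N-count filter per read |
| `max_homopolymer` | 14 bp | longest retained single-base run |
| `min_overlap`, `min_identity` | 15 bp, 0.95 | assembly overlap thresholds |
| `min_clip` | 4 bp | smallest soft-clip treated as a candidate |
| `light` | off | skip the De Bruijn stage entirely (lower memory; more reads reach assembly) |

`itd_params(preset = "flt3")` reproduces the published FLT3 cohort run:
`p_kmer = d_kmer = 15`, coverage window 30–200, range 15–85. A coverage
floor of 30 at ~150× depth corresponds to requiring allele fractions of
roughly 0.2 and up; the package default floor of 2 favours sensitivity on
the small, clean simulations used in tests.

## The simulator: what it emulates, what it does not

`simulate_reads()` draws single-end reads of fixed length uniformly (in
position and strand) from a mixture of the reference allele and one
mutant allele per configured duplication, with mixture weights equal to
the allele fractions, and applies substitution errors at a configurable
rate. Defaults mirror exome-like practice: 75–100 bp reads, ~100×
coverage.

Aligner behaviour is replaced by a deterministic surrogate: a read
reaching ≥ 4 bp beyond a junction of the duplicated copy on both sides is
emitted unmapped; a read overhanging a junction by 1–3 bp is emitted
mapped with the overhang soft-clipped; everything else is mapped at its
reference position. This reproduces the failure mode that makes ITDs
invisible to pileup callers, deterministically and byte-reproducibly
under a fixed seed. It does **not** emulate: paired-end fragments,
quality-score structure, indel errors (substitution-only, so that error
handling is not conflated with the duplication signal), PCR duplicates,
mapping-quality noise, or a real aligner's partial-alignment choices —
in particular the surrogate's soft-clips are always shorter than the
4 bp extraction threshold, so the soft-clip path is exercised by
hand-built SAM records in the tests rather than by the simulator. A
green end-to-end test therefore establishes the algorithm's behaviour on
idealized alignment residue, not robustness to any particular aligner.

References are uniform random sequence with homopolymer runs ≥ 15
regenerated, so fixtures are never silently lost to the homopolymer
filter; real genomes have low-complexity and repetitive structure the
simulator does not model.

## Numerical and design choices

* **Repeat distances are consecutive-occurrence distances**, not all
  pairwise distances: a tandem duplication places copies exactly $L$
  apart in adjacent occurrences; pairwise distances from 3+ occurrences
  would create spurious bins at multiples of $L$.
* **Strand handling.** Repeat distances are strand-invariant (asserted
  property), so binning uses each read as given; orientation is resolved
  in assembly (overlaps are computed in both orientations) and again at
  alignment (both strands of the collapsed contig are tried).
* **Overlap discovery is seeded**: candidate offsets come from exact
  shared 12-mers (length `min(12, min_overlap)`), verified by direct
  comparison. Overlaps lacking an exact seed of that length are not
  found; at 1% substitution error and ≥ 15 bp overlaps this loss is
  negligible.
* **Determinism.** Overlaps are merged in a total order (score = length ×
  identity, then longer, then lexicographic read ids); consensus ties
  resolve to the base carried by the lexicographically smallest covering
  read; contigs are numbered by smallest member read id. Identical input
  (any record order) yields identical output; parallel per-bin execution
  reproduces the serial call set.
* **Alignment acceptance.** The collapsed contig must align locally
  (match 1, mismatch −2, gap −3/−1) with identity ≥ 0.95 over ≥ 90% of
  its length, and beat the best alignment elsewhere (recomputed after
  masking the best locus, both strands) by ≥ 10 score units — an
  operational definition of "high mapping specificity", which the source
  method never quantifies. Identity is computed over alignment columns
  including gaps, so a contig whose "duplication" is actually present in
  the reference (collapse then removes real sequence) generally fails
  here or is classified `non_insertion` by the ≤ 2 bp contiguity rule.
* **Breakpoint canonicalization.** Tandem-duplication breakpoints are
  ambiguous wherever flanking bases match the copy; every call is
  left-normalized (`normalize_dup_locus`) and truth comparisons use the
  same canonical form. At the extreme length `L = read_length − p_kmer`
  exactly one read start position carries the full signature; when it is
  unsampled the contig cannot span the whole event and the breakpoint
  anchor can sit 1–2 bp inside the true interval even though the event —
  length and locus — is detected. The acceptance script scores such
  boundary cases by event identity (exact length, overlapping locus);
  interior lengths are asserted at the exact canonical locus.
* **Allele-fraction denominator.** The source defines the fraction as
  junction-supporting reads over "total coverage over the target" without
  a counting rule. Support = constituent reads of the contig spanning the
  junction ± 5 bp; depth = primary-alignment depth at the insertion point
  *plus* the support (junction reads are unmapped and carry no
  coordinates, so mapped depth alone would exclude exactly the
  ITD-supporting reads and could exceed 1 when inverted).
* **Complex events.** After a collapse, the contig is rescanned (up to
  three rounds) so two duplications assembled into one contig yield two
  calls; coordinates of earlier events are shifted past later removals.
* **Degenerate inputs.** Empty candidate sets, empty bins and empty
  graphs propagate as empty results, not errors; unmapped records with
  missing sequence and reads under 20 bp are skipped with a warning;
  duplicate-marked, secondary and supplementary alignments are ignored.

## What the tests establish

Property suites check the two algorithmic cores against independent
oracles: repeat distances against an all-pairs $O(|S|^2 k)$ scan on
strings ≤ 200 bp, and matrix-power closed-walk detection against a
step-by-step reachability DP on random digraphs ≤ 30 vertices. End-to-end
suites establish exact recovery (canonical locus and length) of implanted
duplications across the entire detection range $[r_{\min}, R - p_{kmer}]$
on error-free 40-bp-read simulations, ≥ 95% recovery over 20 seeds at 1%
error, 100×, allele fraction 0.5, and the boundary laws: nothing below
`p_kmer` (floor 10 with `p_kmer = 10`), nothing above
$R - p_{kmer}$ (60 for 75-bp reads at `p_kmer = 15`). Simulations are
deliberately desk-scale (references of 300–10000 bp); cohort-scale
results from the original study are out of scope.

## Known limitations

Detection is bounded by read length: duplications longer than
`read_length − p_kmer` leave no within-read signature. Partial
duplications shorter than `p_kmer` are invisible. The greedy assembler
can in principle misjoin reads whose overlap lies entirely inside the
periodic region (the identity check rejects this whenever the overlap
crosses a copy boundary, which signature reads always do). Low-complexity
bins inflate graph size and assembly time; the coverage ceiling and the
homopolymer filter are the guards. RNA validation counts junction-
crossing reads on the contig and applies an expression floor of 10
aligned reads; it does not model splicing.
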