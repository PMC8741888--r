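---
title: "Microsatellite marker discovery from pooled libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite marker discovery from pooled libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmarkers)
```

## The problem

Microsatellites (SSRs) are short tandem repeats — units of 1–6 nt — whose
copy number varies between individuals, making them workhorse markers for
population genetics. Developing markers from a *single* individual is easy
but risky: a locus monomorphic in that individual may be monomorphic in the
population, and the wet-lab investment is wasted. Sequencing a *pooled,
untagged* library of many individuals solves this — polymorphic loci reveal
themselves as clusters of reads with identical flanking sequence but
different repeat counts — at the cost of a data-analysis problem: reads
must be cleaned, merged across the repeat, grouped by their true genomic
locus without a reference genome, and screened for allele-count evidence of
polymorphism before primers are designed.

`ssrmarkers` implements that whole path as one auditable pipeline: every
stage is an exported, individually testable function over tibbles, and a
bundled library simulator with a ground-truth manifest lets the pipeline be
scored against known answers.

## Pipeline model, stage by stage

**Trimming.** 3' adapters are located by a substitution-only semi-global
scan: the adapter prefix is laid over every start position, the match
length clipped at the read end, and the leftmost position whose mismatch
rate is at most `adapter_max_error_rate` (default 0.10, minimum matched
length 3) is cut. Quality trimming then slides a `window` of 4 bases 5'→3'
and cuts at the first window whose mean Phred score drops below
`trim_min_q` = 15; reads shorter than `trim_min_len` = 36 are dropped.
These are the conventional defaults of widely used trimmers; all are
configurable. Indel-tolerant adapter matching was deliberately left out:
substitution errors dominate the targeted Illumina chemistry, and the
substitution-only rule has an exact brute-force oracle.

**Pair merging.** The mate is reverse-complemented and every overlap length
`L ≥ merge_min_overlap` (default 10) is scored by mismatch density; the
lowest density wins, ties going to the *longer* overlap, and the merge is
accepted when density ≤ `merge_max_mismatch_density` (default 0.25).
Consensus takes the higher-quality base at disagreements (quality =
|q1−q2|) and the max quality at agreements. The longer-overlap tie-break
matters in this application: repeats make self-similar overlaps common, and
a deterministic rule that prefers the maximal overlap avoids repeat-count
shifts that would fabricate alleles. Mates with byte-identical sequence are
passed through unchanged — that is the single-end mode (supply the same
FASTQ twice).

**Filter 1 — restriction pattern.** Libraries built by enzymatic digestion
retain the residual recognition site at fragment ends, so its presence
authenticates a read as a real digest fragment. The default anchor is
`either` end; `anywhere` is available, and an empty pattern disables the
filter for mechanically sheared libraries.

**SSR mining.** The miner reports maximal perfect repeats of primitive
units of length 1–6 with per-unit-length minimum repeat counts
`{10, 6, 5, 5, 5, 5}` (the de-facto defaults of standard SSR search
tools). The exact semantics are pinned down because edge cases are
otherwise ambiguous: a hit is the leftmost whole-unit run inside a maximal
periodic stretch; units containing `N` or equal to a repetition of a
shorter unit are never reported; overlapping candidates of different unit
lengths are resolved left-to-right, shortest unit first. Adjacent runs
join into compounds: gap 0 gives type `c`, gap 1..`compound_max_gap`
(default 100) gives `c*`; a compound's lattice step (`unit_len`) is the
smallest constituent unit, its `repeats` the largest constituent run. The
paper-facing literature names both compound types without defining the gap
rule, so this reading is isolated in one function (`join_compound()`) and
documented as a choice.

**Filter 2 — candidate selection.** A sequence passes when exactly one
repeat (after type exclusions and the `min_motif_repetition` floor)
qualifies with both flanks at least `min_flank_len` (default 50 bp).
Sequences with several independent qualifying repeats are rejected rather
than arbitrated: downstream clustering excises *one* repeat region per
sequence, and keeping the "best" of several would make locus identity
ambiguous.

**Clustering.** The repeat span is excised and the concatenated flanks form
the locus signature. Signatures are clustered greedily, longest first: each
joins the first existing cluster seed with identity ≥ `cluster_identity`
(default 0.90), else founds a new cluster. Identity is defined as
1 − Levenshtein distance / shorter length (floored at 0): deterministic,
parameter-free, and exactly 0.90 for a 100-mer with 10 substitutions. A
word filter (`cluster_word_size` = 10) skips seed comparisons only when a
q-gram bound on the edit distance (or the length difference) already proves
the threshold unreachable, so the filtered and unfiltered partitions are
identical by construction — the tests assert this against an
`utils::adist`-based reference. Greedy first-fit assignment against seeds
mirrors the standard incremental clustering scheme; the arbitrariness of
seed choice is inherent to that scheme and is why runs are made
deterministic (length-descending order, ties by input order).

**Filter 3 — cluster selection.** Kept clusters need at least
`cluster_min_members` = 2 members: singleton clusters cannot show
polymorphism. An optional motif-consistency check drops clusters whose
members disagree on the canonical (rotation-normalised) repeat unit; it is
off by default because a single sequencing error that alters a motif can
otherwise discard an entire true locus.

**Allele tabulation and locus selection.** Within a cluster, an allele is a
distinct full merged-sequence length — flank length is effectively constant
inside a 90%-identity cluster, so length differences are repeat-number
differences. `observed` is the count of distinct lengths;
`potential = floor((max − min) / unit_len) + 1` counts the lattice
positions of step `unit_len` between the extreme alleles, i.e. the alleles
the wider population could plausibly harbour given the extremes sampled in
the pool (off-grid gaps from flank indels are tolerated by the floor, not
fatal). Selection keeps loci with `observed ≥ min_allele_cnt` (default 5);
enabling *Special Search* **replaces** that criterion with
`potential ≥ special_min_potential` (default 8) — replacement, not
conjunction, because the alternative cannot admit loci that the default
rejects, and admitting sparsely sampled but widely spread loci is the
stated purpose of the option. A diploid pool of N individuals can show at
most 2N alleles per locus (`max_pool_alleles()`); counts near that cap
warrant suspicion of clustering artefacts.

**Representative and primers.** One sequence per locus is drawn uniformly
among the cluster's *distinct* variants (deduplicated, so abundant alleles
get no extra weight) with a seeded generator. The repeat span is then
re-detected on the representative itself rather than trusted from the
member read — upstream spans can be mis-anchored relative to the sequence
primers are designed on. Candidates are every substring of length 18–27
(optimum 20) with GC 20–80%, homopolymers ≤ 4, no internal complementary
stretch over 8, and Tm 57–63 °C (optimum 60). Melting temperature uses
unified nearest-neighbor thermodynamics (per-stack ΔH/ΔS with terminal
initiation terms and the symmetry correction), total strand concentration
50 nM (C/4 in the ln term for non-self-complementary oligos) and the
0.368·(N−1)·ln[Na+] entropy correction at 50 mM monovalent salt; the test
suite holds it within 0.5 °C of an independently computed frozen reference
panel (in practice it agrees to <1e-4 °C). Pairs must not overlap each
other, must span the whole repeat, satisfy the product size range
(100–300 bp) and |ΔTm| ≤ `max_diff_tm` (default 0.5 °C), and are ranked by

```
penalty = Σ_primers (|Tm − 60| + 0.25·|len − 20|) + 2·|ΔTm|
```

with deterministic tie-breaks (smaller product, then leftmost positions).
The weights are an explicit simplification of the reference tool's larger
weighted objective — the sources treat primer design as a black box — and
are configurable. The top `primer_num_return` = 5 pairs are reported, the
rank-1 pair flagged `|BEST|`. A locus whose representative yields no
acceptable pair is dropped and counted, which is why "Primers selected"
can fall below "Unique loci". Requiring primers to avoid the repeat
entirely (`avoid_primer_in_ssr`) is an opt-in post-filter: it prevents
unusable primers inside the repeat at the cost of discarding loci that a
manual redesign could have saved.

## What the simulator emulates — and what it does not

`simulate_library()` generates the library the pipeline assumes: fragments
`site ++ left flank ++ unit×repeats ++ right flank ++ site` with ligated
adapters, 36 diploid individuals drawing two alleles each per locus,
di-/tetranucleotide motifs, 250 bp paired reads that overlap across the
repeat (fragment sizes are validated against `2·read_len − min_overlap`),
uniform per-base substitution errors (default 0.001) and plausible
qualities. Flanks are rejection-sampled so that no incidental repeat
passes detection thresholds, junction bases cannot extend the planted
repeat, and cross-locus signature identity stays below 0.78 — simulation
artefacts must not masquerade as pipeline errors.

It deliberately does **not** model PCR stutter, indel sequencing errors
(available as future work; substitutions dominate the targeted chemistry),
enrichment bias, chimeras, or allele-frequency structure (genotypes are
drawn uniformly). Passing the recovery tests therefore demonstrates that
the pipeline's logic is correct under its own data model — exact allele
recovery on error-free input, high recall at realistic substitution rates
— not that real libraries, whose stutter and indels blur allele lengths,
will yield the same exactness.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; the results table is
  human-facing (`min-max` ranges, `(UNIT)count` motifs, Tm at 2 decimals).
- Identity comparisons use a 1e-12 tolerance on the ≥ threshold so that
  exact-boundary cases (e.g. 0.90) are joins, and ΔTm uses 1e-9 against
  `max_diff_tm`.
- Merging prefers the longer overlap on density ties; consensus base ties
  (equal qualities) take the forward read's base.
- Empty inputs are normal: an empty FASTQ completes with all-zero counts;
  zero selected loci produce a header-only results table; unmerged pairs,
  dropped reads and primer-less loci are counted outcomes, with
  kept + dropped = input asserted at every stage.
- All randomness (representative draw, simulator) flows from explicit
  seeds; identical seed and input give byte-identical output.

## Validation scale

The bundled checks run the full pipeline on simulated libraries of 20 loci
× 36 diploid individuals at coverage 3 (4,320 read pairs) for parameter
recovery, 10,000 fragment reconstructions for merge completeness, 1,000
planted 300-mers against the exhaustive mining oracle, and 200 signatures
against the alignment-oracle clustering reference — sizes chosen to
exercise every code path at full fidelity while keeping a complete run in
minutes on one core.

## Known limitations

- Allele identity is sequence *length*; two alleles of equal length with
  different internal composition (rare within one locus) are counted once.
- The compound-gap threshold and Filter 3 semantics are documented
  interpretations of under-specified descriptions in the source material
  for this class of pipeline; both are isolated behind single functions
  and configurable.
- Greedy clustering depends on seed order (inherent to the scheme); the
  pipeline makes it deterministic rather than order-free.
- Tm modelling covers perfectly matched duplexes only — no hairpin or
  cross-dimer ΔG, no divalent-cation or dNTP corrections.
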