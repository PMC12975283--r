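---
title: "UMI deduplication: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI deduplication: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `umidedup`, the
parameters that matter, and the design decisions taken where more than
one defensible choice existed. The package does three things: it
collapses UMI-tagged alignments to one representative read per template
molecule, it simulates benchmark data with known ground truth, and it
scores variant calls against that truth.

# The deduplication model

## Grouping

A template molecule is identified by where its reads map, not only by
its barcode: two identical UMIs at different positions are different
templates. Records are therefore partitioned by
`(reference, corrected 5' start, strand)`, where the corrected start
undoes soft clipping — `POS - leading clip` on the forward strand and
`POS + reference-consumed length + trailing clip - 1` on the reverse
strand. Without this correction, adapter- or quality-trimmed reads from
one template scatter across neighboring keys. Strand is part of the key
by default (`ignoreStrand = FALSE` to disable); with
`lengthStratify = TRUE` the exact read length joins the key, which keeps
variable-length shotgun fragments with coincident 5' ends apart. For
paired data the unit is the template: mates are joined by name and keyed
on read 1. Secondary, supplementary and unmapped records are dropped and
counted; coordinate-unsorted input is a fatal error rather than a
warning, because grouping silently fragments on unsorted input.

## UMI error correction

Within one position group, the observed UMI multiset is explained as a
few true barcodes plus their mutated copies. Because barcodes are fixed
length and the dominant error process is substitution, distance is
Hamming (an `N` mismatches everything, including another `N` — ambiguous
positions never argue *for* merging). Neighbor search uses a BK-tree,
a metric tree whose triangle-inequality pruning makes radius-1 queries
cheap even with tens of thousands of distinct UMIs in one group.

*Directional* clustering processes UMIs in descending count order (ties
broken lexicographically, C locale, for determinism) and absorbs an
unassigned neighbor `v` of any current member `u` when
`count(u) >= m * count(v) - 1` with `m = 2` by default, continuing to
closure. The `2n - 1` form encodes the expectation that an error copy is
much rarer than its source; the multiplier is exposed
(`thresholdMultiplier`). Testing the rule against the absorbing member —
not the root — is what makes the mode iterative: a chain
`root -> child -> grandchild` may merge even if the grandchild is two
edits from the root. *Acyclic* mode is the one-hop restriction (only
root-adjacent UMIs, threshold against the root), trading sensitivity for
protection against over-collapsing when UMIs are long or PCR cycles few.
*Raw* mode applies no correction. The absorbed set of a closure is a
least fixed point, so the partition does not depend on traversal order;
together with the sorted processing order the whole clustering is a pure
function of the count mapping.

## Consensus and sparse clusters

Each cluster emits an **existing read**, not a synthetic per-column
consensus: the read (pair) whose full sequence is the modal sequence of
the cluster. Mapping quality deliberately plays no role in choosing the
sequence — MAPQ measures alignment confidence against a reference, and
in deep clusters many reads tie at the maximum, so MAPQ-based selection
degenerates to an arbitrary pick that can fixate a sequencing error.
MAPQ is used only to choose among reads that already carry the winning
sequence (then name, lexicographically, for full determinism). A count
tie between distinct sequences is broken toward the lexicographically
smallest sequence; this is an explicit, deterministic convention, and
its consequences in small clusters are discussed under *Limitations*.

Clusters with one or two reads are discarded by default: with fewer than
three observations the majority vote cannot out-vote a single errored
read, and such clusters are largely products of UMI errors in the first
place. `keepSingletons = TRUE` retains them when sensitivity matters
more than precision; `minReads` generalizes the threshold.

Overlapping mates of a retained template can be merged
(`mergePairs = TRUE`) into one fragment-spanning record: overlap located
by alignment coordinates only (M-only CIGARs; indel-aware realignment is
out of scope — pairs with clips/indels are left unmerged and counted),
agreeing bases keep the higher quality, disagreements take the
higher-quality base (ties go to read 1) with quality `|q1 - q2|`, the
standard read-merger convention.

# The simulator

The generator mimics an amplicon UMI protocol: `N` template molecules
(default 30000) over a reference (default 500 bp, random unless given),
single-nucleotide variants planted at exact allele frequencies — each
variant is assigned to exactly `round(f * N)` carriers, sampled
independently per variant, so planted frequencies are exactly
recoverable — then per-template fragmentation, UMI tagging, PCR and read
simulation, in that order. Fragmentation *precedes* tagging and
amplification, as in the laboratory protocol; this is what makes all
PCR copies of a template share coordinates and hence a position group.

**Fragment geometry.** The default is `fragment = "amplicon"`: the
fragment is the whole template and paired 2 × 250 bp reads tile a 500 bp
amplicon exactly, so every planted variant is covered by every carrier.
This mirrors amplicon-based UMI designs for viral populations, where a
fixed region is amplified and read end-to-end. A shotgun-style mode
(`fragment = "normal"`, length ~ Normal(`fragmentMean`, `fragmentSd`)
truncated to `[R, template]`, uniform start) is provided, but note that
with it a low-frequency variant can fall outside all of its carriers'
read windows, making recall a random variable of the design rather than
of the method.

**PCR.** Amplification is a branching process: each cycle, every
molecule is copied with probability `e` (default 0.9), giving expected
pool growth `(1 + e)^c` (7 cycles by default; `1.9^7 ≈ 89` expected
copies per template). Replication errors occur at `mu` (default 1e-6)
per base per copy event. Two error models are implemented:

* `errorModel = "replication"` (default): the simulator tracks each
  final molecule's ancestral replication count `r` and draws its errors
  as Binomial(insert length, `r * mu`) independently per molecule. This
  reproduces the correct marginal error rate while keeping errors
  independent across molecules.
* `errorModel = "lineage"`: errors are drawn at each copy event and
  inherited by all descendants of the erroneous copy, so an early-cycle
  error can come to dominate a family.

The default is the independent model. The reasoning: a first-cycle
replication error under full inheritance reaches roughly half of its
family, so with `N * e * L * mu ≈ 13` first-cycle errors in a default
run, lineage inheritance makes ~6 clusters emit a mutant consensus *by
construction* — an effect of simulator topology, not of the
deduplication method under study. Holding the marginal error rate fixed
while removing lineage correlation isolates the method's behavior; the
lineage model remains available to study the confounded regime.

**Sequencing.** Each pool molecule yields one read pair (a configurable
`yield` fraction subsamples). Read bases substitute uniformly at
`seqErrorRate` (default 1e-3, written as the matching Phred quality,
Q30); the UMI copy carried into the read name substitutes independently
at `umiErrorRate` per base (default 0.005, an Illumina-class barcode
error rate), so the fraction of pairs with a perturbed UMI follows
`1 - (1 - eps)^L` (≈ 4.9% at defaults). UMIs are uniform over
`{A,C,G,T}^L` (default L = 10); collisions are permitted and counted —
they are a real feature of finite barcode spaces (expected
`N^2 / (2 * 4^L)`, ≈ 1.4% of templates at defaults) — and a warning
fires only when the expected collision count exceeds 5% of templates,
i.e. when the design itself is degenerate.

**Truth and outputs.** The truth table (0-based position, ref, alt,
frequency, carrier count) serializes as TSV with plain-decimal
frequencies (`0.0001`, never `1e-04`) and as VCF 4.x with the simulated
frequency in the `AF` INFO field. Reads can be written as paired FASTQ
(mate 2 reverse-complemented) or directly as a truth-placed,
coordinate-sorted BAM: simulated reads carry substitutions only, so
their optimal alignment is their generating coordinates, and read
mapping itself is outside the package's scope.

**What the simulator does not model:** indels (excluded by design, to
isolate substitution-level error correction), platform-specific
quality-by-cycle profiles, GC or position-dependent amplification bias,
chimeras, and duplex (two-mate) UMI designs. Passing tests on this
generator therefore demonstrate correctness of the clustering/consensus
machinery under a substitution-only error model, not robustness to every
artifact of real libraries.

# Evaluation

The caller is a deliberately threshold-free pileup: every non-reference
allele with at least `minAltReads` (default 1) supporting reads becomes
a call. Any frequency floor would mask exactly the singleton-driven
false positives that sparse-cluster handling is supposed to remove, so
the default hides nothing. Scoring matches calls to truth by exact
position *and* alternate allele; precision, recall and F1 use the
conventional 0 fallback when undefined. `frequencyConcordance()` reports
mean observed frequency and relative bias per planted-frequency stratum,
with empty strata reported as such rather than dropped.
`clusterStats()` summarizes cluster structure: size histogram, the
fraction of reads differing from their cluster's dominant sequence (with
a mismatch-count histogram; length-deviant reads land in an `"other"`
bucket), the fraction of clusters with two or more reads tied at maximal
MAPQ (the ambiguity MAPQ-based selection cannot resolve), and the
sparse-cluster fraction.

# Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; BAM/VCF conventions
  apply only at file boundaries.
* All string orderings (UMI tie-breaks, sequence tie-breaks, name
  tie-breaks) use C-locale radix order, so results are independent of
  the session locale.
* Empty inputs flow through: an empty BAM deduplicates to a valid
  empty-body BAM with intact header and all-zero statistics; an empty
  SNV specification yields header-only truth files.
* Unequal-length sequences never enter a Hamming comparison: clustering
  refuses them (stratify first), divergence statistics bucket them as
  `"other"`.
* The abundance rule compares `count(u) >= m * count(v) - 1` in floating
  point with a 1e-9 slack so non-integer multipliers behave predictably.
* `threads` is accepted for interface compatibility and echoed in the
  run summary; the implementation is sequential and its output is
  defined without reference to any partitioning, so results are
  thread-count invariant by construction.

# Problem sizes used by the test suite

The suite exercises the full pipeline at 30000 templates / 5 PCR cycles
(~7.4 × 10^5 read pairs) once per session and shares that run across
checks; property tests run 10^4 random clustering instances against a
brute-force reference, 10^4 branching-process replicates against the
closed-form mean, and smaller seeded simulations (10^2–10^3 templates)
for zero-noise exactness, idempotence and determinism. These sizes were
chosen to keep a full run in single-digit minutes on one CPU while still
covering the regimes where the algorithms differ.

# Limitations

* **Small families defeat majority voting.** A cluster of 3–6 reads in
  which every read carries at least one sequencing error has no
  error-free majority; whichever read wins contributes its errors to the
  output, and a threshold-free caller will report them. With
  ~`(1 + e)^c` expected reads per family, few-cycle designs (c ≤ 5 at
  e = 0.9) leave a non-negligible mass of such clusters, while c = 7
  pushes the expected family size near 90 and the effect essentially
  vanishes. This is a regime property of any
  emit-an-existing-read consensus, not an implementation artifact;
  raising `minReads`, sequencing deeper, or per-column consensus (out of
  scope here) are the standard mitigations.
* Frequency-based representative selection can fixate an early PCR
  error if one dominates a cluster (observable with
  `errorModel = "lineage"`).
* Cell-barcode + UMI composite designs and dual-UMI (per-mate) designs
  are not supported; one UMI per template is assumed.
* Pair merging is coordinate-arithmetic only; indel-containing or
  clipped mates are written unmerged.
* Spliced alignments collapse by the CIGAR rule only; there is no
  RNA-specific position handling, and CRAM is not read.
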