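# umidedup

UMI-aware deduplication and error correction for amplicon and shotgun
sequencing, with a built-in PCR/sequencing simulator and a
precision/recall evaluation layer.

## The problem

Unique molecular identifiers (UMIs) are short random oligonucleotides
ligated to template molecules before PCR, so that all reads descending
from one template share a barcode. Collapsing each UMI family back to a
single representative enables molecular counting and suppresses
PCR/sequencing errors — critical when the signal of interest is an
ultra-low-frequency single-nucleotide variant (0.01%–1%), as in viral
quasispecies or circulating tumor DNA work. Two practical failure modes
dominate:

* **UMI errors** create spurious families: a sequencing error inside the
  barcode splits one template into several apparent templates. These are
  corrected by merging low-count UMIs into nearby high-count UMIs.
* **Sparse clusters** (one or two reads per UMI after correction) carry
  too little depth for consensus error correction; retaining them floods
  downstream variant calling with false positives.

`umidedup` implements the full workflow:

1. **Grouping** — stream a coordinate-sorted BAM, parse the UMI from each
   read name (last `_`-separated token), and partition primary alignments
   by (reference, soft-clip-corrected 5′ start, strand), optionally
   stratified by read length. Paired data are grouped per template via
   read 1's key.
2. **UMI clustering** — within each position group, correct barcode
   errors with one of three modes over a BK-tree index under Hamming
   distance:
   * *directional*: iterative merging of any unassigned UMI `v` within
     `k` edits (default 1) of a cluster member `u` when
     `count(u) ≥ 2·count(v) − 1`, expanded transitively from
     high-count roots;
   * *acyclic*: the single-hop restriction (only root-adjacent UMIs
     merge), preventing over-collapsing;
   * *raw*: no correction, every exact UMI is its own cluster.
3. **Consensus** — each cluster emits an existing read (pair) whose full
   sequence is the modal sequence of the cluster (majority vote); MAPQ is
   used only to pick among reads already carrying the winning sequence,
   never to pick the sequence itself. Clusters of ≤ 2 reads are dropped
   by default (`keepSingletons` retains them); overlapping mates can be
   merged into one fragment-spanning record.
4. **Simulation & evaluation** — a generative benchmark (templates with
   SNVs planted at exact allele frequencies, branching-process PCR with
   per-base replication errors, paired 2×250 bp reads with sequencing
   errors and per-base UMI errors) plus a threshold-free pileup caller
   and precision/recall/F1 scoring against the emitted truth table.

## Worked example

Simulate 10000 templates on a 400 bp amplicon (nine SNVs at 3 × {1%,
0.1%, 0.01%}), 5 PCR cycles at 0.9 efficiency, then deduplicate and
score:

```r
library(umidedup)

cfg <- simConfig(referenceLength = 400L, nTemplates = 10000L,
                 pcrCycles = 5L, readLength = 200L)
sim <- simulateReads(cfg, seed = 7)
writeSimulatedBam(sim, "reads.bam")

res <- dedupBam("reads.bam", "dedup.bam", grouping = "directional",
                mergePairs = TRUE)
calls   <- pileupVariants("dedup.bam", sim@reference)
metrics <- scoreCalls(calls, simTruth(sim))
```

which prints:

```
UmiSimulation: 10000 templates, 247493 read pairs, 9 planted SNVs
  reference: 400 bp; UMI collisions: 42 ; pairs with UMI errors: 11928
DedupResult (directional mode)
  input 494986, accepted 494986, groups 1
  clusters: 21508 exact-UMI -> 9929 corrected; 138 sparse dropped, 9791 retained
  records written: 9791 -> dedup.bam
EvalMetrics: TP=9 FP=1 FN=0  precision=0.9 recall=1 F1=0.9474
  simFreq nTruth nDetected  meanObsFreq         bias
1   1e-02      3         3 0.0100432370  0.004323699
2   1e-03      3         3 0.0009873013 -0.012698737
3   1e-04      3         3 0.0001021346  0.021346134
```

Reading this: the 21508 distinct observed UMIs (10000 true barcodes plus
~12000 error copies) collapse to 9929 clusters; sparse clusters are
removed and each surviving template is written once as a merged 400 bp
record. All nine planted SNVs are recovered (recall 1) with allele
frequencies within a few percent of the planted values down to 0.01%.
The single false positive comes from a small (3–5 read) cluster in which
every read carried a sequencing error, so the majority vote had no clean
winner — see the methods vignette for why this is a property of
few-cycle, small-family regimes.

Command-line wrappers for each stage live in `inst/scripts/`
(`dedup.R`, `simulate.R`, `evaluate.R`, `extract.R`), e.g.

```sh
Rscript inst/scripts/dedup.R --in sorted.bam --out dedup.bam \
    --grouping directional --merge-pairs
```

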