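---
title: "Methods and design notes for taphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for taphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`taphos` authenticates taxonomic assignments of ancient environmental DNA
after competitive mapping and lowest-common-ancestor (LCA) assignment. Its
unit of work is a synchronized pair of streams: a read-name-grouped BAM/SAM
and an LCA text file with one line per read, in the same read order. Both
streams are consumed monotonically, holding at most one read's alignments in
memory, so file size never dictates RAM.

The statistical model is deliberately simple and descriptive. For every
taxonomic node we accumulate, over all reads assigned to the node *or any of
its descendants*:

* **read-level** quantities, counted once per read regardless of how many
  alignments it has: read count, DUST complexity, read length, read GC, and
  canonical k-mers (total count plus a HyperLogLog sketch of distinct
  k-mers);
* **alignment-level** quantities, weighted by one of three modes:
  substitution counts by terminal offset, ANI (matched/aligned columns) and
  aligned-reference GC.

Reads assigned to a genus contribute to the genus and its ancestors, never
to descendant species. `unaggregated_reads` counts reads assigned exactly to
the node, and over a file it sums to the number of LCA lines processed — a
conservation property the tests assert.

## Terminal damage

Postmortem deamination shows up as C-to-T transitions at the 5' end of the
sequenced molecule and, depending on library chemistry, C-to-T (single
stranded) or G-to-A (double stranded) at the 3' end. Every aligned column is
therefore reported in *read orientation*: reverse-strand alignments are
complement-flipped so "5' offset 1" always means the first sequenced base.
The reported `damage_5` is
`count(5', offset 1, C->T) / count(5', offset 1, C->*)` — conditional on the
reference carrying a C — and `damage_3` analogously with the
chemistry-appropriate transition. Zero denominators yield `NA`, never 0:
absence of evidence is not an estimate.

Reference bases are reconstructed from the query plus CIGAR and MD tags, not
from a reference FASTA — competitive-mapping databases are terabyte-scale
and cannot be assumed present. Alignments with missing or inconsistent MD
are excluded and tallied, not silently repaired.

## Alignment-weighting modes

Mode 1 uses the AS-best alignment per read (ties broken uniformly at random
under the configured seed), mode 2 spreads weight 1/m over a read's m
parseable alignments, mode 3 weights every alignment equally. On reads with
a single alignment all three coincide, and the acceptance suite checks
byte-identical output in that case. Read-level statistics are
alignment-independent by construction; attaching modes only to substitution
frequencies, ANI and reference GC keeps, say, mean read length from
depending on how promiscuously a read maps.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `rank_threshold` | "family" | rank name | assignments above family are rarely reported in eDNA studies; membership test, not a rank ladder (ladders are database-dependent) |
| `min_reads` | 5 | reads | below ~5 aggregated reads no per-node statistic is interpretable |
| `min_similarity` | 0.9 | fraction | matched columns / full read length, *inclusive*; soft-clipped bases stay in the denominator so clipping is penalized |
| `max_dust` | off | 0–100 score | opt-in low-complexity read filter; the common advisory threshold is ~7 |
| `mode` | 1 | — | fastest and least sensitive to alignment multiplicity |
| `stranded` | none at CLI | ds/ss | silently wrong chemistry corrupts `damage_3`; the API defaults to "ds" for programmatic use but the CLI demands it |
| `k` | 29 | bp | long enough to be nearly unique in toy and real genomes, short enough that typical 35–90 bp reads carry many windows |
| `P` | 15 | offsets | covers the deamination decay range; keeps substitution files small |
| `precision` | 14 | log2 registers | HyperLogLog RSE `1.04/sqrt(2^14)` ≈ 0.81%, inside the 1% contract |
| `seed` | 4711 | — | AS tie-breaks and any sampling are reproducible |

PMD annotation (`annotate_pmd`) scores each alignment with the
log-likelihood ratio of a geometric damage model
`D(z) = p (1-p)^(z-1) + const` against a flat base-error null;
`p = 0.3`, `const = 0.01`, `base_error = 0.001` are parameters of the
conventional model, not ground truth, and live in `pmd_params()`.

# The synthetic world

The generator emulates exactly the stated conditions of the pipeline's
inputs: a small rooted taxonomy (two orders, two families, three genera,
five species), homologous per-species references (sibling species diverge by
5% substitutions from a genus ancestor), ancient-DNA-sized fragments
(normal, 60 ± 10 bp, clamped to 35–90), geometric terminal deamination with
amplitude `d0 = 0.3` and decay `r = 0.5` per offset, flat sequencing error
2e-3, a 30% chance of a secondary alignment to a sibling species (which
pushes the LCA to the genus), 15% of reads assigned above the family
threshold, and optional 1–2 bp indels and 1–5 bp soft clips (5% each).
CIGAR/MD/NM/AS are computed against the true references, so reference
reconstruction can be checked exactly against generator truth.

What it does **not** emulate: realistic fragment-length distributions,
nick-position chemistry, database contamination, quality scores (all bases
written as `I`), or mapping itself (alignments are planted, not discovered).
A green test therefore establishes correctness of the accounting —
filtering, aggregation, weighting, frequency estimation — under a known
truth, not robustness to aligner quirks.

# Numerical and design choices

* **Aggregated `min_reads`.** Whether the 5-read floor uses node-exact or
  aggregated counts was genuinely open; we use aggregated counts so a genus
  inherits support from its species, consistent with how every other
  statistic aggregates.
* **Inclusive similarity.** "More than" a 0.9 threshold is implemented as
  `>= 0.9`, so the documented default still admits an exactly-0.9 alignment.
* **Exclusion semantics.** A read is excluded if *any* node of its path is
  on the exclusion list, so excluding a genus removes its species' reads —
  the decontamination use case. Counts are re-aggregated afterwards.
* **DUST scaling.** Whole-read triplet form, no windowing, normalized so a
  homopolymer scores exactly 100 (the Prinseq convention; other DUST
  variants scale differently). The DUST filter runs in pass 2 only; pass-1
  counts are pre-DUST.
* **Shrink idempotence has one edge case.** If a kept read loses *all* of
  its alignments to the similarity filter it is dropped from both outputs;
  on a re-run the assigned node's aggregated count is then smaller and may
  fall under `min_reads`, cascading further drops. Shrinking a shrunken
  output is a fixed point whenever no read lost every alignment (the common
  case, and the one our fixtures exercise); with such total drops the
  operation is only contractive.
* **Duplicity denominator.** Reported duplicity uses the HyperLogLog
  estimate, not exact counting, so one machine serves files of any size;
  tests pin it within 2% of the exact-count value. A node with zero unique
  k-mers (all reads shorter than k) reports duplicity 0 rather than a
  division error.
* **Determinism.** The k-mer hash is a fixed-constant 64-bit FNV-1a /
  splitmix64 combination; estimates are identical across runs and platforms.
  Linear counting handles the small-cardinality regime; at 1e5 distinct keys
  and 2^14 registers the raw estimator is outside its biased band.
* **Offsets ignore indels.** Terminal offsets are read-coordinate offsets
  (soft clips included) regardless of indels; whether indel-adjacent columns
  should shift damage offsets is unspecified upstream and the simple
  convention is reproducible.
* **ANI.** "Average nucleotide identity" is given no formula upstream; we
  define it per alignment as matched columns / aligned (M) columns, weighted
  by the mode weights, which matches the divergence notion the modes govern.
* **Output formatting.** Six significant digits everywhere; the
  substitution file is sparse (zeros omitted) with deterministic token
  order, so write → read → write is byte-identical.
* **ngsLCA identifier metadata.** LCA read fields may extend the read name
  with `:length:sequence` metadata; the BAM read name is authoritative and
  matching accepts the exact name or any colon-extension of it. Converting
  other LCA dialects (e.g. sam2lca output) is left to the user.
* **Krona rendering.** NA damage is emitted as 0 with a parallel
  `damage_defined` attribute of 0, because colour scales need numerics; the
  "top reference" in extraction is the one hit by the most distinct
  qualifying reads, ties to the lexicographically smallest name.

# Known limitations

* No model-based damage fitting (briggs-type likelihoods); `taphos`
  estimates frequencies and leaves inference to dedicated tools.
* No per-reference breadth/depth of coverage — duplicity is the deliberate
  stand-in at metagenomic scale.
* Single-threaded; streaming keeps memory flat but wall-clock grows linearly
  with alignments (mode 1 parses one alignment per read and is fastest).
* Coordinate-sorted BAMs are rejected by design; the toolkit relies on
  read-name grouping, and paired-end mate handling is out of scope (ancient
  eDNA reads are merged single-end).
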