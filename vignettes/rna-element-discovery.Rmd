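---
title: "Coverage-based RNA element discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based RNA element discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redar)
```

## The model

`redar` treats transcription as a per-base coverage signal rather than a
set of transcript structures. An *RNA element* (RE) is a contiguous
genomic interval whose read coverage surpasses a threshold; it is the
atomic unit of every downstream analysis and deliberately makes no claim
about splicing, strand, or transcript identity. This suits RNA sources
where transcripts arrive fragmented — mature sperm, oocytes, degraded
clinical samples — and where assembly-based tools undercall.

The procedure, per sample:

1. **Thresholding.** The user-level threshold μ is in reads per million
   mapped reads (RPM), so samples of different depth are comparable; it
   is converted per sample to an absolute depth
   `d = μ × library_size / 10⁶`.
2. **Binning.** Mean per-base depth is computed for every 10 bp bin on a
   fixed grid anchored at coordinate 0. Anchoring at 0 (rather than at
   coverage-run starts) makes results independent of how the bedGraph
   happens to be fragmented into records; the conservation property
   (depth mass is preserved by binning) and fragmentation-invariance are
   both tested.
3. **Expressed-bin calling.** Bins with mean depth strictly greater than
   `d` that do not overlap any exonic RE by even one base are retained.
4. **Merging.** Retained bins separated by at most 150 bp are fused into
   per-sample novel elements; the same gap rule then fuses novel
   elements across samples, and each merged element records the set of
   samples that contributed to it. Exonic REs do not participate in
   merging.
5. **Classification.** Each novel element is Intronic if it lies wholly
   inside some gene's intron; otherwise NearExon if its minimum gap to
   an exon is ≤ 10 kb; otherwise Orphan.
6. **Extension.** An exonic RE absorbs an adjacent NearExon element when
   the gap is ≤ 50 bp and the relative difference in mean coverage is
   strictly below 50%.

The exon universe comes from a GTF/GFF annotation: all exon features
(plus transcript-level non-coding entries that lack exon children,
treated as single exons) are collapsed into one disjoint exon track.
Overlapping exons of *different* genes merge into a single exonic RE
carrying both gene names — a single disjoint track forces this choice,
and it keeps "novel" well-defined as "outside every annotated exon".
Introns are per-gene: the gaps in each gene's own exon union. A region
exonic in gene A and intronic in gene B therefore counts as exonic.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `mu` | 2.5 | RPM | discovery threshold; converted per sample to absolute depth |
| `bin_size` | 10 | bp | grid for mean-coverage reduction |
| `merge_gap` | 150 | bp | maximum bridged coverage hole, within and across samples |
| `near_exon_distance` | 10 000 | bp | NearExon vs Orphan boundary |
| `extension_gap` | 50 | bp | exon-extension adjacency |
| `extension_max_coverage_diff` | 0.5 | fraction | exon-extension similarity (strict `<`) |
| expression threshold | 25 | RPKM | expressed-RE call on the per-cell-type median |
| enrichment `alpha` | 0.05 | — | cutoff on the Bonferroni-adjusted tail |
| enrichment `min_diff` | 10 | elements | effect-size filter, strict `>` |

All of these surface as named arguments (and as keys of the flat
key = value run configuration used by `run_pipeline()` and the `reda`
command line), defaulting to the canonical values above.

## Numerical and boundary choices

Coordinates are 0-based half-open throughout, matching BED/bedGraph;
GTF input is converted on read. The gap between two intervals is
`start(later) − end(earlier)`, so "within 50 bp" means gap ≤ 50,
"maximum 150 bp between" means gap ≤ 150, and "within 10 kb" means
gap ≤ 10 000 — one distance definition everywhere.

*Strictness.* A bin must strictly exceed the absolute depth threshold
("surpassing"); a bin at exactly the threshold is excluded. This reading
is configurable (`strict_threshold = FALSE` gives `≥`). The 25 RPKM
expressed call, the transmission thresholds, the 5 TPM / 25 RPKM
intersect cuts and the `> 10` effect filter are likewise strict, exactly
as their definitions print them. The PPV formula partitions novel
elements at `median > t` versus `median ≤ t`.

*Merging across short exons.* Fusing bins across a 150 bp gap could
bridge over an exon shorter than the gap, producing a "novel" element
that overlaps an exon. Merged novel elements are therefore clipped
against the exon track after merging; the two flanks remain separate
elements. The invariant that novel elements never overlap exonic REs is
tested per base.

*Extension.* "Read coverage" in the extension rule is taken as mean
per-base depth over each element (pooled across samples), and the
difference is measured relative to the larger of the two depths — a
symmetric, scale-free choice. When both depths are zero the relative
difference is undefined and the extension does not fire. Extension is
applied once per exonic/near-exon adjacency, nearest neighbour first,
without chaining several novel elements onto one exon; the extended
element keeps class Exonic, the exon's gene names and its source
samples.

*Classification precedence.* NearExon is defined among non-intronic
elements, so a fully intronic element within 10 kb of an exon (always
true) is Intronic. An element straddling an intron boundary is not
"within an intron" and falls back to the exon-distance rule.

*Enrichment.* For each repeat name the universe is all N elements, of
which K overlap the repeat; the expressed set for a cell type is the
sample of size n with k hits. Both tails of
`X ~ Hypergeometric(N, K, n)` are computed; the tail matching the
observed direction (k versus the expectation nK/N) is Bonferroni-scaled
by the number of repeat names tested. The significance level applied to
the adjusted value defaults to 0.05 (conventional; the correction itself
does not fix a cutoff) and is configurable, as is rolling the test up
from repeat names to families or classes. Counting an element as
overlapping a repeat requires ≥ 1 shared base.

*Quantification.* Read counts are estimated from coverage as
(per-base depth mass over the element) / read length, and from explicit
read placements by ≥ 1 bp overlap; both give
`RPKM = 10⁹·count/(L·length)`. The library size L is the mapped-read
count supplied per sample — mapped rather than sequenced reads, as is
standard for RPKM. The median is the default cell-type aggregator;
the fold-change screen uses means, as its formula states, with a 0.5
RPKM pseudocount by default (settable to 0) to guard zero means.

*Transmission tiers.* The two paternal rules nest (oocyte < 2 implies
oocyte < 5); the most stringent applicable label is reported, so the
"moderate confidence" tier is effectively 2 ≤ oocyte < 5. The label set
is proven mutually exclusive and exhaustive over the full boundary
lattice of the printed thresholds.

*Degenerate inputs.* Empty coverage yields only exonic REs; an empty
element list yields empty (typed) tables; a μ with no discovered novel
elements yields an undefined PPV recorded as `NA`; elements on
chromosomes absent from a sample quantify to 0 with a warning.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds, deterministically from a seed: a toy
annotation (by default 6 genes of 4 × 300 bp exons with 2.5 kb introns
on two 200 kb chromosomes, genes confined to the left of each
chromosome so a gene-free zone > 10 kb from every exon exists); a repeat
track drawn from a fixed palette of five repeat names at 15 features per
10 kb (~45% of the genome repetitive, comparable to a mammalian
genome); and four coverage tracks of 2 × 10⁷ mapped reads with
negative-binomial background noise (mean 5, dispersion 5 per 10 bp bin)
truncated below the μ = 2.5 absolute threshold, into which seven
elements — one exonic boost, two intronic, two near-exon, two orphan —
are planted at ten times that threshold. An optional fragmentation mode
punches one ≤ 150 bp zero-coverage hole into each planted element to
exercise the merge-gap logic. Planted novel classes are checked against
the classifier itself at generation time, so truth labels can never
drift from the classification rules.

The generator emulates the *geometry* of the problem (class placement,
library-size-dependent thresholds, coverage holes, repeat overlap), not
the biology of any protocol: no read-level simulation, no sequencing
error, no strand, no splicing, no expression gradients, and noise is
independent across bins. Passing the recovery tests therefore shows the
algorithm is correct on signal that respects its own assumptions; it
does not show robustness to alignment artefacts, GC bias or annotation
incompleteness in real data.

## Problem sizes used by the test suite

The suite verifies the interval operations (gap merging, exon-universe
construction, repeat overlap, binning) against per-base brute-force
oracles on 100 random fixtures of ≤ 50 kb chromosomes each; classifies
1 000 random novel intervals with per-base confirmation of every
Intronic and Orphan call; checks hypergeometric tails against exact
combinatorial enumeration for every universe up to N = 30 (and against
full subset enumeration for N ≤ 12); sweeps the full 19 × 200 PPV grid;
and runs the end-to-end pipeline twice from one seed to confirm
byte-identical outputs. These sizes keep the default run around a
minute while still exercising every rule at its boundary.

## Known limitations

- Discovery is unstranded; antisense and overlapping sense signal fuse
  into one element.
- Elements are not transcript models: no splice junctions, no isoforms,
  no TSS/TES semantics.
- Coverage-based read-count estimation is approximate for reads
  partially overlapping an element boundary; exact counts are available
  via `quantify_res_from_reads()` when read placements exist.
- The expected behaviour at exactly the depth threshold, and whether
  per-million normalisation uses mapped or total reads, are convention
  choices (strict `>`, mapped) exposed as options rather than facts.
- The transmission tiers' false-discovery rates are not estimated; the
  labels are rule applications only.
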