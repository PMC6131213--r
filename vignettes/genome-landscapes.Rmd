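---
title: "Methods: genome landscape analysis on synthetic chromosome-scale assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome landscape analysis on synthetic chromosome-scale assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`genomescape` re-implements, as a tested and reusable pipeline, the analyses
used to characterise the large-scale landscape of a chromosome-scale plant
genome assembly: contiguity statistics, terminal telomere tracks, a
centromeric satellite (a ~317-bp monomer arranged in tandem arrays),
pericentromeric LTR retrotransposon fields, tandem gene arrays and their fate
across assembly versions, collinear synteny against a related species, and an
expression atlas with FPKM-based detectability and tissue-specificity
filters.

Chromosome-scale real data (tens of Mb per chromosome, tens of thousands of
genes) is not reproducible at desk scale, so the package is built around a
first-class synthetic-genome module: every analysis is exercised end-to-end
on simulated chromosomes in which every feature is planted at known
coordinates and recorded in a truth ledger. A green test therefore
establishes that the *method* recovers what was planted under the stated
noise model — not that any specific biological genome has particular
properties.

# The simulated world

`simulation_config()` describes one world; `raspberry_preset()` fixes the
package's reference world, chosen to mirror the qualitative structure of a
seven-chromosome Rosaceae assembly:

* **Chromosomes.** Seven, 1.2 Mb each. Real chromosomes are 34–51 Mb;
  everything that scales linearly (window sizes, array lengths, gene counts)
  is scaled down roughly 30-fold so the full pipeline runs in minutes on one
  CPU. Background sequence is i.i.d. uniform A/C/G/T — the simplest null
  under which local-alignment statistics behave like the classical
  Karlin–Altschul theory.
* **Telomeres.** Tandem runs of the plant consensus motif `TTTAGGG`
  (40 copies, 280 bp) at both ends of four chromosomes and one end of two
  more — ten tracks in total — with the motif on the left end and its
  reverse complement on the right. The source analyses do not print the
  motif; the Arabidopsis-type consensus is the standard choice for
  rosaceous genomes.
* **Centromeres.** One tandem array of a 317-bp monomer per chromosome,
  110–1204 copies (the reported per-chromosome range for the real
  satellite), each copy carrying i.i.d. substitutions at rate 0.11 so
  element-to-consensus identity averages ~89%. One chromosome (the sixth)
  carries only four isolated monomers and no pericentromeric enrichment,
  emulating a chromosome whose centromere is missing from the assembly; the
  caller must report it as `no_call`.
* **Pericentromere.** 80 kb on each side of the array annotated with LTR
  intervals at 90% coverage density. The planted truth interval for a
  centromere is array plus pericentromeric fields, matching the caller's
  border definition (satellite support extended while LTR density
  exceeds 85%).
* **Genes.** 40 singleton genes per chromosome (600–1500 bp, uniform) plus
  tandem arrays of 2–26 members whose sequences diverge 5% from a shared
  progenitor. Array members share an orientation and are planted
  strand-aware, so strand-aware extraction recovers comparable sequences
  through later inversions.
* **Hi-C.** Binned intra-chromosomal contacts with expected count
  proportional to `(1 + d)^-1`, multiplied by 0.3 for any bin pair touching
  a centromere, with negative-binomial noise (dispersion 0.05). The
  negative binomial is the standard overdispersed count model; dispersion 0
  switches noise off deterministically.
* **Expression.** Ten tissues. A configurable fraction of genes is planted
  tissue-specific (target FPKM 5–50 in one tissue, ≤0.05 elsewhere);
  the detectable fraction defaults to 6070/9301 ≈ 0.65, mirroring an atlas
  in which about two-thirds of newly annotated genes are expressed. Margins
  are deliberately clear of the FPKM = 1 threshold so the filters are tested
  against the rule, not against borderline noise.

Two derived genomes complete the world. `degrade_assembly()` produces a
short-read-like assembly: a sampled fraction of tandem arrays collapse to a
few members (gene bodies and spacers excised, coordinates shifted),
gene-run inversions emulate mis-oriented scaffolds, and the pericentromere
can be replaced by `N` gaps. `generate_ortholog_genome()` produces a second
species: uniform substitutions (default 6%), preserved gene order except
planted inversions, and lineage-specific array expansions or contractions.
Inversions are placed over runs of consecutive genes within one chromosome
arm — never across a centromere or a collapse junction — and, in the
ortholog, are flanked by at least five collinear genes so both orientations
are recoverable by chaining.

## What the simulator does *not* emulate

Real repeat landscapes contain higher-order satellite structure, indels
within monomers, segmental duplications, nested transposons, GC
heterogeneity, and assembly gaps; genes have introns and alternative
transcripts; Hi-C has distance-dependent biases beyond a single power law.
Recovery rates measured here are therefore upper bounds for idealised
signals, and the package's thresholds (below) are calibrated against this
world, not against any real genome.

# Methods and numerical choices

**NX statistics.** `nx_value()` returns the largest length `L` such that
sequences at least `L` long jointly cover the requested fraction of the
assembly; at an exact boundary the boundary-crossing length is returned (the
standard N50 convention). Verified against a brute-force cumulative-sum
oracle on random instances.

**Telomere detection.** Each terminal window (default 10 kb) is scanned for
the longest run of motif copies spaced exactly one motif length apart, for
both the motif and its reverse complement; a call needs ≥10 copies, each
within 10% divergence of the motif. Reverse-complementing every chromosome
maps each call to the opposite end with identical copy number, which the
tests assert.

**Monomer discovery.** Periods are detected by a k-mer (k = 13)
recurrence-distance histogram: distances between successive occurrences of
each k-mer vote for periods, and a period needs 25 votes — calibrated so 10
kb of random sequence reports nothing, while a 30-copy array at 15%
divergence still gives hundreds of votes. The consensus is the per-column
majority base of the period-phased frame stack; when the input begins
mid-array the consensus is a rotation of the planted monomer, which is
irrelevant for tandem scanning. Because the simulator plants substitutions
only, recurrence distances are exact multiples of the period; indel-rich
satellites would spread the histogram and are out of scope.

**Array scanning.** Matches are seeded on the monomer's 20-bp prefix
(mismatch budget scaled to the identity floor), verified by full-monomer
Hamming identity, merged across gaps up to two monomer lengths, and then
phased into consecutive monomer-length frames anchored at the first match —
the operational definition of an "element" adopted because the source
workflow does not define element boundaries. Copy number counts frames at
or above the identity floor (default 70%); `mean_identity` averages their
identities. Identity is computed element-vs-consensus rather than all-pairs
(linear rather than quadratic cost; the reported "average homology" of a
satellite is ambiguous between the two, and element-vs-consensus is the
convention of satellite annotation tools). `mean_element_identity()`
exposes the alignment-based per-element identity for arbitrary elements.

**Centromere calling.** Three evidence tracks: satellite arrays, windowed
LTR density (50-kb windows, 25-kb step — the landscape-figure geometry), and
the relative Hi-C interaction statistic (smoothed row sums over the
chromosome median, scale-invariant by construction). The source describes a
workflow, not formulas, so two constants are simulation-calibrated and
configurable: bins below 0.6 relative interaction form the depressed
region (planted depression factors 0.2–0.5 land well below, Poisson-level
noise stays above), and borders extend while LTR density exceeds 0.85
with one sub-threshold window tolerated (the 85% rule is stated; gap
handling is not). Arrays win when repeat and Hi-C evidence disagree on
location, matching the stated validation order. A call requires satellite
support, or depression plus LTR support; four stray monomers on a flat
chromosome fall below the five-copy floor and yield `no_call`.

**Homology.** Local alignment under +1/−2 match/mismatch with affine gaps
(open 5, extend 2), rescaled to bit scores with λ solved from the
Karlin–Altschul identity for uniform composition and K = 0.621 (the
ungapped value; e-value scale, not ranking, depends on it), and
`E = m·n·2^(−bit)` against the total database length. The all-vs-all driver
prefilters candidate pairs by shared distinct 8-mers (≥40), which separates
true homologs (hundreds shared at ≤15% divergence) from random 1-kb pairs
(~15 shared) by several standard deviations; very diverged homologs below
the prefilter are accepted losses at desk scale. External 12-column hit
tables can be substituted for the built-in aligner.

**Tandem arrays.** Two genes are linked when they share a chromosome, their
hit passes e ≤ 1e−5, and their annotation ranks differ by ≤10 genes — rank
distance is strand-agnostic, the MCScan convention, since "gene distance"
is otherwise undefined. Arrays are single-linkage components of size ≥2,
verified against an independent graph-components oracle. Cross-assembly
comparison matches arrays by largest shared mapped membership (ties by
chromosome, then position) and reports both array-level and gene-level
novelty, because "novel" can reasonably count either.

**Synteny.** Anchors are reciprocal top-k hits (k = 1 by default, a partial
matching). Chains maximise anchors-minus-gap-penalty (0.05 per skipped
rank) under strict monotonicity in both genomes and a 25-rank gap bound,
greedily extracted per chromosome pair; both orientations are tried and
chains under 5 anchors discarded. Verified against exhaustive best-chain
search on instances of ≤12 anchors. Syntenic depth counts overlapping block
spans per genome; because a forward chain may legitimately bridge a small
inversion, the block it spans overlaps the inverted block and neither is
1:1 — so the package reports the block-wise fraction alongside a base-wise
fraction (covered bases at depth 1), and the 100%-1:1 acceptance check uses
an inversion-free ortholog. Depth is symmetric under swapping genomes,
which is tested.

**Expression.** FPKM is fragments per kilobase per million mapped
fragments from the supplied library sizes. Detectable means FPKM > 1 in at
least one tissue; tissue-specific means FPKM > 1 in exactly one tissue and
< 1 in all others. Both inequalities are strict — a value exactly at 1
satisfies neither — with an opt-in inclusive flag for the "other tissues"
bound, since the source does not state whether its lower bound was strict.
The heat-map transform is log2(FPKM + 1); the pseudocount is unstated in
the source and +1 is the bounded-at-zero standard.

# Determinism and seeds

Every generator takes an explicit seed and runs under a save/restore RNG
guard, so identical configuration and seed give byte-identical FASTA, GFF3,
BED, contact and count outputs, and callers' RNG state is never disturbed.
`run_report()` derives per-stage seeds (seed, seed+1, seed+2, seed+3) so
stages are individually reproducible.

# Coordinates

All internal coordinates are 1-based inclusive, the R/Bioconductor
convention (the natural choice for an R implementation, in place of the
0-based half-open convention a Python implementation would use); GFF3 is
written 1-based inclusive and BED 0-based half-open, per those format
standards. Gene ranks are 1-based and consecutive within each chromosome;
only rank differences carry meaning.

# Known limitations

* The satellite scanner assumes substitution-dominated divergence; long
  indels inside monomers would shift frames and undercount copies.
* The k-mer prefilter bounds homology sensitivity at roughly 20–25%
  nucleotide divergence for kb-scale genes.
* Centromere-call thresholds (0.6 relative interaction, 0.85 LTR density,
  one-window gap tolerance) are calibrated on this simulator and should be
  re-examined before use on real tracks.
* Block-wise 1:1 fractions are deflated when chains bridge small
  inversions; prefer the base-wise fraction for genomes with many
  micro-inversions.
* Recovery suites run at reduced replication (tens of seeds, not
  hundreds) to stay inside desk-scale runtimes; the test seeds are fixed
  and the configurations are stated in the test code.
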