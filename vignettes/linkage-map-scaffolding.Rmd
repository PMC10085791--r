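---
title: "Linkage-map-guided curation and scaffolding with linkscaf"
author: "linkscaf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage-map-guided curation and scaffolding with linkscaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkscaf)
```

## The problem

Long-read assemblies of inbred insect genomes routinely reach megabase
contiguity, but contigs still need to be ordered, oriented and joined into
chromosome-scale pseudomolecules, and misjoined (chimeric) contigs need to
be found and cut. A dense genetic linkage map from an F2 intercross gives
exactly the chromosome-scale signal required: every mapped marker ties a
physical position on a contig to a linkage group and a centimorgan
position. `linkscaf` implements this protocol end to end for the classic
silkworm-style design — two inbred parents, two F1 hybrids, and an
all-female F2 panel genotyped at reduced-representation (ddRAD-style)
markers — together with the assembly-QC surface used to judge the result
(N50 and gap accounting, telomere and telomere-to-telomere (T2T) counts,
and a k-mer-survey consensus QV).

A seeded synthetic-data generator is a first-class module: it produces
truth genomes, crosses, fragmented and chimeric contig sets, coverage
tracks and read k-mer sets with the statistical structure the pipeline
assumes, so every stage is testable without any external data.

## The linkage model

Genotypes are coded `AA` (maternal homozygote), `AB`, `BB` (paternal
homozygote), with missing calls `NA`. Because the parents are inbred
lines, linkage phase is known (coupling in both F1 parents).

**Filters.** F2 individuals, then markers, with more than 20% missing
calls are excluded (`filterMissingness()`; the boundary is strict — a
marker missing in exactly 20% is retained). Individuals are filtered
first so one bad individual cannot drag many markers over the limit.
Autosomal markers must have both F1 parents heterozygous; a missing F1
call means the criterion cannot be verified, so the marker is dropped.

**Z chromosome.** Under ZW sex determination with all-female F2 progeny,
each F2 carries a single, paternally derived Z. A marker is classified
Z-linked (`classifyZMarkers()`) iff (1) the F1 female call equals the
paternal homozygote, (2) the F1 male is heterozygous, and (3) no
non-missing F2 call is heterozygous. Paternal homozygotes of Z markers
are then recoded to `AB` (`convertZToBackcross()`) so the two-class
backcross model applies: `r = R/n` with
`LOD = (n-R)·log10(2(1-r)) + R·log10(2r)`.

**Two-point F2 estimation.** For autosomal pairs the 3×3 joint genotype
table under coupling has class probabilities

| | `AA` | `AB` | `BB` |
|---|---|---|---|
|`AA`| $(1-r)^2/4$ | $r(1-r)/2$ | $r^2/4$ |
|`AB`| $r(1-r)/2$ | $((1-r)^2+r^2)/2$ | $r(1-r)/2$ |
|`BB`| $r^2/4$ | $r(1-r)/2$ | $(1-r)^2/4$ |

Every class determines its recombinant-gamete count except the double
heterozygote, which mixes zero- and two-recombinant configurations;
`estimateRfF2()` runs EM over that ambiguity (weight
$r^2/(r^2+(1-r)^2)$), iterating to $|\Delta r| < 10^{-6}$ or 100
iterations, with $\hat r$ clamped to $[0, 0.5]$. The LOD score is the
log10 likelihood ratio against $r = 0.5$. The test suite checks the EM
against an exhaustive grid search of the same likelihood on a
$10^{-4}$ grid.

**Grouping and ordering.** Markers are grouped by single-linkage
transitive closure at LOD ≥ 3 (`groupMarkers()`), the threshold of the
classical protocol; no auxiliary maximum-r rule is applied, since the
protocol states LOD only. One caveat of single linkage is worth knowing:
under the null, a marker pair reaches LOD 3 with probability about
2×10⁻⁴, so maps with very many markers can occasionally see one spurious
bridge between chromosomes; the package reports group sizes so such
bridges are visible. Within a group, `orderMarkers()` minimizes the sum
of adjacent recombination fractions by greedy nearest-neighbour seeding
plus 2-opt refinement — a transparent seriation with a stated objective,
standing in for multipoint ordering heuristics whose internals are not
specified. The order is defined up to whole-group reversal and is
canonicalized by marker name. Cumulative cM positions come from the
mapping function: Kosambi by default (some crossover interference is the
safer default for real data), Haldane available; both invert exactly.
The generator itself simulates meiosis without interference, so Haldane
is the internally consistent choice when analysing simulated crosses —
the ordering and grouping results do not depend on this choice, only the
cM scale does.

## Curation: chimeras and artifact flags

A contig carrying at least 2 markers from each of two linkage groups is
called chimeric (`detectChimeras()`); a single stray marker is more
plausibly a genotyping error, hence the support threshold. The search
interval spans between the innermost conflicting markers, and the
breakpoint is placed at the centre of the minimum-depth coverage window
inside the interval (`locateBreakpoint()`, leftmost on ties) — "extremely
low coverage" is operationalized as the argmin, since read support
genuinely collapses at a misjoin. Without coverage the interval midpoint
is used and flagged low-confidence. `splitContig()` conserves every base
and remaps markers. Separately, `flagArtifactContigs()` flags contigs
whose modal windowed depth falls below 5 or above 250 — the modal depth,
not the mean, is robust to repeat-induced spikes. Flags are reports, not
removals.

## Scaffolding

`anchorContigs()` gives each markered contig a chromosome, a genetic
position (median marker cM) and an orientation (sign of the Spearman
correlation between marker bp and cM; fewer than two distinct cM values
leaves the orientation unknown, emitted as `+` with a flag). Contigs are
ordered by median cM, ties broken by guide position then name.

Adjacent oriented contigs are tested for a terminal overlap
(`detectTerminalOverlap()`): the terminal 31-mer of the upstream contig
is matched (≤1 mismatch) in the downstream contig's 5′ window, each hit
implies a candidate end-anchored overlap, candidates are verified
base-by-base longest-first, and the first with mismatch fraction below
1% wins. Indels are not aligned through: at sub-percent divergence an
indel simply truncates the usable overlap, which is the stricter
reading of a "mismatch" budget. An overlap of at least 3,000 bp is
accepted for joining; the merged sequence keeps the overlap bases from
the upstream contig (a deterministic choice — no consensus rule is
attempted). Unmerged adjacencies get a gap of exactly 100 N
(AGP `U` records, linkage `yes`, evidence `map`).

Contigs without markers can be inserted at gap boundaries using a guide
alignment (`placeMarkerless()`) under three criteria: (1) the insertion
point is consistent with the guide (same chromosome, within a position
tolerance, 100 kb by default); (2) a terminal overlap with the flanking
sequence longer than 3,500 bp; (3) mismatch fraction below 1%. The
failed criterion is recorded for every rejected contig. The two
thresholds differ deliberately: 3,000 bp reflects what neighbouring
anchored contigs typically share, while an unanchored insertion demands
the stronger 3,500 bp evidence.

`buildPseudomolecules()` emits FASTA plus an AGP 2.1 table; the AGP
reconstructs the FASTA byte-identically (`agpToFasta()`), and
coordinates are 1-based inclusive in AGP with 0-based arithmetic kept
internal. Chromosomes are named `chr01..chrN` by descending length
(stable and configurable), with the Z linkage group named `chrZ`.

## QC surface

`assemblyStats()` counts every maximal run of N (length ≥ 1) as one gap,
which makes "4 gaps / 400 N" an arithmetic identity under the 100-N
convention. `detectTelomere()` scans the outermost 1 kb for a tandem
array of at least 10 `CCTAA` units at the 5′ end (`TTAGG`, the reverse
complement, at 3′), allowing one inexact unit per ten — parameters chosen
to call (motif)×50 constructions robustly while rejecting random
sequence, and all configurable since no published criterion is standard.
A pseudomolecule with arrays at both ends and zero gaps is T2T gap-free.
`kmerQV()` implements the k-mer-survey estimator: with `a` the fraction
of assembly k-mers (with multiplicity) unsupported by the read set, the
per-base error is `E = 1-(1-a)^(1/k)` and `QV = -10·log10(E)`; `a = 0`
reports a configurable cap (99) rather than infinity.
`mapConsistencyCheck()` re-orders markers by final physical position,
fixes each chromosome's direction by majority cM step sign, and counts
adjacent pairs whose genetic order contradicts the physical order; the
pipeline reconstructs the map on final coordinates before running it.

## The synthetic-data generator

`simulateGenome()` writes uniform-random sequence at a configurable GC
fraction (default 0.38, lepidopteran-like) with `CCTAA`-unit telomere
arrays implanted at the ends. `simulateCross()` lays markers on a
regular cM grid (bp positions from a linear bp↔cM relation at a
configurable recombination rate, default 3 cM/Mb) and simulates meiosis
as a Markov chain along each chromosome under the Haldane model —
independent recombination in each interval, no interference. ZW
inheritance is simulated exactly for all-female or mixed progeny.
`fragmentGenome()` tiles chromosomes into roughly equal fragments whose
neighbours share a sampled terminal overlap (default 3–8 kb), optionally
implanting two-part cross-chromosome chimeras, shuffling contig order
and strands. `simulateCoverage()` draws Poisson window depths (the
right scale of noise for windowed short-read depth) with
Poisson-distributed dips at chimera junctions. `simulateKmerReadset()`
models read errors at the k-mer level: each of `depth` copies of a
genomic k-mer survives error-free with probability `(1-e)^k`, errored
copies emitting a single-substitution mutant — read-level FASTQ
simulation is deliberately out of scope. `mutateSequences()` plants an
exact substitution count, giving assemblies of precisely known per-base
error for QV calibration.

What the generator does **not** emulate — repeats and segmental
duplication, residual heterozygosity, indel errors, platform error
profiles, crossover interference, achiasmatic female meiosis (the
likelihood used is the standard both-sexes-recombine F2 model of the
classical mapping software), segregation distortion, and non-uniform
marker density. Passing tests therefore demonstrate the correctness of
the algorithms under the stated model, not robustness to every artifact
of real data.

## Problem sizes and numerical choices

The round-trip suite uses a genome physically down-scaled about 1000×
(3 chromosomes of 180/160/140 kb) while keeping the genetic scale
realistic: at 300 cM/Mb each chromosome spans ~40–55 cM, the per-
chromosome map length of a typical lepidopteran. Markers sit on a 10 cM
grid and the F2 panel has n = 200, which puts the z-score separating
adjacent marker positions near 6 — large enough that ordering and
orientation are recovered essentially always, so a failure signals a
defect rather than noise. Chimera recovery runs over 20 seeds with two
implanted chimeras each; QV calibration uses a 5 Mb genome at k = 21.
k-mers are 2-bit packed into doubles, exact for k ≤ 25 (the 53-bit
mantissa), so the supported k range is 11–25 (odd); k = 21 is the
default throughout. Ties are broken deterministically everywhere
(leftmost minimum window, name-ordered seriation canonicalization), and
the pipeline itself contains no randomness: identical inputs and
configuration give byte-identical FASTA and AGP.

## Interface

The package is a library: `runPipeline()` composes the stages, and
`pipelineConfig()` carries every threshold (serialized into the run
report so any output is reproducible from config + inputs). Readers and
writers cover FASTA, the genotype TSV dialect, AGP 2.1, bedGraph
coverage, TSV/PAF guide tables and JSON reports. No shell entry point is
shipped beyond `scripts/acceptance.R`; R users drive the pipeline from
code, as with other Bioconductor-style packages.

## Known limitations

- Single-linkage grouping at LOD 3 can, rarely, bridge chromosomes via
  one spurious pair (see above); inspect group sizes on dense maps.
- Overlap detection requires a clean terminal seed (≤1 mismatch in the
  last 31 bp); a divergent or indel-bearing terminus falls back to a
  gap rather than a join.
- Markerless insertion evaluates the adjacency nearest the guide
  position only, and inserts at gap boundaries and object ends, not
  inside merged runs.
- The backcross LOD treats the Z as a simple two-class system; partially
  informative or dominant markers are out of scope.
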