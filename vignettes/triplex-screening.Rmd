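---
title: "Screening cis-acting lncRNAs for DNA:RNA triplex regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cis-acting lncRNAs for DNA:RNA triplex regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question and the screen's logic

Long non-coding RNAs (lncRNAs) can regulate nearby genes by invading the
major groove of promoter DNA and forming a DNA:RNA triplex: a stretch of the
RNA (the triplex-forming oligonucleotide, TFO) binds a purine-rich duplex
segment (the triplex target site, TTS) through Hoogsteen or
reverse-Hoogsteen base triads rather than Watson–Crick pairs. Because such
binding concentrates at CpG-island-rich promoters and can recruit chromatin
modifiers, a computational triplex screen is a natural way to shortlist
candidate lncRNA regulators of a gene set of interest — for example,
fertility-candidate genes emerging from a genome-wide association study.

`triplexscreen` implements that screen end to end, as five testable stages:

1. **Cis pairing.** Each target gene is given a fixed window of ±50 kb
   around its TSS; lncRNA loci overlapping the window become candidate
   partners. Promoters are taken as −3500/+1500 bp around the TSS
   (strand-aware), and significant SNPs are intersected with lncRNA loci.
2. **Triplex scanning.** The canonical lncRNA transcript is scanned against
   the promoter duplex under a Hoogsteen triad table; the densest cluster of
   overlapping predicted triplexes (TFO1) summarizes the interaction.
3. **Permutation and biological controls.** The same scan is run with a
   shuffled transcript, a shuffled promoter, and the promoter of an
   unrelated control gene; the target/control ratio is the fold enrichment.
4. **Genomic and structural context.** TFO1 hits are intersected with CpG
   islands on the DNA side and, on the RNA side, with structurally
   accessible regions derived from a windowed partition-function
   accessibility profile.
5. **Hierarchical prioritization.** Pairs are tiered: specificity over the
   nulls is the gating criterion; density, accessibility and CpG context
   decide high confidence.

All five stages run on synthetic locus sets with planted ground truth, so
the whole pipeline is exercised without any database access.

## The triad scan

The scan is ungapped and diagonal-wise. For each duplex strand (either may
be the purine-rich strand) and each third-strand orientation, the transcript
is slid along the DNA at every offset; each aligned position receives a
weight from the triad table (0, 1 or 2). The default table encodes the
canonical parallel (pyrimidine-motif) triads U·A:T and C·G:C at weight 2,
the weak parallel triads G·G:C and G·T:A at weight 1, the canonical
antiparallel (purine-motif) triads A·A:T, G·G:C and U·A:T at weight 2 and
the weak C·A:T at weight 1. The table ships as an editable TSV
(`system.file("extdata", "triad_table.tsv", package = "triplexscreen")`).

A window on a diagonal qualifies as a triplex when it is at least `lg = 50`
nt long, at least `i = 60`% of its positions form some admissible triad
(identity), and its mean triad weight is at least `S = 1.0` (stability).
These thresholds prioritize high-affinity interactions over short chance
matches. Qualifying windows on one diagonal that overlap are collapsed to a
single non-redundant hit — the window with the highest mean stability
(ties: longest, then leftmost). We chose the stability-maximal window
rather than the longest qualifying window deliberately: the longest window
can legally pad itself with up to 40% non-interacting positions, which
blurs hit boundaries; the stability-maximal core reports the segment that
actually drives the interaction. Different diagonals report separate hits,
and their overlap on the target is the density signal: `select_tfo1()`
sweeps the hit set for the position of maximal coverage depth, and that
depth — the number of overlapping predicted triplexes — is the screen's
strength indicator, mirroring how a planted or genuine purine tract
produces qualifying alignments at every shifted register.

The scan is exact: an exhaustive enumeration oracle (every window on every
diagonal) reproduces its output identically in the test suite; the early
termination bounds used by the C++ implementation are conservative suffix
bounds and cannot skip a qualifying window.

## Controls and enrichment

`shuffle_sequence()` provides a seeded mononucleotide permutation (the
default null; simplest reading of sequence randomization) and an
Altschul–Erickson dinucleotide shuffle (random Eulerian walk over the
dinucleotide transition multigraph) because CpG density influences triplex
tracts. One shuffle replicate per null is the default, mirroring screens
that report single control counts; `n_shuffle` reports the median over
replicates when stabilization is wanted. Fold enrichment is
`target/control`, with `0/0 = 1` (no signal anywhere) and `x/0 = Inf` for
`x > 0`.

## CpG islands

`detect_cpg_islands()` applies the Gardiner-Garden–Frommer rule: 200-bp
windows at step 1 qualify when GC ≥ 50% and observed/expected CpG
`(N_CG · L)/(N_C · N_G)` ≥ 0.6; overlapping qualifying windows merge and the
merged island is re-scored. These defaults emulate a predicted-CpG-island
annotation track; the stricter Takai–Jones thresholds (500 bp, 55%, 0.65)
are available through the arguments. Islands read from BED bypass
validation and carry a provenance flag, since the provider is then the
source of truth. A hit overlaps an island with one shared base; no
minimum-fraction rule is applied.

## RNA accessibility

Triplex formation requires the TFO to be free of Watson–Crick pairing, so
transcripts are profiled with a windowed McCaskill partition function:
within each 70-nt window (step 1, pair span capped at 70), base-pair
probabilities are computed by an inside–outside dynamic programme over
pseudoknot-free structures, and the per-base unpaired probability
`P_unp(i) = 1 − Σ_j P(i,j)` is averaged over all windows containing the
base. Accessible regions are maximal runs with `P_unp ≥ 0.5`, and a TFO1
hit is accessibility-supported when its TFO shares at least one base with
such a region. The 0.5 cutoff and the 70/70 window/span follow the
screen's reference settings; local folding reflects the co-transcriptional
tendency of RNA to pair locally.

The energy model is deliberately minimal: a structure's energy is the sum
of its pair energies (defaults GC −3, AU −2, GU −1, kT 0.616; hairpin loops
≥ 3 nt; lone pairs allowed; dangles ignored). We chose this over the full
nearest-neighbour model because the screen uses the profile only through a
binary 0.5 cut, and because the simple model is fully verifiable: the test
suite checks the windowed dynamic programme against brute-force Boltzmann
enumeration of all secondary structures to |ΔP_unp| < 1e−9. Probabilities
from the real folding engine would differ in detail; parity with any
specific folding binary is a non-goal, and the `model` argument provides
the hook to swap energies for cross-checks.

## Hierarchical prioritization

Four conditions are evaluated per pair:

* **A, specificity** (gating): target TFO1 count exceeds both permutation
  nulls and enrichment over the control is ≥ 2.0;
* **B, accessibility**: ≥ 1 TFO1 hit in accessible RNA;
* **C, CpG context**: ≥ 1 TFO1 hit overlapping a CpG island;
* **D, density**: target TFO1 count ≥ 20 overlapping triplexes.

`rejected` means A failed; `high_confidence` means all four passed;
anything else is `partial`. The density cutoff deserves a note: the
screen's primary criterion is the density of overlapping triplexes, and on
the published reference counts a pure specificity-plus-context rule would
admit moderately dense pairs (17 or 14 overlapping triplexes) into the top
tier alongside the three pairs the reference screen actually named. A
density floor of 20 — between the 17 of the densest non-named pair and the
22 of the weakest named one — reproduces the published tier split and
expresses "high density" as an absolute requirement for the top tier while
leaving the rejection logic purely specificity-driven (a dense-enough but
context-poor pair is partial, not rejected). SNP co-localization is
annotated but never filters: it is interpretive evidence about causal
variants, not a property of the triplex interaction.

## The synthetic locus generator

`simulate_locus_set()` builds complete input sets — genome FASTA, GFF3
annotation, transcript FASTA, VCF, island BED, control promoter and a truth
table — with one gene per chromosome, lncRNA loci placed 1.5–45 kb upstream
of the TSS, and planted triplex sites:

* **Planted TTS.** A homopurine (poly-G) tract of 50–150 bp (the observed
  size range of predicted interaction sites) is written into the promoter
  between −3500 and +1500 of the TSS.
* **Exposed TFO.** The parallel triad image of the tract (poly-C, with
  seeded non-adjacent mismatches when identity < 100%) is embedded in an
  A-rich transcript inside 15-nt poly-A guards. Adenosine forms no parallel
  triad with any duplex base, so the guards are invisible to the scan and
  the recovered site matches the plant exactly; A and C do not pair each
  other, so the tract sits in unstructured RNA and its unpaired
  probabilities are near 1.
* **Buried TFO.** Burying a 50+ nt tract under a 70-nt pairing span is only
  possible if the tract pairs with itself, so the buried construct is a
  self-folding tract of alternating C and G blocks (C·G:C weight 2, G·G:C
  weight 1: identity 100 against poly-G at every register). Its layout is
  dictated by the scan's window algebra: a single central C8 block makes
  the window anchored on it the unique stability-maximal window, so hits
  stack at the centre of the 134-bp target; U21 blocks flank the fold,
  scoring nothing against any reachable DNA column while exceeding the
  20-position zero-padding budget that the 60% identity floor allows a
  window, so boundary-register hits pad into folded RNA instead of the
  guards; and the fold's terminal blocks — whose one-sided pairing deficit
  pins the obligatory hairpin loops — stay outside every reportable
  window. Poly-C DNA spacers (a column that scores no triad in either
  orientation) isolate the TTS from its island flanks for the same reason.
* **Islands and SNPs.** Planted islands are CpG-repeat flanks around the
  TTS (total span ≈ 700–800 bp, merging across the spacers); SNPs are
  placed at the lncRNA locus centre ("inside") or 30 kb downstream
  ("outside").

Backgrounds are i.i.d. with GC 0.42 (mammalian-like), with one deliberate
exception: promoter and control backgrounds are rejection-resampled so that
no 50-bp window reaches 56% A or T. Such windows are themselves genuine
U·A:T/A·A:T triplex targets under the triad model, and a competing true
site in the "background" would make the planted ground truth ill-defined —
in early versions chance A-tracts hijacked the TFO1 cluster in a few
percent of simulations. Transcript backgrounds are A-rich
(A/C/U/G = 0.63/0.10/0.22/0.05): A and C are inert in parallel triads and
pair nothing relevant, G is scarce so exposed plants stay unstructured, and
the low pyrimidine content keeps shuffled copies of planted transcripts
from re-matching the homopurine target by composition alone.

What the generator does **not** emulate: repeat families, isochores,
realistic gene structure, linkage disequilibrium, transcript–genome
sequence identity (transcripts are supplied as separate FASTA, as cDNA
would be), or the thermodynamics of a full folding engine. Passing tests on
synthetic loci therefore demonstrate that every stage implements its
contract and that the stages compose correctly — not that the screen's
biological error rates on real genomes match those measured here.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (Ensembl/GFF3 convention);
  BED is converted on read and write.
* Threshold comparisons in the scan use exact integer-weighted arithmetic
  with a 1e−9 slack, so identity exactly 60% or stability exactly 1.0
  qualifies, in both the implementation and the oracle.
* The partition function uses per-position rescaling, keeping windows of a
  few hundred nt in double range; the scale cancels exactly in every
  probability.
* Ties: equal-depth TFO1 peaks resolve by higher mean member stability,
  then leftmost; equal-stability windows on a diagonal resolve by length,
  then leftmost; ranking resolves by tier, target count, enrichment, then
  pair identifiers. All outputs are deterministic for a given seed.
* Degenerate inputs: empty annotation sets, empty hit sets, profiles of
  unpairable sequences, and header-only reports are all defined and tested;
  ambiguous bases score weight 0 and trigger a warning above 10% of a
  sequence.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the defaults described
above: 5001-bp promoters, 500-nt transcripts, planted sites of 60–134 bp,
100-replicate recovery and discrimination studies, scan-oracle equivalence
on sequences up to 120 nt and folding-oracle equivalence up to 22 nt.
These sizes exercise every code path (full and boundary registers, merged
islands, multi-window profiles) while keeping the whole suite quick to run.

## Known limitations

* The scan is ungapped; insertions/deletions within a triplex are not
  modelled, and parity with gapped scanners is out of scope.
* Triad weights are a dimensionless 0/1/2 scale, not free energies; the pH
  dependence of C⁺·G:C is not modelled.
* The accessibility model ignores stacking, dangles and pseudoknots.
* The hierarchical filter's cutoffs are screen-level conventions; they
  reproduce the reference tier split but are not calibrated error rates.
* Cis-only: trans-chromosomal pairing is excluded by construction.
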