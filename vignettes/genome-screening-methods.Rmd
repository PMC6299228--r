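---
title: "Screening genomes for reductive dehalogenase gene clusters: methods and design notes"
author: "dehaloscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for reductive dehalogenase gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehaloscout)
```

## The screening model

Organohalide-respiring bacteria (OHRB) conserve energy by using halogenated
organic compounds as terminal electron acceptors. The key catalysts are
reductive dehalogenases, whose catalytic subunit (RDase A) is recognizable in
genome sequence by a small set of conserved features rather than by overall
sequence identity (which can fall below 10% between genuine RDase As):

* a twin-arginine translocation (Tat) export signal, `RRXFXK`, near the
  N terminus — its presence suggests a periplasmic mature protein, its
  absence a cytoplasmic one;
* two iron–sulfur cluster binding motifs, `CXXCXXCXXXCP` and `CXXCXXXCP`
  (X = any residue). Note that the long motif structurally nests an instance
  of the short one at offset +3, so the short motif is never absent when the
  long one is present;
* a small hydrophobic membrane-anchor protein (RDase B) encoded in close
  association, typically immediately downstream of RDase A;
* frequently, a sigma-54-dependent transcriptional activator (bacterial
  enhancer-binding protein, bEBP) nearby and a sigma-54 −24/−12 promoter
  element, degenerate consensus `YTGGCACGRNNNTTGC`, in the operon promoter.

`dehaloscout` operationalizes these features as a reusable pipeline: motif
scanning (`scan_motif()`), candidate calling (`call_rdase_candidates()`),
cluster characterization (`locate_rdase_b()`, `locate_regulators()`,
`scan_sigma54_promoter()`, `build_cluster_report()`), multi-genome surveys
(`survey_genomes()`), identity-based ortholog grouping and neighbor-joining
clade assignment (`ortholog_groups()`, `nj_tree()`, `assign_clades()`), and
the physiology calculations used to confirm that dehalogenation supports
growth (`electron_equivalents()`, `protein_yield()`, `mass_balance()`,
`relative_expression()`).

## Motif semantics

Motifs are degenerate strings: protein motifs over the 20 standard residues
plus the wildcard `X`, nucleotide motifs over the IUPAC codes. Scanning
reports **every overlapping occurrence** — completeness is cheap at these
motif lengths — and is deliberately conservative about ambiguity: an `N` in a
scanned nucleotide sequence and an `X` in a scanned protein match *no* motif
position, including motif `N`/`X`. An ambiguous base cannot certify a
promoter element, nor an ambiguous residue a Tat signal.

Both published spellings of the sigma-54 element are registered:
`sigma54_core` (the 16-mer, the shipped default) and `sigma54_extended`
(with the degenerate trailing `W`). Promoter scans use the coding-strand
window only by default, because the −24/−12 element is oriented with
transcription; a `both_strands` flag is available. `expand_motif()`
enumerates the concrete strings a motif denotes (refusing above a degeneracy
limit) and is the brute-force oracle the scanner is tested against.

## Candidate policy and cluster heuristics

A gene is called an RDase A candidate when it carries **both** Fe–S motifs
and its protein is 250–750 aa, or when an externally supplied domain-hit
table (hmmscan-style; domain id pfam13486) lists it. The Tat signal is
recorded as evidence and drives the localization prediction, but is never
required — a substantial fraction of genuine RDase As lack it. The both-motif
requirement can be relaxed to either-motif for sensitivity studies.

Where the underlying biology gives only qualitative guidance ("in close
association", "nearby"), the pipeline uses explicit, configurable windows
that are echoed into every report:

* RDase B is searched within 3 genes of the candidate (either side, same
  contig). A gene qualifies by annotation keyword (`reductive dehalogenase`,
  `anchoring`, `RdhB`, `membrane`, with protein ≤ 130 aa) or by a labelled
  hydropathy heuristic: ≤ 130 aa with at least two 19-residue windows of
  mean Kyte–Doolittle hydropathy ≥ 1.6, a crude membrane-anchor signature.
  When two genes qualify, the nearest wins; at equal distance downstream
  wins, since downstream is the canonical arrangement and upstream the rare
  exception.
* Regulators are searched within 5 genes. bEBPs are recognized by annotation
  keywords (`sigma-54`, `RpoN`, `Fis family`); as an auxiliary heuristic the
  invariant `GAFTGA` hexapeptide of the bEBP AAA+ domain is accepted and
  explicitly labelled `gaftga_heuristic` in the output. MarR and CRP/FNR
  regulators are flagged from annotation only.
* The promoter is scanned for the **operon's first gene only** (one promoter
  per operon, 500 bp by default). The operon is approximated as the maximal
  run of adjacent same-strand genes containing the candidate; its 5′-most
  member in reading orientation is the first gene. How far upstream a
  "promoter region" extends is not a settled quantity, so the window is an
  explicit parameter rather than a hidden constant.

## Identity, grouping, and trees

Percent identity is computed from a Needleman–Wunsch global alignment
(BLOSUM62, gap opening 10, gap extension 0.5; a gap of length L costs
10 + 0.5L) as 100 × matches / alignment length, with gap columns —
including terminal overhangs — in the denominator. Identity has no single
community definition; this full-length denominator is stable and
conservative for length-divergent RDases, and the choice is recorded here so
reported ranges are interpretable.

Ortholog groups at the conventional 90% cutoff are the connected components
of the ≥ cutoff graph (single linkage): a sequence joins a group when it
clears the cutoff to *any* member. Raising the cutoff can only split groups,
lowering it only merge them.

Alignment columns are filtered by site coverage before distance estimation:
a column is kept when at least 60% of rows carry an unambiguous, non-gap
residue (`X` counts as ambiguous). Distances are p-distances over the
pairwise-comparable columns, optionally Poisson-corrected (−ln(1−p)).
Maximum-likelihood JTT distances and ML tree search are deliberately out of
scope; the package provides Saitou–Nei neighbor joining, implemented
in-package so its output is bit-deterministic: Q-matrix ties are broken on
the lexicographically smallest leaf-label pair, and negative branch-length
estimates are clamped to zero with the deficit moved to the sister branch,
preserving the joined pair's path length. On additive matrices NJ is exact;
the test suite verifies reconstruction of 50 random additive matrices (4–8
taxa) to < 1e-9 and cross-checks topologies against an independent NJ
implementation.

Clade assignment is reference-based: each query leaf takes the clade of its
nearest reference leaf by patristic distance, exact ties are reported as
`ambiguous`, and the (unrooted) monophyly of every reference clade is checked
and reported. This nearest-reference rule is a proxy for designation by tree
node, which is inherently judgment-based; assignments on trees whose
reference clades are not monophyletic should be treated with caution.

## Physiology calculations

Reductive debromination transfers two electrons per bromine removed. For a
culture fed a brominated phenol, the electrons routed into dehalogenation
are reconstructed from product concentrations:
e⁻ (mmol) = 2 × Σ products (bromines removed × µM × litres) / 1000.
Electrons consumed by co-occurring sulfate or sulfur reduction are
deliberately not counted — the yield assay conditions this bookkeeping
mirrors used lactate plus the bromophenol only. Protein yield is then
mg protein per mmol e⁻, with mean ± sd over biological replicates.
The phenol-ring mass balance checks that the summed concentration of parent,
intermediates and product stays at its initial value; the default tolerance
of 15% reflects HPLC variability and is configurable.

qPCR expression uses the relative standard curve method: per gene, a gDNA
dilution series is fit as Cq = slope·log10(q) + intercept (efficiency
10^(−1/slope) − 1); technical replicates are averaged on the Cq scale before
interpolation (common practice; averaging quantities instead changes results
only at second order in the noise); target quantities are normalized to the
16S rRNA gene within each biological replicate; and the fold change is mean
induced / mean control normalized expression, with the sd taken across
biological replicates against the mean control. Controls are matched per
timepoint. The fold change is invariant to rescaling all quantities, so the
arbitrary units of the dilution series cancel.

## What the synthetic data emulate — and what they do not

The generators provide ground truth, not realism. `gen_genome()` plants
complete operons — RDase A with the requested motifs, RDase B downstream or
upstream, a divergently placed bEBP gene adjacent or one gene away, and a
concrete sigma-54 element at a stated offset (40–300 bp) upstream of the
operon's first gene — among motif-free background genes and decoys carrying
exactly one Fe–S motif or broken motifs. Defaults mirror the study
conditions: 1–3 operons, 5 decoys and 50 background genes per genome over
two contigs; Tat present with probability 0.5 (about half of surveyed RDase
As carry it); RDase B downstream/upstream/absent at 0.8/0.1/0.1; bEBP
adjacent/within-window/absent at 0.6/0.2/0.2; sigma-54 element present with
probability 0.85.

Three simplifications matter for interpreting green tests. First, background
composition is i.i.d. uniform with rejection sampling against the motif
registry (and `GAFTGA`), and whole genomes are re-drawn if a sigma-54 match
appears anywhere outside the planted sites — so planted-truth recovery is
exact *by construction*, and sensitivity/precision of 1.0 on synthetic
genomes says nothing about annotation noise, pseudogenes, or borderline
motif variants in real genomes. Second, the genes flanking a planted operon
are forced onto the opposite strand, so the same-strand-run operon
approximation is exact on synthetic data; in real genomes an adjacent
co-oriented gene can extend the run and shift the scanned promoter. Third,
back-translation uses a fixed codon per residue and no attempt is made to
mimic GC content or codon usage; nucleotide-level statistics of these
genomes are unrealistic by design.

The kinetics generator uses closed-form sequential first-order kinetics
(parent → intermediate → phenol), chosen for fixture realism only — the
organisms' actual rate laws are not inferred, and `k1 = k2` is rejected
rather than special-cased with the limit form. The qPCR generator puts
standards exactly on the line and perturbs only sample Cq values, which is
what makes the noiseless inversion (recovered fold within 1e-6 of truth at
folds 1–600, spanning the experimentally observed induction range) a
meaningful round-trip test of the analysis code rather than of the
instrument model.

## Numerical and validation choices

* Coordinates are 1-based inclusive everywhere (the GenBank/GFF3 native
  convention); no internal half-open conversion exists to get wrong.
* Translation is fixed to bacterial code 11; alternative initiation codons
  render as M; ambiguity codes other than N are rejected at genome read time.
* Validation problem sizes were chosen to keep the whole suite comfortably
  interactive: 20 synthetic genomes (≈55 genes each) for recovery, 10 × 50 kb
  nucleotide and 10 × 5 kaa protein sequences for the motif oracle, 50
  additive matrices for NJ, 20 alignments for the column filter, and short
  peptides for the exhaustive alignment oracle (whose cost grows
  combinatorially).
* The exhaustive alignment oracle enumerates *all* co-optimal global
  alignments; since co-optimal alignments can differ in identity, tests
  assert membership of the implementation's identity in the optimal set
  rather than equality with an arbitrary one.

## Known limitations

* Motif-based calling cannot see RDase As with degenerate Fe–S spacings;
  the external domain-table path exists precisely for profile-HMM evidence,
  but the HMM search itself is out of scope.
* No gene calling: annotations (GenBank or GFF3+FASTA) are required.
* No profile or mismatch-tolerant motif search, no position weight matrices.
* Trees are NJ on p/Poisson distances, not ML; deep branching orders should
  not be over-interpreted, and clade assignment inherits this approximation.
* Survey statistics describe whatever genome set is supplied; they are not
  comparable across annotation pipelines with different product vocabularies
  without harmonizing the keyword lists (all of which are arguments).
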