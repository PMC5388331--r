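---
title: "Structural comparative analysis of plastomes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural comparative analysis of plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plastid genomes are small, circular and structurally conservative, which is
exactly what makes their rare structural changes valuable systematic
characters. In papilionoid legumes three kinds of change dominate the
literature: large LSC inversions (a ~50-kb inversion shared by most
papilionoids; a ~36-kb inversion, nested inside it, marking the core
genistoids and mediated by flip-flop recombination between 29-bp repeats
near *trnS*-GGA and *trnS*-GCU; and a ~24-kb inversion nested further
inside, between spacers near *trnC*-GCA and *trnF*-GAA), repeated
pseudogenization or loss of *rps16*, and IR loss (out of scope here).
`plastomeR` implements the full desk-scale analysis chain for these
characters — quadripartite partitioning, gene-status classification,
gene-order-based inversion detection, in-silico PCR screening, and
parsimony mapping — driven entirely by a seeded synthetic-plastome
generator, so every claim the package makes is checkable offline.

# The synthetic stated world

The generator (`default_gene_catalog`, `generate_plastome`) does not try to
imitate real sequence evolution; it builds a genome whose *structure* is
right and whose parameters are the ones the analysis depends on:

* **Architecture.** LSC + IRa + SSC + IRb, with IRb the exact reverse
  complement of IRa. Full-profile region lengths are 85,140 / 25,494 /
  18,413 / 25,494 bp (total 154,541 bp), the dimensions of the sequenced
  Sophoreae plastome the pipeline is modelled on. A `"mini"` profile
  (~24 kb total) preserves the gene order and every inversion/assay anchor
  for fast tests; only size-sensitive checks need the full profile.
* **Gene catalog.** 76 protein-coding genes (the 71 conserved plastid
  protein-coding genes used in legume plastome phylogenetics, plus *accD*,
  *rps16*, *ycf1*, *ycf2*, *ycf4*), 31 tRNAs and 4 rRNAs; *rpl22* is absent
  (lost in legumes). *rps16* is modelled with two exons (42 + 231 bp) and
  an 860-bp group II intron, on the minus strand.
* **Homology.** All genomes of a panel share identical gene sequences,
  generated once under a fixed `ancestral_seed`; the per-genome `seed`
  varies only the intergenic spacers. Without this, cross-taxon alignment
  of "homologs" would see random indels everywhere and the gene-status
  module would be meaningless.
* **Base composition.** Spacers (and the base mix inside generated genes)
  use a 36.5% GC dial, the value reported for the reference genome.
  Because coding sequence is constrained (ATG starts, stop codons, no
  internal stops), the realized genome-wide GC lands near 37.2%, slightly
  above the dial; this is a property of the generator, not a tuning target.
* **Inversion anchors.** The 50-kb segment lies between the spacers after
  *trnK* and before *accD*; a 29-bp repeat pair in inverted orientation is
  planted next to *trnS*-GCU and *trnS*-GGA to delimit the 36-kb segment;
  the 24-kb segment sits inside it with *ndhJ* immediately outside its
  right breakpoint. All six breakpoints are pairwise distinct and interior
  to the LSC — the precondition for the seven-block decomposition below.
  The nesting is fully hierarchical (24 inside 36 inside 50), the default
  choice where the source material only states "embedded".
* **Primer sites.** The published screening primers are planted literally:
  each diagnostic site hugs its gene with a fixed 30-bp spacer and the
  breakpoint-facing spacers are a fixed 400 bp (200 bp in mini), which
  guarantees that the spacer midpoint — where `apply_inversion` cuts —
  falls strictly between the inside and outside sites, and that every
  diagnostic amplicon stays well under the 3,000-bp default length cap.
* **Mutation spectrum.** `mutate_gene` realizes start/stop-codon
  mutations, frameshift indels (including the exon2 "AAAC" duplication:
  the generator plants a unique AAAC motif at codon 10 of exon2, followed
  by codons chosen so that duplicating the motif shifts the frame onto an
  immediate in-frame stop), exon2 truncation, ~200-bp intron deletion, and
  whole-gene deletion.

What a green test does *not* establish: realism of nucleotide-level
variation (no substitution model along the tree), IR expansion/contraction,
sequencing artefacts, or annotation error. The generator's genomes are
perfectly annotated by construction; the pipeline's robustness to
mis-annotation is untested and out of scope.

# Models and numerical choices

**Inverted-repeat detection** is exact-match by default (`max_mismatch = 0`)
with `min_len = 1000` bp: the generator produces exact IRs and real plastid
IRs are conventionally near-identical. Candidate pairings are seeded with
100-bp probes matched against the reverse complement, deduplicated by
anti-diagonal, and extended in the paired sense (left end of one copy with
the right end of the other). The generator repairs its region junctions so
that the planted IR cannot be co-extended by chance, making recovery of the
planted length exact. Ties between equal-length candidate pairs go to the
pair with the larger minimum circular gap, then the lower start coordinate.
Copies that meet on the circle are flagged `degenerate`.

**Gene status** is a strict decision list: DELETED (locus absent) →
TRUNCATED (any exon aligned at coverage < 0.5 of its reference exon, or a
whole exon missing) → PUTATIVE_PSEUDOGENE (non-ATG/GTG start, lost
reference stop, net internal indel length not divisible by 3, or an
in-frame stop before the final 5% of the coding length) → INTACT. The 0.5
coverage threshold operationalizes "significant deletion", which the
source material leaves unquantified; it is a named parameter and the
survey records per-exon coverage so any other threshold can be re-applied.
Indels whose reference position lies within 9 bp of an exon end are
ignored for the frameshift rule — intact plastid genes tolerate small
end-of-exon indels — and that 9-bp window is this package's choice, not a
published number. Truncation outranks pseudogene evidence so categories
stay mutually exclusive. Intron damage is recorded as evidence but never
drives the category by itself. Pairwise alignment is global with affine
gaps (match +2, mismatch −3, gap open −5, gap extend −2; a gap of length L
costs open + L·extend), computed by `Biostrings::pairwiseAlignment` behind
the package's `global_align` contract and cross-checked against an
independent plain-R Gotoh implementation in the test suite. Tie-breaking
among co-optimal alignments follows Biostrings' deterministic traceback.

**Inversion detection** works on signed gene-order permutations rather than
sequence anchors: genomes are linearized at the IRb/LSC junction, one IR
copy is removed, and each single-copy gene becomes a signed marker
relative to a reference genome. This is exact, download-free, and
sufficient for multi-kilobase inversions; nucleotide-level collinear-block
anchoring (a Mauve re-implementation) is a declared non-goal, and the
package assumes — as the acceptance test states — that gene-adjacency
blocks correspond one-to-one to the published sequence-level blocks for
these genomes. A collinear block is a maximal run of reference markers
whose adjacencies (signs included) are conserved across all genomes;
the 4-genome panel (no inversion / 50 / 50+36 / 50+36+24) has six distinct
interior breakpoints and therefore exactly seven blocks. Histories are
inferred greedily: repeatedly reverse the longest interval that strictly
increases the count of correctly signed, correctly ordered adjacencies
(ties: leftmost). For nested histories this reports events outermost-first
and matches the exact reversal distance; for transposition-like
permutations the greedy path can stall, which is reported as `UNRESOLVED`
(with `fallback = "none"`). Because the module also promises agreement
with the exact BFS distance for ≤10 markers, the default
`fallback = "exact"` replaces a stalled or non-minimal greedy result with
a BFS shortest reversal sequence; the greedy contract remains available
and tested. Replaying inferred events in reverse order on the identity
always reproduces the observed permutation.

**In-silico PCR** uses a pure mismatch-count annealing model: a primer
binds where at most 2 mismatches occur and the 3 bases at its 3' end match
exactly; thermodynamics (Tm, dimers) are deliberately not modelled. Every
rightward-extending site paired with a leftward-extending site yields a
product along the arc the polymerase traverses, inclusive of both primers,
capped at 3,000 bp — consistent with the short extension times used in the
published screens. A genome is called PRESENT when only the presence pair
amplifies, ABSENT when only the absence pair does, AMBIGUOUS otherwise;
AMBIGUOUS taxa are excluded from tallies with a warning.

**Character mapping** uses Fitch parsimony with missing states free at the
tips. The synapomorphy test asks whether some minimal reconstruction has
exactly one 0→1 gain and no loss; it is computed with a loss-forbidden
Sankoff pass rooted in the ancestral (absent) state, whose optimum counts
independent gains. Characters with no informative 0-state taxon are
reported `single_origin = TRUE` but flagged low-information. Polytomies
are resolved arbitrarily with a warning (counts become upper bounds). Two
screening-panel topologies ship as fixtures: the main arrangement, under
which the nine 24-kb-positive taxa are monophyletic, and an
alternative nuclear-ITS-style arrangement that nests the two
24-kb-negative Sophoreae genera inside that clade, under which the
single-origin test correctly fails. The package asserts nothing about
which topology is true.

# Design decisions that were genuinely open

* The 24-kb preset anchors are expressed through the *outside* flanking
  genes (after *psaI*, before *ndhJ*) rather than the inside flanks
  (*trnC*, *trnF*) used in verbal descriptions: the outside genes do not
  move when the segment inverts, so the anchors resolve to the same
  physical spacer in either orientation and applying a preset twice is an
  exact involution of the gene order. Breakpoint labels still show the
  *trnC*/*trnF* flanks in the inverted genome.
* The 36-kb flip-flop cut points sit at symmetric offsets inside the two
  29-bp repeat copies (offset h from copy A's start pairs with offset h
  from copy B's end). With an odd repeat length, naive midpoints corrupt
  one repeat base and break the involution; the symmetric choice preserves
  both copies exactly.
* Published per-genome feature tallies are ambiguous about whether IR
  duplicates and introns are counted (135 "genic features" vs 111 unique
  genes); `genome_summary` reports unique counts, counts with IR
  duplicates, and the number of genic parts instead of guessing. The same
  applies to the coding fraction (the published 57.9% does not state its
  treatment of IR duplicates or structural RNAs): both a CDS-only and a
  CDS+tRNA/rRNA variant are reported.
* The four-way survey of the 33-genome panel is a synthetic stand-in: the
  real survey needs 33 GenBank downloads. Each panel taxon receives a
  planted mutation from its published status class (frameshift "AAAC"
  duplication plus ~200-bp intron erosion for most pseudogene taxa, one
  start-codon mutant for mechanistic variety, exon2 truncation, whole-gene
  deletion), and the classifier must recover the (15, 4, 8, 6) tally from
  sequence alone.

# Limitations

Marker granularity is genes, so inversions with both breakpoints inside a
single intergenic spacer region between the same gene pair would be
invisible to the permutation layer (the PCR layer can still see them).
Non-inversion rearrangements (transpositions, translocations) are flagged,
not reconstructed. The reversal-distance oracle is exponential and capped
at 10 markers. The annealing model ignores thermodynamics, so degenerate
or AT-rich primers behave more cleanly in silico than at the bench. Test
suites scale some property checks down from their nominal sizes (e.g. 250
rather than 1,000 random primers against the brute-force scan; 40 rather
than 1,000 random I/O round-trips) to stay inside the suite's runtime
budget; the checked models are size-agnostic.
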