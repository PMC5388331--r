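# plastomeR

Structural comparative analysis of plastid genomes (plastomes) in R, built
around the kind of question legume systematists ask: *which large inversions
does this chloroplast genome carry, is a gene such as* rps16 *still
functional, and do those characters mark a clade?*

Plastomes are circular, ~120–160 kb, and quadripartite: a large and a small
single-copy region (LSC, SSC) separated by a pair of inverted repeats
(IRa/IRb, one the reverse complement of the other). Papilionoid legumes are
famous for large LSC inversions — a ~50-kb inversion shared by most
papilionoids, a ~36-kb inversion (mediated by flip-flop recombination
between 29-bp repeats near two *trnS* genes) marking the core genistoids,
and a newly characterized ~24-kb inversion nested inside it — and for
repeated, independent degradation of *rps16*.

The package provides:

* **Quadripartite partitioning** — exact inverted-repeat detection on the
  circle and LSC/IRa/SSC/IRb decomposition with summary statistics
  (`find_inverted_repeat`, `partition_genome`, `genome_summary`).
* **Gene-status classification** — a four-way call per gene against an
  intact reference: `INTACT`, `PUTATIVE_PSEUDOGENE` (start/stop mutation,
  frameshift-inducing indels, premature in-frame stop), `TRUNCATED`
  (significant deletion), `DELETED` (`extract_locus`, `global_align`,
  `classify_locus`, `survey_gene`).
* **Inversion detection** — signed gene-order permutations over a shared
  marker set, locally collinear block (LCB) decomposition, exact
  reversal-distance BFS for small marker counts, greedy nested-inversion
  inference, and breakpoint localization to flanking intergenic spacers
  (`shared_gene_order`, `lcb_decomposition`, `infer_inversion_events`,
  `localize_breakpoints`).
* **In-silico PCR screening** — mismatch-model primer-site finding on
  circular genomes and the dual-assay presence/absence logic used in
  inversion screens (`find_primer_sites`, `predict_amplicons`,
  `screen_inversion`, `run_panel_screen`), with the published 36-kb and
  24-kb screening primers packaged (`screen_primers`, `default_assays`).
* **Parsimony character mapping** — Fitch counting of binary inversion
  characters with missing data and a single-origin (synapomorphy) test
  (`fitch_count`, `assess_synapomorphy`).
* **A synthetic-plastome generator** — seeded, annotated legume-like
  genomes with the quadripartite architecture, a 76-CDS/31-tRNA/4-rRNA
  catalog, planted 29-bp repeats and primer-binding sites, nested inversion
  histories and an *rps16* mutation spectrum, so the entire pipeline is
  testable offline (`default_gene_catalog`, `generate_plastome`,
  `apply_inversion`, `mutate_gene`, `build_panel`).

## Worked example

```r
library(plastomeR)

# an ancestral (uninverted) legume-like plastome at reference scale
genome <- generate_plastome(default_gene_catalog("full"), seed = 1)
part   <- partition_genome(genome)
part
#> Quadripartite partition: total 154,541 bp
#>   LSC    85,140 bp (start 0)
#>   IRa    25,494 bp (start 85140)
#>   SSC    18,413 bp (start 110634)
#>   IRb    25,494 bp (start 129047)

# apply the nested 50-kb -> 36-kb -> 24-kb inversion history
inv <- preset_inversions("full")
g <- apply_inversion(genome, inv$INV50)$record
g <- apply_inversion(g, inv$INV36)$record
g <- apply_inversion(g, inv$INV24)$record

# recover the history from the gene orders alone
perm <- shared_gene_order(g, genome)
hist <- infer_inversion_events(perm, g)
sapply(hist$events, `[[`, "size")
#> [1] 49200 35940 23102
hist$events[[2]]$mediating_repeat
#> $name
#> [1] "trnS-29bp-repeat"
#> $length
#> [1] 29

# screen for the 24-kb inversion with the packaged primer assays
screen_inversion(g, default_assays()$INV24)$call
#> [1] "PRESENT"
screen_inversion(genome, default_assays()$INV24)$call
#> [1] "ABSENT"

# classify a frameshifted rps16 against the intact copy
mut <- mutate_gene(g, "rps16",
                   mutation_spec("FRAMESHIFT_INSERTION", motif = "AAAC",
                                 exon = 2))
classify_locus(extract_locus(mut, "rps16"), extract_locus(genome, "rps16"))
#> Gene status: PUTATIVE_PSEUDOGENE
#>   - internal insertion of 4 bp in exon2 at ref pos 31
#>   - net internal indel length +4 not divisible by 3
#>   - in-frame internal stop at codon 29 of 92
```

The sizes reported by `infer_inversion_events` are the extents of the
inverted marker sets in the query genome, which is why they read slightly
under the nominal 50/36/24 kb (the flanking spacers up to the breakpoints
are not part of the marker extent).

An end-to-end run — simulate a 16-taxon screening panel, partition,
classify *rps16* across a 33-genome panel, detect inversions, screen, and
map the inversion characters on a phylogeny — is one call:

```r
report <- run_pipeline(run_config(seed = 1, profile = "mini"))
report$stages$pcr_screen$result$tallies$INV24$n_present_genera
#> [1] 8
report$stages$map_character$result$INV24$single_origin
#> [1] TRUE
```

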