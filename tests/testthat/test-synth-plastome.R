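# The synthetic-plastome generator: catalog, genome assembly, inversions,
# mutations, panels.

test_that("the default catalog matches the legume core gene set", {
  cat_full <- default_gene_catalog("full")
  cds <- cat_full[cat_full$kind == "CDS", ]
  expect_gte(nrow(cds), 71L)
  expect_equal(sum(cat_full$kind == "tRNA"), 31L)
  expect_equal(sum(cat_full$kind == "rRNA"), 4L)
  # anchors of the three inversions all sit in the LSC
  anchors <- c("accD", "trnK-UUU", "trnC-GCA", "trnF-GAA", "trnS-GCU",
               "trnS-GGA", "ndhJ", "rps16")
  expect_true(all(cat_full$region[cat_full$gene %in% anchors] == "LSC"))
  # genes are unique within each single-copy region
  for (reg in c("LSC", "SSC", "IR")) {
    expect_false(anyDuplicated(cat_full$gene[cat_full$region == reg]) > 0)
  }
})

test_that("rps16 is modelled with two exons and one intron", {
  rec <- mini_genome()
  loc <- extract_locus(rec, "rps16")
  expect_equal(length(loc$exons), 2L)
  expect_equal(length(loc$introns), 1L)
  expect_equal(nchar(loc$exons), c(42L, 231L))
  coding <- paste(loc$exons, collapse = "")
  expect_equal(substr(coding, 1, 3), "ATG")
  expect_true(substr(coding, nchar(coding) - 2, nchar(coding)) %in%
                c("TAA", "TAG", "TGA"))
  expect_true(is.na(first_internal_stop(coding)) ||
                first_internal_stop(coding) == nchar(coding) / 3)
})

test_that("IR genes appear exactly twice with opposite strands", {
  rec <- mini_genome()
  cat_mini <- default_gene_catalog("mini")
  ir_genes <- cat_mini$gene[cat_mini$region == "IR"]
  ft <- rec$features
  for (g in ir_genes) {
    rows <- ft[ft$gene == g & ft$kind %in% c("CDS", "tRNA", "rRNA"), ]
    expect_equal(length(unique(rows$feature_id)), 2L, info = g)
    expect_equal(sort(unique(rows$strand)), c(-1L, 1L), info = g)
  }
})

test_that("generated genome length equals the requested region lengths", {
  rec <- full_genome()
  expect_equal(nchar(rec$sequence), 85140L + 18413L + 2L * 25494L)
  expect_equal(nchar(rec$sequence), 154541L)
  # custom region lengths are honoured exactly
  custom <- generate_plastome(default_gene_catalog("mini"),
                              region_lengths = c(LSC = 16000, SSC = 2200,
                                                 IR = 4000),
                              seed = 5)
  expect_equal(nchar(custom$sequence), 16000L + 2200L + 8000L)
})

test_that("IRb is the exact reverse complement of IRa", {
  rec <- mini_genome()
  part <- partition_genome(rec)
  r <- part$regions
  ira <- substr(rec$sequence, r$start[r$region == "IRa"] + 1L,
                r$start[r$region == "IRa"] + r$length[r$region == "IRa"])
  irb <- substr(rec$sequence, r$start[r$region == "IRb"] + 1L,
                r$start[r$region == "IRb"] + r$length[r$region == "IRb"])
  expect_identical(ira, revcomp(irb))
})

test_that("generation is seeded-deterministic and seed changes only spacers", {
  cat_mini <- default_gene_catalog("mini")
  a <- generate_plastome(cat_mini, seed = 9L)
  b <- generate_plastome(cat_mini, seed = 9L)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$features, b$features)
  c <- generate_plastome(cat_mini, seed = 10L)
  expect_false(identical(a$sequence, c$sequence))
  expect_identical(feature_table(a)$gene, feature_table(c)$gene)
  # gene sequences are shared (ancestral content), spacers differ
  expect_identical(feature_seq(a, "rbcL"), feature_seq(c, "rbcL"))
})

test_that("a too-small region raises a sizing error listing the deficit", {
  expect_error(
    generate_plastome(default_gene_catalog("mini"),
                      region_lengths = c(LSC = 4000, SSC = 2000, IR = 3600),
                      seed = 1),
    "too small.*deficit")
})

test_that("preset inversions realize their nominal sizes within 10%", {
  rec <- full_genome()
  inv <- preset_inversions("full")
  r50 <- apply_inversion(rec, inv$INV50)
  r36 <- apply_inversion(r50$record, inv$INV36)
  r24 <- apply_inversion(r36$record, inv$INV24)
  expect_lt(abs(r50$event$size - 50000) / 50000, 0.10)
  expect_lt(abs(r36$event$size - 36000) / 36000, 0.10)
  expect_lt(abs(r24$event$size - 24000) / 24000, 0.10)
})

test_that("apply_inversion flips contained features and is an involution", {
  rec <- mini_genome()
  inv <- preset_inversions("mini")
  out <- apply_inversion(rec, inv$INV50)
  ev <- out$event
  ft0 <- feature_table(rec)
  ft1 <- feature_table(out$record)
  inside0 <- ft0$start >= ev$start & ft0$end <= ev$end
  m <- match(ft0$feature_id, ft1$feature_id)
  expect_true(all(ft1$strand[m][inside0] == -ft0$strand[inside0]))
  expect_true(all(ft1$strand[m][!inside0] == ft0$strand[!inside0]))
  expect_true(all(ft1$start[m][!inside0] == ft0$start[!inside0]))
  # gene content is invariant
  expect_identical(sort(ft0$gene), sort(ft1$gene))
  # involution restores the gene order
  back <- apply_inversion(out$record, inv$INV50)$record
  expect_identical(feature_table(back)$gene, feature_table(rec)$gene)
})

test_that("an unresolvable anchor raises an anchor-resolution error", {
  rec <- mini_genome()
  spec <- inversion_spec("bad", anchor_igs("nosuchgene", "after"),
                         anchor_igs("accD", "before"))
  expect_error(apply_inversion(rec, spec), "not found")
  spec2 <- inversion_spec("bad2", anchor_repeat("nosuchrepeat", 1L),
                          anchor_repeat("nosuchrepeat", 2L))
  expect_error(apply_inversion(rec, spec2), "not found")
})

test_that("mutations are realized exactly on the coding strand", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")

  # AAAC duplication in exon2
  m <- mutate_gene(rec, "rps16",
                   mutation_spec("FRAMESHIFT_INSERTION", motif = "AAAC",
                                 exon = 2L))
  loc <- extract_locus(m, "rps16")
  expect_equal(nchar(loc$exons[2]), nchar(ref$exons[2]) + 4L)
  expect_true(grepl("AAACAAAC", loc$exons[2], fixed = TRUE))
  expect_identical(loc$exons[1], ref$exons[1])

  # whole-gene deletion removes the locus
  d <- mutate_gene(rec, "rps16", mutation_spec("WHOLE_GENE_DELETION"))
  expect_null(extract_locus(d, "rps16"))
  expect_equal(nchar(d$sequence),
               nchar(rec$sequence) - (42L + 860L + 231L))

  # ~200-bp intron deletion leaves the exons untouched
  i <- mutate_gene(rec, "rps16", mutation_spec("INTRON_DELETION", len = 200L))
  loci <- extract_locus(i, "rps16")
  expect_identical(loci$exons, ref$exons)
  expect_equal(nchar(loci$introns[1]), 860L - 200L)

  # frameshift spec validation
  expect_error(mutation_spec("FRAMESHIFT_INSERTION", motif = "AAACGG"),
               "divisible by 3")
  expect_error(mutate_gene(rec, "nosuchgene",
                           mutation_spec("WHOLE_GENE_DELETION")),
               "not found")
})

test_that("minus-strand extraction returns the reverse complement of the slice", {
  rec <- mini_genome()
  ft <- rec$features
  row <- ft[ft$gene == "psbA" & ft$kind == "CDS", ]
  expect_equal(row$strand, -1L)
  slice <- substr(rec$sequence, row$start + 1L, row$end)
  expect_identical(extract_locus(rec, "psbA")$exons[1], revcomp(slice))
})

test_that("build_panel applies per-taxon inversion states", {
  panel <- mini_screen_panel()
  expect_equal(length(panel), 16L)
  cfg <- screen_panel_config()
  # Maackia has all three inversions, Cladrastis none: their LSC gene
  # orders differ, while two all-absent taxa agree
  go <- function(r) paste(feature_table(r)$gene, collapse = ",")
  expect_false(identical(go(panel$Maackia_fauriei),
                         go(panel$Cladrastis_wilsonii)))
  expect_identical(go(panel$Cladrastis_wilsonii),
                   go(panel$Styphnolobium_japonicum))
  expect_error(build_panel(data.frame(taxon = c("a", "a"))), "unique")
})
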