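# Gene catalog for the synthetic legume plastome generator.
#
# The catalog lists every annotated element of the simulated genome in
# ancestral (pre-inversion) genomic order, with its region (LSC/SSC/IR) and
# a finer "zone" that encodes where the element sits relative to the three
# nested LSC inversion segments:
#
#   z_out_L | z_50L | z_36L |      z_24      | z_36R | z_50R | z_out_R
#          BP50L   BP36L  BP24L            BP24R   BP36R   BP50R
#
# The 50-kb segment is delimited by intergenic spacers near trnK (left) and
# accD (right); the 36-kb segment by the midpoints of two planted 29-bp
# inverted repeats next to trnS-GCU and trnS-GGA; the 24-kb segment by
# spacers near trnC-GCA and trnF-GAA, with ndhJ immediately outside its
# right breakpoint.  This geometry is what makes the packaged PCR assays
# informative: inverting the 24-kb segment moves trnC next to ndhJ and
# moves trnF away.

# Typical plastid gene lengths in bp (CDS lengths are codon multiples and
# include the stop codon; tRNA/rRNA lengths are structural).
PLASTID_GENE_LENGTHS <- c(
  atpA = 1524, atpB = 1497, atpE = 402, atpF = 555, atpH = 246, atpI = 744,
  ccsA = 960, cemA = 690, clpP = 591, matK = 1530,
  ndhA = 1092, ndhB = 1530, ndhC = 363, ndhD = 1503, ndhE = 306,
  ndhF = 2220, ndhG = 531, ndhH = 1182, ndhI = 504, ndhJ = 477, ndhK = 678,
  petA = 963, petB = 648, petD = 483, petG = 114, petL = 96, petN = 90,
  psaA = 2253, psaB = 2205, psaC = 246, psaI = 111, psaJ = 135,
  psbA = 1062, psbB = 1527, psbC = 1386, psbD = 1062, psbE = 252,
  psbF = 120, psbH = 222, psbI = 111, psbJ = 123, psbK = 186, psbL = 117,
  psbM = 105, psbN = 132, psbT = 108, psbZ = 189,
  rbcL = 1434, rpl2 = 1482, rpl14 = 369, rpl16 = 408, rpl20 = 354,
  rpl23 = 282, rpl32 = 174, rpl33 = 201, rpl36 = 114,
  rpoA = 1014, rpoB = 3213, rpoC1 = 2052, rpoC2 = 4110,
  rps2 = 711, rps3 = 657, rps4 = 606, rps7 = 468, rps8 = 405,
  rps11 = 417, rps12 = 372, rps14 = 303, rps15 = 273, rps19 = 279,
  ycf1 = 5400, ycf2 = 6840, ycf3 = 507, ycf4 = 555,
  accD = 1500, rps16 = 273,
  # structural RNAs
  rrn16 = 1491, rrn23 = 2810, rrn4.5 = 103, rrn5 = 121
)

TRNA_LENGTHS_DEFAULT <- 74L

# rps16 internal structure: exon1 + group II intron + exon2; coding length
# (exon1 + exon2) is the 273 bp above.
RPS16_EXON1 <- 42L
RPS16_EXON2 <- 231L
RPS16_INTRON <- 860L

# Genes marked minus-strand in the ancestral arrangement (a representative
# mix; inversions flip strands downstream).
MINUS_STRAND_GENES <- c("psbA", "trnK-UUU", "rps16", "trnQ-UUG", "trnC-GCA",
                        "psaA", "psaB", "rps14", "trnF-GAA", "ndhJ", "ndhK",
                        "ndhC", "rpoA", "rps11", "rpl36", "ndhF", "rpl32",
                        "ccsA", "ndhD", "ndhE", "ndhG", "ndhI", "ndhA",
                        "ndhH", "rps15", "ycf1", "rpl2", "rpl23", "trnI-CAU",
                        "ycf2", "trnL-CAA", "ndhB", "rps7")

catalog_row <- function(gene, kind, region, zone) {
  len <- if (kind == "tRNA") {
    TRNA_LENGTHS_DEFAULT
  } else {
    unname(PLASTID_GENE_LENGTHS[[sub("-.*$", "", gene)]])
  }
  strand <- if (gene %in% MINUS_STRAND_GENES) -1L else 1L
  data.frame(gene = gene, kind = kind, strand = strand, length = len,
             region = region, zone = zone, stringsAsFactors = FALSE)
}

.catalog_genes <- function(profile) {
  g <- function(genes, kind, region, zone) {
    do.call(rbind, lapply(genes, catalog_row, kind = kind, region = region,
                          zone = zone))
  }
  t_ <- function(genes, region, zone) g(genes, "tRNA", region, zone)
  c_ <- function(genes, region, zone) g(genes, "CDS", region, zone)
  r_ <- function(genes, region, zone) g(genes, "rRNA", region, zone)

  if (profile == "full") {
    rbind(
      # --- LSC ---
      t_("trnH-GUG", "LSC", "z_out_L"), c_(c("psbA", "matK"), "LSC", "z_out_L"),
      t_("trnK-UUU", "LSC", "z_out_L"),
      c_("rps16", "LSC", "z_50L"), t_("trnQ-UUG", "LSC", "z_50L"),
      c_(c("psbK", "rps4"), "LSC", "z_50L"),
      t_("trnS-GCU", "LSC", "z_36L"), c_(c("ycf3", "psaI"), "LSC", "z_36L"),
      t_("trnC-GCA", "LSC", "z_24"), c_(c("petN", "psbM"), "LSC", "z_24"),
      t_(c("trnD-GUC", "trnY-GUA", "trnE-UUC", "trnT-GGU"), "LSC", "z_24"),
      c_(c("psbD", "psbC"), "LSC", "z_24"), t_("trnS-UGA", "LSC", "z_24"),
      c_("psbZ", "LSC", "z_24"),
      t_(c("trnG-GCC", "trnfM-CAU"), "LSC", "z_24"),
      c_(c("rps14", "psaB", "psaA"), "LSC", "z_24"),
      t_(c("trnL-UAA", "trnT-UGU", "trnM-CAU", "trnV-UAC"), "LSC", "z_24"),
      c_(c("atpB", "atpE", "rbcL"), "LSC", "z_24"),
      t_("trnF-GAA", "LSC", "z_24"),
      c_(c("ndhJ", "ndhK", "ndhC", "atpI", "atpH", "atpF", "atpA", "rps2"),
         "LSC", "z_36R"),
      t_(c("trnR-UCU", "trnG-UCC", "trnS-GGA"), "LSC", "z_36R"),
      c_(c("psbI", "rpoB", "rpoC1", "rpoC2"), "LSC", "z_50R"),
      c_(c("accD", "ycf4", "cemA", "petA", "psbJ", "psbL", "psbF", "psbE",
           "petL", "petG"), "LSC", "z_out_R"),
      t_(c("trnW-CCA", "trnP-UGG", "trnP-GGG"), "LSC", "z_out_R"),
      c_(c("psaJ", "rpl33", "rps12", "rpl20", "clpP", "psbB", "psbT", "psbN",
           "psbH", "petB", "petD", "rpoA", "rps11", "rpl36", "rps8", "rpl14",
           "rpl16", "rps3", "rps19"), "LSC", "z_out_R"),
      # --- IR (IRa orientation, LSC -> SSC) ---
      c_(c("rpl2", "rpl23"), "IR", "IR"), t_("trnI-CAU", "IR", "IR"),
      c_("ycf2", "IR", "IR"), t_("trnL-CAA", "IR", "IR"),
      c_(c("ndhB", "rps7"), "IR", "IR"), t_("trnV-GAC", "IR", "IR"),
      r_("rrn16", "IR", "IR"), t_(c("trnI-GAU", "trnA-UGC"), "IR", "IR"),
      r_(c("rrn23", "rrn4.5", "rrn5"), "IR", "IR"),
      t_(c("trnR-ACG", "trnN-GUU"), "IR", "IR"),
      # --- SSC ---
      c_(c("ndhF", "rpl32"), "SSC", "SSC"), t_("trnL-UAG", "SSC", "SSC"),
      c_(c("ccsA", "ndhD", "psaC", "ndhE", "ndhG", "ndhI", "ndhA", "ndhH",
           "rps15", "ycf1"), "SSC", "SSC")
    )
  } else {
    rbind(
      t_("trnH-GUG", "LSC", "z_out_L"), c_("psbA", "LSC", "z_out_L"),
      t_("trnK-UUU", "LSC", "z_out_L"),
      c_(c("rps16", "rps4"), "LSC", "z_50L"),
      t_("trnS-GCU", "LSC", "z_36L"), c_(c("ycf3", "psaI"), "LSC", "z_36L"),
      t_("trnC-GCA", "LSC", "z_24"), c_(c("psbD", "rbcL"), "LSC", "z_24"),
      t_("trnF-GAA", "LSC", "z_24"),
      c_(c("ndhJ", "ndhK"), "LSC", "z_36R"), t_("trnS-GGA", "LSC", "z_36R"),
      c_(c("psbI", "petB"), "LSC", "z_50R"),
      c_(c("accD", "rpl16", "rps19"), "LSC", "z_out_R"),
      c_("ndhB", "IR", "IR"), t_("trnV-GAC", "IR", "IR"),
      r_(c("rrn16", "rrn5"), "IR", "IR"),
      c_(c("rpl32", "ccsA", "rps15"), "SSC", "SSC")
    )
  }
}

ZONE_TARGETS <- list(
  full = c(z_out_L = 4500, z_50L = 3500, z_36L = 2500, z_24 = 24000,
           z_36R = 9500, z_50R = 10500, z_out_R = 30640,
           IR = 25494, SSC = 18413),
  mini = c(z_out_L = 1600, z_50L = 2400, z_36L = 1400, z_24 = 3600,
           z_36R = 1900, z_50R = 1300, z_out_R = 3100,
           IR = 3600, SSC = 1900)
)

# Width of the fixed spacer flanking an IGS-anchored inversion breakpoint.
BOUNDARY_GAP <- c(full = 400, mini = 200)
# Width of the small spacer hugging planted primer sites and repeats.
HUG_GAP <- 30

#' Default gene catalog for the synthetic plastome
#'
#' The catalog holds, in ancestral genomic order, the 76 protein-coding
#' genes (the 71 conserved plastid protein-coding genes of the legume core
#' set plus `accD`, `rps16`, `ycf1`, `ycf2` and `ycf4`), 31 tRNAs and the 4
#' ribosomal RNAs, each with its kind, ancestral strand, length and region.
#' `rps16` is modelled with two exons and a group II intron. IR genes are
#' listed once (in IRa orientation); the generator creates the mirrored IRb
#' copies. The `"mini"` profile is a reduced catalog (same ordering, all
#' inversion and assay anchors retained) for fast tests.
#'
#' @param profile `"full"` (~154.5 kb genome) or `"mini"` (~24 kb).
#' @return A data frame with columns `gene`, `kind`, `strand`, `length`,
#'   `region`, `zone`, plus attributes `profile` and `zone_targets`.
#' @export
default_gene_catalog <- function(profile = c("full", "mini")) {
  profile <- match.arg(profile)
  cat <- .catalog_genes(profile)
  rownames(cat) <- NULL
  attr(cat, "profile") <- profile
  attr(cat, "zone_targets") <- ZONE_TARGETS[[profile]]
  cat
}

#' Region lengths implied by a catalog's zone targets
#'
#' @param catalog A catalog from [default_gene_catalog()].
#' @return Named numeric `c(LSC =, SSC =, IR =)` in bp.
#' @export
catalog_region_lengths <- function(catalog) {
  zt <- attr(catalog, "zone_targets")
  lsc <- sum(zt[c("z_out_L", "z_50L", "z_36L", "z_24", "z_36R", "z_50R",
                  "z_out_R")])
  c(LSC = unname(lsc), SSC = unname(zt[["SSC"]]), IR = unname(zt[["IR"]]))
}
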