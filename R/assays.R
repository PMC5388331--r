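# Packaged screening fixtures: the published primer panel for the 36-kb and
# 24-kb LSC inversions, the dual-assay definitions (one primer pair that
# amplifies across the ancestral junction, one across the inverted
# junction), the 16-taxon screening panel with tribe labels and inversion
# states, and the 33-taxon rps16 survey panel with its planted mutation
# classes. All of these are synthetic-world stand-ins driven by the
# generator; taxon names and primer sequences follow the published screen.

#' Screening primers for the 36-kb and 24-kb inversion assays
#'
#' @return Data frame with columns `primer` and `sequence` (5'->3').
#' @export
screen_primers <- function() {
  data.frame(
    primer = c("rps4-bef-F", "ycf3-bef-R", "ycf3-inv-F", "psbI-int-R",
               "FGA-ndhJ-F", "FGA-trnF-R", "FGA-trnC-R"),
    sequence = c("CAATCAAATAATAGATAGTAAATGGGTTG",
                 "GGAATTATTCGTAATAATATATTGGCTAC",
                 "CGTAATAAGATATTGGCTAC",
                 "CTCTTTTCATCTTCGGATTC",
                 "CGTTCCCAATGTGCCTAT",
                 "TGGTAGAGCAGAGGACTG",
                 "CAAATCCTTTTTCCCCAGTT"),
    stringsAsFactors = FALSE)
}

#' Construct a primer pair
#'
#' @param name Pair label.
#' @param forward,reverse Primer sequences, 5'->3', over `ACGT`,
#'   length >= 15.
#' @return A `PrimerPair` object.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- check_dna(forward, "forward primer")
  reverse <- check_dna(reverse, "reverse primer")
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primer sequences must be at least 15 bp", call. = FALSE)
  }
  if (grepl("N", forward) || grepl("N", reverse)) {
    stop("primer sequences must not contain N", call. = FALSE)
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "PrimerPair")
}

#' Construct an inversion assay definition
#'
#' An assay couples the primer pair diagnostic for the ancestral (absence)
#' junction with the pair diagnostic for the inverted (presence) junction.
#'
#' @param inversion Inversion name (e.g. `"INV24"`).
#' @param absence_pair,presence_pair [primer_pair()] objects; must differ.
#' @param max_len Maximum amplicon length in bp considered amplifiable.
#' @return An `AssayDefinition` object.
#' @export
assay_definition <- function(inversion, absence_pair, presence_pair,
                             max_len = 3000L) {
  stopifnot(inherits(absence_pair, "PrimerPair"),
            inherits(presence_pair, "PrimerPair"))
  if (identical(absence_pair[c("forward", "reverse")],
                presence_pair[c("forward", "reverse")])) {
    stop("absence and presence pairs must be distinct", call. = FALSE)
  }
  structure(list(inversion = inversion, absence_pair = absence_pair,
                 presence_pair = presence_pair, max_len = as.integer(max_len)),
            class = "AssayDefinition")
}

#' Packaged inversion assays
#'
#' The 36-kb assay uses the published pairs rps4-bef-F/ycf3-bef-R (absence)
#' and ycf3-inv-F/psbI-int-R (presence); the 24-kb assay shares an anchor
#' primer: FGA-ndhJ-F/FGA-trnF-R (absence) and FGA-ndhJ-F/FGA-trnC-R
#' (presence).
#'
#' @param max_len Maximum amplicon length in bp.
#' @return Named list of [assay_definition()] objects (`INV36`, `INV24`).
#' @export
default_assays <- function(max_len = 3000L) {
  p <- screen_primers()
  pseq <- stats::setNames(p$sequence, p$primer)
  list(
    INV36 = assay_definition(
      "INV36",
      absence_pair = primer_pair("36kb-ancestral", pseq[["rps4-bef-F"]],
                                 pseq[["ycf3-bef-R"]]),
      presence_pair = primer_pair("36kb-inverted", pseq[["ycf3-inv-F"]],
                                  pseq[["psbI-int-R"]]),
      max_len = max_len),
    INV24 = assay_definition(
      "INV24",
      absence_pair = primer_pair("24kb-ancestral", pseq[["FGA-ndhJ-F"]],
                                 pseq[["FGA-trnF-R"]]),
      presence_pair = primer_pair("24kb-inverted", pseq[["FGA-ndhJ-F"]],
                                  pseq[["FGA-trnC-R"]]),
      max_len = max_len)
  )
}

#' The 16-taxon inversion screening panel
#'
#' One row per sampled taxon with its tribe (tribal classification in the
#' pre-merger sense, under which the core genistoids span five tribes), and
#' the inversion states used by the generator: the three genera outside the
#' papilionoid 50-kb inversion clade lack all three inversions; core
#' genistoids carry the 36-kb inversion; the 24-kb inversion marks the
#' Sophoreae/Euchresteae/Thermopsideae subgroup.
#'
#' @return Data frame with columns `taxon`, `tribe`, `inv50`, `inv36`,
#'   `inv24`.
#' @export
screen_panel_config <- function() {
  df <- data.frame(
    taxon = c("Cladrastis_wilsonii", "Styphnolobium_japonicum",
              "Camoensia_brevicalyx", "Crotalaria_capensis",
              "Lupinus_luteus", "Bolusanthus_speciosus",
              "Dicraeopetalum_mahafaliense", "Anagyris_foetida",
              "Baptisia_australis", "Piptanthus_nepalensis",
              "Thermopsis_fabacea", "Maackia_fauriei",
              "Salweenia_bouffordiana", "Sophora_koreensis",
              "Sophora_flavescens", "Euchresta_japonica"),
    tribe = c("Sophoreae p.p.", "Sophoreae p.p.", "Sophoreae s.s.",
              "Crotalarieae", "Genisteae", "Sophoreae s.s.",
              "Sophoreae s.s.", "Thermopsideae", "Thermopsideae",
              "Thermopsideae", "Thermopsideae", "Sophoreae s.s.",
              "Sophoreae s.s.", "Sophoreae s.s.", "Sophoreae s.s.",
              "Euchresteae"),
    inv36 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    inv24 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
              TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  # Taxa outside the 50-kb clade additionally lack the 50-kb inversion.
  df$inv50 <- !(df$taxon %in% c("Cladrastis_wilsonii",
                                "Styphnolobium_japonicum",
                                "Camoensia_brevicalyx"))
  df$genus <- sub("_.*$", "", df$taxon)
  df[c("taxon", "genus", "tribe", "inv50", "inv36", "inv24")]
}

#' The 33-taxon rps16 survey panel (synthetic stand-in)
#'
#' One row per complete legume plastome surveyed for rps16 status, with the
#' published status as the planted truth class for the generator: 15 intact,
#' 4 putative pseudogenes, 8 truncated, 6 deleted.
#'
#' @return Data frame with columns `taxon` and `status` (one of `intact`,
#'   `pseudogene`, `truncated`, `deleted`).
#' @export
rps16_survey_config <- function() {
  data.frame(
    taxon = c("Cercis_canadensis", "Tamarindus_indica", "Ceratonia_siliqua",
              "Caesalpinia_coriaria", "Haematoxylum_brasiletto",
              "Prosopis_glandulosa", "Leucaena_trichandra",
              "Inga_leiocalycina", "Acacia_ligulata", "Arachis_hypogaea",
              "Lupinus_albus", "Lupinus_luteus", "Maackia_fauriei",
              "Indigofera_tinctoria", "Millettia_pinnata", "Apios_americana",
              "Pachyrhizus_erosus", "Glycine_max", "Phaseolus_vulgaris",
              "Vigna_unguiculata", "Robinia_pseudoacacia", "Lotus_japonicus",
              "Wisteria_floribunda", "Glycyrrhiza_glabra",
              "Astragalus_mongholicus", "Cicer_arietinum", "Medicago_truncatula",
              "Trifolium_aureum", "Trifolium_subterraneum", "Pisum_sativum",
              "Lathyrus_sativus", "Vicia_faba", "Lens_culinaris"),
    status = c("intact", "intact", "intact", "intact", "intact", "intact",
               "intact", "intact", "intact", "deleted", "pseudogene",
               "pseudogene", "pseudogene", "intact", "intact", "deleted",
               "intact", "intact", "truncated", "intact", "truncated",
               "intact", "pseudogene", "truncated", "truncated", "truncated",
               "deleted", "truncated", "truncated", "deleted", "deleted",
               "truncated", "deleted"),
    stringsAsFactors = FALSE)
}
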