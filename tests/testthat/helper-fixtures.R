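# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- builder()
  }
  .fixture_cache[[name]]
}

mini_genome <- function(seed = 101L) {
  fixture(paste0("mini_", seed), function() {
    generate_plastome(default_gene_catalog("mini"), seed = seed, id = "mini")
  })
}

full_genome <- function(seed = 101L) {
  fixture(paste0("full_", seed), function() {
    generate_plastome(default_gene_catalog("full"), seed = seed, id = "full")
  })
}

mini_align_panel <- function(seed = 7L) {
  fixture(paste0("align_mini_", seed), function() {
    build_panel(alignment_panel_config(), seed = seed, profile = "mini")
  })
}

mini_screen_panel <- function(seed = 7L) {
  fixture(paste0("screen_mini_", seed), function() {
    build_panel(screen_panel_config(), seed = seed, profile = "mini")
  })
}

# small hand-made record: `genes` is a data.frame(gene, kind, strand, start,
# end) over an explicit sequence
toy_record <- function(sequence, genes = NULL, id = "toy") {
  ft <- if (is.null(genes) || nrow(genes) == 0L) {
    NULL
  } else {
    data.frame(feature_id = paste0(genes$gene, "_f"), gene = genes$gene,
               kind = genes$kind, strand = genes$strand, part = 1L,
               start = genes$start, end = genes$end, stringsAsFactors = FALSE)
  }
  if (is.null(ft)) {
    plastome_record(id, sequence)
  } else {
    plastome_record(id, sequence, ft)
  }
}

signed_perm <- function(perm, taxon = "toy") {
  structure(list(taxon = taxon, perm = as.integer(perm),
                 markers = paste0("m", seq_along(perm))),
            class = "SignedPermutation")
}

random_signed_history <- function(n, k) {
  perm <- seq_len(n)
  ivs <- list()
  for (r in seq_len(k)) {
    ij <- sort(sample(n, 2L))
    perm[ij[1L]:ij[2L]] <- -rev(perm[ij[1L]:ij[2L]])
    ivs[[r]] <- ij
  }
  list(perm = as.integer(perm), reversals = ivs)
}

random_tree <- function(n_tips) {
  ape::rtree(n_tips, rooted = TRUE,
             tip.label = paste0("t", seq_len(n_tips)))
}
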