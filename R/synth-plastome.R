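# Seeded generator of annotated synthetic plastomes.
#
# The generator lays the catalog out zone by zone (see synth-catalog.R),
# fills intergenic spacers with seeded random sequence at a configurable GC
# content, plants the two 29-bp inverted repeats that anchor the 36-kb
# inversion, and plants the published screening-primer binding sites at the
# positions that make the packaged assays informative. IRb is the exact
# reverse complement of IRa by construction.

LSC_ZONES <- c("z_out_L", "z_50L", "z_36L", "z_24", "z_36R", "z_50R",
               "z_out_R")
REPEAT_NAME <- "trnS-29bp-repeat"
REPEAT_LEN <- 29L

# Run code with a temporarily fixed RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable derivation of per-task child seeds from one pipeline seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# --- zone layout ---------------------------------------------------------

item_gene <- function(row, gap) {
  glen <- if (row$gene == "rps16") {
    RPS16_EXON1 + RPS16_INTRON + RPS16_EXON2
  } else {
    row$length
  }
  list(type = "gene", gene = row$gene, kind = row$kind, strand = row$strand,
       coding_len = row$length, genomic_len = as.integer(glen), gap = gap)
}
item_site <- function(primer, orient, gap) {
  seqs <- screen_primers()
  s <- seqs$sequence[seqs$primer == primer]
  list(type = "site", gene = primer, kind = "primer_site",
       strand = as.integer(orient), genomic_len = nchar(s), content = s,
       gap = gap)
}
item_repeat <- function(copy, gap) {
  list(type = "repeat", gene = REPEAT_NAME, kind = "repeat",
       strand = if (copy == 1L) 1L else -1L, genomic_len = REPEAT_LEN,
       copy = copy, gap = gap)
}

# gap classes: "R" random (min 30), "B" fixed boundary spacer, "H" fixed hug
zone_items <- function(zone, catalog, bnd) {
  rows <- catalog[catalog$zone == zone, , drop = FALSE]
  gene_items <- lapply(seq_len(nrow(rows)),
                       function(i) item_gene(rows[i, , drop = FALSE], "R"))
  names(gene_items) <- rows$gene
  ins_after <- function(items, anchor, new) {
    i <- which(vapply(items, function(x) x$gene, character(1)) == anchor)
    append(items, list(new), after = i)
  }
  set_gap <- function(items, gene, gap) {
    i <- which(vapply(items, function(x) x$gene, character(1)) == gene)
    items[[i]]$gap <- gap
    items
  }
  trail <- "R"
  items <- gene_items
  if (zone == "z_out_L") {
    trail <- "B"                                   # BP50L outside
  } else if (zone == "z_50L") {
    items <- set_gap(items, items[[1]]$gene, "B")  # BP50L inside
    items <- ins_after(items, "rps4", item_site("rps4-bef-F", +1L, "H"))
    items <- append(items, list(item_repeat(1L, "H")))
    trail <- "H"                                   # BP36L = repeat A midpoint
  } else if (zone == "z_36L") {
    items <- set_gap(items, "trnS-GCU", "H")
    items <- ins_after(items, "trnS-GCU", item_site("ycf3-bef-R", -1L, "H"))
    items <- set_gap(items, "ycf3", "H")
    items <- ins_after(items, "ycf3", item_site("ycf3-inv-F", -1L, "R"))
    trail <- "B"                                   # BP24L outside
  } else if (zone == "z_24") {
    items <- append(list(item_site("FGA-trnC-R", -1L, "B")), items)
    items <- set_gap(items, "trnC-GCA", "H")
    items <- append(items, list(item_site("FGA-trnF-R", +1L, "H")))
    trail <- "B"                                   # BP24R inside
  } else if (zone == "z_36R") {
    items <- append(list(item_site("FGA-ndhJ-F", -1L, "B")), items)
    items <- set_gap(items, "ndhJ", "H")
    trail <- "H"                                   # BP36R = repeat B midpoint
  } else if (zone == "z_50R") {
    items <- append(list(item_repeat(2L, "H"),
                         item_site("psbI-int-R", -1L, "H")), items)
    items <- set_gap(items, "psbI", "H")
    trail <- "B"                                   # BP50R inside
  } else if (zone == "z_out_R") {
    items <- set_gap(items, items[[1]]$gene, "B")  # BP50R outside
  }
  list(items = items, trail = trail)
}

# --- sequence realization ------------------------------------------------

# Deterministically structured rps16 coding sequence: exon2 contains a
# unique "AAAC" motif (codon 10) followed by codons chosen so that
# duplicating the motif shifts the frame onto an immediate in-frame stop.
make_rps16_parts <- function(gc) {
  sense_codons <- function(n) {
    out <- character(n)
    i <- 0L
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    while (i < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE,
                           prob = p), collapse = "")
      if (!(cand %in% STOP_CODONS)) {
        i <- i + 1L
        out[i] <- cand
      }
    }
    out
  }
  exon1 <- paste0("ATG", paste(sense_codons(RPS16_EXON1 / 3 - 1L),
                               collapse = ""))
  planted <- c("AAA", "CTA", "ATA", "ACT", "AAG")
  n2 <- RPS16_EXON2 / 3
  repeat {
    pre <- sense_codons(9L)
    post <- sense_codons(n2 - 9L - 5L - 1L)
    exon2 <- paste0(paste(pre, collapse = ""), paste(planted, collapse = ""),
                    paste(post, collapse = ""), "TAA")
    # the planted AAAC (coding positions 28..31 of exon2) must be the first
    first <- regexpr("AAAC", exon2, fixed = TRUE)
    if (first == 28L) break
  }
  list(exon1 = exon1, intron = random_seq(RPS16_INTRON, gc), exon2 = exon2)
}

# Ancestral gene content: one coding-orientation sequence per catalog gene
# (plus the rps16 exon/intron parts and the 29-bp repeat motif), generated
# once under a fixed seed so that every genome of a panel carries the same
# homologous gene sequences and only the spacers vary with the genome seed.
ancestral_gene_content <- function(catalog, gc, ancestral_seed) {
  with_seed(ancestral_seed, {
    content <- list(.repeat_motif = random_seq(REPEAT_LEN, gc))
    for (i in seq_len(nrow(catalog))) {
      g <- catalog$gene[i]
      if (g == "rps16") {
        content[[g]] <- make_rps16_parts(gc)
      } else if (catalog$kind[i] == "CDS") {
        content[[g]] <- random_orf(catalog$length[i], gc)
      } else {
        content[[g]] <- random_seq(catalog$length[i], gc)
      }
    }
    content
  })
}

realize_item <- function(item, gc, content) {
  if (item$type == "site") {
    slice <- if (item$strand == 1L) item$content else revcomp(item$content)
    return(list(slice = slice, parts = data.frame(part = 1L, off = 0L,
                                                  len = nchar(slice),
                                                  what = "site")))
  }
  if (item$type == "repeat") {
    return(list(slice = NA_character_, parts = data.frame(part = 1L, off = 0L,
                                                          len = REPEAT_LEN,
                                                          what = "repeat")))
  }
  if (item$gene == "rps16") {
    p <- content[["rps16"]]
    fwd <- paste0(p$exon1, p$intron, p$exon2)
    slice <- if (item$strand == 1L) fwd else revcomp(fwd)
    # offsets of (exon1, intron, exon2) within the genomic slice
    if (item$strand == 1L) {
      offs <- c(0L, nchar(p$exon1), nchar(p$exon1) + nchar(p$intron))
    } else {
      tot <- nchar(fwd)
      offs <- c(tot - nchar(p$exon1),
                nchar(p$exon2),
                0L)
    }
    parts <- data.frame(
      part = c(1L, 1L, 2L),
      off = offs,
      len = c(nchar(p$exon1), nchar(p$intron), nchar(p$exon2)),
      what = c("exon", "intron", "exon"))
    return(list(slice = slice, parts = parts))
  }
  core <- content[[item$gene]]
  slice <- if (item$strand == 1L) core else revcomp(core)
  list(slice = slice, parts = data.frame(part = 1L, off = 0L,
                                         len = nchar(slice),
                                         what = item$kind))
}

# Assemble one zone. Returns sequence and a feature frame in local (zone)
# coordinates. `content` supplies the ancestral gene sequences and the
# planted 29-bp repeat motif.
realize_zone <- function(zone, items, trail, target, gc, bnd, content,
                         fid_suffix = "") {
  gaps <- c(vapply(items, function(x) x$gap, character(1)), trail)
  elen <- vapply(items, function(x) x$genomic_len, integer(1))
  fixed_gap <- sum(ifelse(gaps == "B", bnd, ifelse(gaps == "H", HUG_GAP, 0L)))
  n_rand <- sum(gaps == "R")
  remaining <- target - sum(elen) - fixed_gap
  if (remaining < 30L * n_rand) {
    stop(sprintf(
      "zone '%s' too small: target %d bp, need at least %d bp (deficit %d)",
      zone, target, sum(elen) + fixed_gap + 30L * n_rand,
      sum(elen) + fixed_gap + 30L * n_rand - target), call. = FALSE)
  }
  rand_sizes <- if (n_rand > 0L) {
    extra <- as.vector(stats::rmultinom(1L, remaining - 30L * n_rand,
                                        rep(1, n_rand)))
    30L + extra
  } else {
    integer(0)
  }
  if (n_rand == 0L && remaining != 0L) {
    # no random slot to absorb the slack: widen the trailing spacer
    fixed_gap <- fixed_gap + remaining
  }
  gap_sizes <- integer(length(gaps))
  ri <- 0L
  for (i in seq_along(gaps)) {
    gap_sizes[i] <- switch(gaps[i],
                           B = bnd + if (i == length(gaps) && n_rand == 0L)
                             remaining else 0L,
                           H = HUG_GAP,
                           R = {ri <- ri + 1L; rand_sizes[ri]})
  }
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_along(items)) {
    g <- gap_sizes[i]
    pieces <- c(pieces, random_seq(g, gc))
    pos <- pos + g
    it <- items[[i]]
    rz <- realize_item(it, gc, content)
    slice <- if (it$type == "repeat") {
      if (it$copy == 1L) content$.repeat_motif else
        revcomp(content$.repeat_motif)
    } else {
      rz$slice
    }
    pieces <- c(pieces, slice)
    pp <- rz$parts
    fid_base <- paste0(it$gene, fid_suffix)
    if (it$type == "repeat") fid_base <- paste0(fid_base, "_copy", it$copy)
    for (k in seq_len(nrow(pp))) {
      kind <- switch(pp$what[k], exon = "CDS", intron = "intron",
                     site = "primer_site", "repeat" = "repeat", it$kind)
      fid <- if (pp$what[k] == "intron") paste0(fid_base, ".intron") else
        fid_base
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, gene = it$gene, kind = kind, strand = it$strand,
        part = pp$part[k], start = pos + pp$off[k],
        end = pos + pp$off[k] + pp$len[k], stringsAsFactors = FALSE)
    }
    pos <- pos + it$genomic_len
  }
  g <- gap_sizes[length(gap_sizes)]
  pieces <- c(pieces, random_seq(g, gc))
  pos <- pos + g
  stopifnot(pos == target)
  list(seq = paste(pieces, collapse = ""),
       features = if (length(feats) > 0L) do.call(rbind, feats) else
         empty_features())
}

# --- the generator -------------------------------------------------------

#' Generate an annotated synthetic plastome
#'
#' Builds a circular quadripartite genome (LSC + IRa + SSC + IRb, with IRb
#' the exact reverse complement of IRa) in the ancestral, uninverted legume
#' arrangement. Intergenic spacers are seeded random sequence at `gc` GC
#' content; a 29-bp identical repeat pair (in inverted orientation) is
#' planted at the future 36-kb inversion breakpoints, and the packaged
#' screening-primer binding sites are planted around the 24-kb and 36-kb
#' breakpoints.
#'
#' @param catalog Catalog from [default_gene_catalog()].
#' @param region_lengths Optional named vector `c(LSC=, SSC=, IR=)` in bp;
#'   defaults to the catalog profile's lengths. LSC zone targets are scaled
#'   proportionally.
#' @param seed Integer seed for the intergenic spacers; same inputs and
#'   seed give byte-identical records, different seeds change only the
#'   spacer sequence (gene order and gene sequences stay fixed).
#' @param id Record identifier.
#' @param gc GC fraction of spacers and generated gene sequence.
#' @param ancestral_seed Seed of the shared ancestral gene content; all
#'   genomes meant to be comparable (one panel) must use the same value.
#' @return A [plastome_record()] of length `LSC + SSC + 2*IR`.
#' @export
generate_plastome <- function(catalog, region_lengths = NULL, seed = 1L,
                              id = "synthetic", gc = 0.365,
                              ancestral_seed = 424243L) {
  profile <- attr(catalog, "profile")
  zt <- attr(catalog, "zone_targets")
  if (is.null(zt)) stop("catalog has no zone_targets attribute", call. = FALSE)
  bnd <- BOUNDARY_GAP[[profile]]
  if (!is.null(region_lengths)) {
    lsc_zones <- zt[LSC_ZONES]
    scale <- region_lengths[["LSC"]] / sum(lsc_zones)
    new_lsc <- round(lsc_zones * scale)
    new_lsc[length(new_lsc)] <- region_lengths[["LSC"]] -
      sum(new_lsc[-length(new_lsc)])
    zt[LSC_ZONES] <- new_lsc
    zt[["SSC"]] <- region_lengths[["SSC"]]
    zt[["IR"]] <- region_lengths[["IR"]]
  }
  content <- ancestral_gene_content(catalog, gc, ancestral_seed)
  with_seed(seed, {
    zones_out <- list()
    offset <- 0L
    seq_parts <- character(0)
    feats <- list()
    bounds <- list()
    for (zone in c(LSC_ZONES, "IR", "SSC")) {
      zi <- zone_items(zone, catalog, bnd)
      out <- realize_zone(zone, zi$items, zi$trail, as.integer(zt[[zone]]),
                          gc, bnd, content,
                          fid_suffix = if (zone == "IR") "_ira" else "")
      zones_out[[zone]] <- out
      bounds[[zone]] <- c(start = offset, end = offset + nchar(out$seq))
      if (nrow(out$features) > 0L) {
        f <- out$features
        f$start <- f$start + offset
        f$end <- f$end + offset
        feats[[zone]] <- f
      }
      seq_parts <- c(seq_parts, out$seq)
      offset <- offset + nchar(out$seq)
    }
    # IRb: reverse complement of IRa, mirrored annotations
    ira <- zones_out[["IR"]]
    r <- nchar(ira$seq)
    ira_start <- bounds[["IR"]]["start"]
    irb_start <- offset
    irb_seq <- revcomp(ira$seq)
    fb <- ira$features
    if (nrow(fb) > 0L) {
      s_local <- fb$start
      e_local <- fb$end
      fb$start <- irb_start + (r - e_local)
      fb$end <- irb_start + (r - s_local)
      fb$strand <- -fb$strand
      fb$feature_id <- sub("_ira$", "_irb", fb$feature_id)
      feats[["IRb"]] <- fb
    }
    seq_parts <- c(seq_parts, irb_seq)
    offset <- offset + r
    bounds[["IRb"]] <- c(start = irb_start, end = offset)
    sequence <- paste(seq_parts, collapse = "")
    L <- nchar(sequence)

    # Junction repair: make the IR pair non-extendable so that detection
    # recovers the planted IR length exactly.
    # IRa = [aS, aE), IRb = [bS, L); forbid left/right co-extension.
    aS <- as.integer(bounds[["IR"]]["start"])
    aE <- as.integer(bounds[["IR"]]["end"])
    bS <- as.integer(bounds[["IRb"]]["start"])
    comp1 <- function(x) chartr("ACGTN", "TGCAN", x)
    fix_base <- function(s, pos, partner) {
      # ensure s[pos] != complement(s[partner]) (1-based positions)
      if (substr(s, pos, pos) == comp1(substr(s, partner, partner))) {
        avoid <- comp1(substr(s, partner, partner))
        repl <- setdiff(c("A", "C", "G", "T"), avoid)[1L]
        substr(s, pos, pos) <- repl
      }
      s
    }
    sequence <- fix_base(sequence, aS, 1L)            # last LSC base vs base 0
    sequence <- fix_base(sequence, aE + 1L, bS)       # first SSC vs last SSC

    ft <- do.call(rbind, feats)
    rownames(ft) <- NULL
    rec <- plastome_record(id, sequence, ft, circular = TRUE)
    attr(rec, "zone_bounds") <- do.call(rbind, lapply(names(bounds),
      function(z) data.frame(zone = z, start = bounds[[z]][["start"]],
                             end = bounds[[z]][["end"]],
                             stringsAsFactors = FALSE)))
    rec
  })
}
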