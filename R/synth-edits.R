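# Genome editing operations of the synthetic-data module: applying an
# inversion between resolved breakpoints, planting gene mutations, and
# building multi-taxon panels with per-taxon inversion states.

#' Construct an inversion specification
#'
#' Anchors are breakpoint descriptors, either an intergenic spacer adjacent
#' to a named gene (`anchor_igs`) or a planted named repeat copy
#' (`anchor_repeat`). The realized breakpoint is the midpoint of the spacer
#' (or of the repeat copy) in the current record.
#'
#' @param name Inversion name.
#' @param left_anchor,right_anchor Anchor descriptors.
#' @param size Approximate expected segment size in bp (informational).
#' @return An `InversionSpec` object.
#' @export
inversion_spec <- function(name, left_anchor, right_anchor, size = NA_real_) {
  structure(list(name = name, left_anchor = left_anchor,
                 right_anchor = right_anchor, size = size),
            class = "InversionSpec")
}

#' @rdname inversion_spec
#' @param gene Gene name the spacer is adjacent to.
#' @param side `"after"` (spacer following the gene in genomic order) or
#'   `"before"`.
#' @export
anchor_igs <- function(gene, side = c("after", "before")) {
  list(type = "igs", gene = gene, side = match.arg(side))
}

#' @rdname inversion_spec
#' @param repeat_name Name of the planted repeat feature.
#' @param copy Copy index (1 = lower coordinate).
#' @export
anchor_repeat <- function(repeat_name, copy) {
  list(type = "repeat", name = repeat_name, copy = as.integer(copy))
}

#' Preset specifications of the three nested LSC inversions
#'
#' The 50-kb inversion runs between the spacers after trnK and before accD;
#' the 36-kb inversion between the flip-flop cut points of the planted
#' 29-bp repeat pair next to trnS-GCU and trnS-GGA; and the 24-kb inversion
#' between the spacer near trnC-GCA (whose invariant outside neighbour is
#' the last gene of the left 36-kb margin) and the spacer near trnF-GAA,
#' immediately inside ndhJ. The 24-kb anchors are expressed through the
#' outside genes so that they resolve to the same physical spacer in either
#' orientation, which makes applying a preset twice an exact involution of
#' the gene order.
#'
#' @param profile Catalog profile (accepted for symmetry; both catalogs
#'   share the anchor genes).
#' @return Named list of [inversion_spec()] objects.
#' @export
preset_inversions <- function(profile = c("full", "mini")) {
  profile <- match.arg(profile)
  out24_left <- "psaI"
  list(
    INV50 = inversion_spec("INV50", anchor_igs("trnK-UUU", "after"),
                           anchor_igs("accD", "before"), 50000),
    INV36 = inversion_spec("INV36", anchor_repeat(REPEAT_NAME, 1L),
                           anchor_repeat(REPEAT_NAME, 2L), 36000),
    INV24 = inversion_spec("INV24", anchor_igs(out24_left, "after"),
                           anchor_igs("ndhJ", "before"), 24000)
  )
}

# Extents (min start, max end) of gene-level loci: CDS/tRNA/rRNA parts plus
# the introns that belong to the same gene.
gene_extents <- function(record) {
  ft <- record$features
  ft <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA", "intron"), , drop = FALSE]
  if (nrow(ft) == 0L) {
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  sp <- split(ft, ft$gene)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(gene = p$gene[1L], start = min(p$start), end = max(p$end),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve an anchor descriptor to a breakpoint position in [0, L).
# `role` matters for repeat anchors: a flip-flop cut at offset h from the
# left copy's start must pair with the cut at offset h from the right
# copy's end, otherwise the repeat pair is not preserved exactly.
resolve_anchor <- function(record, anchor, role = c("left", "right")) {
  role <- match.arg(role)
  L <- nchar(record$sequence)
  if (anchor$type == "igs") {
    ext <- gene_extents(record)
    i <- which(ext$gene == anchor$gene)
    if (length(i) == 0L) {
      stop(sprintf("anchor gene '%s' not found", anchor$gene), call. = FALSE)
    }
    if (length(i) > 1L) {
      stop(sprintf("anchor gene '%s' is ambiguous (%d loci)", anchor$gene,
                   length(i)), call. = FALSE)
    }
    n <- nrow(ext)
    if (anchor$side == "after") {
      gap_start <- ext$end[i]
      gap_end <- if (i < n) ext$start[i + 1L] else ext$start[1L] + L
    } else {
      gap_start <- if (i > 1L) ext$end[i - 1L] else ext$end[n] - L
      gap_end <- ext$start[i]
    }
    if (gap_end <= gap_start) {
      stop(sprintf("no intergenic spacer %s '%s'", anchor$side, anchor$gene),
           call. = FALSE)
    }
    as.integer(floor((gap_start + gap_end) / 2) %% L)
  } else if (anchor$type == "repeat") {
    ft <- record$features
    rows <- ft[ft$kind == "repeat" & ft$gene == anchor$name, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop(sprintf("repeat '%s' not found", anchor$name), call. = FALSE)
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    if (anchor$copy > nrow(rows)) {
      stop(sprintf("repeat '%s' has no copy %d", anchor$name, anchor$copy),
           call. = FALSE)
    }
    len <- rows$end[anchor$copy] - rows$start[anchor$copy]
    h <- len %/% 2L
    if (role == "left") {
      as.integer(rows$start[anchor$copy] + h)
    } else {
      as.integer(rows$end[anchor$copy] - h)
    }
  } else {
    stop("unknown anchor type '", anchor$type, "'", call. = FALSE)
  }
}

#' Apply an inversion to a plastome record
#'
#' The segment between the two resolved breakpoints is reverse-complemented
#' in place; contained features flip strand and order, coordinates are
#' remapped. Applying the same specification twice restores the original
#' gene order.
#'
#' @param record A `PlastomeRecord`.
#' @param spec An [inversion_spec()].
#' @return List with elements `record` (the inverted genome) and `event`
#'   (an `InversionEvent` with realized breakpoints and size).
#' @export
apply_inversion <- function(record, spec) {
  stopifnot(inherits(spec, "InversionSpec"))
  bpl <- resolve_anchor(record, spec$left_anchor, role = "left")
  bpr <- resolve_anchor(record, spec$right_anchor, role = "right")
  if (bpl > bpr) { tmp <- bpl; bpl <- bpr; bpr <- tmp }
  if (bpl == bpr) stop("anchors resolve to the same position", call. = FALSE)
  ft <- record$features
  straddle <- ft$start < bpl & ft$end > bpl | ft$start < bpr & ft$end > bpr
  # a breakpoint inside a planted inverted-repeat pair is legitimate
  # (flip-flop recombination): the repeat content is invariant under the
  # midpoint-to-midpoint inversion, so those features stay in place
  straddle <- straddle & ft$kind != "repeat"
  if (any(straddle)) {
    stop(sprintf("breakpoint falls inside feature '%s'",
                 ft$feature_id[straddle][1L]), call. = FALSE)
  }
  seq0 <- record$sequence
  L <- nchar(seq0)
  new_seq <- paste0(substr(seq0, 1L, bpl),
                    revcomp(substr(seq0, bpl + 1L, bpr)),
                    substr(seq0, bpr + 1L, L))
  inside <- ft$start >= bpl & ft$end <= bpr
  new_start <- ifelse(inside, bpl + (bpr - ft$end), ft$start)
  new_end <- ifelse(inside, bpl + (bpr - ft$start), ft$end)
  ft$start <- as.integer(new_start)
  ft$end <- as.integer(new_end)
  ft$strand <- ifelse(inside, -ft$strand, ft$strand)
  out <- plastome_record(record$id, new_seq, ft, circular = record$circular)
  event <- structure(list(name = spec$name, start = bpl, end = bpr,
                          size = bpr - bpl), class = "InversionEvent")
  list(record = out, event = event)
}

# --- genome editing primitives ------------------------------------------

# Insert `what` before 0-based position `pos`; features spanning pos are
# extended, later features shifted.
genome_insert <- function(record, pos, what) {
  what <- check_dna(what, "inserted sequence")
  n <- nchar(what)
  L <- nchar(record$sequence)
  stopifnot(pos >= 0L, pos <= L)
  seq2 <- paste0(substr(record$sequence, 1L, pos), what,
                 substr(record$sequence, pos + 1L, L))
  ft <- record$features
  grow <- ft$start < pos & ft$end > pos
  shift <- ft$start >= pos
  ft$end[grow] <- ft$end[grow] + n
  ft$start[shift] <- ft$start[shift] + n
  ft$end[shift] <- ft$end[shift] + n
  plastome_record(record$id, seq2, ft, circular = record$circular)
}

# Delete [start, end); overlapping feature parts are trimmed, parts fully
# inside are removed (and the whole feature if no part survives).
genome_delete <- function(record, start, end) {
  L <- nchar(record$sequence)
  stopifnot(start >= 0L, end <= L, start < end)
  n <- end - start
  seq2 <- paste0(substr(record$sequence, 1L, start),
                 substr(record$sequence, end + 1L, L))
  ft <- record$features
  remap <- function(p) {
    ifelse(p <= start, p, ifelse(p >= end, p - n, start))
  }
  ft$start <- as.integer(remap(ft$start))
  ft$end <- as.integer(remap(ft$end))
  ft <- ft[ft$end > ft$start, , drop = FALSE]
  # renumber surviving parts per feature, keeping transcription order
  if (nrow(ft) > 0L) {
    ft <- do.call(rbind, lapply(split(ft, ft$feature_id), function(p) {
      p <- p[order(p$part), , drop = FALSE]
      p$part <- seq_len(nrow(p))
      p
    }))
    rownames(ft) <- NULL
  }
  plastome_record(record$id, seq2, ft, circular = record$circular)
}

# Genomic position of the point just before coding position `cpos`
# (0-based, within exon `exon_idx` of the gene's CDS feature), together with
# the strand. Used to place coding-coordinate edits.
coding_to_genomic <- function(record, gene, exon_idx, cpos) {
  ft <- record$features
  cds <- ft[ft$gene == gene & ft$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("gene '", gene, "' not found", call. = FALSE)
  cds <- cds[order(cds$part), , drop = FALSE]
  if (exon_idx > nrow(cds)) stop("gene '", gene, "' has no exon ", exon_idx,
                                 call. = FALSE)
  p <- cds[exon_idx, ]
  stopifnot(cpos >= 0L, cpos <= p$end - p$start)
  if (p$strand == 1L) {
    list(pos = p$start + cpos, strand = 1L)
  } else {
    list(pos = p$end - cpos, strand = -1L)
  }
}

#' Construct a gene mutation specification
#'
#' @param kind One of `START_CODON_MUTATION`, `STOP_CODON_MUTATION`,
#'   `FRAMESHIFT_INSERTION`, `FRAMESHIFT_DELETION`, `EXON_TRUNCATION`,
#'   `INTRON_DELETION`, `WHOLE_GENE_DELETION`.
#' @param ... Payload fields: `motif` (inserted motif; frameshift insertions
#'   duplicate the motif after its first occurrence when `at` is missing),
#'   `at` (0-based coding position within the exon), `len` (deleted length),
#'   `exon` (exon index, default last), `keep` (bp kept at the 5' end of a
#'   truncated exon), `codon` (replacement start/stop codon).
#' @return A `MutationSpec`.
#' @export
mutation_spec <- function(kind, ...) {
  kinds <- c("START_CODON_MUTATION", "STOP_CODON_MUTATION",
             "FRAMESHIFT_INSERTION", "FRAMESHIFT_DELETION",
             "EXON_TRUNCATION", "INTRON_DELETION", "WHOLE_GENE_DELETION")
  kind <- match.arg(kind, kinds)
  payload <- list(...)
  if (kind == "FRAMESHIFT_INSERTION" && !is.null(payload$motif) &&
      nchar(payload$motif) %% 3L == 0L) {
    stop("frameshift insertion length must not be divisible by 3",
         call. = FALSE)
  }
  if (kind == "FRAMESHIFT_DELETION" && !is.null(payload$len) &&
      payload$len %% 3L == 0L) {
    stop("frameshift deletion length must not be divisible by 3",
         call. = FALSE)
  }
  structure(list(kind = kind, payload = payload), class = "MutationSpec")
}

#' Plant a mutation in a gene of a synthetic plastome
#'
#' Mutations are realized exactly on the coding strand: pseudogene-type
#' mutations keep the feature annotation; `WHOLE_GENE_DELETION` removes the
#' gene's whole genomic extent and its features.
#'
#' @param record A `PlastomeRecord`.
#' @param gene Gene name; must be present.
#' @param spec A [mutation_spec()].
#' @param seed Seed used when the payload leaves a position unspecified.
#' @return The mutated `PlastomeRecord`.
#' @export
mutate_gene <- function(record, gene, spec, seed = 1L) {
  stopifnot(inherits(spec, "MutationSpec"))
  ft <- record$features
  if (!any(ft$gene == gene & ft$kind %in% c("CDS", "tRNA", "rRNA"))) {
    stop("gene '", gene, "' not found", call. = FALSE)
  }
  pl <- spec$payload
  cds <- ft[ft$gene == gene & ft$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$part), , drop = FALSE]
  n_exon <- nrow(cds)
  exon_len <- function(k) cds$end[k] - cds$start[k]

  with_seed(seed, switch(spec$kind,
    START_CODON_MUTATION = {
      codon <- if (is.null(pl$codon)) "ACG" else pl$codon
      replace_coding(record, gene, 1L, 0L, 3L, codon)
    },
    STOP_CODON_MUTATION = {
      codon <- if (is.null(pl$codon)) "CAA" else pl$codon
      replace_coding(record, gene, n_exon, exon_len(n_exon) - 3L, 3L, codon)
    },
    FRAMESHIFT_INSERTION = {
      exon <- if (is.null(pl$exon)) n_exon else pl$exon
      motif <- if (is.null(pl$motif)) "AAAC" else pl$motif
      at <- pl$at
      if (is.null(at)) {
        # duplicate the motif after its first occurrence in the exon
        ex_seq <- exon_sequence(record, gene, exon)
        hit <- regexpr(motif, ex_seq, fixed = TRUE)
        if (hit < 0L) {
          # fall back to a random interior position
          at <- sample(seq(10L, nchar(ex_seq) - 10L), 1L)
        } else {
          at <- as.integer(hit) - 1L + nchar(motif)
        }
      }
      loc <- coding_to_genomic(record, gene, exon, at)
      ins <- if (loc$strand == 1L) motif else revcomp(motif)
      genome_insert(record, loc$pos, ins)
    },
    FRAMESHIFT_DELETION = {
      exon <- if (is.null(pl$exon)) n_exon else pl$exon
      len <- if (is.null(pl$len)) 1L else as.integer(pl$len)
      at <- pl$at
      if (is.null(at)) {
        at <- sample(seq(10L, exon_len(exon) - 10L - len), 1L)
      }
      delete_coding(record, gene, exon, at, len)
    },
    EXON_TRUNCATION = {
      exon <- if (is.null(pl$exon)) n_exon else pl$exon
      keep <- if (is.null(pl$keep)) 30L else as.integer(pl$keep)
      delete_coding(record, gene, exon, keep, exon_len(exon) - keep)
    },
    INTRON_DELETION = {
      len <- if (is.null(pl$len)) 200L else as.integer(pl$len)
      introns <- ft[ft$gene == gene & ft$kind == "intron", , drop = FALSE]
      if (nrow(introns) == 0L) stop("gene '", gene, "' has no intron",
                                    call. = FALSE)
      p <- introns[1L, ]
      mid <- p$start + (p$end - p$start - len) %/% 2L
      genome_delete(record, mid, mid + len)
    },
    WHOLE_GENE_DELETION = {
      ext <- gene_extents(record)
      i <- which(ext$gene == gene)
      genome_delete(record, ext$start[i], ext$end[i])
    }))
}

# coding-strand sequence of one exon
exon_sequence <- function(record, gene, exon_idx) {
  cds <- record$features[record$features$gene == gene &
                           record$features$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$part), , drop = FALSE]
  p <- cds[exon_idx, ]
  s <- substr(record$sequence, p$start + 1L, p$end)
  if (p$strand == -1L) revcomp(s) else s
}

# Replace `len` coding bases starting at coding position `at` of one exon.
replace_coding <- function(record, gene, exon_idx, at, len, replacement) {
  stopifnot(nchar(replacement) == len)
  loc <- coding_to_genomic(record, gene, exon_idx, at)
  seq0 <- record$sequence
  if (loc$strand == 1L) {
    substr(seq0, loc$pos + 1L, loc$pos + len) <- replacement
  } else {
    substr(seq0, loc$pos - len + 1L, loc$pos) <- revcomp(replacement)
  }
  plastome_record(record$id, seq0, record$features,
                  circular = record$circular)
}

# Delete `len` coding bases starting at coding position `at` of one exon.
delete_coding <- function(record, gene, exon_idx, at, len) {
  loc <- coding_to_genomic(record, gene, exon_idx, at)
  if (loc$strand == 1L) {
    genome_delete(record, loc$pos, loc$pos + len)
  } else {
    genome_delete(record, loc$pos - len, loc$pos)
  }
}

# --- panels --------------------------------------------------------------

#' Build a multi-taxon synthetic plastome panel
#'
#' One record per configured taxon, all sharing the same catalog and gene
#' order; the preset inversions are applied per the state flags. Per-taxon
#' spacer sequence varies with derived child seeds.
#'
#' @param config Data frame with columns `taxon`, and logical `inv50`,
#'   `inv36`, `inv24` (see [screen_panel_config()]).
#' @param seed Panel seed.
#' @param profile Catalog profile passed to [default_gene_catalog()].
#' @return Named list of `PlastomeRecord`s.
#' @export
build_panel <- function(config, seed = 1L, profile = c("full", "mini")) {
  profile <- match.arg(profile)
  if (anyDuplicated(config$taxon)) {
    stop("panel taxa must be unique", call. = FALSE)
  }
  for (col in c("inv50", "inv36", "inv24")) {
    if (!col %in% names(config)) config[[col]] <- FALSE
    if (!is.logical(config[[col]])) {
      stop("panel state column '", col, "' must be logical", call. = FALSE)
    }
  }
  catalog <- default_gene_catalog(profile)
  inv <- preset_inversions(profile)
  out <- vector("list", nrow(config))
  names(out) <- config$taxon
  for (i in seq_len(nrow(config))) {
    rec <- generate_plastome(catalog, seed = derive_seed(seed, i),
                             id = config$taxon[i])
    if (config$inv50[i]) rec <- apply_inversion(rec, inv$INV50)$record
    if (config$inv36[i]) rec <- apply_inversion(rec, inv$INV36)$record
    if (config$inv24[i]) rec <- apply_inversion(rec, inv$INV24)$record
    out[[i]] <- rec
  }
  out
}

#' Build the synthetic rps16 survey panel
#'
#' One mini-profile record per taxon of [rps16_survey_config()], with the
#' planted rps16 mutation drawn from the taxon's status class: pseudogene
#' taxa receive a frameshift-inducing "AAAC" duplication in exon2 (one taxon
#' a start-codon mutation, for variety of mechanism), truncated taxa lose
#' most of exon2, deleted taxa lose the whole gene.
#'
#' @param config Data frame as returned by [rps16_survey_config()].
#' @param seed Panel seed.
#' @param profile Catalog profile.
#' @return Named list of `PlastomeRecord`s.
#' @export
build_rps16_panel <- function(config = rps16_survey_config(), seed = 1L,
                              profile = "mini") {
  catalog <- default_gene_catalog(profile)
  out <- vector("list", nrow(config))
  names(out) <- config$taxon
  pseudo_seen <- 0L
  for (i in seq_len(nrow(config))) {
    s <- derive_seed(seed, 1000L + i)
    rec <- generate_plastome(catalog, seed = s, id = config$taxon[i])
    rec <- switch(config$status[i],
      intact = rec,
      pseudogene = {
        pseudo_seen <- pseudo_seen + 1L
        if (pseudo_seen == 4L) {
          # one taxon models a start-codon mutation instead of a frameshift
          mutate_gene(rec, "rps16", mutation_spec("START_CODON_MUTATION"),
                      seed = s)
        } else {
          rec2 <- mutate_gene(rec, "rps16",
                              mutation_spec("FRAMESHIFT_INSERTION",
                                            motif = "AAAC", exon = 2L),
                              seed = s)
          # genistoid-style additional intron erosion
          mutate_gene(rec2, "rps16", mutation_spec("INTRON_DELETION",
                                                   len = 200L), seed = s)
        }
      },
      truncated = mutate_gene(rec, "rps16",
                              mutation_spec("EXON_TRUNCATION", exon = 2L,
                                            keep = 30L), seed = s),
      deleted = mutate_gene(rec, "rps16",
                            mutation_spec("WHOLE_GENE_DELETION"), seed = s),
      stop("unknown status '", config$status[i], "'", call. = FALSE))
    out[[i]] <- rec
  }
  out
}
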