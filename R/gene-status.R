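# Four-way status classification of a plastid gene (modelled on rps16)
# from pairwise global alignment against a verified intact reference:
#   INTACT              full-length and in-frame
#   PUTATIVE_PSEUDOGENE start/stop-codon mutation, frameshift-inducing
#                       indels, or a premature in-frame stop
#   TRUNCATED           significant deletion (low exon coverage or a whole
#                       exon missing)
#   DELETED             locus absent

GENE_STATUS_LEVELS <- c("INTACT", "PUTATIVE_PSEUDOGENE", "TRUNCATED",
                        "DELETED")

#' Extract a locus (exons + introns) from a record
#'
#' @param record A `PlastomeRecord`.
#' @param gene Gene name.
#' @return `NULL` when the gene is absent; otherwise a `LocusParts` list
#'   with `gene`, `exons` (coding-strand sequences in transcription order),
#'   `introns`, `strand`, and `coords` (the feature rows). Multiple
#'   single-copy loci with the same name raise an ambiguity error.
#' @export
extract_locus <- function(record, gene) {
  ft <- record$features
  cds <- ft[ft$gene == gene & ft$kind %in% c("CDS", "tRNA", "rRNA"), ,
            drop = FALSE]
  if (nrow(cds) == 0L) return(NULL)
  fids <- unique(cds$feature_id)
  if (length(fids) > 1L && !all(grepl("_ir[ab]$", fids))) {
    stop(sprintf("gene '%s' is ambiguous: %d single-copy loci", gene,
                 length(fids)), call. = FALSE)
  }
  fid <- fids[1L]
  parts <- cds[cds$feature_id == fid, , drop = FALSE]
  parts <- parts[order(parts$part), , drop = FALSE]
  strand <- parts$strand[1L]
  exon_seq_of <- function(p) {
    s <- circ_substr(record$sequence, p$start, p$end)
    if (strand == -1L) revcomp(s) else s
  }
  exons <- vapply(seq_len(nrow(parts)),
                  function(k) exon_seq_of(parts[k, , drop = FALSE]),
                  character(1))
  introns <- character(0)
  intr <- ft[ft$gene == gene & ft$kind == "intron", , drop = FALSE]
  if (nrow(intr) > 0L) {
    intr <- intr[order(intr$part), , drop = FALSE]
    introns <- vapply(seq_len(nrow(intr)),
                      function(k) exon_seq_of(intr[k, , drop = FALSE]),
                      character(1))
  }
  structure(list(gene = gene, exons = exons, introns = introns,
                 strand = strand, coords = parts), class = "LocusParts")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under an affine gap scheme (a gap of
#' length L costs `gap_open + L * gap_extend`). The Biostrings dynamic
#' programming engine does the work; this wrapper fixes the scoring
#' convention and reports indels in reference coordinates.
#'
#' @param query,reference Nucleotide strings (non-empty).
#' @param scoring Named list/vector with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @return List with `score`, `aligned_query`, `aligned_reference`,
#'   `indels` (data frame: `ref_pos` 0-based position in the reference
#'   after which the indel occurs, `length`, `type` in
#'   insertion/deletion), and `coverage` (fraction of reference positions
#'   aligned to a query base).
#' @export
global_align <- function(query, reference,
                         scoring = c(match = 2, mismatch = -3,
                                     gap_open = -5, gap_extend = -2)) {
  query <- check_dna(query, "query")
  reference <- check_dna(reference, "reference")
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring[["match"]], mismatch = scoring[["mismatch"]],
    baseOnly = FALSE)
  keep <- c("A", "C", "G", "T", "N")
  mat <- mat[keep, keep]
  mat["N", ] <- 0; mat[, "N"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = mat,
    gapOpening = -scoring[["gap_open"]],
    gapExtension = -scoring[["gap_extend"]])
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  qv <- strsplit(aq, "", fixed = TRUE)[[1]]
  rv <- strsplit(ar, "", fixed = TRUE)[[1]]
  # walk the alignment once to collect indel runs and coverage
  indels <- list()
  ref_pos <- 0L
  run_type <- NA_character_
  run_len <- 0L
  run_ref <- 0L
  flush_run <- function() {
    if (!is.na(run_type)) {
      indels[[length(indels) + 1L]] <<- data.frame(
        ref_pos = run_ref, length = run_len, type = run_type,
        stringsAsFactors = FALSE)
    }
    run_type <<- NA_character_
    run_len <<- 0L
  }
  covered <- 0L
  for (i in seq_along(qv)) {
    if (rv[i] == "-") {          # insertion relative to the reference
      if (!identical(run_type, "insertion")) { flush_run()
        run_type <- "insertion"; run_ref <- ref_pos }
      run_len <- run_len + 1L
    } else if (qv[i] == "-") {   # deletion relative to the reference
      if (!identical(run_type, "deletion")) { flush_run()
        run_type <- "deletion"; run_ref <- ref_pos }
      run_len <- run_len + 1L
      ref_pos <- ref_pos + 1L
    } else {
      flush_run()
      covered <- covered + 1L
      ref_pos <- ref_pos + 1L
    }
  }
  flush_run()
  indels <- if (length(indels) > 0L) do.call(rbind, indels) else
    data.frame(ref_pos = integer(0), length = integer(0),
               type = character(0), stringsAsFactors = FALSE)
  list(score = Biostrings::score(aln), aligned_query = aq,
       aligned_reference = ar, indels = indels,
       coverage = covered / nchar(reference))
}

#' Classify a locus against an intact reference
#'
#' Decision procedure, applied in order: (1) absent locus is DELETED;
#' (2) any exon whose aligned coverage of the reference exon falls below
#' the truncation threshold, or an entirely missing exon, makes the locus
#' TRUNCATED; (3) a non-canonical start codon, a lost reference stop, a net
#' internal coding indel length not divisible by 3, or an in-frame stop
#' before the final 5% of the coding length makes it PUTATIVE_PSEUDOGENE;
#' (4) otherwise INTACT. Indels whose reference position lies within
#' `end_window` bp of an exon end are ignored for rule (3): intact plastid
#' genes tolerate small end-of-exon indels. Intron damage is recorded as
#' evidence but never drives the category on its own.
#'
#' @param query A `LocusParts` (from [extract_locus()]) or `NULL` (absent).
#' @param reference A `LocusParts` of a verified intact copy.
#' @param truncation_threshold Minimum exon coverage fraction in (0, 1).
#' @param end_window Exon-end window in bp ignored by the frameshift rule.
#' @param terminal_stop_frac Fraction of the coding tail within which an
#'   in-frame stop is not "internal".
#' @param scoring Alignment scoring passed to [global_align()].
#' @return A `GeneStatusReport`: list with `category` and `evidence`
#'   (character vector; non-empty for every non-INTACT call), plus
#'   per-exon `coverage` and the `indels` table.
#' @export
classify_locus <- function(query, reference, truncation_threshold = 0.5,
                           end_window = 9L, terminal_stop_frac = 0.05,
                           scoring = c(match = 2, mismatch = -3,
                                       gap_open = -5, gap_extend = -2)) {
  if (truncation_threshold <= 0 || truncation_threshold >= 1) {
    stop("truncation_threshold must be in (0, 1)", call. = FALSE)
  }
  report <- function(category, evidence, coverage = numeric(0),
                     indels = NULL) {
    structure(list(category = category, evidence = evidence,
                   coverage = coverage, indels = indels),
              class = "GeneStatusReport")
  }
  if (is.null(query)) {
    return(report("DELETED", "locus absent from genome"))
  }
  stopifnot(inherits(query, "LocusParts"), inherits(reference, "LocusParts"))
  n_ref <- length(reference$exons)
  evidence <- character(0)
  coverage <- rep(NA_real_, n_ref)
  all_indels <- list()

  if (length(query$exons) < n_ref) {
    return(report("TRUNCATED",
                  sprintf("exon(s) missing: query has %d of %d exons",
                          length(query$exons), n_ref), coverage))
  }

  net_internal_indel <- 0L
  truncated <- FALSE
  for (k in seq_len(n_ref)) {
    aln <- global_align(query$exons[k], reference$exons[k], scoring)
    coverage[k] <- aln$coverage
    ref_len <- nchar(reference$exons[k])
    if (aln$coverage < truncation_threshold) {
      truncated <- TRUE
      evidence <- c(evidence,
                    sprintf("exon%d coverage %.2f below threshold %.2f",
                            k, aln$coverage, truncation_threshold))
    }
    if (nrow(aln$indels) > 0L) {
      internal <- aln$indels$ref_pos >= end_window &
        aln$indels$ref_pos <= ref_len - end_window
      idl <- aln$indels
      idl$exon <- k
      idl$internal <- internal
      all_indels[[k]] <- idl
      sgn <- ifelse(idl$type == "insertion", 1L, -1L)
      net_internal_indel <- net_internal_indel +
        sum(sgn[internal] * idl$length[internal])
      for (j in which(internal)) {
        evidence <- c(evidence,
                      sprintf("internal %s of %d bp in exon%d at ref pos %d",
                              idl$type[j], idl$length[j], k, idl$ref_pos[j]))
      }
    }
  }
  indels <- if (length(all_indels) > 0L) do.call(rbind, all_indels) else NULL

  if (truncated) {
    return(report("TRUNCATED", evidence, coverage, indels))
  }

  pseudo <- FALSE
  coding <- paste(query$exons, collapse = "")
  start_codon <- substr(coding, 1L, 3L)
  if (!(start_codon %in% START_CODONS)) {
    pseudo <- TRUE
    evidence <- c(evidence, sprintf("start codon '%s' is not ATG/GTG",
                                    start_codon))
  }
  ref_coding <- paste(reference$exons, collapse = "")
  ref_has_stop <- substr(ref_coding, nchar(ref_coding) - 2L,
                         nchar(ref_coding)) %in% STOP_CODONS
  qry_stop <- substr(coding, nchar(coding) - 2L, nchar(coding))
  if (ref_has_stop && !(qry_stop %in% STOP_CODONS)) {
    pseudo <- TRUE
    evidence <- c(evidence, sprintf("reference stop codon lost ('%s')",
                                    qry_stop))
  }
  if (net_internal_indel %% 3L != 0L) {
    pseudo <- TRUE
    evidence <- c(evidence,
                  sprintf("net internal indel length %+d not divisible by 3",
                          net_internal_indel))
  }
  stop_at <- first_internal_stop(coding)
  n_codons <- nchar(coding) %/% 3L
  if (!is.na(stop_at) && stop_at < n_codons * (1 - terminal_stop_frac)) {
    pseudo <- TRUE
    evidence <- c(evidence, sprintf("in-frame internal stop at codon %d of %d",
                                    stop_at, n_codons))
  }
  # intron evidence (recorded, never category-driving on its own)
  if (length(reference$introns) > 0L && length(query$introns) > 0L) {
    for (k in seq_along(reference$introns)) {
      if (k > length(query$introns)) {
        evidence <- c(evidence, sprintf("intron%d missing", k))
        next
      }
      dlen <- nchar(reference$introns[k]) - nchar(query$introns[k])
      if (abs(dlen) >= 50L) {
        evidence <- c(evidence,
                      sprintf("intron%d length change of %+d bp", k, -dlen))
      }
    }
  } else if (length(reference$introns) > 0L && length(query$introns) == 0L) {
    evidence <- c(evidence, "intron(s) missing")
  }

  if (pseudo) {
    return(report("PUTATIVE_PSEUDOGENE", evidence, coverage, indels))
  }
  report("INTACT", evidence, coverage, indels)
}

#' @export
print.GeneStatusReport <- function(x, ...) {
  cat(sprintf("Gene status: %s\n", x$category))
  if (length(x$evidence) > 0L) {
    cat(paste0("  - ", x$evidence, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Survey one gene across a panel of genomes
#'
#' @param records Named list of `PlastomeRecord`s (names are taxa).
#' @param gene Gene name to classify.
#' @param reference A `LocusParts` of the intact reference copy, or a
#'   `PlastomeRecord` to extract it from.
#' @param ... Passed to [classify_locus()].
#' @return List with `table` (data frame: `taxon`, `category`,
#'   `n_evidence`, `min_exon_coverage`, `evidence` collapsed) and `tally`
#'   (named count per category, in the order intact / putative pseudogene /
#'   truncated / deleted).
#' @export
survey_gene <- function(records, gene, reference, ...) {
  if (inherits(reference, "PlastomeRecord")) {
    reference <- extract_locus(reference, gene)
    if (is.null(reference)) {
      stop("reference record does not contain gene '", gene, "'",
           call. = FALSE)
    }
  }
  taxa <- names(records)
  if (is.null(taxa)) taxa <- paste0("genome", seq_along(records))
  rows <- lapply(seq_along(records), function(i) {
    q <- extract_locus(records[[i]], gene)
    rep_i <- classify_locus(q, reference, ...)
    data.frame(taxon = taxa[i], category = rep_i$category,
               n_evidence = length(rep_i$evidence),
               min_exon_coverage = if (length(rep_i$coverage) > 0L)
                 suppressWarnings(min(rep_i$coverage, na.rm = TRUE)) else NA_real_,
               evidence = paste(rep_i$evidence, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tally <- stats::setNames(
    vapply(GENE_STATUS_LEVELS, function(lv) sum(tab$category == lv),
           integer(1)), GENE_STATUS_LEVELS)
  list(table = tab, tally = tally)
}
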