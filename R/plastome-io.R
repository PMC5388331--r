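# Readers and writers for the formats the pipeline touches.
#
# Internally every coordinate is 0-based half-open; the conversion to
# GenBank's 1-based inclusive convention happens only at (de)serialization.
# Only the GenBank subset this pipeline needs is emitted: LOCUS, FEATURES
# with gene/CDS/tRNA/rRNA/intron/repeat_region/primer_bind/misc_feature
# keys, ORIGIN. Unknown feature keys are preserved verbatim on read (as
# IGS_label with a note) and dropped on write with a warning.

GBK_KEY_OF_KIND <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     intron = "intron", "repeat" = "repeat_region",
                     primer_site = "primer_bind", IGS_label = "misc_feature")
KIND_OF_GBK_KEY <- stats::setNames(names(GBK_KEY_OF_KIND), GBK_KEY_OF_KIND)

# --- GenBank location strings -------------------------------------------

# parts: data.frame rows of one feature in transcription order.
# Convention (also used by the parser): plus-strand joins list parts in
# transcription order, minus-strand joins in reverse transcription order --
# for non-wrapping features both give the usual ascending-coordinate join,
# and origin-wrapping features stay unambiguous.
gbk_location <- function(parts) {
  minus <- parts$strand[1L] == -1L
  p <- parts[order(parts$part), , drop = FALSE]
  if (minus) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  spans <- sprintf("%d..%d", p$start + 1L, p$end)
  loc <- if (length(spans) > 1L) {
    sprintf("join(%s)", paste(spans, collapse = ","))
  } else {
    spans
  }
  if (minus) sprintf("complement(%s)", loc) else loc
}

parse_gbk_location <- function(loc, line_no) {
  loc0 <- loc
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(spans, regexec("^([0-9]+)\\.\\.([0-9]+)$", spans))
  if (any(vapply(m, length, integer(1)) != 3L)) {
    stop(sprintf("GenBank parse error at line %d: bad location '%s'",
                 line_no, loc0), call. = FALSE)
  }
  start <- vapply(m, function(x) as.integer(x[2]), integer(1)) - 1L
  end <- vapply(m, function(x) as.integer(x[3]), integer(1))
  # listed order is transcription order (reversed for complement joins)
  part <- if (strand == 1L) seq_along(start) else rev(seq_along(start))
  data.frame(strand = strand, part = part, start = start, end = end,
             stringsAsFactors = FALSE)
}

# --- GenBank flat file ---------------------------------------------------

write_genbank <- function(record, path) {
  L <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA",
                     record$id, L, topo), con)
  writeLines(sprintf("DEFINITION  %s synthetic plastome record.", record$id),
             con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- record$features
  if (nrow(ft) > 0L) {
    tab <- feature_table(record)
    for (fid in tab$feature_id) {
      parts <- ft[ft$feature_id == fid, , drop = FALSE]
      parts <- parts[order(parts$part), , drop = FALSE]
      kind <- parts$kind[1L]
      key <- GBK_KEY_OF_KIND[[kind]]
      writeLines(sprintf("     %-15s %s", key, gbk_location(parts)), con)
      writeLines(sprintf("                     /gene=\"%s\"", parts$gene[1L]),
                 con)
      writeLines(sprintf("                     /note=\"kind=%s\"", kind), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(groups), collapse = " ")),
               con)
  }
  writeLines("//", con)
  invisible(NULL)
}

read_genbank <- function(path, circular = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) {
    stop(sprintf("GenBank parse error at line 1: no LOCUS line in '%s'", path),
         call. = FALSE)
  }
  locus <- strsplit(trimws(lines[locus_i[1L]]), "[[:space:]]+")[[1]]
  id <- if (length(locus) >= 2L) locus[2L] else "unnamed"
  circ_from_file <- any(grepl("circular", locus, ignore.case = TRUE))
  lin_from_file <- any(grepl("^linear$", locus, ignore.case = TRUE))
  if (is.null(circular)) {
    circular <- if (lin_from_file) FALSE else circ_from_file || TRUE
    if (!circ_from_file && !lin_from_file) circular <- TRUE
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) {
    stop(sprintf("GenBank parse error: no ORIGIN section in '%s'", path),
         call. = FALSE)
  }
  orig_i <- orig_i[1L]

  # sequence
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i) > 0L) end_i[1L] else length(lines) + 1L
  seq_lines <- lines[seq(orig_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- check_dna(sequence, sprintf("sequence in '%s'", path))

  # features
  rows <- list()
  dropped <- character(0)
  if (length(feat_i) > 0L) {
    i <- feat_i[1L] + 1L
    fid_n <- 0L
    while (i < orig_i) {
      line <- lines[i]
      m <- regexec("^     ([A-Za-z_0-9']+) +(.+)$", line)
      mm <- regmatches(line, m)[[1]]
      if (length(mm) == 3L && !grepl("^ {6}", line)) {
        key <- mm[2L]
        loc <- mm[3L]
        # multi-line locations
        j <- i + 1L
        while (j < orig_i && grepl("^ {21}[^/]", lines[j])) {
          loc <- paste0(loc, trimws(lines[j]))
          j <- j + 1L
        }
        # qualifiers
        gene <- NA_character_
        note_kind <- NA_character_
        while (j < orig_i && grepl("^ {21}/", lines[j])) {
          q <- trimws(lines[j])
          if (grepl("^/gene=", q)) gene <- gsub("^/gene=\"?|\"$", "", q)
          if (grepl("^/note=\"kind=", q)) {
            note_kind <- gsub("^/note=\"kind=|\"$", "", q)
          }
          j <- j + 1L
        }
        if (key %in% names(KIND_OF_GBK_KEY)) {
          kind <- unname(KIND_OF_GBK_KEY[[key]])
          if (!is.na(note_kind) && note_kind %in% FEATURE_KINDS) {
            kind <- note_kind
          }
          if (key == "misc_feature" && is.na(note_kind)) kind <- "IGS_label"
          fid_n <- fid_n + 1L
          parts <- parse_gbk_location(loc, i)
          parts$feature_id <- sprintf("f%04d", fid_n)
          parts$gene <- if (is.na(gene)) sprintf("feature_%d", fid_n) else gene
          parts$kind <- kind
          rows[[length(rows) + 1L]] <- parts
        } else if (key != "source") {
          dropped <- c(dropped, key)
          parse_gbk_location(loc, i)  # still validate syntax
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(dropped) > 0L) {
    warning("preserving-unknown-keys is read-only; ignored feature key(s): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  ft <- if (length(rows) > 0L) {
    out <- do.call(rbind, rows)
    out[c("feature_id", "gene", "kind", "strand", "part", "start", "end")]
  } else {
    empty_features()
  }
  rec <- plastome_record(id, sequence, ft, circular = circular)
  if (any(rec$features$end > nchar(sequence))) {
    stop("validation error: features outside sequence", call. = FALSE)
  }
  rec
}

# --- FASTA + feature table ----------------------------------------------

write_fasta_table <- function(record, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(record$sequence, record$id))
  Biostrings::writeXStringSet(dna, path, width = 70L)
  tab_path <- paste0(path, ".features.tsv")
  ft <- record$features
  ft$circular <- rep(record$circular, nrow(ft))
  utils::write.table(ft, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

read_fasta_table <- function(path, circular = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) != 1L) {
    stop(sprintf("expected exactly one FASTA record in '%s', found %d",
                 path, length(dna)), call. = FALSE)
  }
  tab_path <- paste0(path, ".features.tsv")
  ft <- empty_features()
  circ <- TRUE
  if (file.exists(tab_path)) {
    tab <- utils::read.delim(tab_path, stringsAsFactors = FALSE)
    if (nrow(tab) > 0L) {
      if ("circular" %in% names(tab)) circ <- isTRUE(tab$circular[1L])
      ft <- tab[c("feature_id", "gene", "kind", "strand", "part",
                  "start", "end")]
    }
  }
  if (!is.null(circular)) circ <- circular
  plastome_record(names(dna)[1L], as.character(dna[[1L]]), ft,
                  circular = circ)
}

# --- public operations ---------------------------------------------------

#' Load an annotated plastome
#'
#' @param path Path to a GenBank flat file, or to a FASTA file with a
#'   `<path>.features.tsv` companion table (0-based half-open coordinates).
#' @param format `"genbank"` or `"fasta+table"`.
#' @param circular Override the circularity flag; by default it is read
#'   from the GenBank LOCUS line (assumed circular for FASTA input).
#' @return A [plastome_record()] with features in ascending start order.
#' @export
load_plastome <- function(path, format = c("genbank", "fasta+table"),
                          circular = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- switch(format,
                genbank = read_genbank(path, circular = circular),
                `fasta+table` = read_fasta_table(path, circular = circular))
  # features in ascending start order (per instance extent)
  tab <- feature_table(rec)
  ord <- match(rec$features$feature_id, tab$feature_id)
  rec$features <- rec$features[order(ord, rec$features$part), , drop = FALSE]
  rownames(rec$features) <- NULL
  rec
}

#' Save an annotated plastome
#'
#' The emitted file re-loads to an equal record (round-trip identity up to
#' feature identifiers).
#' @param record A `PlastomeRecord`.
#' @param path Output path.
#' @param format `"genbank"` or `"fasta+table"`.
#' @export
save_plastome <- function(record, path, format = c("genbank", "fasta+table")) {
  format <- match.arg(format)
  validate_record(record)
  switch(format,
         genbank = write_genbank(record, path),
         `fasta+table` = write_fasta_table(record, path))
  invisible(NULL)
}

#' Load a phylogeny from a Newick file
#'
#' @param path Path to a Newick tree.
#' @return An [ape::read.tree()] `phylo` object with unique leaf labels.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) {
    stop("Newick parse error in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}
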