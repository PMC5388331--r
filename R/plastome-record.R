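# The central container: an annotated, usually circular, plastid genome.
#
# Features are stored in a flat data.frame with one row per coordinate part.
# A feature instance (identified by `feature_id`) may own several parts:
# multi-exon genes (e.g. the two exons of rps16) and features that wrap the
# circular origin. `part` gives transcription order within the instance.

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "intron", "IGS_label",
                   "repeat", "primer_site")

empty_features <- function() {
  data.frame(feature_id = character(0), gene = character(0),
             kind = character(0), strand = integer(0), part = integer(0),
             start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct an annotated plastome record
#'
#' @param id Record identifier.
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param features Data frame with columns `feature_id`, `gene`, `kind`
#'   (one of CDS, tRNA, rRNA, intron, IGS_label, repeat, primer_site),
#'   `strand` (+1/-1), `part` (1-based part index in transcription order),
#'   `start`, `end` (0-based half-open, within `[0, length)`; a feature may
#'   wrap the origin by being split into several parts).
#' @param circular Is the molecule circular?
#' @return An object of class `PlastomeRecord`.
#' @export
plastome_record <- function(id, sequence, features = empty_features(),
                            circular = TRUE) {
  sequence <- check_dna(sequence)
  if (nchar(sequence) == 0L) stop("sequence length must be > 0", call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("feature_id", "gene", "kind", "strand", "part", "start", "end")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols) > 0L) {
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  features <- features[need]
  features$strand <- as.integer(features$strand)
  features$part <- as.integer(features$part)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  obj <- structure(list(id = as.character(id), sequence = sequence,
                        circular = isTRUE(circular), features = features),
                   class = "PlastomeRecord")
  validate_record(obj)
  obj
}

#' Validate a PlastomeRecord
#'
#' Checks the container invariants: coordinates in range, non-empty
#' non-overlapping parts per feature, strands in `{-1, +1}`, known feature
#' kinds. Returns the record invisibly; stops on violation.
#' @param record A `PlastomeRecord`.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "PlastomeRecord"))
  L <- nchar(record$sequence)
  ft <- record$features
  if (nrow(ft) == 0L) return(invisible(record))
  if (any(!ft$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind(s): ",
         paste(unique(setdiff(ft$kind, FEATURE_KINDS)), collapse = ", "),
         call. = FALSE)
  }
  if (any(!ft$strand %in% c(-1L, 1L))) stop("strand must be +1 or -1",
                                            call. = FALSE)
  if (any(ft$start < 0L | ft$end > L | ft$start >= ft$end)) {
    bad <- ft[ft$start < 0L | ft$end > L | ft$start >= ft$end, , drop = FALSE]
    stop(sprintf("feature '%s' has coordinates outside [0, %d)",
                 bad$feature_id[1L], L), call. = FALSE)
  }
  for (fid in unique(ft$feature_id)) {
    p <- ft[ft$feature_id == fid, , drop = FALSE]
    p <- p[order(p$part), , drop = FALSE]
    if (any(duplicated(p$part))) {
      stop(sprintf("feature '%s' has duplicated part indices", fid),
           call. = FALSE)
    }
    if (nrow(p) > 1L) {
      q <- p[order(p$start), , drop = FALSE]
      if (any(q$end[-nrow(q)] > q$start[-1L])) {
        stop(sprintf("feature '%s' has overlapping parts", fid),
             call. = FALSE)
      }
    }
  }
  invisible(record)
}

#' @export
print.PlastomeRecord <- function(x, ...) {
  cat(sprintf("PlastomeRecord '%s': %s bp, %s, %d feature part(s), %d feature(s)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), length(unique(x$features$feature_id))))
  invisible(x)
}

#' @export
length.PlastomeRecord <- function(x) nchar(x$sequence)

# Sequence of one feature instance, parts concatenated in transcription
# order and reverse-complemented to the coding strand for minus features.
feature_seq <- function(record, feature_id) {
  p <- record$features[record$features$feature_id == feature_id, , drop = FALSE]
  if (nrow(p) == 0L) stop("no feature with id '", feature_id, "'",
                          call. = FALSE)
  p <- p[order(p$part), , drop = FALSE]
  pieces <- mapply(function(s, e) circ_substr(record$sequence, s, e),
                   p$start, p$end)
  if (p$strand[1L] == -1L) {
    # parts are in transcription order: reverse-complement each genomic
    # slice, then join (genomic order of minus-strand parts is reversed)
    paste(vapply(pieces, revcomp, character(1)), collapse = "")
  } else {
    paste(pieces, collapse = "")
  }
}

# One row per feature instance with the genomic extent (min start, max end)
# and representative strand/kind, ordered by ascending start.
feature_table <- function(record, kinds = NULL) {
  ft <- record$features
  if (!is.null(kinds)) ft <- ft[ft$kind %in% kinds, , drop = FALSE]
  if (nrow(ft) == 0L) {
    return(data.frame(feature_id = character(0), gene = character(0),
                      kind = character(0), strand = integer(0),
                      start = integer(0), end = integer(0), n_parts = integer(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(ft, ft$feature_id)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(feature_id = p$feature_id[1L], gene = p$gene[1L],
               kind = p$kind[1L], strand = p$strand[1L],
               start = min(p$start), end = max(p$end), n_parts = nrow(p),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Records are equal when sequence, circularity and the feature set agree
# (feature row order and feature_id labels are not significant; coordinates,
# parts, strands, kinds and gene names are).
records_equal <- function(a, b) {
  if (nchar(a$sequence) != nchar(b$sequence)) return(FALSE)
  if (a$sequence != b$sequence) return(FALSE)
  if (a$circular != b$circular) return(FALSE)
  key <- function(ft) {
    k <- ft[order(ft$gene, ft$kind, ft$strand, ft$part, ft$start, ft$end), ,
            drop = FALSE]
    paste(k$gene, k$kind, k$strand, k$part, k$start, k$end, sep = "|")
  }
  identical(key(a$features), key(b$features))
}

#' Rotate a circular record to a new origin
#'
#' Shifts the sequence so that old position `origin` becomes position 0 and
#' remaps all feature coordinates; parts that come to straddle the new
#' origin are split into wrap parts.
#' @param record A circular `PlastomeRecord`.
#' @param origin New origin (0-based position in the old coordinates).
#' @return The rotated `PlastomeRecord`.
#' @export
rotate_record <- function(record, origin) {
  stopifnot(inherits(record, "PlastomeRecord"))
  if (!record$circular) stop("cannot rotate a linear record", call. = FALSE)
  L <- nchar(record$sequence)
  origin <- as.integer(origin %% L)
  if (origin == 0L) return(record)
  seq2 <- rotate_str(record$sequence, origin)
  ft <- record$features
  rows <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    s <- (ft$start[i] - origin) %% L
    e <- s + (ft$end[i] - ft$start[i])
    if (e <= L) {
      rows[[i]] <- transform(ft[i, , drop = FALSE], start = s, end = e,
                             sub = 1L)
    } else {
      # split at the origin; `sub` encodes transcription order of the halves
      # (a minus-strand feature is transcribed right-to-left)
      plus <- ft$strand[i] == 1L
      a <- transform(ft[i, , drop = FALSE], start = s, end = L,
                     sub = if (plus) 1L else 2L)
      b <- transform(ft[i, , drop = FALSE], start = 0L, end = e - L,
                     sub = if (plus) 2L else 1L)
      rows[[i]] <- rbind(a, b)
    }
  }
  ft2 <- do.call(rbind, rows)
  if (!is.null(ft2) && nrow(ft2) > 0L) {
    # renumber parts per feature in transcription order
    ft2 <- do.call(rbind, lapply(split(ft2, ft2$feature_id), function(p) {
      p <- p[order(p$part, p$sub), , drop = FALSE]
      p$part <- seq_len(nrow(p))
      p
    }))
    ft2$sub <- NULL
    rownames(ft2) <- NULL
  } else {
    ft2 <- empty_features()
  }
  plastome_record(record$id, seq2, ft2, circular = TRUE)
}
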