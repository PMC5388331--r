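# Inverted-repeat detection and quadripartite partitioning of circular
# plastomes, plus the genome summary statistics reported alongside.

COMP_RAW <- {
  tab <- raw(256)
  f <- function(x) as.integer(charToRaw(x))
  tab[f("A")] <- charToRaw("T"); tab[f("T")] <- charToRaw("A")
  tab[f("C")] <- charToRaw("G"); tab[f("G")] <- charToRaw("C")
  tab[f("N")] <- charToRaw("N")
  tab
}

#' Find the inverted-repeat pair of a circular sequence
#'
#' Locates the two maximal-length disjoint intervals A and B such that the
#' sequence of A equals the reverse complement of the sequence of B, with
#' length at least `min_len`. Matching is exact by default (`max_mismatch`
#' is a knob for near-identical repeats; seed hits and extension then
#' tolerate up to that many mismatches). Maximality holds in the paired
#' sense: co-extending both copies by one base breaks the equality. Ties
#' between equal-length candidate pairs are broken by the larger minimum
#' circular gap between the copies, then by the lower start coordinate.
#'
#' @param sequence Nucleotide string (treated as circular).
#' @param min_len Minimum repeat copy length in bp (>= 100).
#' @param max_mismatch Maximum mismatches tolerated (default 0, exact).
#' @return `NULL` when no such pair exists; otherwise a list with
#'   `copy_a`/`copy_b` (each `c(start, end)`, 0-based half-open, possibly
#'   wrapping so that `end` may exceed the sequence length), `length`, and
#'   `degenerate` (`TRUE` when extension was stopped by the copies meeting
#'   on the circle).
#' @export
find_inverted_repeat <- function(sequence, min_len = 1000L,
                                 max_mismatch = 0L) {
  sequence <- check_dna(sequence)
  if (min_len < 100L) stop("min_len must be >= 100", call. = FALSE)
  L <- nchar(sequence)
  if (L < 2L * min_len) return(NULL)

  sv <- charToRaw(sequence)
  cv <- COMP_RAW[as.integer(sv)]
  subj <- Biostrings::DNAString(sequence)

  w <- min(100L, min_len)
  stride <- max(1L, (min_len - w) %/% 2L + 1L)
  probe_starts <- seq(0L, L - w, by = stride)

  seen_d <- new.env(hash = TRUE)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) return(cand)
    if (cand$length > best$length) return(cand)
    if (cand$length == best$length) {
      if (cand$sep > best$sep) return(cand)
      if (cand$sep == best$sep && cand$copy_a[1L] < best$copy_a[1L]) {
        return(cand)
      }
    }
    best
  }

  for (p in probe_starts) {
    probe <- substr(sequence, p + 1L, p + w)
    if (grepl("N", probe, fixed = TRUE)) next
    pat <- revcomp(probe)
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    starts <- Biostrings::start(hits) - 1L
    for (qs in starts) {
      d <- (p + qs + w - 1L) %% L  # anti-diagonal identifier
      key <- as.character(d)
      if (!is.null(seen_d[[key]])) next
      seen_d[[key]] <- TRUE
      cand <- extend_ir_candidate(sv, cv, L, p, p + w, qs, qs + w,
                                  max_mismatch)
      if (is.null(cand) || cand$length < min_len) next
      best <- consider(cand)
    }
  }
  if (is.null(best)) return(NULL)
  best$sep <- NULL
  best
}

# Extend a seeded pairing (A=[a1,a2), B=[b1,b2), seq(A)==revcomp(seq(B)))
# maximally in both paired directions on the circle. Indices 0-based;
# returns normalized intervals with a1 in [0, L).
extend_ir_candidate <- function(sv, cv, L, a1, a2, b1, b2, budget = 0L) {
  at <- function(i) sv[(i %% L) + 1L]
  ct <- function(i) cv[(i %% L) + 1L]
  # guard: overlapping seed (palindrome on itself) is not a two-copy repeat
  span <- function(x1, x2) (x2 - x1)
  overlap <- function() {
    # copies overlap on the circle?
    ia <- ((a1:(a2 - 1L)) %% L)
    ib <- ((b1:(b2 - 1L)) %% L)
    length(intersect(ia, ib)) > 0L
  }
  if (overlap()) return(NULL)
  degenerate <- FALSE
  mm_used <- 0L
  # paired extension: left end of A with right end of B
  repeat {
    if (span(a1, a2) + span(b1, b2) >= L) { degenerate <- TRUE; break }
    # stop when the next base would belong to both copies at once
    na <- (a1 - 1L) %% L
    if (na == (b2 %% L)) { degenerate <- TRUE; break }
    ok <- at(a1 - 1L) == ct(b2)
    if (!ok) {
      if (mm_used < budget) mm_used <- mm_used + 1L else break
    }
    a1 <- a1 - 1L
    b2 <- b2 + 1L
  }
  # paired extension: right end of A with left end of B
  repeat {
    if (span(a1, a2) + span(b1, b2) >= L) { degenerate <- TRUE; break }
    nb <- (b1 - 1L) %% L
    if (nb == ((a2) %% L)) { degenerate <- TRUE; break }
    ok <- at(a2) == ct(b1 - 1L)
    if (!ok) {
      if (mm_used < budget) mm_used <- mm_used + 1L else break
    }
    a2 <- a2 + 1L
    b1 <- b1 - 1L
  }
  len <- span(a1, a2)
  # normalize: copy_a is the copy with the lower (mod L) start
  s_a <- a1 %% L; s_b <- b1 %% L
  ca <- c(s_a, s_a + len); cb <- c(s_b, s_b + span(b1, b2))
  if (s_b < s_a) { tmp <- ca; ca <- cb; cb <- tmp }
  gap1 <- (cb[1L] - ca[2L]) %% L
  gap2 <- (ca[1L] - cb[2L]) %% L
  list(copy_a = as.integer(ca), copy_b = as.integer(cb),
       length = as.integer(len), degenerate = degenerate,
       sep = min(gap1, gap2))
}

#' Partition a circular plastome into LSC / IRa / SSC / IRb
#'
#' The single-copy stretches between the detected repeat copies are
#' assigned LSC (longer) and SSC (shorter); IRa is the repeat copy
#' immediately downstream of the LSC. The four intervals tile the circle
#' exactly once and the result is invariant under rotation of the input.
#'
#' @param record A circular `PlastomeRecord` (or a plain sequence string).
#' @param min_len Minimum IR length passed to [find_inverted_repeat()].
#' @param max_mismatch Mismatch tolerance for IR detection.
#' @return A `QuadripartitePartition`: list with `regions` (data frame with
#'   `region`, `start`, `length`; starts 0-based on the input sequence,
#'   regions may wrap) and `lengths` (named vector LSC/IRa/SSC/IRb).
#' @export
partition_genome <- function(record, min_len = 1000L, max_mismatch = 0L) {
  sequence <- if (inherits(record, "PlastomeRecord")) record$sequence else
    check_dna(record)
  L <- nchar(sequence)
  ir <- find_inverted_repeat(sequence, min_len = min_len,
                             max_mismatch = max_mismatch)
  if (is.null(ir)) {
    stop("no inverted repeat found; try lowering min_len", call. = FALSE)
  }
  a <- ir$copy_a; b <- ir$copy_b
  # single-copy gaps: after a (to b's start) and after b (to a's start)
  gap_ab <- c(start = a[2L] %% L, length = (b[1L] - a[2L]) %% L)
  gap_ba <- c(start = b[2L] %% L, length = (a[1L] - b[2L]) %% L)
  if (gap_ab[["length"]] == 0L || gap_ba[["length"]] == 0L) {
    stop("degenerate repeat pair: no single-copy regions", call. = FALSE)
  }
  if (gap_ab[["length"]] >= gap_ba[["length"]]) {
    lsc <- gap_ab; ssc <- gap_ba; ira <- b; irb <- a
  } else {
    lsc <- gap_ba; ssc <- gap_ab; ira <- a; irb <- b
  }
  ir_len <- ir$length
  regions <- data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = as.integer(c(lsc[["start"]], ira[1L], ssc[["start"]], irb[1L])),
    length = as.integer(c(lsc[["length"]], ir_len, ssc[["length"]], ir_len)),
    stringsAsFactors = FALSE)
  lengths <- stats::setNames(regions$length, regions$region)
  if (sum(lengths) != L) {
    stop("partition does not tile the genome", call. = FALSE)  # invariant
  }
  structure(list(regions = regions, lengths = lengths, total = L),
            class = "QuadripartitePartition")
}

#' @export
print.QuadripartitePartition <- function(x, ...) {
  cat(sprintf("Quadripartite partition: total %s bp\n",
              format(x$total, big.mark = ",")))
  for (i in seq_len(nrow(x$regions))) {
    cat(sprintf("  %-3s %9s bp (start %d)\n", x$regions$region[i],
                format(x$regions$length[i], big.mark = ","),
                x$regions$start[i]))
  }
  invisible(x)
}

# membership test: which region does 0-based position p fall in?
region_of_position <- function(partition, p) {
  L <- partition$total
  for (i in seq_len(nrow(partition$regions))) {
    s <- partition$regions$start[i]
    len <- partition$regions$length[i]
    if (((p - s) %% L) < len) return(partition$regions$region[i])
  }
  NA_character_
}

#' Genome summary statistics
#'
#' Computes totals, base composition, the coding fraction, and feature
#' counts. The coding fraction is the union of CDS exon intervals over the
#' total length (IR-duplicated CDS count in both copies since the fraction
#' is of total sequence); a variant that adds tRNA/rRNA intervals is also
#' reported. Feature counts are reported both deduplicated by gene name
#' and with IR duplicates, and the total count of annotated genic feature
#' parts (exons/introns counted separately) is included, since published
#' per-genome tallies differ in which of these they count.
#'
#' @param record A `PlastomeRecord`.
#' @param partition Optional [partition_genome()] result (adds region
#'   lengths to the summary).
#' @return A list of class `SummaryStats`.
#' @export
genome_summary <- function(record, partition = NULL) {
  L <- nchar(record$sequence)
  gc <- gc_content(record$sequence, percent = TRUE)
  ft <- record$features
  union_len <- function(kinds) {
    rows <- ft[ft$kind %in% kinds, , drop = FALSE]
    if (nrow(rows) == 0L) return(0L)
    ir <- IRanges::IRanges(start = rows$start + 1L, end = rows$end)
    sum(IRanges::width(IRanges::reduce(ir)))
  }
  coding_len <- union_len("CDS")
  coding_rna_len <- union_len(c("CDS", "tRNA", "rRNA"))
  count_kind <- function(kind) {
    rows <- ft[ft$kind == kind, , drop = FALSE]
    c(unique = length(unique(rows$gene)),
      with_duplicates = length(unique(rows$feature_id)))
  }
  counts <- list(CDS = count_kind("CDS"), tRNA = count_kind("tRNA"),
                 rRNA = count_kind("rRNA"))
  genic <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA", "intron"), , drop = FALSE]
  out <- list(
    total_bp = L,
    region_lengths = if (!is.null(partition)) partition$lengths else NULL,
    gc_percent = gc,
    at_percent = 100 - gc,
    coding_fraction_cds = 100 * coding_len / L,
    coding_fraction_cds_rna = 100 * coding_rna_len / L,
    counts = counts,
    n_features_unique = length(unique(genic$gene)),
    n_features_with_ir_duplicates = length(unique(genic$feature_id)),
    n_genic_parts = nrow(genic))
  structure(out, class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("Total length: %s bp\n", format(x$total_bp, big.mark = ",")))
  if (!is.null(x$region_lengths)) {
    cat("Regions:", paste(sprintf("%s=%s", names(x$region_lengths),
                                  format(x$region_lengths, big.mark = ",")),
                          collapse = ", "), "\n")
  }
  cat(sprintf("GC %.1f%% / AT %.1f%%\n", x$gc_percent, x$at_percent))
  cat(sprintf("Coding fraction (CDS) %.1f%%; with structural RNAs %.1f%%\n",
              x$coding_fraction_cds, x$coding_fraction_cds_rna))
  cat(sprintf("Genes: %d CDS, %d tRNA, %d rRNA (unique); %d features with IR duplicates; %d genic parts\n",
              x$counts$CDS[["unique"]], x$counts$tRNA[["unique"]],
              x$counts$rRNA[["unique"]], x$n_features_with_ir_duplicates,
              x$n_genic_parts))
  invisible(x)
}
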