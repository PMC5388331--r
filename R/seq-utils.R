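# Low-level nucleotide string helpers. All sequences in this package are
# plain uppercase character scalars over the alphabet {A,C,G,T,N}; all
# coordinates are 0-based half-open and, on circular molecules, taken
# modulo the sequence length.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over `A,C,G,T,N`.
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Validate a nucleotide string
#'
#' Rejects ambiguity codes other than `N` so that downstream
#' reverse-complement and ORF logic stays exact.
#' @param x Character scalar.
#' @param what Label used in error messages.
#' @return Invisibly, `x` (uppercased).
#' @keywords internal
check_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                 what, substr(bad, 1L, 10L)), call. = FALSE)
  }
  invisible(x)
}

#' GC content of a nucleotide string
#'
#' @param x Character scalar.
#' @param percent Return a percentage instead of a fraction.
#' @return GC fraction (or percent) over unambiguous bases; `N` is excluded
#'   from both numerator and denominator.
#' @export
gc_content <- function(x, percent = FALSE) {
  n_gc <- nchar(gsub("[^GC]", "", x))
  n_ok <- nchar(gsub("[^ACGT]", "", x))
  if (n_ok == 0L) return(NA_real_)
  out <- n_gc / n_ok
  if (percent) out * 100 else out
}

# Extract [start, end) from a circular string, wrapping past the origin if
# end > nchar(x). start is 0-based.
circ_substr <- function(x, start, end) {
  L <- nchar(x)
  stopifnot(end >= start)
  if (end - start > L) stop("interval longer than sequence", call. = FALSE)
  start <- start %% L
  span <- end - start
  if (span == 0L) return("")
  if (start + span <= L) {
    substr(x, start + 1L, start + span)
  } else {
    paste0(substr(x, start + 1L, L), substr(x, 1L, span - (L - start)))
  }
}

# Rotate a circular string so that old position `origin` becomes position 0.
rotate_str <- function(x, origin) {
  L <- nchar(x)
  origin <- origin %% L
  if (origin == 0L) return(x)
  paste0(substr(x, origin + 1L, L), substr(x, 1L, origin))
}

#' Seeded random nucleotide sequence
#'
#' Base composition is controlled by a GC fraction; A/T and G/C are used in
#' equal proportions within their class.
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return Character scalar of length `n`.
#' @export
random_seq <- function(n, gc = 0.365) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# The bacterial/plastid genetic code (translation table 11) only matters to
# this package through its stop codons and permitted start codons.
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG")

# Split a coding string into consecutive codons (last partial codon kept).
codons_of <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  substring(x, starts, pmin(starts + 2L, n))
}

# Position (1-based codon index) of the first in-frame stop, or NA.
first_internal_stop <- function(x) {
  cod <- codons_of(x)
  cod <- cod[nchar(cod) == 3L]
  hit <- which(cod %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Random in-frame coding sequence: ATG + (n/3 - 2) sense codons + stop.
# n must be a multiple of 3, n >= 9. Used by the synthetic generator; base
# composition follows the same GC dial as the intergenic spacers.
random_orf <- function(n, gc = 0.365) {
  stopifnot(n %% 3L == 0L, n >= 9L)
  n_sense <- n %/% 3L - 2L
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sense <- character(n_sense)
  i <- 0L
  while (i < n_sense) {
    cand <- paste(sample(bases, 3L, replace = TRUE, prob = p), collapse = "")
    if (!(cand %in% STOP_CODONS)) {
      i <- i + 1L
      sense[i] <- cand
    }
  }
  paste0("ATG", paste(sense, collapse = ""), sample(STOP_CODONS, 1L))
}
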