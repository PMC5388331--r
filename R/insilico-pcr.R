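# In-silico PCR on circular genomes: primer-site finding under a
# mismatch-count annealing model (with an exact 3'-terminal window),
# amplicon prediction from convergent site pairs, and the dual-assay
# presence/absence calling logic used for the inversion screen.

# All hits of `primer` on the circular `sequence`.
# Returns data.frame(pos, strand, mismatches): `pos` is the 0-based
# position of the leftmost base of the site on the plus strand; strand +1
# means the primer anneals so that extension proceeds rightward (site
# content equals the primer), -1 leftward (site content equals its reverse
# complement). A site spanning the origin is reported once.

#' Find primer binding sites on a circular sequence
#'
#' A primer anneals where at most `max_mismatch` positions differ and the
#' `three_prime_exact` bases at the primer's 3' end match exactly.
#'
#' @param sequence Nucleotide string (circular).
#' @param primer Primer sequence, 5'->3'.
#' @param max_mismatch Maximum mismatches over the whole primer.
#' @param three_prime_exact Length of the exact-match 3'-terminal window.
#' @return Data frame with columns `pos` (0-based plus-strand position of
#'   the site's leftmost base), `strand` (+1 rightward extension, -1
#'   leftward), `mismatches`.
#' @export
find_primer_sites <- function(sequence, primer, max_mismatch = 2L,
                              three_prime_exact = 3L) {
  sequence <- check_dna(sequence)
  primer <- check_dna(primer, "primer")
  k <- nchar(primer)
  if (k < three_prime_exact) {
    stop("primer shorter than the exact 3' window", call. = FALSE)
  }
  L <- nchar(sequence)
  if (L < k) {
    return(data.frame(pos = integer(0), strand = integer(0),
                      mismatches = integer(0)))
  }
  doubled <- paste0(sequence, substr(sequence, 1L, k - 1L))
  sv <- charToRaw(doubled)
  scan_one <- function(pat, exact_at_start) {
    pv <- charToRaw(pat)
    mism <- integer(L)
    exact_ok <- rep(TRUE, L)
    idx0 <- seq_len(L) - 1L
    for (j in seq_len(k)) {
      neq <- sv[idx0 + j] != pv[j]
      mism <- mism + as.integer(neq)
      in_window <- if (exact_at_start) j <= three_prime_exact else
        j > k - three_prime_exact
      if (in_window) exact_ok <- exact_ok & !neq
    }
    which(mism <= max_mismatch & exact_ok) - 1L
  }
  # plus strand: site content = primer; 3' end = last bases of the window
  pos_plus <- scan_one(primer, exact_at_start = FALSE)
  # minus strand: site content = revcomp(primer); the primer's 3' end maps
  # to the first bases of the window
  pos_minus <- scan_one(revcomp(primer), exact_at_start = TRUE)
  mism_at <- function(pos, pat) {
    vapply(pos, function(p) {
      sum(charToRaw(substr(doubled, p + 1L, p + k)) != charToRaw(pat))
    }, integer(1))
  }
  out <- rbind(
    if (length(pos_plus) > 0L) {
      data.frame(pos = pos_plus, strand = 1L,
                 mismatches = mism_at(pos_plus, primer))
    },
    if (length(pos_minus) > 0L) {
      data.frame(pos = pos_minus, strand = -1L,
                 mismatches = mism_at(pos_minus, revcomp(primer)))
    })
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), strand = integer(0),
                      mismatches = integer(0))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Predict amplicons of a primer pair on a circular genome
#'
#' Every combination of a rightward-extending site of one primer and a
#' leftward-extending site of the other, with the 3' ends converging,
#' yields one amplicon; its length is measured inclusive of both primers
#' along the arc the polymerase traverses, and only products of at most
#' `max_len` bp are reported.
#'
#' @param sequence Nucleotide string (circular).
#' @param pair A [primer_pair()].
#' @param max_len Maximum product length in bp.
#' @param max_mismatch,three_prime_exact Annealing model parameters.
#' @return Data frame with columns `start` (0-based position of the
#'   leftward-most base), `length`, `fwd_primer`, `rev_primer`.
#' @export
predict_amplicons <- function(sequence, pair, max_len = 3000L,
                              max_mismatch = 2L, three_prime_exact = 3L) {
  stopifnot(inherits(pair, "PrimerPair"))
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  sites_f <- find_primer_sites(sequence, pair$forward, max_mismatch,
                               three_prime_exact)
  sites_r <- find_primer_sites(sequence, pair$reverse, max_mismatch,
                               three_prime_exact)
  out <- list()
  add_products <- function(plus_sites, plus_len, minus_sites, minus_len,
                           plus_name, minus_name) {
    for (a in plus_sites) {
      for (b in minus_sites) {
        # plus site extends rightward from a; minus site ends at b+len-1
        prod_len <- ((b + minus_len - a) %% L)
        if (prod_len == 0L) prod_len <- L
        if (prod_len >= plus_len + minus_len && prod_len <= max_len) {
          out[[length(out) + 1L]] <<- data.frame(
            start = a, length = prod_len, fwd_primer = plus_name,
            rev_primer = minus_name, stringsAsFactors = FALSE)
        }
      }
    }
  }
  kf <- nchar(pair$forward); kr <- nchar(pair$reverse)
  add_products(sites_f$pos[sites_f$strand == 1L], kf,
               sites_r$pos[sites_r$strand == -1L], kr,
               "forward", "reverse")
  add_products(sites_r$pos[sites_r$strand == 1L], kr,
               sites_f$pos[sites_f$strand == -1L], kf,
               "reverse", "forward")
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), length = integer(0),
                      fwd_primer = character(0), rev_primer = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$length), , drop = FALSE]
}

#' Screen one genome for one inversion
#'
#' Calls PRESENT when the presence pair amplifies and the absence pair does
#' not, ABSENT in the converse case, and AMBIGUOUS otherwise (both or
#' neither amplify).
#'
#' @param record A `PlastomeRecord` (or sequence string).
#' @param assay An [assay_definition()].
#' @param max_mismatch,three_prime_exact Annealing model parameters.
#' @return A `ScreenCall`: list with `inversion`, `call`, and the
#'   amplicon tables `absence_amplicons` / `presence_amplicons`.
#' @export
screen_inversion <- function(record, assay, max_mismatch = 2L,
                             three_prime_exact = 3L) {
  stopifnot(inherits(assay, "AssayDefinition"))
  sequence <- if (inherits(record, "PlastomeRecord")) record$sequence else
    check_dna(record)
  abs_amp <- predict_amplicons(sequence, assay$absence_pair, assay$max_len,
                               max_mismatch, three_prime_exact)
  pre_amp <- predict_amplicons(sequence, assay$presence_pair, assay$max_len,
                               max_mismatch, three_prime_exact)
  call <- if (nrow(pre_amp) > 0L && nrow(abs_amp) == 0L) {
    "PRESENT"
  } else if (nrow(abs_amp) > 0L && nrow(pre_amp) == 0L) {
    "ABSENT"
  } else {
    "AMBIGUOUS"
  }
  structure(list(inversion = assay$inversion, call = call,
                 absence_amplicons = abs_amp, presence_amplicons = pre_amp),
            class = "ScreenCall")
}

#' Run the inversion screen over a panel
#'
#' @param panel Named list of `PlastomeRecord`s (names are taxa).
#' @param assays List of [assay_definition()]s.
#' @param metadata Optional data frame with columns `taxon` and any of
#'   `genus`, `tribe`; used for the genus- and tribe-level tallies.
#' @param ... Passed to [screen_inversion()].
#' @return A `ScreenResult`: list with `calls` (taxon x inversion data
#'   frame of PRESENT/ABSENT/AMBIGUOUS), and `tallies` (per inversion:
#'   `n_present_taxa`, and when metadata is given `n_present_genera`,
#'   `n_present_tribes`; AMBIGUOUS taxa are excluded from tallies with a
#'   warning).
#' @export
run_panel_screen <- function(panel, assays, metadata = NULL, ...) {
  taxa <- names(panel)
  if (length(assays) == 0L) {
    return(structure(list(calls = data.frame(taxon = taxa,
                                             stringsAsFactors = FALSE),
                          tallies = list()), class = "ScreenResult"))
  }
  calls <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (assay in assays) {
    calls[[assay$inversion]] <-
      vapply(panel, function(rec) screen_inversion(rec, assay, ...)$call,
             character(1))
  }
  tallies <- list()
  for (assay in assays) {
    inv <- assay$inversion
    cc <- calls[[inv]]
    if (any(cc == "AMBIGUOUS")) {
      warning(sprintf("%s: excluding %d AMBIGUOUS taxa from tallies", inv,
                      sum(cc == "AMBIGUOUS")), call. = FALSE)
    }
    present <- calls$taxon[cc == "PRESENT"]
    t_entry <- list(n_present_taxa = length(present))
    if (!is.null(metadata)) {
      md <- metadata[match(present, metadata$taxon), , drop = FALSE]
      if ("genus" %in% names(metadata)) {
        t_entry$n_present_genera <- length(unique(md$genus))
        t_entry$present_genera <- sort(unique(md$genus))
      }
      if ("tribe" %in% names(metadata)) {
        t_entry$n_present_tribes <- length(unique(md$tribe))
        t_entry$present_tribes <- sort(unique(md$tribe))
      }
    }
    tallies[[inv]] <- t_entry
  }
  structure(list(calls = calls, tallies = tallies), class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  print(x$calls)
  for (inv in names(x$tallies)) {
    t <- x$tallies[[inv]]
    cat(sprintf("%s: %d taxa PRESENT", inv, t$n_present_taxa))
    if (!is.null(t$n_present_genera)) {
      cat(sprintf(", %d genera", t$n_present_genera))
    }
    if (!is.null(t$n_present_tribes)) {
      cat(sprintf(", %d tribes", t$n_present_tribes))
    }
    cat("\n")
  }
  invisible(x)
}
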