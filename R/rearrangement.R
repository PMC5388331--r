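# Inversion detection via signed gene-order permutations: linearization of
# circular genomes (one IR copy removed, LSC first), collinear-block
# decomposition over a panel, greedy nested-inversion inference with an
# exact breadth-first-search oracle for small marker counts, and breakpoint
# localization to flanking loci.

# Ordered single-copy gene table of a record: gene-level loci (CDS, tRNA,
# rRNA; extents include introns) with coordinates linearized at the
# IRb/LSC junction (LSC first, then IRa, then SSC); IRb copies dropped.
single_copy_order <- function(record, min_len = 1000L) {
  part <- partition_genome(record, min_len = min_len)
  L <- part$total
  lsc_start <- part$regions$start[part$regions$region == "LSC"]
  irb_start <- part$regions$start[part$regions$region == "IRb"]
  irb_len <- part$regions$length[part$regions$region == "IRb"]
  ext <- gene_extents(record)
  rel <- (ext$start - lsc_start) %% L
  mid <- (ext$start + (ext$end - ext$start) %/% 2L) %% L
  in_irb <- ((mid - irb_start) %% L) < irb_len
  ext <- ext[!in_irb, , drop = FALSE]
  rel <- rel[!in_irb]
  # representative strand per locus (strand of its first feature row)
  ft <- record$features
  ft <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  strand_of <- vapply(ext$gene, function(g) {
    ft$strand[ft$gene == g][1L]
  }, integer(1))
  out <- data.frame(gene = ext$gene, strand = strand_of, pos = rel,
                    start = ext$start, end = ext$end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared signed gene-order permutation
#'
#' Represents the gene order of `record` relative to `reference` as a
#' signed permutation over a shared single-copy marker set: both genomes
#' are linearized at the IRb/LSC junction with one IR copy removed; the
#' reference maps to the identity `+1..+n`, and a marker's sign is its
#' strand relative to the reference.
#'
#' @param record,reference `PlastomeRecord`s.
#' @param marker_set Optional character vector of gene names; defaults to
#'   all genes occurring exactly once in each linearized genome.
#' @param min_len Minimum IR length for partitioning.
#' @return A `SignedPermutation`: list with `taxon`, `perm` (signed integer
#'   vector), `markers` (marker names in reference order).
#' @export
shared_gene_order <- function(record, reference, marker_set = NULL,
                              min_len = 1000L) {
  oq <- single_copy_order(record, min_len)
  or <- single_copy_order(reference, min_len)
  count_q <- table(oq$gene)
  count_r <- table(or$gene)
  if (is.null(marker_set)) {
    marker_set <- intersect(names(count_r)[count_r == 1L],
                            names(count_q)[count_q == 1L])
  } else {
    bad_q <- marker_set[!(marker_set %in% names(count_q)) |
                          count_q[marker_set] != 1L]
    bad_r <- bad_missing <- marker_set[!(marker_set %in% names(count_r)) |
                                         count_r[marker_set] != 1L]
    bad <- unique(c(bad_q[!is.na(bad_q)], bad_r[!is.na(bad_r)]))
    if (length(bad) > 0L) {
      stop("marker(s) missing or duplicated: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  or <- or[or$gene %in% marker_set, , drop = FALSE]
  oq <- oq[oq$gene %in% marker_set, , drop = FALSE]
  idx_of <- stats::setNames(seq_len(nrow(or)), or$gene)
  sgn_ref <- stats::setNames(or$strand, or$gene)
  perm <- unname(as.integer(idx_of[oq$gene]) *
                   ifelse(oq$strand == sgn_ref[oq$gene], 1L, -1L))
  structure(list(taxon = record$id, perm = perm, markers = or$gene),
            class = "SignedPermutation")
}

#' @export
print.SignedPermutation <- function(x, ...) {
  cat(sprintf("SignedPermutation '%s' over %d markers\n", x$taxon,
              length(x$perm)))
  invisible(x)
}

# extended permutation with virtual framing markers 0 and n+1
extend_perm <- function(perm) c(0L, perm, length(perm) + 1L)

# number of identity adjacencies (correctly ordered, correctly signed)
identity_adjacencies <- function(perm) {
  e <- extend_perm(perm)
  sum(diff(e) == 1L)
}

apply_reversal <- function(perm, i, j) {
  perm[i:j] <- -rev(perm[i:j])
  perm
}

#' Locally collinear block decomposition of a permutation panel
#'
#' Blocks are the maximal runs of reference markers between the union of
#' breakpoints, where a breakpoint is any reference adjacency (signs
#' included) not conserved across all permutations. Blocks tile every
#' permutation, each appearing once per taxon with an orientation.
#'
#' @param perms List of `SignedPermutation`s over the same marker set.
#' @return List of `CollinearBlock`s: each a list with `id`, `ref_range`
#'   (`c(first, last)` reference marker indices), `markers`, and
#'   `per_taxon` (data frame `taxon`, `start_pos`, `end_pos`, `orient`).
#' @export
lcb_decomposition <- function(perms) {
  if (length(perms) < 2L) stop("need at least 2 permutations", call. = FALSE)
  markers <- perms[[1L]]$markers
  for (p in perms) {
    if (!identical(p$markers, markers)) {
      stop("permutations are over different marker sets", call. = FALSE)
    }
  }
  n <- length(markers)
  # adjacency (i, i+1) conserved in a permutation when (i, i+1) or
  # (-(i+1), -i) occur consecutively in its extension
  conserved <- rep(TRUE, n - 1L)
  for (p in perms) {
    e <- extend_perm(p$perm)
    pair_key <- paste(e[-length(e)], e[-1L], sep = ",")
    have <- new.env(hash = TRUE)
    for (k in pair_key) have[[k]] <- TRUE
    for (i in seq_len(n - 1L)) {
      ok <- !is.null(have[[paste(i, i + 1L, sep = ",")]]) ||
        !is.null(have[[paste(-(i + 1L), -i, sep = ",")]])
      if (!ok) conserved[i] <- FALSE
    }
  }
  boundaries <- which(!conserved)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    a <- starts[b]; z <- ends[b]
    per_taxon <- do.call(rbind, lapply(perms, function(p) {
      pos <- match(c(a:z), abs(p$perm))
      stopifnot(!anyNA(pos))
      rng <- range(pos)
      if (rng[2L] - rng[1L] != z - a) {
        stop("block not contiguous in taxon '", p$taxon, "'", call. = FALSE)
      }
      vals <- p$perm[rng[1L]:rng[2L]]
      orient <- if (identical(vals, a:z)) "+" else if
      (identical(vals, -(z:a))) "-" else
        stop("block orientation inconsistent in '", p$taxon, "'",
             call. = FALSE)
      data.frame(taxon = p$taxon, start_pos = rng[1L], end_pos = rng[2L],
                 orient = orient, stringsAsFactors = FALSE)
    }))
    blocks[[b]] <- structure(list(id = b, ref_range = c(a, z),
                                  markers = markers[a:z],
                                  per_taxon = per_taxon),
                             class = "CollinearBlock")
  }
  blocks
}

# Breadth-first search from `v` to the identity; returns the shortest
# reversal sequence as a list of c(i, j) position intervals (empty when v
# is already the identity). Deterministic: intervals are explored in
# ascending (i, j) order.
bfs_sort_path <- function(v, max_states = 2e6) {
  n <- length(v)
  target <- paste(seq_len(n), collapse = ",")
  key <- paste(v, collapse = ",")
  if (key == target) return(list())
  parent <- new.env(hash = TRUE)
  parent[[key]] <- NA
  frontier <- list(v)
  n_visited <- 1L
  repeat {
    if (length(frontier) == 0L) {
      stop("identity unreachable (invalid permutation)", call. = FALSE)
    }
    nxt <- list()
    for (p in frontier) {
      pk <- paste(p, collapse = ",")
      for (i in seq_len(n)) {
        for (j in i:n) {
          q <- apply_reversal(p, i, j)
          k <- paste(q, collapse = ",")
          if (k == target) {
            # reconstruct: walk parents back to the start
            path <- list(c(i, j))
            ck <- pk
            while (!identical(parent[[ck]], NA)) {
              step <- parent[[ck]]
              path <- c(list(step$ij), path)
              ck <- step$from
            }
            return(path)
          }
          if (is.null(parent[[k]])) {
            parent[[k]] <- list(from = pk, ij = c(i, j))
            n_visited <- n_visited + 1L
            if (n_visited > max_states) {
              stop("BFS state limit exceeded", call. = FALSE)
            }
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
    }
    frontier <- nxt
  }
}

#' Exact signed reversal distance by breadth-first search
#'
#' Oracle for inversion inference: the minimum number of signed reversals
#' transforming a permutation into the identity, by breadth-first search
#' over permutation space. Only practical for small marker counts.
#'
#' @param perm A `SignedPermutation` or a signed integer vector.
#' @param max_markers Size guard (<= 10).
#' @return Integer distance.
#' @export
reversal_distance_bfs <- function(perm, max_markers = 10L) {
  v <- if (inherits(perm, "SignedPermutation")) perm$perm else as.integer(perm)
  n <- length(v)
  if (n > max_markers) {
    stop("too many markers for BFS (", n, " > ", max_markers, ")",
         call. = FALSE)
  }
  length(bfs_sort_path(v))
}

#' Infer an inversion history from a signed permutation
#'
#' Greedy nested-inversion reconstruction: repeatedly reverse the
#' maximal-length interval that strictly increases the number of correctly
#' signed, correctly ordered adjacencies, until the identity is reached
#' (ties: leftmost interval). Events are reported in the order found
#' (outermost first for nested histories); replaying the recorded intervals
#' in reverse order on the identity reproduces the observed permutation.
#' When no improving reversal exists before the identity is reached the
#' result is flagged `UNRESOLVED`; for small marker counts the event count
#' is checked against [reversal_distance_bfs()] and flagged `NON_MINIMAL`
#' when larger.
#'
#' @param perm A `SignedPermutation`.
#' @param record Optional source `PlastomeRecord`; adds realized segment
#'   sizes and breakpoint labels (via [localize_breakpoints()]) to events.
#' @param max_bfs Marker-count limit for the BFS minimality check.
#' @param min_len Minimum IR length when `record` is given.
#' @param fallback `"exact"` (default) replaces a stalled or non-minimal
#'   greedy result with an exact BFS shortest reversal sequence when the
#'   marker count permits; `"none"` keeps the flagged greedy outcome.
#' @return List with `events` (each an `InversionEvent` list: `order`,
#'   `positions`, `markers`, and when `record` is given `size`,
#'   `left_label`, `right_label`, `mediating_repeat`), `status` (`"OK"`,
#'   `"UNRESOLVED"` or `"NON_MINIMAL"`), and `method` (`"greedy"` or
#'   `"exact_bfs"`).
#' @export
infer_inversion_events <- function(perm, record = NULL, max_bfs = 10L,
                                   min_len = 1000L,
                                   fallback = c("exact", "none")) {
  stopifnot(inherits(perm, "SignedPermutation"))
  fallback <- match.arg(fallback)
  p <- perm$perm
  n <- length(p)
  events <- list()
  status <- "OK"
  method <- "greedy"
  while (!identical(p, seq_len(n))) {
    base_adj <- identity_adjacencies(p)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in i:n) {
        gain <- identity_adjacencies(apply_reversal(p, i, j)) - base_adj
        if (gain > 0L) {
          len <- j - i
          if (is.null(best) || len > best$len ||
              (len == best$len && i < best$i)) {
            best <- list(i = i, j = j, len = len)
          }
        }
      }
    }
    if (is.null(best)) {
      status <- "UNRESOLVED"
      break
    }
    ev <- list(order = length(events) + 1L,
               positions = c(best$i, best$j),
               markers = perm$markers[abs(p[best$i:best$j])])
    events[[length(events) + 1L]] <- structure(ev, class = "InversionEvent")
    p <- apply_reversal(p, best$i, best$j)
  }
  if (status == "OK" && n <= max_bfs) {
    d <- reversal_distance_bfs(perm, max_markers = max_bfs)
    if (length(events) > d) status <- "NON_MINIMAL"
  }
  if (status != "OK" && fallback == "exact" && n <= max_bfs) {
    # exact reconstruction: shortest reversal sequence by BFS
    path <- bfs_sort_path(perm$perm)
    p <- perm$perm
    events <- vector("list", length(path))
    for (k in seq_along(path)) {
      ij <- path[[k]]
      events[[k]] <- structure(
        list(order = k, positions = ij,
             markers = perm$markers[abs(p[ij[1L]:ij[2L]])]),
        class = "InversionEvent")
      p <- apply_reversal(p, ij[1L], ij[2L])
    }
    status <- "OK"
    method <- "exact_bfs"
  }
  if (!is.null(record) && length(events) > 0L) {
    events <- lapply(events, function(ev) {
      loc <- localize_breakpoints(ev, record, min_len = min_len)
      ev$size <- loc$size
      ev$left_label <- loc$left_label
      ev$right_label <- loc$right_label
      ev$mediating_repeat <- loc$mediating_repeat
      ev
    })
  }
  list(events = events, status = status, method = method)
}

#' Replay inferred inversion events on the identity order
#'
#' Applies the recorded position intervals in reverse order of inference;
#' the result equals the observed permutation the events were inferred
#' from.
#'
#' @param events Event list from [infer_inversion_events()].
#' @param n Number of markers.
#' @return Signed integer vector.
#' @export
replay_events <- function(events, n) {
  p <- seq_len(n)
  for (ev in rev(events)) {
    p <- apply_reversal(p, ev$positions[1L], ev$positions[2L])
  }
  p
}

#' Localize the breakpoints of an inversion event
#'
#' Labels each breakpoint by the two flanking gene-level loci in the source
#' genome (`"IGS(geneA-geneB)"`). When a planted repeat lies in the
#' flanking spacer, the breakpoint is additionally annotated with the
#' repeat's name and length. A breakpoint at the linearization origin is
#' labelled `"ORIGIN"`.
#'
#' @param event An `InversionEvent` (needs `markers`).
#' @param record The source `PlastomeRecord`.
#' @param min_len Minimum IR length for partitioning.
#' @return List with `size` (bp extent of the segment's markers in the
#'   source genome), `left_label`, `right_label`, `mediating_repeat`
#'   (`NULL` or list `name`/`length`).
#' @export
localize_breakpoints <- function(event, record, min_len = 1000L) {
  sco <- single_copy_order(record, min_len = min_len)
  idx <- match(event$markers, sco$gene)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop("event markers not found in record", call. = FALSE)
  }
  rng <- range(idx)
  seg <- sco[rng[1L]:rng[2L], , drop = FALSE]
  size <- max(seg$end) - min(seg$start)
  label_of <- function(outside_i, inside_i) {
    if (outside_i < 1L || outside_i > nrow(sco)) return("ORIGIN")
    sprintf("IGS(%s-%s)", sco$gene[outside_i], sco$gene[inside_i])
  }
  left_label <- label_of(rng[1L] - 1L, rng[1L])
  right_label <- label_of(rng[2L] + 1L, rng[2L])
  # planted repeat in a flanking spacer?
  rep_rows <- record$features[record$features$kind == "repeat", ,
                              drop = FALSE]
  mediating <- NULL
  if (nrow(rep_rows) > 0L) {
    seg_lo <- min(seg$start); seg_hi <- max(seg$end)
    flank_lo <- if (rng[1L] > 1L) sco$end[rng[1L] - 1L] else seg_lo - 2000L
    flank_hi <- if (rng[2L] < nrow(sco)) sco$start[rng[2L] + 1L] else
      seg_hi + 2000L
    near <- (rep_rows$end > flank_lo & rep_rows$start < seg_lo) |
      (rep_rows$end > seg_hi & rep_rows$start < flank_hi)
    if (any(near)) {
      r <- rep_rows[near, , drop = FALSE][1L, ]
      mediating <- list(name = r$gene, length = r$end - r$start)
    }
  }
  list(size = size, left_label = left_label, right_label = right_label,
       mediating_repeat = mediating)
}
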