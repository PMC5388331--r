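# Parsimony mapping of binary inversion characters on a phylogeny: Fitch
# counting with missing data, and a single-origin (synapomorphy) test based
# on a loss-forbidden reconstruction rooted in the ancestral (absent)
# state.

# Normalize a states input (named vector over tips) to integers 0/1/NA.
normalize_states <- function(states, tip_labels) {
  if (!is.null(names(states))) {
    states <- states[tip_labels]
  } else if (length(states) != length(tip_labels)) {
    stop("states must be named by tip label or match the number of tips",
         call. = FALSE)
  }
  s <- as.character(unlist(states))
  s[s %in% c("?", "NA", "")] <- NA
  out <- suppressWarnings(as.integer(s))
  bad <- !is.na(s) & (is.na(out) | !(out %in% c(0L, 1L)))
  if (any(bad)) {
    stop("states must be 0, 1 or ?", call. = FALSE)
  }
  out
}

# Resolve polytomies (warning) and check the tree is usable.
prepare_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) {
    warning("tree has polytomies; resolved arbitrarily (counts are upper bounds)",
            call. = FALSE)
    tree <- ape::multi2di(tree)
  }
  tree
}

#' Minimum state changes of a binary character by Fitch parsimony
#'
#' Missing states (`?`) are unconstrained at the tip (standard Fitch
#' extension). Polytomies are resolved arbitrarily with a warning.
#'
#' @param tree A rooted `phylo` tree.
#' @param states Binary states (0/1/`?`), named by tip label.
#' @return List with `changes` (minimum number of state changes),
#'   `downpass` (per-node Fitch state sets, coded 1 = \{0\}, 2 = \{1\},
#'   3 = \{0,1\}), and `tree` (the tree actually used).
#' @export
fitch_count <- function(tree, states) {
  tree <- prepare_tree(tree)
  s <- normalize_states(states, tree$tip.label)
  if (sum(!is.na(s)) < 1L) {
    stop("all states are missing", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  mask <- integer(n_node)
  mask[seq_len(n_tip)] <- ifelse(is.na(s), 3L, s + 1L)  # {0}->1, {1}->2
  changes <- 0L
  edge <- tree$edge
  # postorder over internal nodes
  po <- unique(edge[ape::postorder(tree), 1L])
  for (nd in po) {
    kids <- edge[edge[, 1L] == nd, 2L]
    m <- 3L
    inter <- Reduce(bitwAnd, mask[kids])
    if (inter != 0L) {
      m <- inter
    } else {
      m <- Reduce(bitwOr, mask[kids])
      changes <- changes + 1L
    }
    mask[nd] <- m
  }
  list(changes = changes, downpass = mask, tree = tree)
}

# Sankoff dynamic programming for a binary character with an arbitrary
# 2x2 transition cost matrix (rows = parent state 0/1, cols = child state).
# Returns the per-state cost vector at the root.
sankoff_root_costs <- function(tree, s, cost) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  INF <- 1e9
  c0 <- rep(0, n_node); c1 <- rep(0, n_node)
  c0[seq_len(n_tip)] <- ifelse(!is.na(s) & s == 1L, INF, 0)
  c1[seq_len(n_tip)] <- ifelse(!is.na(s) & s == 0L, INF, 0)
  edge <- tree$edge
  po <- unique(edge[ape::postorder(tree), 1L])
  for (nd in po) {
    kids <- edge[edge[, 1L] == nd, 2L]
    acc0 <- 0; acc1 <- 0
    for (k in kids) {
      acc0 <- acc0 + min(c0[k] + cost[1L, 1L], c1[k] + cost[1L, 2L])
      acc1 <- acc1 + min(c0[k] + cost[2L, 1L], c1[k] + cost[2L, 2L])
    }
    c0[nd] <- acc0; c1[nd] <- acc1
  }
  root <- n_tip + 1L
  c(`0` = c0[root], `1` = c1[root])
}

# tips descended from an internal node
node_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    kids <- edge[edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  sort(out)
}

#' Test whether a binary character is a clean synapomorphy on a tree
#'
#' A character has a single origin when some minimal reconstruction places
#' exactly one 0-to-1 gain and no loss; this is evaluated with a
#' loss-forbidden parsimony reconstruction rooted in the ancestral (0)
#' state, whose optimum counts the number of independent gains. When
#' 0-state taxa nest inside the positives' clade the test fails and the
#' conflicting taxa are listed.
#'
#' @param tree A rooted `phylo` tree.
#' @param matrix Data frame of states: rows named by (or a `taxon` column
#'   matching) tip labels, one column per character, values 0/1/`?`.
#' @param character Character (column) name to assess.
#' @return A `MappingReport` entry: list with `character`, `min_changes`
#'   (Fitch), `n_gains` (loss-forbidden minimum), `single_origin`,
#'   `low_information` (TRUE when no 0-state taxon contrasts the clade),
#'   `clade` (tip labels of the supported clade when `single_origin`),
#'   `conflicting_taxa`.
#' @export
assess_synapomorphy <- function(tree, matrix, character) {
  tree <- prepare_tree(tree)
  if (!is.null(matrix$taxon)) {
    rownames(matrix) <- matrix$taxon
  }
  if (!character %in% colnames(matrix)) {
    stop("character '", character, "' not in matrix", call. = FALSE)
  }
  states <- stats::setNames(matrix[[character]], rownames(matrix))
  s <- normalize_states(states, tree$tip.label)
  fc <- fitch_count(tree, stats::setNames(s, tree$tip.label))
  n_tip <- length(tree$tip.label)
  positives <- which(!is.na(s) & s == 1L)
  negatives <- which(!is.na(s) & s == 0L)

  if (length(positives) == 0L) {
    return(structure(list(character = character, min_changes = fc$changes,
                          n_gains = 0L, single_origin = FALSE,
                          low_information = TRUE, clade = character(0),
                          conflicting_taxa = character(0)),
                     class = "MappingReport"))
  }
  low_info <- length(negatives) == 0L || length(positives) == 1L
  if (length(negatives) == 0L) {
    # every informative taxon carries the state: a single gain below the
    # root is consistent but untestable
    return(structure(list(character = character, min_changes = fc$changes,
                          n_gains = 1L, single_origin = TRUE,
                          low_information = TRUE,
                          clade = tree$tip.label,
                          conflicting_taxa = character(0)),
                     class = "MappingReport"))
  }
  # loss-forbidden reconstruction, root forced to the ancestral state 0
  INF <- 1e9
  cost <- base::matrix(c(0, 1, INF, 0), nrow = 2L, byrow = TRUE)
  rc <- sankoff_root_costs(fc$tree, s, cost)
  n_gains <- as.integer(round(rc[["0"]]))
  single_origin <- n_gains == 1L

  mrca <- if (length(positives) > 1L) {
    ape::getMRCA(fc$tree, positives)
  } else {
    positives
  }
  clade_tips <- tree$tip.label[node_descendants(fc$tree, mrca)]
  conflicting <- intersect(clade_tips, tree$tip.label[negatives])
  structure(list(character = character, min_changes = fc$changes,
                 n_gains = n_gains, single_origin = single_origin,
                 low_information = low_info,
                 clade = if (single_origin) clade_tips else character(0),
                 conflicting_taxa = if (single_origin) character(0) else
                   conflicting),
            class = "MappingReport")
}

#' @export
print.MappingReport <- function(x, ...) {
  cat(sprintf("Character '%s': %d change(s), %d gain(s); single origin: %s%s\n",
              x$character, x$min_changes, x$n_gains,
              if (x$single_origin) "yes" else "no",
              if (x$low_information) " (low information)" else ""))
  if (length(x$clade) > 0L) {
    cat("  supported clade:", paste(x$clade, collapse = ", "), "\n")
  }
  if (length(x$conflicting_taxa) > 0L) {
    cat("  conflicting taxa:", paste(x$conflicting_taxa, collapse = ", "),
        "\n")
  }
  invisible(x)
}
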