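# Independent brute-force oracles. These deliberately avoid the package's
# production code paths: plain-R dynamic programming, sliding-window scans
# and exhaustive enumeration at tiny problem sizes.

# Affine-gap global alignment score (Gotoh): gap of length L costs
# open + L * extend (penalties negative). Returns the optimal score only.
oracle_align_score <- function(q, r, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  rv <- strsplit(r, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(rv)
  NEG <- -1e9
  gap_cost <- function(L) gap_open + L * gap_extend
  # M: q[i] aligned to r[j]; X: gap in r (insertion in q); Y: gap in q
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_cost(i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_cost(j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qv[i] == rv[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_extend,
                               X[i, j + 1L] + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_extend,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Longest reverse-complement match of a linear sequence against itself with
# disjoint copies, by longest-common-substring DP between S and revcomp(S).
# Returns the maximal length (0 when none).
oracle_longest_rc_match <- function(s) {
  n <- nchar(s)
  a <- strsplit(s, "", fixed = TRUE)[[1]]
  b <- strsplit(revcomp(s), "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(n)
  for (j in seq_len(n)) {
    cur <- integer(n)
    eq <- a == b[j]
    cur[1L] <- as.integer(eq[1L])
    if (n > 1L) cur[2L:n] <- ifelse(eq[2L:n], prev[1L:(n - 1L)] + 1L, 0L)
    for (i in which(cur > best)) {
      len <- cur[i]
      # copy in S: [i-len, i); in revcomp coords ends at j -> S interval
      # [n-j, n-j+len). Require disjoint copies.
      a1 <- i - len; a2 <- i
      b1 <- n - j; b2 <- n - j + len
      if (a2 <= b1 || b2 <= a1) best <- len
    }
    prev <- cur
  }
  best
}

# Sliding-window primer scan on a circular sequence, character by
# character; mirrors the documented annealing model.
oracle_primer_scan <- function(sequence, primer, max_mismatch = 2L,
                               three_prime_exact = 3L) {
  L <- nchar(sequence)
  k <- nchar(primer)
  dbl <- strsplit(paste0(sequence, substr(sequence, 1L, k - 1L)), "",
                  fixed = TRUE)[[1]]
  scan <- function(pat, exact_head) {
    pv <- strsplit(pat, "", fixed = TRUE)[[1]]
    hits <- integer(0)
    for (p in 0:(L - 1L)) {
      w <- dbl[(p + 1L):(p + k)]
      mm <- sum(w != pv)
      if (mm > max_mismatch) next
      idx <- if (exact_head) seq_len(three_prime_exact) else
        (k - three_prime_exact + 1L):k
      if (any(w[idx] != pv[idx])) next
      hits <- c(hits, p)
    }
    hits
  }
  list(plus = scan(primer, FALSE), minus = scan(revcomp(primer), TRUE))
}

# Exhaustive minimum-change count for a binary character on a rooted binary
# tree: enumerate all internal-node labelings; missing tips cost 0.
oracle_fitch_enum <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  s <- suppressWarnings(as.integer(states[tree$tip.label]))
  edge <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  # columns indexed by internal node id - n_tip
  cost <- numeric(nrow(combos))
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; chl <- edge[e, 2L]
    pv <- combos[, par - n_tip]
    if (chl <= n_tip) {
      if (is.na(s[chl])) next
      cost <- cost + (pv != s[chl])
    } else {
      cost <- cost + (pv != combos[, chl - n_tip])
    }
  }
  as.integer(min(cost))
}

# Independent distance map over all signed permutations of n markers:
# level-by-level expansion from the identity (reversal moves are
# involutions, so distance is symmetric).
oracle_reversal_distances <- function(n) {
  all_rev <- function(v) {
    out <- list()
    for (i in seq_len(n)) {
      for (j in i:n) {
        w <- v
        w[i:j] <- -rev(w[i:j])
        out[[length(out) + 1L]] <- w
      }
    }
    out
  }
  dist <- new.env(hash = TRUE)
  id <- seq_len(n)
  dist[[paste(id, collapse = ",")]] <- 0L
  frontier <- list(id)
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- list()
    for (v in frontier) {
      for (w in all_rev(v)) {
        key <- paste(w, collapse = ",")
        if (is.null(dist[[key]])) {
          dist[[key]] <- d
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
  }
  dist
}
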