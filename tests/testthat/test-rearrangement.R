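# Signed gene-order permutations, collinear blocks, reversal distances and
# inversion-history inference.

test_that("the reference maps to the identity permutation", {
  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  p <- shared_gene_order(ref, ref)
  expect_identical(p$perm, seq_along(p$markers))
})

test_that("one applied inversion produces one signed reversed run", {
  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  inv <- preset_inversions("mini")
  one <- apply_inversion(ref, inv$INV24)$record
  p <- shared_gene_order(one, ref)$perm
  n <- length(p)
  changed <- which(p != seq_len(n))
  expect_gt(length(changed), 0L)
  i <- min(changed); j <- max(changed)
  expect_identical(p[i:j], -rev(seq.int(i, j)))
  expect_identical(p[setdiff(seq_len(n), i:j)],
                   setdiff(seq_len(n), i:j))
})

test_that("a missing marker raises a marker-set error naming it", {
  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  expect_error(shared_gene_order(panel$Maackia_fauriei, ref,
                                 marker_set = c("rbcL", "ghostGene")),
               "ghostGene")
})

test_that("LCB decomposition matches hand-enumerated toys", {
  # two identical permutations -> one block
  a <- signed_perm(1:6, "a"); b <- signed_perm(1:6, "b")
  expect_length(lcb_decomposition(list(a, b)), 1L)

  # identity vs one interior inversion -> 3 blocks
  c_ <- signed_perm(c(1, -4, -3, -2, 5, 6), "c")
  blocks <- lcb_decomposition(list(a, c_))
  expect_length(blocks, 3L)
  expect_equal(lapply(blocks, function(x) x$ref_range),
               list(c(1L, 1L), c(2L, 4L), c(5L, 6L)))
  orient_c <- vapply(blocks, function(x)
    x$per_taxon$orient[x$per_taxon$taxon == "c"], character(1))
  expect_equal(orient_c, c("+", "-", "+"))

  # an inversion touching an end -> 2 blocks
  d <- signed_perm(c(-3, -2, -1, 4, 5, 6), "d")
  expect_length(lcb_decomposition(list(a, d)), 2L)

  expect_error(lcb_decomposition(list(a)), "at least 2")
  expect_error(lcb_decomposition(list(a, signed_perm(1:5))), "marker sets")
})

test_that("the 4-genome panel decomposes into seven collinear blocks", {
  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  perms <- lapply(panel, shared_gene_order, reference = ref)
  blocks <- lcb_decomposition(perms)
  expect_length(blocks, 7L)
  # blocks tile every permutation exactly
  for (p in perms) {
    covered <- sort(unlist(lapply(blocks, function(b)
      seq.int(b$ref_range[1], b$ref_range[2]))))
    expect_identical(covered, seq_along(p$perm))
  }
})

test_that("reversal_distance_bfs matches a hand-checked set and the oracle map", {
  expect_equal(reversal_distance_bfs(c(1, 2, 3)), 0L)
  expect_equal(reversal_distance_bfs(c(-3, -2, -1)), 1L)
  # (+2,+1) needs three signed reversals: flip the pair, then each sign
  expect_equal(reversal_distance_bfs(c(2, 1)), 3L)
  expect_error(reversal_distance_bfs(seq_len(12)), "too many")

  # all signed permutations of 3 markers against an independent
  # distance-from-identity expansion
  dmap <- oracle_reversal_distances(3L)
  perms3 <- expand.grid(rep(list(c(-3:-1, 1:3)), 3))
  for (r in seq_len(nrow(perms3))) {
    v <- as.integer(perms3[r, ])
    if (length(unique(abs(v))) != 3L) next
    key <- paste(v, collapse = ",")
    expect_equal(reversal_distance_bfs(v), dmap[[key]], info = key)
  }
})

test_that("inference recovers single and nested inversion histories", {
  one <- signed_perm(c(1, 2, 3, -9, -8, -7, -6, -5, -4, 10))
  h <- infer_inversion_events(one)
  expect_equal(h$status, "OK")
  expect_length(h$events, 1L)
  expect_equal(h$events[[1]]$positions, c(4L, 9L))

  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  pm <- shared_gene_order(panel$Maackia_fauriei, ref)
  hm <- infer_inversion_events(pm, panel$Maackia_fauriei)
  expect_equal(hm$status, "OK")
  expect_length(hm$events, 3L)
  # outermost first: event sizes decrease
  sizes <- vapply(hm$events, function(e) e$size, numeric(1))
  expect_true(all(diff(sizes) < 0))
  # replay reproduces the observed permutation
  expect_identical(replay_events(hm$events, length(pm$perm)), pm$perm)
})

test_that("a transposition-like permutation is flagged by the greedy path", {
  p <- signed_perm(c(1, 3, 2))
  flagged <- infer_inversion_events(p, fallback = "none")
  expect_true(flagged$status %in% c("UNRESOLVED", "NON_MINIMAL"))
  exact <- infer_inversion_events(p, fallback = "exact")
  expect_equal(exact$status, "OK")
  expect_equal(exact$method, "exact_bfs")
  expect_length(exact$events, reversal_distance_bfs(c(1, 3, 2)))
})

test_that("inferred counts equal BFS distance on random seeded histories", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:10, 1L)
    k <- sample(0:3, 1L)
    hist <- random_signed_history(n, k)
    po <- signed_perm(hist$perm)
    h <- infer_inversion_events(po)
    d <- reversal_distance_bfs(hist$perm)
    expect_lte(d, k)
    expect_equal(length(h$events), d, info = paste(i, "n", n, "k", k))
    expect_identical(replay_events(h$events, n), hist$perm, info = i)
  }
})

test_that("breakpoints localize to the expected flanking loci", {
  panel <- mini_align_panel()
  ref <- panel$Tamarindus_indica
  pm <- shared_gene_order(panel$Maackia_fauriei, ref)
  hm <- infer_inversion_events(pm, panel$Maackia_fauriei)

  ev24 <- hm$events[[3]]
  expect_match(paste(ev24$left_label, ev24$right_label), "trnC-GCA")
  expect_match(paste(ev24$left_label, ev24$right_label), "trnF-GAA")

  ev36 <- hm$events[[2]]
  expect_false(is.null(ev36$mediating_repeat))
  expect_equal(ev36$mediating_repeat$length, 29L)

  # a segment touching the linearization origin is labelled ORIGIN
  ev <- structure(list(order = 1L, positions = c(1L, 2L),
                       markers = c("trnH-GUG", "psbA")),
                  class = "InversionEvent")
  loc <- localize_breakpoints(ev, ref)
  expect_equal(loc$left_label, "ORIGIN")
})
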