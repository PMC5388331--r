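# Fitch parsimony counting and the single-origin (synapomorphy) test.

test_that("fitch_count handles constant, clean and missing characters", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  all1 <- stats::setNames(c(1, 1, 1, 1), c("a", "b", "c", "d"))
  expect_equal(fitch_count(tr, all1)$changes, 0L)
  clean <- stats::setNames(c(1, 1, 0, 0), c("a", "b", "c", "d"))
  expect_equal(fitch_count(tr, clean)$changes, 1L)
  conflicted <- stats::setNames(c(1, 0, 1, 0), c("a", "b", "c", "d"))
  expect_equal(fitch_count(tr, conflicted)$changes, 2L)
  with_missing <- stats::setNames(c(1, NA, 0, NA), c("a", "b", "c", "d"))
  expect_equal(fitch_count(tr, with_missing)$changes, 1L)
  expect_error(fitch_count(tr, stats::setNames(rep(NA, 4), letters[1:4])),
               "missing")
})

test_that("the nine 24-kb-positive taxa map with a single change", {
  tree <- load_tree(packaged_tree_path("main"))
  cfg <- screen_panel_config()
  states <- stats::setNames(as.integer(cfg$inv24), cfg$taxon)
  expect_equal(fitch_count(tree, states)$changes, 1L)
  states36 <- stats::setNames(as.integer(cfg$inv36), cfg$taxon)
  expect_equal(fitch_count(tree, states36)$changes, 1L)
})

test_that("fitch counts equal exhaustive enumeration on random trees", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:12, 1L)
    tr <- random_tree(n)
    s <- sample(c(0L, 1L, NA), n, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    if (all(is.na(s))) s[1] <- 1L
    states <- stats::setNames(s, tr$tip.label)
    expect_equal(fitch_count(tr, states)$changes,
                 oracle_fitch_enum(tr, states), info = i)
  }
})

test_that("fitch counts are invariant under rerooting", {
  set.seed(62)
  tr <- random_tree(10L)
  states <- stats::setNames(sample(c(0L, 1L), 10L, replace = TRUE),
                            tr$tip.label)
  base <- fitch_count(tr, states)$changes
  for (k in 1:10) {
    out <- sample(tr$tip.label, 1L)
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    expect_equal(fitch_count(rr, states)$changes, base, info = out)
  }
})

test_that("polytomies are resolved with a warning", {
  tr <- ape::read.tree(text = "(a,b,c,d);")
  states <- stats::setNames(c(1, 1, 0, 0), letters[1:4])
  expect_warning(fc <- fitch_count(tr, states), "polytomies")
  expect_gte(fc$changes, 1L)
})

test_that("a monophyletic character is a single-origin synapomorphy", {
  tree <- load_tree(packaged_tree_path("main"))
  cfg <- screen_panel_config()
  m <- data.frame(taxon = cfg$taxon,
                  INV24 = as.character(as.integer(cfg$inv24)),
                  INV36 = as.character(as.integer(cfg$inv36)),
                  stringsAsFactors = FALSE)
  r <- assess_synapomorphy(tree, m, "INV24")
  expect_true(r$single_origin)
  expect_equal(r$min_changes, 1L)
  expect_setequal(r$clade, cfg$taxon[cfg$inv24])
  expect_length(r$clade, 9L)
})

test_that("negative taxa nested inside the clade break single origin", {
  tree <- load_tree(packaged_tree_path("its_alt"))
  cfg <- screen_panel_config()
  m <- data.frame(taxon = cfg$taxon,
                  INV24 = as.character(as.integer(cfg$inv24)),
                  stringsAsFactors = FALSE)
  r <- assess_synapomorphy(tree, m, "INV24")
  expect_false(r$single_origin)
  expect_gte(r$n_gains, 2L)
  expect_setequal(r$conflicting_taxa,
                  c("Bolusanthus_speciosus", "Dicraeopetalum_mahafaliense"))
})

test_that("a constructed counterexample on the main tree needs two changes", {
  tree <- load_tree(packaged_tree_path("main"))
  cfg <- screen_panel_config()
  states <- as.integer(cfg$inv24)
  # add one positive far outside the clade: two independent gains
  states[cfg$taxon == "Cladrastis_wilsonii"] <- 1L
  m <- data.frame(taxon = cfg$taxon, INV24 = as.character(states),
                  stringsAsFactors = FALSE)
  r <- assess_synapomorphy(tree, m, "INV24")
  expect_false(r$single_origin)
  expect_equal(r$min_changes, 2L)
})

test_that("single-informative-taxon characters are flagged low information", {
  tree <- load_tree(packaged_tree_path("main"))
  cfg <- screen_panel_config()
  states <- rep("?", nrow(cfg))
  states[cfg$taxon == "Maackia_fauriei"] <- "1"
  m <- data.frame(taxon = cfg$taxon, X = states, stringsAsFactors = FALSE)
  r <- assess_synapomorphy(tree, m, "X")
  expect_true(r$single_origin)
  expect_true(r$low_information)
})
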