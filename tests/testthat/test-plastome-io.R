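# GenBank / FASTA+table / Newick I/O and the circular-coordinate
# conventions.

test_that("a minimal GenBank fixture parses with 0-based half-open coordinates", {
  gb <- c(
    "LOCUS       toy              60 bp    DNA     circular     UNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(4..9,16..21)",
    "                     /gene=\"gA\"",
    "     tRNA            complement(31..40)",
    "                     /gene=\"tB\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(rep("acgtacgtac", 6)[1:6], collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- load_plastome(path, "genbank")
  expect_equal(nchar(rec$sequence), 60L)
  expect_true(rec$circular)
  expect_equal(length(unique(rec$features$feature_id)), 2L)
  cds <- rec$features[rec$features$gene == "gA", ]
  # GenBank 4..9 is 0-based half-open [3, 9)
  expect_equal(cds$start, c(3L, 15L))
  expect_equal(cds$end, c(9L, 21L))
  expect_equal(cds$part, c(1L, 2L))
  trna <- rec$features[rec$features$gene == "tB", ]
  expect_equal(trna$strand, -1L)
  expect_equal(c(trna$start, trna$end), c(30L, 40L))
})

test_that("malformed GenBank input raises informative parse errors", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS x 10 bp", "FEATURES",
               "     CDS             4..x9", "ORIGIN", "        1 acgtacgtac",
               "//"), path)
  expect_error(load_plastome(path, "genbank"), "parse error")
  writeLines(c("no locus here"), path)
  expect_error(load_plastome(path, "genbank"), "LOCUS")
  expect_error(load_plastome(file.path(tempdir(), "absent.gb"), "genbank"),
               "not found")
})

test_that("unknown feature keys are dropped with a warning on load", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy              20 bp    DNA     circular     UNA",
    "FEATURES             Location/Qualifiers",
    "     promoter        2..5",
    "                     /gene=\"p\"",
    "     CDS             7..12",
    "                     /gene=\"g\"",
    "ORIGIN",
    "        1 acgtacgtac acgtacgtac",
    "//"), path)
  expect_warning(rec <- load_plastome(path, "genbank"), "promoter")
  expect_equal(unique(rec$features$gene), "g")
})

test_that("save/load round-trips both formats, including wrapped features", {
  rec <- mini_genome()
  for (fmt in c("genbank", "fasta+table")) {
    path <- withr::local_tempfile()
    save_plastome(rec, path, fmt)
    expect_true(records_equal(rec, load_plastome(path, fmt)), info = fmt)
  }
  # rotate so features straddle the origin: split into ordered parts
  rot <- rotate_record(rec, nchar(rec$sequence) - 500L)
  wrapped <- rot$features[rot$features$start == 0L & rot$features$part > 1L, ]
  path <- withr::local_tempfile()
  save_plastome(rot, path, "genbank")
  expect_true(records_equal(rot, load_plastome(path, "genbank")))
})

test_that("round-trip is the identity on randomly generated records", {
  set.seed(404)
  for (i in 1:40) {
    n <- sample(60:300, 1L)
    seqs <- random_seq(n, gc = runif(1, 0.2, 0.6))
    n_feat <- sample(0:4, 1L)
    ft <- NULL
    if (n_feat > 0L) {
      starts <- sort(sample(0:(n - 12L), n_feat))
      ft <- data.frame(gene = paste0("g", seq_len(n_feat)),
                       kind = sample(c("CDS", "tRNA", "rRNA"), n_feat,
                                     replace = TRUE),
                       strand = sample(c(-1L, 1L), n_feat, replace = TRUE),
                       start = starts, end = starts + sample(6:10, n_feat,
                                                             replace = TRUE))
    }
    rec <- toy_record(seqs, ft, id = paste0("r", i))
    for (fmt in c("genbank", "fasta+table")) {
      path <- withr::local_tempfile()
      save_plastome(rec, path, fmt)
      expect_true(records_equal(rec, load_plastome(path, fmt)),
                  info = paste(i, fmt))
    }
  }
})

test_that("empty feature list writes valid FASTA with no table rows", {
  rec <- toy_record("ACGTACGTACGT")
  path <- withr::local_tempfile(fileext = ".fa")
  save_plastome(rec, path, "fasta+table")
  rec2 <- load_plastome(path, "fasta+table")
  expect_equal(nrow(rec2$features), 0L)
  expect_equal(rec2$sequence, rec$sequence)
})

test_that("sequences with ambiguity codes other than N are rejected", {
  expect_error(plastome_record("x", "ACGTRY"), "outside")
  expect_silent(plastome_record("x", "ACGTN"))
})

test_that("load_tree validates Newick input", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,B);", path)
  tr <- load_tree(path)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))

  main <- load_tree(packaged_tree_path("main"))
  expect_equal(length(main$tip.label), 16L)
  expect_setequal(main$tip.label, screen_panel_config()$taxon)

  writeLines("(A,(B,A));", path)
  expect_error(load_tree(path), "duplicate")
  writeLines("((A,B;", path)
  expect_error(load_tree(path))
})
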