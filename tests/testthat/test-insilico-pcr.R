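# Primer-site finding, amplicon prediction and the dual-assay screen.

test_that("a planted exact site is found once with zero mismatches", {
  set.seed(51)
  primer <- "ACGTTGCAACGGTCCATAGG"
  s <- paste0(random_seq(400), primer, random_seq(400))
  hits <- find_primer_sites(s, primer)
  plus <- hits[hits$strand == 1L, ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$pos, 400L)
  expect_equal(plus$mismatches, 0L)
})

test_that("a site spanning the circular origin is found once, not twice", {
  set.seed(52)
  primer <- "GGATCCATTGCGCAATGGTT"
  s <- paste0(substr(primer, 11, 20), random_seq(500), substr(primer, 1, 10))
  hits <- find_primer_sites(s, primer)
  plus <- hits[hits$strand == 1L, ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$pos, nchar(s) - 10L)
})

test_that("site finding equals the brute-force sliding-window oracle", {
  set.seed(53)
  s <- random_seq(4000, gc = 0.4)
  for (i in 1:60) {
    primer <- if (i %% 3 == 0) {
      # near-match of a real substring: exercises the mismatch paths
      p0 <- circ_substr(s, i * 37, i * 37 + 20L)
      v <- strsplit(p0, "", fixed = TRUE)[[1]]
      pos <- sample(20, sample(0:3, 1L))
      v[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      paste(v, collapse = "")
    } else {
      random_seq(20)
    }
    got <- find_primer_sites(s, primer, max_mismatch = 2L,
                             three_prime_exact = 3L)
    want <- oracle_primer_scan(s, primer, max_mismatch = 2L,
                               three_prime_exact = 3L)
    expect_identical(got$pos[got$strand == 1L], want$plus, info = i)
    expect_identical(got$pos[got$strand == -1L], want$minus, info = i)
  }
})

test_that("convergent planted sites give one amplicon of the planted length", {
  set.seed(54)
  f <- "ACGGATTCAACGGTCCATAG"
  r <- "TTGCCGTAAGCGGATCAACT"
  insert <- random_seq(800 - nchar(f) - nchar(r))
  s <- paste0(random_seq(300), f, insert, revcomp(r), random_seq(300))
  pair <- primer_pair("toy", f, r)
  amp <- predict_amplicons(s, pair, max_len = 3000)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 800L)

  # divergent (back-to-back) orientation: only the long way around the
  # circle, and only under max_len
  s2 <- paste0(random_seq(300), revcomp(r), random_seq(100), f,
               random_seq(300))
  amp2 <- predict_amplicons(s2, pair, max_len = 500)
  expect_equal(nrow(amp2), 0L)
  amp3 <- predict_amplicons(s2, pair, max_len = nchar(s2))
  expect_equal(nrow(amp3), 1L)
  expect_equal(amp3$length, nchar(s2) - 100L)
})

test_that("assay calls are correct across the inversion states", {
  panel <- mini_align_panel()
  assays <- default_assays()
  want <- list(
    Tamarindus_indica = c(INV36 = "ABSENT", INV24 = "ABSENT"),
    Arachis_hypogaea = c(INV36 = "ABSENT", INV24 = "ABSENT"),
    Lupinus_luteus = c(INV36 = "PRESENT", INV24 = "ABSENT"),
    Maackia_fauriei = c(INV36 = "PRESENT", INV24 = "PRESENT"))
  for (tx in names(want)) {
    for (inv in c("INV36", "INV24")) {
      expect_equal(screen_inversion(panel[[tx]], assays[[inv]])$call,
                   unname(want[[tx]][inv]), info = paste(tx, inv))
    }
  }
})

test_that("orientation soundness: inverting a segment swaps the diagnostic pair", {
  panel <- mini_align_panel()
  inv <- preset_inversions("mini")
  assays <- default_assays()
  base <- panel$Lupinus_luteus          # 50+36 applied, 24 absent
  flipped <- apply_inversion(base, inv$INV24)$record
  expect_equal(screen_inversion(base, assays$INV24)$call, "ABSENT")
  expect_equal(screen_inversion(flipped, assays$INV24)$call, "PRESENT")
  # details: the absence pair loses its amplicon, the presence pair gains one
  a0 <- screen_inversion(base, assays$INV24)
  a1 <- screen_inversion(flipped, assays$INV24)
  expect_gt(nrow(a0$absence_amplicons), 0L)
  expect_equal(nrow(a0$presence_amplicons), 0L)
  expect_equal(nrow(a1$absence_amplicons), 0L)
  expect_gt(nrow(a1$presence_amplicons), 0L)
})

test_that("screen calls are invariant under genome rotation", {
  panel <- mini_align_panel()
  assays <- default_assays()
  rec <- panel$Maackia_fauriei
  for (shift in c(977L, 9781L)) {
    rot <- rotate_record(rec, shift)
    expect_equal(screen_inversion(rot, assays$INV24)$call, "PRESENT")
    expect_equal(screen_inversion(rot, assays$INV36)$call, "PRESENT")
  }
})

test_that("a genome without primer sites is AMBIGUOUS", {
  set.seed(55)
  bare <- toy_record(random_seq(6000))
  assays <- default_assays()
  expect_equal(screen_inversion(bare, assays$INV24)$call, "AMBIGUOUS")
})

test_that("run_panel_screen produces the call matrix and tallies", {
  panel <- mini_screen_panel()
  res <- run_panel_screen(panel, default_assays(),
                          metadata = screen_panel_config())
  cfg <- screen_panel_config()
  expect_equal(res$calls$INV24,
               ifelse(cfg$inv24[match(res$calls$taxon, cfg$taxon)],
                      "PRESENT", "ABSENT"))
  expect_equal(res$calls$INV36,
               ifelse(cfg$inv36[match(res$calls$taxon, cfg$taxon)],
                      "PRESENT", "ABSENT"))
  expect_equal(res$tallies$INV24$n_present_genera, 8L)
  expect_equal(res$tallies$INV36$n_present_tribes, 5L)

  empty <- run_panel_screen(panel[1:2], list())
  expect_equal(names(empty$calls), "taxon")

  # AMBIGUOUS taxa are excluded from tallies with a warning
  panel2 <- panel[1:3]
  panel2$weird <- toy_record(random_seq(6000), id = "weird")
  md <- rbind(cfg[1:3, c("taxon", "genus", "tribe")],
              data.frame(taxon = "weird", genus = "Weird", tribe = "None"))
  w <- capture_warnings(res2 <- run_panel_screen(panel2, default_assays(),
                                                 metadata = md))
  expect_true(any(grepl("AMBIGUOUS", w)))
  expect_false("Weird" %in% res2$tallies$INV24$present_genera)
})

test_that("primer pair validation enforces the documented invariants", {
  expect_error(primer_pair("x", "ACGTACGTAC", "ACGTACGTACGTACG"), "15")
  expect_error(primer_pair("x", "ACGTNACGTACGTACG", "ACGTACGTACGTACG"), "N")
  p <- primer_pair("ok", "ACGTACGTACGTACG", "TGCATGCATGCATGC")
  expect_error(assay_definition("inv", p, p), "distinct")
})
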