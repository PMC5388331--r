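# Pairwise alignment and the four-way gene-status classification.

test_that("global_align handles identity and simple indels", {
  a <- global_align("ACGTACGTACGTACGT", "ACGTACGTACGTACGT")
  expect_equal(nrow(a$indels), 0L)
  expect_equal(a$coverage, 1.0)
  expect_equal(a$score, 2 * 16)

  ref <- "ACGTACGTACGTACGTACGT"
  qry <- paste0(substr(ref, 1, 10), "TTTT", substr(ref, 11, 20))
  a2 <- global_align(qry, ref)
  expect_equal(nrow(a2$indels), 1L)
  expect_equal(a2$indels$type, "insertion")
  expect_equal(a2$indels$length, 4L)
  expect_equal(a2$indels$ref_pos, 10L)

  a3 <- global_align(substr(ref, 1, 12), ref)
  expect_equal(sum(a3$indels$length[a3$indels$type == "deletion"]), 8L)
  expect_lt(a3$coverage, 1.0)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment scores equal the brute-force affine DP oracle", {
  set.seed(31)
  for (i in 1:120) {
    n1 <- sample(5:60, 1L)
    q <- random_seq(n1, gc = runif(1, 0.25, 0.6))
    r <- if (runif(1) < 0.5) {
      random_seq(sample(5:60, 1L), gc = 0.5)
    } else {
      # mutated copy: closer to the biological use-case
      v <- strsplit(q, "", fixed = TRUE)[[1]]
      k <- sample(0:3, 1L)
      if (k > 0L) {
        pos <- sample(length(v), k)
        v[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      }
      paste(v, collapse = "")
    }
    got <- global_align(q, r)$score
    want <- oracle_align_score(q, r)
    expect_equal(got, want, info = paste(i, q, r))
  }
})

test_that("the decision procedure covers all four categories with evidence", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")

  expect_equal(classify_locus(ref, ref)$category, "INTACT")
  expect_equal(classify_locus(NULL, ref)$category, "DELETED")

  fs <- classify_locus(
    extract_locus(mutate_gene(rec, "rps16",
                              mutation_spec("FRAMESHIFT_INSERTION",
                                            motif = "AAAC", exon = 2L)),
                  "rps16"), ref)
  expect_equal(fs$category, "PUTATIVE_PSEUDOGENE")
  expect_true(any(grepl("not divisible by 3", fs$evidence)))
  expect_true(any(grepl("internal stop", fs$evidence)))

  tr <- classify_locus(
    extract_locus(mutate_gene(rec, "rps16",
                              mutation_spec("EXON_TRUNCATION", exon = 2L,
                                            keep = 30L)), "rps16"), ref)
  expect_equal(tr$category, "TRUNCATED")
  expect_true(any(grepl("coverage", tr$evidence)))

  st <- classify_locus(
    extract_locus(mutate_gene(rec, "rps16",
                              mutation_spec("START_CODON_MUTATION")),
                  "rps16"), ref)
  expect_equal(st$category, "PUTATIVE_PSEUDOGENE")
  expect_true(any(grepl("start codon", st$evidence)))

  sl <- classify_locus(
    extract_locus(mutate_gene(rec, "rps16",
                              mutation_spec("STOP_CODON_MUTATION")),
                  "rps16"), ref)
  expect_equal(sl$category, "PUTATIVE_PSEUDOGENE")
  expect_true(any(grepl("stop codon lost", sl$evidence)))
})

test_that("classification is total and evidence is non-empty off INTACT", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")
  muts <- list(
    mutation_spec("FRAMESHIFT_DELETION", exon = 2L, len = 2L),
    mutation_spec("EXON_TRUNCATION", exon = 2L, keep = 40L),
    mutation_spec("WHOLE_GENE_DELETION"),
    mutation_spec("INTRON_DELETION", len = 200L))
  for (k in seq_along(muts)) {
    q <- extract_locus(mutate_gene(rec, "rps16", muts[[k]], seed = k),
                       "rps16")
    rep <- classify_locus(q, ref)
    expect_true(rep$category %in% c("INTACT", "PUTATIVE_PSEUDOGENE",
                                    "TRUNCATED", "DELETED"))
    if (rep$category != "INTACT") expect_gt(length(rep$evidence), 0L)
  }
  expect_error(classify_locus(ref, ref, truncation_threshold = 1.2),
               "truncation_threshold")
})

test_that("truncation takes precedence over pseudogene evidence", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")
  # both truncated and frameshifted: category must be TRUNCATED
  m <- mutate_gene(rec, "rps16", mutation_spec("EXON_TRUNCATION", exon = 2L,
                                               keep = 31L))
  rep <- classify_locus(extract_locus(m, "rps16"), ref)
  expect_equal(rep$category, "TRUNCATED")
})

test_that("intron damage alone does not drive the category", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")
  m <- mutate_gene(rec, "rps16", mutation_spec("INTRON_DELETION", len = 200L))
  rep <- classify_locus(extract_locus(m, "rps16"), ref)
  expect_equal(rep$category, "INTACT")
  expect_true(any(grepl("intron", rep$evidence)))
})

test_that("planted-truth recovery holds on seeded mutants of every class", {
  rec <- mini_genome()
  ref <- extract_locus(rec, "rps16")
  classes <- c("INTACT", "PUTATIVE_PSEUDOGENE", "TRUNCATED", "DELETED")
  n_per <- 15L
  set.seed(32)
  for (cl in classes) {
    for (k in seq_len(n_per)) {
      m <- switch(cl,
        INTACT = rec,
        PUTATIVE_PSEUDOGENE = {
          kind <- sample(c("FRAMESHIFT_INSERTION", "FRAMESHIFT_DELETION",
                           "START_CODON_MUTATION", "STOP_CODON_MUTATION"), 1)
          spec <- switch(kind,
            FRAMESHIFT_INSERTION = mutation_spec(kind, motif = strrep("A",
              sample(c(1L, 2L, 4L), 1L)), exon = 2L,
              at = sample(40:180, 1L)),
            FRAMESHIFT_DELETION = mutation_spec(kind, exon = 2L,
              len = sample(c(1L, 2L, 4L), 1L), at = sample(40:180, 1L)),
            mutation_spec(kind))
          mutate_gene(rec, "rps16", spec, seed = k)
        },
        TRUNCATED = mutate_gene(rec, "rps16",
                                mutation_spec("EXON_TRUNCATION", exon = 2L,
                                              keep = sample(10:80, 1L)),
                                seed = k),
        DELETED = mutate_gene(rec, "rps16",
                              mutation_spec("WHOLE_GENE_DELETION"), seed = k))
      got <- classify_locus(extract_locus(m, "rps16"), ref)$category
      expect_equal(got, cl, info = paste(cl, k))
    }
  }
})

test_that("survey_gene tallies a mixed panel correctly", {
  rec <- mini_genome()
  panel <- list(
    intact1 = rec,
    pseudo1 = mutate_gene(rec, "rps16",
                          mutation_spec("FRAMESHIFT_INSERTION",
                                        motif = "AAAC", exon = 2L)),
    trunc1 = mutate_gene(rec, "rps16",
                         mutation_spec("EXON_TRUNCATION", exon = 2L,
                                       keep = 30L)),
    del1 = mutate_gene(rec, "rps16", mutation_spec("WHOLE_GENE_DELETION")))
  sv <- survey_gene(panel, "rps16", rec)
  expect_equal(unname(sv$tally),
               c(1L, 1L, 1L, 1L))
  expect_equal(sv$table$category,
               c("INTACT", "PUTATIVE_PSEUDOGENE", "TRUNCATED", "DELETED"))

  all_intact <- survey_gene(stats::setNames(rep(list(rec), 5),
                                            paste0("t", 1:5)),
                            "rps16", rec)
  expect_equal(unname(all_intact$tally[["INTACT"]]), 5L)
})
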