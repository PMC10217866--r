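test_that("motif files parse with case folding, comments and tab ids", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "tgccgc", "hex2\tCGCGCA"), f)
  ms <- read_motifs(f)
  expect_equal(ms$word, c("TGCCGC", "CGCGCA"))
  expect_equal(ms$id[2], "hex2")
  expect_false(attr(ms, "complemented"))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("TGCXGC", bad)
  expect_error(read_motifs(bad), class = "icrscan_alphabet_error",
               regexp = "line 1")
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TGCCGC", "tgccgc"), dup)
  expect_error(read_motifs(dup), class = "icrscan_format_error",
               regexp = "duplicate")
})

test_that("complement expansion closes the set and dedupes palindromes", {
  ms <- add_complements(motif_set("TGCCGC"))
  expect_setequal(ms$word, c("TGCCGC", "GCGGCA"))
  expect_true(attr(ms, "complemented"))
  expect_error(add_complements(ms), class = "icrscan_state_error")

  pal <- add_complements(motif_set("ACGCGT"))
  expect_equal(nrow(pal), 1L)

  set.seed(3)
  for (i in 1:10) {
    words <- unique(vapply(rep(6, 4), rand_word, character(1)))
    out <- add_complements(motif_set(words))
    expect_lte(nrow(out), 2L * length(words))
    expect_setequal(out$word, reverse_complement(out$word))
  }
})

test_that("overlap generation matches the brute-force placement oracle", {
  got <- overlap_motifs(motif_set("TGCCGC"),
                        motif_set("CGCGCG", origin = "morpheme"),
                        min_overlap = 3)
  expect_equal(got$word, "TGCCGCGCG")
  # full self-overlap returns the word itself (word keeps >= 2 CpGs)
  self <- overlap_motifs(motif_set("TGCCGCG"),
                         motif_set("TGCCGCG", origin = "morpheme"),
                         min_overlap = 7)
  expect_equal(self$word, "TGCCGCG")
  # letter-incompatible words produce nothing
  none <- overlap_motifs(motif_set("TGCCGC"),
                         motif_set("AAAAAA", origin = "morpheme"),
                         min_overlap = 1)
  expect_equal(nrow(none), 0L)

  set.seed(41)
  for (i in 1:40) {
    z <- rand_word(sample(4:8, 1))
    m <- rand_word(sample(4:8, 1))
    mo <- sample(1:4, 1)
    got <- overlap_motifs(motif_set(z), motif_set(m, origin = "morpheme"),
                          min_overlap = mo)
    expect_identical(sort(got$word), brute_overlaps(z, m, mo),
                     info = paste(z, m, mo))
  }
})

test_that("every overlap word embeds its source and carries >= 2 CpGs", {
  set.seed(17)
  zfbs <- motif_set("TGCCGC")
  for (i in 1:20) {
    m <- rand_word(6)
    ov <- overlap_motifs(zfbs, motif_set(m, origin = "morpheme"))
    if (nrow(ov) == 0L) next
    expect_true(all(grepl("TGCCGC", ov$word, fixed = TRUE) |
                      grepl(m, ov$word, fixed = TRUE)))
    rep <- validate_overlaps(ov)
    expect_gte(rep$min_cpg, 2L)
    expect_false(any(rep$report$flagged))
  }
  # expansion of generated overlaps stays closed under reverse complement
  ov <- overlap_motifs(default_zfbs(), default_morphemes())
  ex <- add_complements(ov)
  expect_setequal(ex$word, reverse_complement(ex$word))
})

test_that("validate_overlaps flags CpG-poor overlap words and handles empties", {
  ms <- motif_set("TGCCGC", origin = "overlap")
  rep <- validate_overlaps(ms)
  expect_equal(rep$report$cpg_count, 1L)
  expect_true(rep$report$flagged)
  empty <- overlap_motifs(motif_set("TGCCGC"),
                          motif_set("AAAAAA", origin = "morpheme"))
  erep <- validate_overlaps(empty)
  expect_equal(nrow(erep$report), 0L)
  expect_true(is.na(erep$min_cpg))
})
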