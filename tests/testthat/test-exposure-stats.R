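# Expected values in this file were enumerated by hand from the
# toy_joined() table in helper-fixtures.R.

test_that("complexity_summary counts complex words among annotated band words", {
  j <- toy_joined()
  # band b1: 6 annotated words present, 4 complex (unlock, lockable,
  # snowman, teacher) -> 67%
  cs <- complexity_summary(j, "b1")
  expect_equal(cs$n_annotated, 6)
  expect_equal(cs$n_complex, 4)
  expect_equal(cs$pct_complex, 67)
  expect_error(complexity_summary(j, "b9"), "unknown band")
})

test_that("complexity is 0% on an all-monomorphemic corpus", {
  specs <- data.frame(
    form = "ness", position = "suffix", n_attach = 1L,
    bound_frac = 0, p_alter = 1, stringsAsFactors = FALSE
  )
  cfg <- synth_config(
    n_free_stems = 20, n_bound_stems = 0, affix_specs = specs,
    pseudo_rate = 0, n_books = 5, tokens_total = 200, seed = 4
  )
  corp <- generate_lexicon(cfg)
  keep <- corp$labels == "simple"
  entries <- corp$entries[corp$entries$word %in% names(corp$labels)[keep], ]
  attr(entries, "bands") <- "all"
  attr(entries, "books_per_band") <- 5
  gold <- corp$gold[corp$gold$word %in% entries$word, ]
  j <- cross_reference(entries, gold)
  expect_equal(complexity_summary(j, "all")$pct_complex, 0)
})

test_that("frequency_band_table splits word classes at the thresholds", {
  j <- toy_joined()
  # b1 multimorphemic freqs {5,1,300,60}: <=5 -> 2/4, >=50 -> 2/4,
  # >=100 -> 1/4; monomorphemic freqs {10,7}: all between 5 and 50
  tab <- frequency_band_table(j, "b1", at_most = 5, at_least = c(50, 100))
  multi <- tab[tab$word_class == "multimorphemic", ]
  mono <- tab[tab$word_class == "monomorphemic", ]
  expect_equal(multi$n_distinct, 4)
  expect_equal(multi$pct_le_5, 50)
  expect_equal(multi$pct_ge_50, 50)
  expect_equal(multi$pct_ge_100, 25)
  expect_equal(mono$n_distinct, 2)
  expect_equal(mono$pct_le_5, 0)
  expect_equal(mono$pct_ge_50, 0)
  # word-class partition covers the annotated band words
  expect_equal(sum(tab$n_distinct), complexity_summary(j, "b1")$n_annotated)
})

test_that("all words at frequency 1 fall in the <=5 bin entirely", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "word\tfreq_b1\tbooks_b1",
    "aa\t1\t1", "bb\t1\t1", "cc\t1\t1"
  ), tsv)
  entries <- read_band_lexicon(tsv)
  morph <- build_morph_records(
    c("aa", "bb", "cc"),
    list(
      parse_segmentation("root:a suffix:a", "plain"),
      parse_segmentation("root:bb", "plain"),
      parse_segmentation("root:cc", "plain")
    )
  )
  tab <- frequency_band_table(
    cross_reference(entries, morph), "b1",
    at_most = 5, at_least = 100
  )
  expect_equal(tab$pct_le_5, c(100, 100))
  expect_equal(tab$pct_ge_100, c(0, 0))
})

test_that("dispersion_table applies thresholds to book counts", {
  j <- toy_joined()
  # b1 multimorphemic books {2,1,250,120}: >=100 -> 2/4, >=200 -> 1/4
  tab <- dispersion_table(j, "b1", at_least = c(100, 200))
  multi <- tab[tab$word_class == "multimorphemic", ]
  expect_equal(multi$pct_ge_100, 50)
  expect_equal(multi$pct_ge_200, 25)
  mono <- tab[tab$word_class == "monomorphemic", ]
  expect_equal(mono$pct_ge_100, 0)

  # every word in one book -> nothing reaches >=100 books
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tfreq_b1\tbooks_b1", "aa\t4\t1", "bb\t2\t1"), tsv)
  entries <- read_band_lexicon(tsv)
  morph <- build_morph_records(
    c("aa", "bb"),
    list(
      parse_segmentation("root:a suffix:a", "plain"),
      parse_segmentation("root:bb", "plain")
    )
  )
  tab1 <- dispersion_table(
    cross_reference(entries, morph), "b1",
    at_least = 100
  )
  expect_equal(tab1$pct_ge_100, c(0, 0))
})

test_that("structure_distribution partitions complex words by affix layout", {
  j <- toy_joined()
  # b1 complex words: unlock (prefix only), lockable + teacher (suffix
  # only), snowman (unaffixed compound)
  sd <- structure_distribution(j, "b1")
  expect_equal(sd$n_complex, 4)
  cats <- sd$categories
  expect_equal(cats$n[cats$category == "prefix_only"], 1)
  expect_equal(cats$n[cats$category == "suffix_only"], 2)
  expect_equal(cats$n[cats$category == "prefix_and_suffix"], 0)
  expect_equal(cats$n[cats$category == "unaffixed_compound"], 1)
  # the four categories partition the complex words
  expect_equal(sum(cats$n), sd$n_complex)
  expect_equal(unname(sd$derived["pct_suffixed"]), 50)
  expect_equal(unname(sd$derived["pct_prefixed"]), 25)
  expect_equal(unname(sd$derived["pct_suffixed_without_prefix"]), 100)
  expect_equal(unname(sd$derived["pct_prefixed_with_suffix"]), 0)
})

test_that("a compounds-only corpus is 100% unaffixed compounds", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tfreq_b1\tbooks_b1", "snowman\t4\t1", "postbox\t2\t1"), tsv)
  entries <- read_band_lexicon(tsv)
  morph <- build_morph_records(
    c("snowman", "postbox"),
    list(
      parse_segmentation("root:snow root:man", "plain"),
      parse_segmentation("root:post root:box", "plain")
    )
  )
  sd <- structure_distribution(cross_reference(entries, morph), "b1")
  cats <- sd$categories
  expect_equal(cats$pct[cats$category == "unaffixed_compound"], 100)
})

test_that("reference_gap_summary counts missing words and their complex share", {
  j <- toy_joined()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tall", "corner\t10", "lock\t10", "teacher\t10"), tsv)
  ref <- read_reference_lexicon(tsv, channel = "ALL")
  # b1 missing: unlock, lockable, snowman (all complex); frequent
  # (>=50) complex missing: snowman only, of 4 complex words -> 25%
  gap <- reference_gap_summary(j, ref, "b1", freq_cutoff = 50)
  expect_equal(gap$n_missing, 3)
  expect_equal(gap$n_missing_complex, 3)
  expect_equal(gap$pct_missing_complex, 100)
  expect_equal(gap$n_missing_frequent_complex, 1)
  expect_equal(gap$pct_missing_frequent_complex, 25)
  expect_true(gap$n_missing_complex <= gap$n_missing)

  # a reference containing every corpus word leaves no gap
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tall", paste0(j$words$word, "\t5")), tsv2)
  full_ref <- read_reference_lexicon(tsv2, channel = "ALL")
  expect_equal(reference_gap_summary(j, full_ref, "b1")$n_missing, 0)
})

test_that("band_novelty_summary finds words new to the later band", {
  j <- toy_joined()
  # only relock is in b2 but not b1, and it is complex
  nv <- band_novelty_summary(j, "b2", "b1")
  expect_equal(nv$n_novel, 1)
  expect_equal(nv$n_novel_complex, 1)
  expect_equal(nv$pct_novel_complex, 100)
  expect_error(band_novelty_summary(j, "b1", "b1"), "distinct")
})

test_that("statistics are invariant to row order of the joined table", {
  j <- toy_joined()
  j2 <- j
  set.seed(1)
  perm <- sample(nrow(j2$words))
  j2$words <- j2$words[perm, , drop = FALSE]
  expect_equal(complexity_summary(j, "b1"), complexity_summary(j2, "b1"))
  expect_equal(
    frequency_band_table(j, "b1"), frequency_band_table(j2, "b1")
  )
  expect_equal(dispersion_table(j, "b1"), dispersion_table(j2, "b1"))
  expect_equal(
    structure_distribution(j, "b1")$categories,
    structure_distribution(j2, "b1")$categories
  )
})
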