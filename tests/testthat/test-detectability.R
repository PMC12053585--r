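att <- fixture_attested()
affs <- fixture_affixes()

test_that("candidate_stems positions patterns and applies reversal rules in order", {
  cs <- candidate_stems("teacher", "er", "suffix")
  expect_equal(cs$stem[1], "teach")
  expect_equal(cs$rule[1], "identity")
  # doubled consonant: identity candidate first, un-doubling second
  expect_equal(
    candidate_stems("sunny", "y", "suffix"),
    data.frame(stem = c("sunn", "sun"), rule = c("identity", "undouble"))
  )
  # prefix side: pattern match only, identity rule only
  expect_equal(
    candidate_stems("under", "un", "prefix"),
    data.frame(stem = "der", rule = "identity")
  )
  # pattern absent at required position -> no candidates
  expect_equal(nrow(candidate_stems("teacher", "un", "prefix")), 0)
  expect_equal(nrow(candidate_stems("sustain", "sub", "prefix")), 0)
  # i -> y restoration before a consonant-initial suffix
  cs <- candidate_stems("happiness", "ness", "suffix")
  expect_true(any(cs$stem == "happy" & cs$rule == "y_restore"))
})

test_that("strip_once detects the first attested candidate in rule-priority order", {
  out <- strip_once("teacher", "er", "suffix", att)
  expect_true(out$detected)
  expect_equal(out$stem, "teach")
  expect_equal(out$rule, "identity")

  expect_false(strip_once("infer", "er", "suffix", att)$detected)

  out <- strip_once("corner", "er", "suffix", att)
  expect_true(out$detected)
  expect_equal(out$stem, "corn")

  out <- strip_once("adorable", "able", "suffix", att)
  expect_true(out$detected)
  expect_equal(out$rule, "e_restore")
  expect_equal(out$stem, "adore")

  out <- strip_once("sunny", "y", "suffix", att)
  expect_true(out$detected)
  expect_equal(out$rule, "undouble")
  expect_equal(out$stem, "sun")
})

test_that("segment_recursive strips recursively, suffixes first, longest pattern first", {
  s <- segment_recursive("soundlessly", affs, att)
  expect_equal(s$suffixes, c("ly", "less"))
  expect_equal(s$stem, "sound")
  expect_equal(nrow(s$steps), 2)

  s <- segment_recursive("corner", affs, att)
  expect_equal(s$suffixes, "er")
  expect_equal(s$stem, "corn")

  # unsegmentable word is its own terminal stem
  s <- segment_recursive("sound", affs, att)
  expect_equal(length(s$prefixes) + length(s$suffixes), 0)
  expect_equal(s$stem, "sound")

  # "-ly" is tried before "-y": no spurious "-y" parse of quickly
  s <- segment_recursive("quickly", affs, att)
  expect_equal(s$suffixes, "ly")
  expect_equal(s$stem, "quick")

  # max_depth truncates recursion
  s1 <- segment_recursive("soundlessly", affs, att, max_depth = 1)
  expect_equal(s1$suffixes, "ly")
  expect_equal(s1$stem, "soundless")
})

test_that("every segmentation reconstructs its word under forward alteration", {
  for (w in att) {
    s <- segment_recursive(w, affs, att)
    expect_identical(reconstruct_segmentation(s), w)
  }
  # including alteration steps
  s <- segment_recursive("sunny", affs, att)
  expect_identical(reconstruct_segmentation(s), "sunny")
  s <- segment_recursive("adorable", affs, att)
  expect_identical(reconstruct_segmentation(s), "adorable")
  s <- segment_recursive("happiness", affs, att)
  expect_identical(reconstruct_segmentation(s), "happiness")
})

test_that("detect_affix_in_word answers reachability through recursion", {
  expect_true(detect_affix_in_word("soundlessly", "less", "suffix", affs, att))
  expect_true(detect_affix_in_word("soundlessly", "ly", "suffix", affs, att))
  expect_false(detect_affix_in_word("sustain", "sub", "prefix", affs, att))
  expect_false(detect_affix_in_word("teacher", "un", "prefix", affs, att))
  expect_true(detect_affix_in_word("quickly", "ly", "suffix", affs, att))
  # "quickl" is not attested, so -y is undetectable in quickly
  expect_false(detect_affix_in_word("quickly", "y", "suffix", affs, att))
})

test_that("classify_word distinguishes hits, misses, false alarms, not-applicable", {
  morph <- build_morph_records(
    c("teacher", "corner", "aaargh", "depend", "sustain", "quickly"),
    list(
      parse_segmentation("root:teach suffix:er", "plain"),
      parse_segmentation("root:corner", "plain"),
      parse_segmentation("root:aaargh", "plain"),
      parse_segmentation("prefix:de root:pend", "plain"),
      parse_segmentation("prefix:sub root:tain", "plain"),
      parse_segmentation("root:quick suffix:ly", "plain")
    )
  )
  cls <- function(w, a, p) {
    classify_word(w, morph_row(morph, w), a, p, affs, att)
  }
  expect_equal(cls("teacher", "er", "suffix"), "hit")
  expect_equal(cls("corner", "er", "suffix"), "false_alarm")
  expect_equal(cls("aaargh", "a", "prefix"), "false_alarm")
  expect_equal(cls("depend", "de", "prefix"), "miss")
  expect_equal(cls("sustain", "sub", "prefix"), "miss")
  # genuinely suffixed word is not in the suffix false-alarm pool
  expect_equal(cls("quickly", "y", "suffix"), "not_applicable")
  expect_equal(cls("teacher", "ly", "suffix"), "not_applicable")
})

test_that("brute-force oracle enumerates all valid complete segmentations", {
  or <- brute_force_oracle("soundlessly", affs, att)
  # contains the two-suffix parse ending at "sound"
  has_full <- any(vapply(or, function(s) {
    identical(s$steps$affix, c("ly", "less")) && s$terminal == "sound"
  }, logical(1)))
  expect_true(has_full)
  expect_true(oracle_detects(or, "less", "suffix"))
  expect_false(oracle_detects(or, "er", "suffix"))

  # no matching patterns -> single trivial parse
  or <- brute_force_oracle("sound", affs, att)
  expect_equal(length(or), 1)
  expect_equal(or[[1]]$terminal, "sound")
  expect_equal(nrow(or[[1]]$steps), 0)

  or <- brute_force_oracle("quickly", affs, att)
  expect_true(oracle_detects(or, "ly", "suffix"))
  expect_false(oracle_detects(or, "y", "suffix"))

  expect_error(
    brute_force_oracle(strrep("a", 26), affs, att),
    "25 characters"
  )
})

test_that("run_detectability satisfies the conservation identity and disjointness", {
  corp <- generate_lexicon(small_synth_config(seed = 5))
  joined <- cross_reference(corp$entries, corp$gold)
  tally <- run_detectability(joined, select_common_affixes(joined))
  expect_true(all(tally$n_hits + tally$n_misses == tally$n_genuine))
  for (i in seq_len(nrow(tally))) {
    h <- tally$hits[[i]]
    m <- tally$misses[[i]]
    f <- tally$false_alarm_words[[i]]
    expect_equal(length(intersect(h, m)), 0)
    expect_equal(length(intersect(h, f)), 0)
    expect_equal(length(intersect(m, f)), 0)
  }
  # false-alarm words are etymologically affix-free at the position
  gold <- corp$gold
  for (i in seq_len(nrow(tally))) {
    faw <- tally$false_alarm_words[[i]]
    n_at <- if (tally$position[i] == "prefix") {
      gold$n_prefixes[match(faw, gold$word)]
    } else {
      gold$n_suffixes[match(faw, gold$word)]
    }
    expect_true(all(n_at == 0))
  }
})

test_that("enlarging the attested set never removes detections (monotonicity)", {
  corp <- generate_lexicon(small_synth_config(seed = 9))
  joined <- cross_reference(corp$entries, corp$gold)
  common <- select_common_affixes(joined)
  base_att <- joined$words$word
  t_base <- run_detectability(joined, common, attested = base_att)
  set.seed(42)
  for (rep in 1:3) {
    extra <- replicate(25, paste(
      sample(letters, sample(3:8, 1), replace = TRUE),
      collapse = ""
    ))
    grown <- union(base_att, extra)
    t_grown <- run_detectability(joined, common, attested = grown)
    expect_true(all(t_grown$n_hits >= t_base$n_hits))
    expect_true(all(t_grown$n_false_alarms >= t_base$n_false_alarms))
    for (i in seq_len(nrow(t_base))) {
      expect_true(all(t_base$hits[[i]] %in% t_grown$hits[[i]]))
      expect_true(all(
        t_base$false_alarm_words[[i]] %in% t_grown$false_alarm_words[[i]]
      ))
    }
    base_att <- grown
    t_base <- t_grown
  }
})

test_that("detectability_summary derives identifiable counts and shares", {
  corp <- generate_lexicon(small_synth_config(seed = 5))
  joined <- cross_reference(corp$entries, corp$gold)
  tally <- run_detectability(joined, select_common_affixes(joined))
  s <- detectability_summary(tally)
  expect_equal(s$n_identifiable, s$n_hits + s$n_false_alarms)
  # percentages recomputed from their own counts match at integer rounding
  expect_equal(
    s$pct_false_alarm,
    round(100 * s$n_false_alarms / s$n_identifiable)
  )
  expect_equal(s$pct_detected, round(100 * s$n_hits / s$n_genuine))
})
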