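# Attested-word fixture holding every worked-example word: genuinely
# affixed words with their stems, pseudo-affixed words with their
# apparent stems, and unsegmentable controls.
fixture_attested <- function() {
  c(
    "teach", "teacher", "corn", "corner", "infer", "sun", "sunny",
    "adore", "adorable", "sound", "soundless", "soundlessly",
    "sustain", "aaargh", "aargh", "quick", "quickly", "depend",
    "lock", "unlock", "lockable", "snowman", "happy", "happiness"
  )
}

# Affix inventory covering the worked examples.
fixture_affixes <- function() {
  data.frame(
    form = c("ly", "less", "er", "y", "able", "ness", "un", "a", "de",
      "sub"),
    position = c(rep("suffix", 6), rep("prefix", 4)),
    stringsAsFactors = FALSE
  )
}

# One-row morph annotation accessor for classify_word().
morph_row <- function(morph, word) {
  morph[morph$word == word, , drop = FALSE]
}

# Hand-built two-band joined lexicon used by the exposure statistics
# tests; every expected value in those tests was enumerated by hand from
# this table.
toy_joined <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "word\tfreq_b1\tbooks_b1\tfreq_b2\tbooks_b2",
    "corner\t10\t3\t5\t2",
    "unlock\t5\t2\t0\t0",
    "lockable\t1\t1\t2\t1",
    "snowman\t300\t250\t1\t1",
    "teacher\t60\t120\t60\t50",
    "lock\t7\t4\t7\t3",
    "relock\t0\t0\t9\t2",
    "zzz\t2\t1\t0\t0"
  ), tsv)
  entries <- read_band_lexicon(tsv)
  unlink(tsv)
  seg <- c(
    corner = "root:corner",
    unlock = "prefix:un root:lock",
    lockable = "root:lock suffix:able",
    snowman = "root:snow root:man",
    teacher = "root:teach suffix:er",
    lock = "root:lock",
    relock = "prefix:re root:lock"
  )
  morph <- build_morph_records(
    names(seg),
    lapply(unname(seg), parse_segmentation, dialect = "plain")
  )
  cross_reference(entries, morph)
}

# Small, fast synthetic corpus for unit tests (the full study-condition
# defaults are exercised in the acceptance suite).
small_synth_config <- function(seed = 11, ...) {
  specs <- data.frame(
    form = c("ness", "able", "y", "un", "re"),
    position = c("suffix", "suffix", "suffix", "prefix", "prefix"),
    n_attach = c(40L, 32L, 24L, 32L, 24L),
    bound_frac = c(0.25, 0.25, 0.25, 0.5, 0.5),
    p_alter = 1,
    stringsAsFactors = FALSE
  )
  synth_config(
    n_free_stems = 300, n_bound_stems = 60, affix_specs = specs,
    pseudo_rate = 0.05, n_books = 50, tokens_total = 20000, seed = seed,
    ...
  )
}
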