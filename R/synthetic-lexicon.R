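#' Default affix specification table for the synthetic generator
#'
#' Six suffixes and three prefixes with exact attachment counts, the
#' fraction of attachments that use bound stems (0.3 for suffixes, 0.5
#' for prefixes, mirroring the detectability profile of real book
#' lexicons where roughly a third of suffixed and half of prefixed words
#' have bound stems), and the probability that a licensed orthographic
#' alteration is applied at word formation. The forms are chosen so that
#' no suffix pattern is a suffix of another and no prefix pattern is a
#' prefix of another, which keeps gold parses unambiguous.
#'
#' @return Data frame with columns `form`, `position`, `n_attach`,
#'   `bound_frac`, `p_alter`.
#' @export
synth_affix_specs <- function() {
  data.frame(
    form = c("ness", "able", "ish", "y", "ment", "ous", "un", "re", "over"),
    position = c(rep("suffix", 6), rep("prefix", 3)),
    n_attach = c(150L, 120L, 80L, 100L, 90L, 80L, 120L, 100L, 60L),
    bound_frac = c(rep(0.3, 6), rep(0.5, 3)),
    p_alter = rep(1, 9),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic lexicon generator
#'
#' The defaults define the study conditions: about 2,000 distinct words
#' built from 1,200 free and 250 bound stems, nine affixes, 5% injected
#' pseudo-affixed words, Zipfian token frequencies with exponent 1 (the
#' most common word about twice as frequent as the second), 400 books per
#' band and 200,000 tokens.
#'
#' @param n_free_stems,n_bound_stems Stem inventory sizes.
#' @param affix_specs Affix table, see [synth_affix_specs()].
#' @param pseudo_rate Fraction (of each affix's attachment count) of
#'   additional monomorphemic pseudo-affixed words, built as an attested
#'   word plus the affix string.
#' @param zipf_exponent Zipf exponent for token frequencies.
#' @param n_books Books per band.
#' @param tokens_total Target token total per band.
#' @param seed Integer seed; the whole corpus is deterministic given it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_free_stems = 1200, n_bound_stems = 250,
                         affix_specs = synth_affix_specs(),
                         pseudo_rate = 0.05, zipf_exponent = 1,
                         n_books = 400, tokens_total = 200000, seed = 1) {
  cfg <- list(
    n_free_stems = as.integer(n_free_stems),
    n_bound_stems = as.integer(n_bound_stems),
    affix_specs = affix_specs,
    pseudo_rate = pseudo_rate,
    zipf_exponent = zipf_exponent,
    n_books = as.integer(n_books),
    tokens_total = as.integer(tokens_total),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_free_stems > 0, cfg$n_bound_stems >= 0,
    cfg$pseudo_rate >= 0, cfg$pseudo_rate <= 1,
    cfg$zipf_exponent > 0, cfg$n_books >= 1, cfg$tokens_total > 0,
    is.data.frame(affix_specs),
    all(c("form", "position", "n_attach", "bound_frac", "p_alter")
    %in% names(affix_specs)),
    all(affix_specs$position %in% c("prefix", "suffix")),
    all(affix_specs$n_attach > 0),
    all(affix_specs$bound_frac >= 0 & affix_specs$bound_frac <= 1),
    all(affix_specs$p_alter >= 0 & affix_specs$p_alter <= 1)
  )
  n_bound_need <- round(affix_specs$bound_frac * affix_specs$n_attach)
  n_free_need <- affix_specs$n_attach - n_bound_need
  if (any(n_free_need > cfg$n_free_stems) ||
    any(n_bound_need > cfg$n_bound_stems)) {
    stop("affix attachment counts exceed the stem inventory", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Realize the surface spelling of an affixed word
#'
#' Forward direction of the orthographic alterations: prefixes
#' concatenate without alteration; before a suffix, a stem-final *y*
#' after a consonant becomes *i* (unless the suffix starts with *i*), a
#' silent final *e* is dropped before a vowel-initial suffix, and a final
#' consonant after a single vowel is doubled before a vowel-initial
#' suffix, each only when the corresponding flag is supplied.
#'
#' @param stem Stem spelling (non-empty).
#' @param affix Affix form.
#' @param position `"suffix"` or `"prefix"`.
#' @param alterations Character subset of
#'   `c("y_to_i", "e_drop", "doubling")`; flags for which alterations may
#'   apply when orthographically licensed.
#' @return Surface spelling.
#' @examples
#' realize_surface_form("sun", "y", "suffix", "doubling")
#' realize_surface_form("adore", "able", "suffix", "e_drop")
#' realize_surface_form("lock", "un", "prefix")
#' @export
realize_surface_form <- function(stem, affix,
                                 position = c("suffix", "prefix"),
                                 alterations = character()) {
  position <- match.arg(position)
  stopifnot(nzchar(stem), nzchar(affix))
  if (position == "prefix") {
    return(paste0(affix, stem))
  }
  vowel_initial <- is_vowel_initial(affix)
  s <- stem
  if ("y_to_i" %in% alterations && grepl("[^aeiou]y$", s) &&
    !startsWith(affix, "i")) {
    s <- paste0(drop_last(s), "i")
  } else if ("e_drop" %in% alterations && vowel_initial &&
    last_char(s) == "e") {
    s <- drop_last(s)
  } else if ("doubling" %in% alterations && vowel_initial &&
    grepl("[aeiou][^aeiouhwxy]$", s)) {
    s <- paste0(s, last_char(s))
  }
  paste0(s, affix)
}

# Pronounceable CVC(C) stem strings that avoid the affix-pattern
# boundaries of `specs`: no stem starts with a prefix pattern or ends
# with a suffix pattern, so a stem can never strip and every genuine or
# injected parse is recovered exactly once downstream.
make_stems <- function(n, specs, exclude = character()) {
  onsets <- c(
    "b", "br", "c", "cl", "d", "dr", "f", "fl", "g", "gr", "h",
    "j", "k", "l", "m", "n", "p", "pl", "pr", "s", "st", "t",
    "tr", "v", "w", "z"
  )
  vowels <- c("a", "e", "i", "o", "u")
  codas <- c(
    "b", "ck", "d", "g", "l", "m", "n", "p", "r", "t", "st",
    "nd", "mp", "ne", "de", "se", "ve", "te", "le"
  )
  prefixes <- specs$form[specs$position == "prefix"]
  suffixes <- specs$form[specs$position == "suffix"]
  ok <- function(w) {
    !any(startsWith(w, prefixes)) && !any(endsWith(w, suffixes)) &&
      !(w %in% exclude)
  }
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L * n) {
      stop("stem generation failed to find enough valid stems",
        call. = FALSE
      )
    }
    two_syll <- stats::runif(1) < 0.5
    w <- paste0(sample(onsets, 1), sample(vowels, 1))
    if (two_syll) w <- paste0(w, sample(onsets, 1), sample(vowels, 1))
    w <- paste0(w, sample(codas, 1))
    if (ok(w) && !(w %in% out)) out <- c(out, w)
  }
  out
}

units_root <- function(word) {
  data.frame(kind = "root", form = word, stringsAsFactors = FALSE)
}

units_affixed <- function(stem, affix, position) {
  if (position == "prefix") {
    data.frame(
      kind = c("prefix", "root"), form = c(affix, stem),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      kind = c("root", "suffix"), form = c(stem, affix),
      stringsAsFactors = FALSE
    )
  }
}

# Build the type inventory (words, gold annotations, labels, per-affix
# gold tallies) for one corpus. Assumes the RNG is already seeded.
synth_types <- function(config) {
  specs <- config$affix_specs
  free <- make_stems(config$n_free_stems, specs)
  bound <- make_stems(config$n_bound_stems, specs, exclude = free)

  words <- free
  units <- lapply(free, units_root)
  labels <- rep("simple", length(free))

  affix_rows <- list()
  alter_flags <- c("y_to_i", "e_drop", "doubling")
  for (i in seq_len(nrow(specs))) {
    form <- specs$form[i]
    pos <- specs$position[i]
    n_b <- round(specs$bound_frac[i] * specs$n_attach[i])
    n_f <- specs$n_attach[i] - n_b
    # Single-letter suffixes cannot restore a dropped silent -e (the
    # restored stem would be as long as the word, which the stripping
    # contract rejects), so keep e-final stems away from them.
    free_pool <- free
    if (pos == "suffix" && nchar(form) == 1) {
      free_pool <- free[!endsWith(free, "e")]
    }
    f_stems <- sample(free_pool, n_f)
    b_stems <- if (n_b > 0) sample(bound, n_b) else character(0)
    stems <- c(f_stems, b_stems)
    kinds <- c(rep("complex_free", n_f), rep("complex_bound", n_b))
    for (k in seq_along(stems)) {
      flags <- if (stats::runif(1) < specs$p_alter[i]) {
        alter_flags
      } else {
        character(0)
      }
      surf <- realize_surface_form(stems[k], form, pos, flags)
      words <- c(words, surf)
      units <- c(units, list(units_affixed(stems[k], form, pos)))
      labels <- c(labels, kinds[k])
    }
    n_p <- round(config$pseudo_rate * specs$n_attach[i])
    # carriers must differ from this affix's genuine stems, else the
    # pseudo surface would duplicate a genuine one
    carrier_pool <- setdiff(free, f_stems)
    carriers <- if (n_p > 0) sample(carrier_pool, n_p) else character(0)
    for (cr in carriers) {
      surf <- if (pos == "prefix") paste0(form, cr) else paste0(cr, form)
      words <- c(words, surf)
      units <- c(units, list(units_root(surf)))
      labels <- c(labels, paste0("pseudo(", form, ")"))
    }
    affix_rows[[i]] <- data.frame(
      form = form, position = pos, n_attach = specs$n_attach[i],
      n_free = n_f, n_bound = n_b, n_pseudo = n_p,
      stringsAsFactors = FALSE
    )
  }

  # Construction guards: entries must be unique, and no bound-stem
  # surface may strip (under the default rule set) to a string that is
  # itself an entry -- otherwise the exact-recovery properties would not
  # hold. Violations are vanishingly rare; regenerate the offender.
  rules <- default_spelling_rules()
  for (pass in 1:50) {
    dup <- duplicated(words)
    clash <- rep(FALSE, length(words))
    aset <- attested_set(words)
    bound_idx <- which(labels == "complex_bound")
    for (k in bound_idx) {
      u <- units[[k]]
      form <- u$form[u$kind != "root"]
      pos <- u$kind[u$kind != "root"]
      cands <- candidate_stems(words[k], form, pos, rules)
      if (any(vapply(cands$stem, is_attested, logical(1), aset))) {
        clash[k] <- TRUE
      }
    }
    bad <- which(dup | clash)
    if (length(bad) == 0) break
    if (pass == 50) {
      stop("could not build a collision-free synthetic corpus",
        call. = FALSE
      )
    }
    for (k in bad) {
      u <- units[[k]]
      if (all(u$kind == "root")) {
        if (startsWith(labels[k], "pseudo(")) {
          # duplicated pseudo word: rebuild from a fresh carrier
          form <- sub("^pseudo\\((.*)\\)$", "\\1", labels[k])
          pos <- specs$position[specs$form == form][1]
          repeat {
            cr <- sample(free, 1)
            surf <- if (pos == "prefix") {
              paste0(form, cr)
            } else {
              paste0(cr, form)
            }
            if (!surf %in% words[-k]) break
          }
          words[k] <- surf
          units[[k]] <- units_root(surf)
        } else {
          # duplicated simple word: replace with a fresh stem
          new <- make_stems(1, specs, exclude = c(words, free, bound))
          words[k] <- new
          units[[k]] <- units_root(new)
        }
        next
      }
      form <- u$form[u$kind != "root"]
      pos <- u$kind[u$kind != "root"]
      pool <- if (labels[k] == "complex_bound") bound else free
      repeat {
        stem <- sample(pool, 1)
        surf <- realize_surface_form(stem, form, pos,
          alterations = c("y_to_i", "e_drop", "doubling")
        )
        if (!surf %in% words[-k]) break
      }
      words[k] <- surf
      u$form[u$kind == "root"] <- stem
      units[[k]] <- u
    }
  }

  list(
    words = words, units = units, labels = labels,
    affix_gold = do.call(rbind, affix_rows),
    bound_stems = bound
  )
}

# Zipfian token frequencies over `n` types scaled to `tokens_total`.
zipf_frequencies <- function(n, exponent, tokens_total) {
  ranks <- sample.int(n) # random rank assignment over types
  p <- ranks^(-exponent)
  p <- p / sum(p)
  pmax(1L, as.integer(round(tokens_total * p)))
}

#' Assign token occurrences to books and count the dispersion
#'
#' Each token of each word is independently assigned to one of `n_books`
#' uniformly at random; a word's book count is the number of distinct
#' books that received at least one of its tokens.
#'
#' @param type_freqs Named integer vector, word -> token count. Words
#'   with zero tokens are excluded from the result.
#' @param n_books Number of books.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_lexicon()]).
#' @return Named integer vector, word -> number of books containing it.
#' @export
assign_book_dispersion <- function(type_freqs, n_books, seed = NULL) {
  stopifnot(n_books >= 1)
  if (!is.null(seed)) set.seed(seed)
  type_freqs <- type_freqs[type_freqs > 0]
  vapply(type_freqs, function(f) {
    length(unique(sample.int(n_books, f, replace = TRUE)))
  }, integer(1))
}

#' Generate a synthetic corpus with gold morphological tags
#'
#' Builds a lexicon with the statistical structure the analysis assumes:
#' free and bound stems, affixed words realized with orthographic
#' alterations, injected pseudo-affixed monomorphemic words, Zipfian
#' token frequencies and multinomial book dispersion. Attachment counts
#' are exact combinatorial draws, so per-affix recovery properties hold
#' exactly: with no bound stems the detectability hit rate is 1, with a
#' bound fraction *b* it is 1 - *b*, and recovered false alarms equal the
#' injected pseudo count.
#'
#' @param config A [synth_config()].
#' @param band Band identifier used for the frequency/dispersion columns.
#' @return A `synth_corpus` list: `entries` (a `band_lexicon`), `gold`
#'   (a `morph_annotations`), `labels` (named character: word -> one of
#'   `simple`, `complex_free`, `complex_bound`, `pseudo(<affix>)`),
#'   `affix_gold` (per-affix gold tallies) and `config`.
#' @export
generate_lexicon <- function(config, band = "all") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ty <- synth_types(config)
  n <- length(ty$words)
  freq <- zipf_frequencies(n, config$zipf_exponent, config$tokens_total)
  names(freq) <- ty$words
  books <- assign_book_dispersion(freq, config$n_books)

  entries <- data.frame(word = ty$words, stringsAsFactors = FALSE)
  entries[[freq_col(band)]] <- as.integer(freq)
  entries[[books_col(band)]] <- as.integer(books[ty$words])
  entries$total_freq <- as.integer(freq)
  entries <- new_band_lexicon(entries, band, config$n_books)

  structure(
    list(
      entries = entries,
      gold = build_morph_records(ty$words, ty$units),
      labels = stats::setNames(ty$labels, ty$words),
      affix_gold = ty$affix_gold,
      bound_stems = ty$bound_stems,
      config = config
    ),
    class = "synth_corpus"
  )
}

#' Generate a multi-band synthetic corpus over a linked type inventory
#'
#' One type inventory is generated, then each band draws its own
#' presence pattern (each type enters a band with probability
#' `presence_prob`), Zipfian frequencies and book dispersion. Types
#' absent from every band are forced into the last (most advanced) band
#' so each word occurs somewhere; bands therefore differ in which words
#' they contain, supporting the between-band novelty statistics.
#'
#' @param config A [synth_config()].
#' @param bands Character vector of band identifiers.
#' @param presence_prob Per-band inclusion probabilities (recycled).
#' @return A `synth_corpus` whose `entries` has one freq/books column
#'   pair per band.
#' @export
generate_multiband <- function(config, bands = c("7_9", "10_12", "13"),
                               presence_prob = c(0.7, 0.8, 0.9)) {
  stopifnot(inherits(config, "synth_config"), length(bands) >= 2)
  presence_prob <- rep_len(presence_prob, length(bands))
  set.seed(config$seed)
  ty <- synth_types(config)
  n <- length(ty$words)

  present <- matrix(FALSE, n, length(bands))
  for (j in seq_along(bands)) {
    present[, j] <- stats::runif(n) < presence_prob[j]
  }
  nowhere <- !apply(present, 1, any)
  present[nowhere, length(bands)] <- TRUE

  entries <- data.frame(word = ty$words, stringsAsFactors = FALSE)
  for (j in seq_along(bands)) {
    idx <- which(present[, j])
    freq <- integer(n)
    freq[idx] <- zipf_frequencies(
      length(idx), config$zipf_exponent,
      config$tokens_total
    )
    names(freq) <- ty$words
    books <- integer(n)
    bk <- assign_book_dispersion(freq[idx], config$n_books)
    books[idx] <- as.integer(bk)
    entries[[freq_col(bands[j])]] <- as.integer(freq)
    entries[[books_col(bands[j])]] <- books
  }
  entries$total_freq <- as.integer(
    rowSums(entries[freq_col(bands)])
  )
  entries <- new_band_lexicon(entries, bands, config$n_books)

  structure(
    list(
      entries = entries,
      gold = build_morph_records(ty$words, ty$units),
      labels = stats::setNames(ty$labels, ty$words),
      affix_gold = ty$affix_gold,
      bound_stems = ty$bound_stems,
      config = config
    ),
    class = "synth_corpus"
  )
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(
    "Synthetic corpus: ", nrow(x$entries), " words (",
    sum(x$labels == "simple"), " simple, ",
    sum(x$labels == "complex_free"), " complex/free, ",
    sum(x$labels == "complex_bound"), " complex/bound, ",
    sum(startsWith(x$labels, "pseudo")), " pseudo); seed ",
    x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Serialize a unit table in the plain segmentation dialect.
units_to_plain <- function(units) {
  paste(paste0(units$kind, ":", units$form), collapse = " ")
}

#' Write the gold annotation table of a synthetic corpus
#'
#' TSV with columns `word`, `label` and `segmentation` (plain dialect),
#' preceded by a comment line recording the generator seed.
#'
#' @param corpus A `synth_corpus`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gold_annotations <- function(corpus, path) {
  df <- data.frame(
    word = corpus$gold$word,
    label = unname(corpus$labels[corpus$gold$word]),
    segmentation = vapply(corpus$gold$units, units_to_plain, ""),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# seed: ", corpus$config$seed), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
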