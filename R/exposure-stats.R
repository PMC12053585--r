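# All statistics operate on the annotated subset of a joined lexicon
# (words with a morphological record), restricted to the words actually
# present in the requested band (band token frequency > 0).

pct <- function(n, d) {
  out <- rep(NA_integer_, length(n))
  ok <- rep_len(d > 0, length(n))
  dd <- rep_len(d, length(n))
  out[ok] <- as.integer(round(100 * n[ok] / dd[ok]))
  out
}

check_band <- function(joined, band) {
  if (!band %in% joined$bands) {
    stop("unknown band id: ", band, call. = FALSE)
  }
  invisible(band)
}

band_subset <- function(joined, band, annotated_only = TRUE) {
  check_band(joined, band)
  w <- joined$words
  keep <- w[[freq_col(band)]] > 0
  if (annotated_only) keep <- keep & w$annotated
  w[keep, , drop = FALSE]
}

#' Morphological complexity prevalence in one age band
#'
#' Counts, among the annotated words present in the band, how many are
#' morphologically complex (at least one affix, or at least two roots).
#'
#' @param joined A `joined_lexicon`.
#' @param band Band identifier.
#' @return Data frame with `band`, `n_annotated`, `n_complex`,
#'   `pct_complex` (whole percent).
#' @export
complexity_summary <- function(joined, band) {
  w <- band_subset(joined, band)
  if (nrow(w) == 0) {
    stop("no annotated words with nonzero frequency in band '", band, "'",
      call. = FALSE
    )
  }
  n <- nrow(w)
  nc <- sum(w$is_complex)
  data.frame(
    band = band, n_annotated = n, n_complex = nc,
    pct_complex = pct(nc, n), stringsAsFactors = FALSE
  )
}

band_class_table <- function(w, values, at_most, at_least) {
  classes <- list(
    multimorphemic = w$is_complex,
    monomorphemic = !w$is_complex
  )
  rows <- lapply(names(classes), function(cl) {
    v <- values[classes[[cl]]]
    row <- data.frame(
      word_class = cl, n_distinct = length(v),
      stringsAsFactors = FALSE
    )
    for (t in at_most) {
      row[[paste0("pct_le_", t)]] <- pct(sum(v <= t), length(v))
      row[[paste0("n_le_", t)]] <- sum(v <= t)
    }
    for (t in at_least) {
      row[[paste0("pct_ge_", t)]] <- pct(sum(v >= t), length(v))
      row[[paste0("n_ge_", t)]] <- sum(v >= t)
    }
    row
  })
  do.call(rbind, rows)
}

#' Token-frequency band table (multimorphemic vs monomorphemic)
#'
#' For each word class, the share of distinct words whose band token
#' frequency falls at or below / at or above the given thresholds
#' (defaults mirror the "encountered <= 5 times" / ">= 100 times" bands).
#'
#' @param joined A `joined_lexicon`.
#' @param band Band identifier.
#' @param at_most Upper thresholds (`<=`).
#' @param at_least Lower thresholds (`>=`).
#' @return Data frame, one row per word class, counts and whole-percent
#'   shares per threshold.
#' @export
frequency_band_table <- function(joined, band, at_most = 5,
                                 at_least = c(50, 100)) {
  stopifnot(length(at_most) + length(at_least) > 0)
  w <- band_subset(joined, band)
  band_class_table(w, w[[freq_col(band)]], at_most, at_least)
}

#' Book-dispersion band table (multimorphemic vs monomorphemic)
#'
#' As [frequency_band_table()], but thresholds apply to the number of
#' distinct books containing the word (of the 400 per band in the
#' emulated corpus; defaults mirror ">= 100 books" / ">= 200 books").
#'
#' @inheritParams frequency_band_table
#' @export
dispersion_table <- function(joined, band, at_most = integer(),
                             at_least = c(100, 200)) {
  stopifnot(length(at_most) + length(at_least) > 0)
  w <- band_subset(joined, band)
  band_class_table(w, w[[books_col(band)]], at_most, at_least)
}

#' Distribution of morphological structure types among complex words
#'
#' Partitions the band's complex words into suffix-only, prefix-only,
#' prefix+suffix and unaffixed-compound categories, and derives the
#' shares discussed alongside: the fraction of complex words containing
#' any suffix (resp. prefix), the fraction of suffixed words without a
#' prefix, and the fraction of prefixed words that also carry a suffix.
#'
#' @param joined A `joined_lexicon`.
#' @param band Band identifier.
#' @return List with `band`, `n_complex`, `categories` (data frame:
#'   category, n, pct) and `derived` (named whole-percent shares).
#' @export
structure_distribution <- function(joined, band) {
  w <- band_subset(joined, band)
  w <- w[w$is_complex, , drop = FALSE]
  if (nrow(w) == 0) {
    stop("no complex words in band '", band, "'", call. = FALSE)
  }
  has_pre <- w$n_prefixes >= 1
  has_suf <- w$n_suffixes >= 1
  compound <- !has_pre & !has_suf # complex via >= 2 roots only
  n <- nrow(w)
  cats <- data.frame(
    category = c(
      "suffix_only", "prefix_only", "prefix_and_suffix",
      "unaffixed_compound"
    ),
    n = c(
      sum(has_suf & !has_pre), sum(has_pre & !has_suf),
      sum(has_pre & has_suf), sum(compound)
    ),
    stringsAsFactors = FALSE
  )
  cats$pct <- pct(cats$n, n)
  list(
    band = band,
    n_complex = n,
    categories = cats,
    derived = c(
      pct_suffixed = pct(sum(has_suf), n),
      pct_prefixed = pct(sum(has_pre), n),
      pct_suffixed_without_prefix = pct(
        sum(has_suf & !has_pre),
        sum(has_suf)
      ),
      pct_prefixed_with_suffix = pct(
        sum(has_pre & has_suf),
        sum(has_pre)
      )
    )
  )
}

#' Words present in books but missing from a reference lexicon
#'
#' Membership is an exact test on normalized forms. Reports how many of
#' the band's annotated words are absent from the reference, how many of
#' those are complex, and how many complex words that are *frequent* in
#' the band (raw frequency at or above `freq_cutoff`) are missing, as a
#' share of all complex words in the band.
#'
#' @param joined A `joined_lexicon`.
#' @param reference A `reference_lexicon`.
#' @param band Band identifier.
#' @param freq_cutoff Raw band frequency defining "frequent" (default 50).
#' @return One-row data frame: `band`, `reference`, `n_missing`,
#'   `n_missing_complex`, `pct_missing_complex`,
#'   `n_missing_frequent_complex`, `pct_missing_frequent_complex`.
#' @export
reference_gap_summary <- function(joined, reference, band,
                                  freq_cutoff = 50) {
  stopifnot(inherits(reference, "reference_lexicon"))
  if (nrow(reference$entries) == 0) {
    stop("reference lexicon is empty", call. = FALSE)
  }
  w <- band_subset(joined, band)
  missing <- !(w$word %in% reference$entries$word)
  n_complex_band <- sum(w$is_complex)
  n_missing_complex <- sum(missing & w$is_complex)
  n_freq <- sum(missing & w$is_complex & w[[freq_col(band)]] >= freq_cutoff)
  data.frame(
    band = band, reference = reference$label,
    n_missing = sum(missing),
    n_missing_complex = n_missing_complex,
    pct_missing_complex = pct(n_missing_complex, sum(missing)),
    n_missing_frequent_complex = n_freq,
    pct_missing_frequent_complex = pct(n_freq, n_complex_band),
    stringsAsFactors = FALSE
  )
}

#' Novel words between two age bands
#'
#' Counts annotated words present (band frequency > 0) in `band_new` but
#' absent from `band_old`, and the complex share among them.
#'
#' @param joined A `joined_lexicon`.
#' @param band_new,band_old Distinct band identifiers.
#' @return One-row data frame: `band_new`, `band_old`, `n_novel`,
#'   `n_novel_complex`, `pct_novel_complex`.
#' @export
band_novelty_summary <- function(joined, band_new, band_old) {
  check_band(joined, band_new)
  check_band(joined, band_old)
  if (identical(band_new, band_old)) {
    stop("band ids must be distinct", call. = FALSE)
  }
  w <- joined$words
  novel <- w$annotated & w[[freq_col(band_new)]] > 0 &
    w[[freq_col(band_old)]] == 0
  n <- sum(novel)
  nc <- sum(novel & w$is_complex)
  data.frame(
    band_new = band_new, band_old = band_old,
    n_novel = n, n_novel_complex = nc,
    pct_novel_complex = pct(nc, n),
    stringsAsFactors = FALSE
  )
}
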