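# Per-word sets of distinct etymological affixes, by position, pulled
# from the annotation unit lists.
word_affixes <- function(units, position) {
  if (is.null(units)) {
    return(character(0))
  }
  unique(units$form[units$kind == position])
}

#' Tally per-affix type and token frequency from annotations
#'
#' For every etymological affix occurring in the joined lexicon and every
#' band: the type frequency (number of distinct words present in the band
#' that contain the affix) and the token frequency (summed band token
#' counts of those words). A word carrying k distinct affixes contributes
#' to k tallies; a word containing the same affix twice counts once.
#' Affix identity is the annotation source's canonical form, so allomorph
#' grouping follows the annotations, not the orthography.
#'
#' @param joined A `joined_lexicon`.
#' @return An `affix_tally` data frame, one row per (affix, position,
#'   band): `affix`, `position`, `band`, `type_freq`, `token_freq`.
#'   Rows are ordered by position, affix, band for determinism.
#' @export
tally_affix_usage <- function(joined) {
  ann <- joined$words[joined$words$annotated, , drop = FALSE]
  pairs <- list()
  for (pos in c("prefix", "suffix")) {
    affs <- lapply(ann$units, word_affixes, position = pos)
    n_per <- lengths(affs)
    if (sum(n_per) == 0) next
    pairs[[pos]] <- data.frame(
      word = rep(ann$word, n_per),
      row = rep(seq_len(nrow(ann)), n_per),
      affix = unlist(affs, use.names = FALSE),
      position = pos,
      stringsAsFactors = FALSE
    )
  }
  if (length(pairs) == 0) {
    out <- data.frame(
      affix = character(), position = character(), band = character(),
      type_freq = integer(), token_freq = integer(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("affix_tally", "data.frame")
    return(out)
  }
  pairs <- do.call(rbind, pairs)
  rows <- list()
  for (b in joined$bands) {
    f <- ann[[freq_col(b)]][pairs$row]
    present <- f > 0
    if (!any(present)) next
    key <- paste(pairs$position[present], pairs$affix[present], sep = "\r")
    kf <- factor(key, levels = sort(unique(key)))
    rows[[b]] <- data.frame(
      affix = sub("^[a-z]+\r", "", levels(kf)),
      position = sub("\r.*$", "", levels(kf)),
      band = b,
      type_freq = as.integer(table(kf)),
      token_freq = as.integer(rowsum(f[present], kf)[, 1]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$affix, out$band), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("affix_tally", "data.frame")
  out
}

#' Select the common-affix inventory by the 1% criterion
#'
#' An affix is *common* when it appears in at least `threshold` (default
#' 1%) of the band's affixed word types, computed separately for prefixes
#' (denominator: distinct prefixed words in the band) and suffixes
#' (distinct suffixed words). Membership requires meeting the threshold
#' in every band; affixes that reach it in some but not all bands are
#' recorded as excluded, with the failing bands. Ties at exactly the
#' threshold count as meeting it.
#'
#' @param joined A `joined_lexicon`.
#' @param threshold Commonness fraction (default 0.01).
#' @return A `common_affix_set`: list with `prefixes`, `suffixes` (forms
#'   meeting the criterion in all bands), `threshold`, `excluded` (data
#'   frame: affix, position, failing bands) and `candidates` (forms
#'   meeting it in at least one band, the pre-exclusion set).
#' @export
select_common_affixes <- function(joined, threshold = 0.01) {
  tally <- tally_affix_usage(joined)
  bands <- joined$bands
  denom <- matrix(0L, nrow = 2, ncol = length(bands),
    dimnames = list(c("prefix", "suffix"), bands)
  )
  ann <- joined$words[joined$words$annotated, , drop = FALSE]
  for (b in bands) {
    present <- ann[[freq_col(b)]] > 0
    for (pos in c("prefix", "suffix")) {
      n_at <- if (pos == "prefix") ann$n_prefixes else ann$n_suffixes
      denom[pos, b] <- sum(present & n_at >= 1)
    }
  }
  key <- unique(tally[c("affix", "position")])
  # a position only needs a nonzero denominator where it has candidates
  for (pos in unique(key$position)) {
    if (any(denom[pos, ] == 0)) {
      stop("zero ", pos, "ed words in at least one band", call. = FALSE)
    }
  }
  meets <- matrix(FALSE, nrow(key), length(bands),
    dimnames = list(NULL, bands)
  )
  for (i in seq_len(nrow(key))) {
    for (b in bands) {
      r <- tally$affix == key$affix[i] & tally$position == key$position[i] &
        tally$band == b
      tf <- if (any(r)) tally$type_freq[r] else 0L
      meets[i, b] <- tf >= threshold * denom[key$position[i], b]
    }
  }
  in_all <- apply(meets, 1, all)
  in_any <- apply(meets, 1, any)
  excluded <- key[in_any & !in_all, , drop = FALSE]
  excluded$failing_bands <- vapply(
    which(in_any & !in_all),
    function(i) paste(bands[!meets[i, ]], collapse = ","), ""
  )
  rownames(excluded) <- NULL
  structure(
    list(
      prefixes = sort(key$affix[in_all & key$position == "prefix"]),
      suffixes = sort(key$affix[in_all & key$position == "suffix"]),
      threshold = threshold,
      excluded = excluded,
      candidates = key[in_any, , drop = FALSE]
    ),
    class = "common_affix_set"
  )
}

#' @export
print.common_affix_set <- function(x, ...) {
  cat(
    "Common affix set (threshold ", 100 * x$threshold, "% of affixed ",
    "word types in every band):\n  prefixes (", length(x$prefixes),
    "): ", paste(x$prefixes, collapse = ", "), "\n  suffixes (",
    length(x$suffixes), "): ", paste(x$suffixes, collapse = ", "),
    "\n  excluded as inconsistent across bands: ",
    if (nrow(x$excluded)) paste(x$excluded$affix, collapse = ", ")
    else "none", "\n",
    sep = ""
  )
  invisible(x)
}

#' Book-dispersion profile of one affix in one band
#'
#' One value per distinct word containing the affix (etymologically) and
#' present in the band: the number of books containing that word; plus
#' the unweighted mean over words.
#'
#' @param affix Affix form.
#' @param joined A `joined_lexicon`.
#' @param band Band identifier.
#' @param position `"prefix"` or `"suffix"`.
#' @return List with `affix`, `position`, `band`, `words` (data frame:
#'   word, books) and `mean_books`.
#' @export
affix_book_dispersion <- function(affix, joined, band,
                                  position = c("suffix", "prefix")) {
  position <- match.arg(position)
  w <- band_subset(joined, band)
  has <- vapply(w$units, function(u) {
    affix %in% word_affixes(u, position)
  }, logical(1))
  if (!any(has)) {
    stop("affix '", affix, "' absent from band '", band, "'",
      call. = FALSE
    )
  }
  words <- data.frame(
    word = w$word[has], books = w[[books_col(band)]][has],
    stringsAsFactors = FALSE
  )
  words <- words[order(words$word), , drop = FALSE]
  rownames(words) <- NULL
  list(
    affix = affix, position = position, band = band,
    words = words, mean_books = mean(words$books)
  )
}
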