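#' Normalize a surface word
#'
#' Lowercases and trims surrounding whitespace. Internal apostrophes and
#' hyphens are preserved verbatim, so `"o'clock"` and `"twenty-one"` keep
#' their punctuation. Normalization is idempotent.
#'
#' @param raw Character vector of raw surface forms.
#' @return Character vector of normalized words.
#' @examples
#' normalize_word(c("Teacher ", "corner", "aaargh"))
#' @export
normalize_word <- function(raw) {
  if (!is.character(raw) || length(raw) == 0) {
    stop("`raw` must be a non-empty character vector", call. = FALSE)
  }
  out <- tolower(trimws(raw))
  if (any(!nzchar(out))) {
    stop("malformed record: word empty after normalization", call. = FALSE)
  }
  out
}

freq_col <- function(band) paste0("freq_", band)
books_col <- function(band) paste0("books_", band)

#' Bands of a band lexicon or joined lexicon
#' @param x A `band_lexicon` or `joined_lexicon` object.
#' @return Character vector of age-band identifiers.
#' @export
lexicon_bands <- function(x) {
  if (inherits(x, "joined_lexicon")) return(x$bands)
  attr(x, "bands")
}

new_band_lexicon <- function(df, bands, books_per_band) {
  rownames(df) <- NULL
  structure(df,
    bands = bands,
    books_per_band = books_per_band,
    class = c("band_lexicon", "data.frame")
  )
}

validate_band_lexicon <- function(df, bands, books_per_band) {
  for (b in bands) {
    f <- df[[freq_col(b)]]
    k <- df[[books_col(b)]]
    if (any(f < 0) || any(k < 0)) {
      stop("negative counts in band '", b, "'", call. = FALSE)
    }
    if (any(k > books_per_band)) {
      stop("book counts exceed books_per_band (", books_per_band,
        ") in band '", b, "'",
        call. = FALSE
      )
    }
    if (any((k == 0) != (f == 0))) {
      stop("inconsistent dispersion in band '", b,
        "': band_books must be 0 exactly when band_freq is 0",
        call. = FALSE
      )
    }
  }
  invisible(df)
}

#' Read a word-frequency lexicon with per-band counts
#'
#' The canonical dialect is a UTF-8 tab-separated table with one word per
#' row and, for every age band `<b>`, a `freq_<b>` token-count column and a
#' `books_<b>` book-dispersion column (lines starting with `#` are
#' comments). Published spreadsheet layouts are mapped into this dialect
#' with `col_map`. Duplicate surface forms (after normalization) are merged
#' by summing token counts and taking the maximum of book counts.
#'
#' @param path Path to the table.
#' @param dialect `"canonical"` (TSV) or `"csv"` (same columns, commas).
#' @param col_map Optional named character vector mapping file column names
#'   to canonical ones, e.g. `c(Word = "word", F79 = "freq_7_9")`.
#' @param books_per_band Number of books per age band (400 in the emulated
#'   corpus); used to validate dispersion counts.
#' @return A `band_lexicon` data frame with columns `word`, `freq_<band>`,
#'   `books_<band>` and `total_freq`, plus `bands` and `books_per_band`
#'   attributes.
#' @export
read_band_lexicon <- function(path, dialect = c("canonical", "csv"),
                              col_map = NULL, books_per_band = 400) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  if (!"word" %in% names(df)) {
    stop("missing required column 'word'", call. = FALSE)
  }
  bands <- sub("^freq_", "", grep("^freq_", names(df), value = TRUE))
  if (length(bands) == 0) {
    stop("missing required columns: no freq_<band> column found",
      call. = FALSE
    )
  }
  missing_books <- setdiff(books_col(bands), names(df))
  if (length(missing_books) > 0) {
    stop("missing required columns: ", paste(missing_books, collapse = ", "),
      call. = FALSE
    )
  }
  df$word <- normalize_word(df$word)
  cols <- c("word", as.vector(rbind(freq_col(bands), books_col(bands))))
  df <- df[cols]

  if (anyDuplicated(df$word)) {
    key <- factor(df$word, levels = unique(df$word))
    merged <- data.frame(word = levels(key), stringsAsFactors = FALSE)
    for (b in bands) {
      merged[[freq_col(b)]] <-
        as.integer(rowsum(df[[freq_col(b)]], key)[, 1])
      merged[[books_col(b)]] <- as.integer(
        tapply(df[[books_col(b)]], key, max)
      )
    }
    df <- merged
  }
  df$total_freq <- as.integer(rowSums(df[freq_col(bands)]))
  validate_band_lexicon(df, bands, books_per_band)
  new_band_lexicon(df, bands, books_per_band)
}

#' Write a band lexicon in the canonical TSV dialect
#'
#' @param x A `band_lexicon` data frame.
#' @param path Output path.
#' @param header_comments Optional character vector written as leading
#'   `#`-prefixed comment lines (the synthetic generator records its seed
#'   here).
#' @return Invisibly, `path`.
#' @export
write_band_lexicon <- function(x, path, header_comments = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(as.data.frame(x), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Parse a morphological segmentation string
#'
#' Two dialects are supported. The MorphoLex convention wraps prefixes in
#' `<`, suffixes in `>` and roots in parentheses, e.g.
#' `"{(sound)>less>>ly>}"`. The plain fixture dialect is a whitespace
#' separated list of `kind:form` tokens, e.g.
#' `"prefix:un root:lock suffix:able"`.
#'
#' @param seg Segmentation string (non-empty).
#' @param dialect `"morpholex"` or `"plain"`.
#' @return Data frame of ordered morph units with columns `kind`
#'   (`"prefix"`, `"root"`, `"suffix"`) and `form`.
#' @examples
#' parse_segmentation("{(sound)>less>>ly>}", "morpholex")
#' parse_segmentation("prefix:un root:lock suffix:able", "plain")
#' @export
parse_segmentation <- function(seg, dialect = c("morpholex", "plain")) {
  dialect <- match.arg(dialect)
  if (!is.character(seg) || length(seg) != 1 || !nzchar(seg)) {
    stop("`seg` must be a single non-empty string", call. = FALSE)
  }
  if (dialect == "plain") {
    toks <- strsplit(trimws(seg), "[[:space:]]+")[[1]]
    parts <- strsplit(toks, ":", fixed = TRUE)
    bad <- vapply(parts, function(p) {
      length(p) != 2 || !p[1] %in% c("prefix", "root", "suffix") ||
        !nzchar(p[2])
    }, logical(1))
    if (any(bad)) {
      stop("malformed annotation: ", paste(toks[bad], collapse = " "),
        call. = FALSE
      )
    }
    units <- data.frame(
      kind = vapply(parts, `[`, "", 1),
      form = vapply(parts, `[`, "", 2),
      stringsAsFactors = FALSE
    )
  } else {
    pat <- "<([a-z'-]+)<|>([a-z'-]+)>|\\(([a-z'-]+)\\)"
    m <- gregexpr(pat, seg, perl = TRUE)[[1]]
    if (m[1] == -1) stop("malformed annotation: ", seg, call. = FALSE)
    toks <- regmatches(seg, gregexpr(pat, seg, perl = TRUE))[[1]]
    leftover <- gsub(pat, "", seg, perl = TRUE)
    leftover <- gsub("[{}[:space:]]", "", leftover)
    if (nzchar(leftover)) {
      stop(
        "malformed annotation (unbalanced delimiters): ", seg,
        call. = FALSE
      )
    }
    kind <- ifelse(startsWith(toks, "<"), "prefix",
      ifelse(startsWith(toks, ">"), "suffix", "root")
    )
    form <- gsub("[<>()]", "", toks)
    units <- data.frame(kind = kind, form = form, stringsAsFactors = FALSE)
  }
  if (!any(units$kind == "root")) {
    stop("malformed annotation: no root in ", seg, call. = FALSE)
  }
  units
}

#' Build morphological records from words and their unit lists
#'
#' Computes the unit counts and the complexity flags that every downstream
#' statistic relies on: a word is morphologically complex when it has at
#' least one affix or at least two roots; an unaffixed compound has two or
#' more roots and no affixes.
#'
#' @param words Character vector of normalized words.
#' @param units_list List of unit data frames (as from
#'   [parse_segmentation()]), parallel to `words`.
#' @return A `morph_annotations` data frame with columns `word`,
#'   `n_prefixes`, `n_roots`, `n_suffixes`, `is_complex`,
#'   `is_unaffixed_compound` and a list column `units`.
#' @export
build_morph_records <- function(words, units_list) {
  stopifnot(length(words) == length(units_list))
  n_pre <- vapply(units_list, function(u) sum(u$kind == "prefix"), 0L)
  n_root <- vapply(units_list, function(u) sum(u$kind == "root"), 0L)
  n_suf <- vapply(units_list, function(u) sum(u$kind == "suffix"), 0L)
  if (any(n_root < 1)) {
    stop("every morphological record needs at least one root", call. = FALSE)
  }
  df <- data.frame(
    word = words,
    n_prefixes = n_pre, n_roots = n_root, n_suffixes = n_suf,
    is_complex = (n_pre + n_suf >= 1) | (n_root >= 2),
    is_unaffixed_compound = (n_root >= 2) & (n_pre + n_suf == 0),
    stringsAsFactors = FALSE
  )
  df$units <- units_list
  rownames(df) <- NULL
  class(df) <- c("morph_annotations", "data.frame")
  df
}

#' Read an etymological morphological annotation table
#'
#' Expects a two-column table (`word`, `segmentation`); the segmentation
#' column is parsed with [parse_segmentation()]. When a word carries
#' several annotation rows the first parse is kept and the duplicates are
#' reported via `message()`.
#'
#' @param path Path to the annotation table.
#' @param dialect Segmentation dialect passed to [parse_segmentation()].
#' @param sep Field separator (tab by default).
#' @return A `morph_annotations` data frame (see [build_morph_records()]).
#' @export
read_morph_annotations <- function(path, dialect = c("morpholex", "plain"),
                                   sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    comment.char = "#", stringsAsFactors = FALSE, fileEncoding = "UTF-8"
  )
  need <- c("word", "segmentation")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ",
      paste(setdiff(need, names(df)), collapse = ", "),
      call. = FALSE
    )
  }
  df$word <- normalize_word(df$word)
  dup <- duplicated(df$word)
  if (any(dup)) {
    message(
      sum(dup), " duplicate annotation row(s) dropped (first parse kept): ",
      paste(utils::head(unique(df$word[dup]), 5), collapse = ", ")
    )
    df <- df[!dup, , drop = FALSE]
  }
  units <- lapply(df$segmentation, parse_segmentation, dialect = dialect)
  build_morph_records(df$word, units)
}

#' Cross-reference a band lexicon against morphological annotations
#'
#' Exact-match join on the normalized word. Lexicon words without an
#' annotation are retained with `annotated = FALSE`; coverage counts report
#' how many lexicon words matched.
#'
#' @param entries A `band_lexicon` data frame.
#' @param morph A `morph_annotations` data frame.
#' @return A `joined_lexicon` object: a list with `words` (the joined
#'   table), `coverage` (named counts `matched`/`unmatched`), `bands` and
#'   `books_per_band`.
#' @export
cross_reference <- function(entries, morph) {
  stopifnot(nrow(entries) > 0, nrow(morph) > 0)
  idx <- match(entries$word, morph$word)
  words <- as.data.frame(entries)
  words$annotated <- !is.na(idx)
  for (cl in c("n_prefixes", "n_roots", "n_suffixes")) {
    words[[cl]] <- ifelse(is.na(idx), NA_integer_, morph[[cl]][idx])
  }
  for (cl in c("is_complex", "is_unaffixed_compound")) {
    words[[cl]] <- ifelse(is.na(idx), NA, morph[[cl]][idx])
  }
  units <- vector("list", nrow(words))
  units[words$annotated] <- morph$units[idx[words$annotated]]
  words$units <- units
  structure(
    list(
      words = words,
      coverage = c(
        matched = sum(words$annotated),
        unmatched = sum(!words$annotated)
      ),
      bands = lexicon_bands(entries),
      books_per_band = attr(entries, "books_per_band")
    ),
    class = "joined_lexicon"
  )
}

#' @export
print.joined_lexicon <- function(x, ...) {
  cat(
    "Joined lexicon: ", nrow(x$words), " words (",
    x$coverage[["matched"]], " annotated, ",
    x$coverage[["unmatched"]], " unannotated); bands: ",
    paste(x$bands, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a reference (spoken-language) lexicon
#'
#' The canonical dialect is a TSV with a `word` column and one token-count
#' column per channel label (e.g. `cbbc`, `all`); `channel` selects which
#' column to use (case-insensitively). Words with a zero or missing count
#' in the selected channel are dropped, so all retained counts are >= 1.
#'
#' @param path Path to the table.
#' @param dialect `"canonical"` (TSV) or `"csv"`.
#' @param channel Channel label selecting the count column, e.g. `"CBBC"`
#'   for the children's-channel subset or `"ALL"` for the whole corpus.
#' @param col_map Optional named character vector renaming file columns.
#' @return A `reference_lexicon`: a list with `entries` (data frame
#'   `word`, `count`) and `label`.
#' @export
read_reference_lexicon <- function(path, dialect = c("canonical", "csv"),
                                   channel = "ALL", col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  if (!"word" %in% names(df)) {
    stop("missing required column 'word'", call. = FALSE)
  }
  chan_col <- which(tolower(names(df)) == tolower(channel))
  if (length(chan_col) != 1) {
    stop("unknown channel id: ", channel, call. = FALSE)
  }
  words <- normalize_word(df$word)
  counts <- df[[chan_col]]
  keep <- !is.na(counts) & counts >= 1
  entries <- data.frame(
    word = words[keep], count = as.numeric(counts[keep]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(entries$word)) {
    key <- factor(entries$word, levels = unique(entries$word))
    entries <- data.frame(
      word = levels(key),
      count = as.numeric(rowsum(entries$count, key)[, 1]),
      stringsAsFactors = FALSE
    )
  }
  structure(list(entries = entries, label = toupper(channel)),
    class = "reference_lexicon"
  )
}

#' @export
print.reference_lexicon <- function(x, ...) {
  cat(
    "Reference lexicon '", x$label, "': ", nrow(x$entries),
    " distinct words, ", sum(x$entries$count), " tokens\n",
    sep = ""
  )
  invisible(x)
}
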