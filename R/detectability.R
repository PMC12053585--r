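#' Build a fast membership set of attested words
#'
#' The stripping algorithm decides whether a residual letter string is a
#' word by looking it up in the attested-word dictionary (normally the
#' full normalized lexicon word list, proper names and interjections
#' included). This helper hashes the list for O(1) lookup.
#'
#' @param words Character vector of normalized words.
#' @return An `attested_set` environment.
#' @export
attested_set <- function(words) {
  env <- new.env(parent = emptyenv(), size = max(length(words), 16L))
  for (w in words) assign(w, TRUE, envir = env)
  class(env) <- "attested_set"
  env
}

as_attested <- function(attested) {
  if (inherits(attested, "attested_set")) {
    return(attested)
  }
  if (is.character(attested)) {
    return(attested_set(attested))
  }
  stop("`attested` must be a character vector or an attested_set",
    call. = FALSE
  )
}

is_attested <- function(word, attested) {
  exists(word, envir = attested, inherits = FALSE)
}

# Normalize an affix specification (common_affix_set or data frame) to a
# data frame with columns form / position.
as_affix_table <- function(affixes) {
  if (inherits(affixes, "common_affix_set")) {
    affixes <- data.frame(
      form = c(affixes$prefixes, affixes$suffixes),
      position = c(
        rep("prefix", length(affixes$prefixes)),
        rep("suffix", length(affixes$suffixes))
      ),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    is.data.frame(affixes),
    all(c("form", "position") %in% names(affixes))
  )
  stopifnot(all(affixes$position %in% c("prefix", "suffix")))
  stopifnot(all(nzchar(affixes$form)))
  affixes[c("form", "position")]
}

# Spec order for recursion: suffixes before prefixes, longest pattern
# first (so "-ly" is tried before "-y"); stable within ties.
ordered_affixes <- function(affixes) {
  affixes[order(
    match(affixes$position, c("suffix", "prefix")),
    -nchar(affixes$form)
  ), , drop = FALSE]
}

#' Candidate stems for one affix stripped from one word
#'
#' Checks that the affix's orthographic pattern is present at the required
#' position (word start for prefixes, word end for suffixes), removes it
#' once, and applies every applicable spelling-reversal rule to the
#' residual. The identity candidate always comes first; duplicates are
#' removed preserving order; candidates at least as long as the word
#' itself are discarded (each strip must shorten the string).
#'
#' @param word Normalized word.
#' @param affix Affix form (orthographic pattern, no hyphen).
#' @param position `"prefix"` or `"suffix"`.
#' @param rules Spelling-rule list, see [default_spelling_rules()].
#' @return Data frame with columns `stem` and `rule` (possibly 0 rows).
#' @examples
#' candidate_stems("sunny", "y", "suffix")
#' @export
candidate_stems <- function(word, affix, position = c("suffix", "prefix"),
                            rules = default_spelling_rules()) {
  position <- match.arg(position)
  stopifnot(nzchar(affix))
  empty <- data.frame(
    stem = character(), rule = character(),
    stringsAsFactors = FALSE
  )
  na <- nchar(affix)
  nw <- nchar(word)
  if (nw <= na) {
    return(empty)
  }
  if (position == "suffix") {
    if (!endsWith(word, affix)) {
      return(empty)
    }
    residual <- substr(word, 1, nw - na)
  } else {
    if (!startsWith(word, affix)) {
      return(empty)
    }
    residual <- substr(word, na + 1, nw)
  }
  stems <- character()
  rule_names <- character()
  for (r in rules) {
    if (r$position != "both" && r$position != position) next
    if (!isTRUE(r$condition(affix))) next
    s <- r$transform(residual)
    if (is.na(s) || !nzchar(s) || nchar(s) >= nw) next
    if (!s %in% stems) {
      stems <- c(stems, s)
      rule_names <- c(rule_names, r$name)
    }
  }
  data.frame(stem = stems, rule = rule_names, stringsAsFactors = FALSE)
}

#' Attempt a single affix strip against the attested-word dictionary
#'
#' Detaches the affix pattern (if present at the required position) and
#' checks the candidate stems, in rule-priority order, against the
#' attested set. The first attested candidate wins.
#'
#' @inheritParams candidate_stems
#' @param attested Character vector or [attested_set()] of attested words.
#' @return A `strip_outcome` list: `word`, `affix`, `position`,
#'   `residual`, `candidates` (data frame), `stem`, `rule` and `detected`.
#' @examples
#' strip_once("teacher", "er", "suffix", c("teach", "teacher"))
#' @export
strip_once <- function(word, affix, position = c("suffix", "prefix"),
                       attested, rules = default_spelling_rules()) {
  position <- match.arg(position)
  attested <- as_attested(attested)
  cands <- candidate_stems(word, affix, position, rules)
  hit <- NA_integer_
  for (i in seq_len(nrow(cands))) {
    if (is_attested(cands$stem[i], attested)) {
      hit <- i
      break
    }
  }
  residual <- if (nrow(cands) > 0) {
    if (position == "suffix") {
      substr(word, 1, nchar(word) - nchar(affix))
    } else {
      substr(word, nchar(affix) + 1, nchar(word))
    }
  } else {
    NA_character_
  }
  structure(
    list(
      word = word, affix = affix, position = position,
      residual = residual, candidates = cands,
      stem = if (!is.na(hit)) cands$stem[hit] else NA_character_,
      rule = if (!is.na(hit)) cands$rule[hit] else NA_character_,
      detected = !is.na(hit)
    ),
    class = "strip_outcome"
  )
}

#' Recursive orthographic segmentation of a word
#'
#' Applies [strip_once()] repeatedly: at each level the affixes are tried
#' suffixes-first in longest-pattern-first order, the first successful
#' strip is taken, and the algorithm recurses on its attested stem until
#' no strip succeeds or `max_depth` is exhausted. An unsegmentable word
#' returns itself as the terminal stem.
#'
#' @inheritParams strip_once
#' @param affixes Affix set: data frame with columns `form`/`position`, or
#'   a `common_affix_set`.
#' @param max_depth Maximum number of strips (default 6, safely above the
#'   deepest plausible English derivation).
#' @return A `segmentation` list: `word`, `prefixes` and `suffixes` (in
#'   strip order, outermost first), terminal `stem`, and `steps` (the
#'   per-strip trace: affix, position, rule, stem).
#' @examples
#' affs <- data.frame(form = c("ly", "less"), position = "suffix")
#' segment_recursive("soundlessly", affs, c("sound", "soundless"))
#' @export
segment_recursive <- function(word, affixes, attested,
                              rules = default_spelling_rules(),
                              max_depth = 6) {
  stopifnot(max_depth >= 1)
  affixes <- ordered_affixes(as_affix_table(affixes))
  attested <- as_attested(attested)
  current <- word
  steps <- list()
  for (depth in seq_len(max_depth)) {
    stripped <- FALSE
    for (i in seq_len(nrow(affixes))) {
      out <- strip_once(
        current, affixes$form[i], affixes$position[i],
        attested, rules
      )
      if (out$detected) {
        steps[[length(steps) + 1]] <- data.frame(
          affix = out$affix, position = out$position,
          rule = out$rule, stem = out$stem, stringsAsFactors = FALSE
        )
        current <- out$stem
        stripped <- TRUE
        break
      }
    }
    if (!stripped) break
  }
  steps <- if (length(steps)) {
    do.call(rbind, steps)
  } else {
    data.frame(
      affix = character(), position = character(),
      rule = character(), stem = character(), stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      word = word,
      prefixes = steps$affix[steps$position == "prefix"],
      suffixes = steps$affix[steps$position == "suffix"],
      stem = current,
      steps = steps
    ),
    class = "segmentation"
  )
}

#' Reconstruct the original word from a segmentation trace
#'
#' Re-applies the forward orthographic alterations: starting from the
#' terminal stem, each strip step is undone in reverse order by inverting
#' its spelling rule and re-attaching the affix. Every valid segmentation
#' reconstructs its word exactly.
#'
#' @param seg A `segmentation` from [segment_recursive()].
#' @param rules The rule set the segmentation was produced with.
#' @return The reconstructed word (character scalar).
#' @export
reconstruct_segmentation <- function(seg, rules = default_spelling_rules()) {
  current <- seg$stem
  steps <- seg$steps
  for (i in rev(seq_len(nrow(steps)))) {
    r <- rule_by_name(rules, steps$rule[i])
    residual <- r$invert(current)
    current <- if (steps$position[i] == "suffix") {
      paste0(residual, steps$affix[i])
    } else {
      paste0(steps$affix[i], residual)
    }
  }
  current
}

#' Can a target affix be detected in a word by orthographic stripping?
#'
#' Answers whether any sequence of attested strips exposes the target
#' affix: either the target strips directly from the word, or some other
#' affix strips to an attested stem from which the target is (recursively)
#' detectable. This existential reading makes the answer independent of
#' the order in which affixes are tried and agrees with the exhaustive
#' enumeration oracle ([brute_force_oracle()]) by construction.
#'
#' @inheritParams segment_recursive
#' @param affix Target affix form.
#' @param position Target affix position.
#' @return `TRUE` if the affix is orthographically detectable in the word.
#' @examples
#' affs <- data.frame(form = c("ly", "less"), position = "suffix")
#' detect_affix_in_word("soundlessly", "less", "suffix", affs,
#'   c("sound", "soundless"))
#' @export
detect_affix_in_word <- function(word, affix,
                                 position = c("suffix", "prefix"),
                                 affixes, attested,
                                 rules = default_spelling_rules(),
                                 max_depth = 6) {
  position <- match.arg(position)
  affixes <- ordered_affixes(as_affix_table(affixes))
  attested <- as_attested(attested)
  search <- function(w, depth) {
    if (strip_once(w, affix, position, attested, rules)$detected) {
      return(TRUE)
    }
    if (depth >= max_depth) {
      return(FALSE)
    }
    for (i in seq_len(nrow(affixes))) {
      out <- strip_once(
        w, affixes$form[i], affixes$position[i],
        attested, rules
      )
      if (out$detected && search(out$stem, depth + 1)) {
        return(TRUE)
      }
    }
    FALSE
  }
  search(word, 1L)
}

#' Exhaustively enumerate all valid complete segmentations
#'
#' Test oracle: explores every sequence of (affix, rule) strips whose
#' intermediate stems are attested, extending each branch until no strip
#' succeeds. The main algorithm's greedy parse is always a member of this
#' set, and an affix is detectable exactly when some member contains it.
#'
#' @inheritParams segment_recursive
#' @return List of segmentations, each a list with `steps` (data frame:
#'   affix, position, rule, stem) and `terminal` (the final stem).
#' @export
brute_force_oracle <- function(word, affixes, attested,
                               rules = default_spelling_rules(),
                               max_depth = 6) {
  if (nchar(word) > 25) {
    stop("oracle restricted to words of <= 25 characters", call. = FALSE)
  }
  affixes <- ordered_affixes(as_affix_table(affixes))
  attested <- as_attested(attested)
  enumerate <- function(w, steps, depth) {
    branches <- list()
    if (depth < max_depth) {
      for (i in seq_len(nrow(affixes))) {
        cands <- candidate_stems(
          w, affixes$form[i], affixes$position[i],
          rules
        )
        for (j in seq_len(nrow(cands))) {
          if (!is_attested(cands$stem[j], attested)) next
          step <- data.frame(
            affix = affixes$form[i], position = affixes$position[i],
            rule = cands$rule[j], stem = cands$stem[j],
            stringsAsFactors = FALSE
          )
          branches <- c(
            branches,
            enumerate(cands$stem[j], rbind(steps, step), depth + 1)
          )
        }
      }
    }
    if (length(branches) == 0) {
      return(list(list(steps = steps, terminal = w)))
    }
    branches
  }
  empty <- data.frame(
    affix = character(), position = character(),
    rule = character(), stem = character(), stringsAsFactors = FALSE
  )
  enumerate(word, empty, 0L)
}

#' Does any oracle segmentation contain a given affix?
#'
#' @param oracle Result of [brute_force_oracle()].
#' @param affix,position Target affix form and position.
#' @return Logical scalar.
#' @export
oracle_detects <- function(oracle, affix, position) {
  any(vapply(oracle, function(seg) {
    any(seg$steps$affix == affix & seg$steps$position == position)
  }, logical(1)))
}

# Etymological containment: does the annotation's unit list include the
# affix form at the given position?
morph_contains_affix <- function(units, affix, position) {
  !is.null(units) && any(units$kind == position & units$form == affix)
}

#' Classify one word for one target affix
#'
#' * `hit` - etymologically contains the affix and the affix is
#'   orthographically detectable;
#' * `miss` - etymologically contains it but stripping cannot expose it
#'   (typically a bound stem);
#' * `false_alarm` - etymologically has *no* affix at the target position
#'   yet a single-step strip of the target succeeds (pseudo-affixation,
#'   e.g. *corner* for *-er*); false alarms are single-step by design,
#'   no recursion;
#' * `not_applicable` - everything else.
#'
#' @inheritParams detect_affix_in_word
#' @param morph One row of a `morph_annotations` data frame for `word`
#'   (its `units[[1]]`, `n_prefixes`, `n_suffixes` are consulted).
#' @return One of `"hit"`, `"miss"`, `"false_alarm"`, `"not_applicable"`.
#' @export
classify_word <- function(word, morph, affix,
                          position = c("suffix", "prefix"),
                          affixes, attested,
                          rules = default_spelling_rules(),
                          max_depth = 6) {
  position <- match.arg(position)
  attested <- as_attested(attested)
  units <- if (is.data.frame(morph$units[[1]]) ||
    is.null(morph$units[[1]])) {
    morph$units[[1]]
  } else {
    morph$units
  }
  if (morph_contains_affix(units, affix, position)) {
    detected <- detect_affix_in_word(
      word, affix, position, affixes,
      attested, rules, max_depth
    )
    return(if (detected) "hit" else "miss")
  }
  n_at_pos <- if (position == "prefix") morph$n_prefixes else morph$n_suffixes
  if (n_at_pos == 0) {
    if (strip_once(word, affix, position, attested, rules)$detected) {
      return("false_alarm")
    }
  }
  "not_applicable"
}

#' Run the detectability analysis over a joined lexicon
#'
#' For every affix in the inventory: the hit/miss tally is computed over
#' the annotated words that etymologically contain that affix (detection
#' via [detect_affix_in_word()] with the full inventory available for
#' recursion), and the false-alarm tally over the annotated words with
#' zero affixes at that position (single-step strip). The attested-word
#' dictionary defaults to the full lexicon word list, unannotated words
#' included.
#'
#' @param joined A `joined_lexicon` from [cross_reference()].
#' @param affixes Affix inventory (data frame `form`/`position` or a
#'   `common_affix_set`).
#' @param attested Attested-word dictionary; defaults to all words of
#'   `joined`.
#' @param rules,max_depth See [segment_recursive()].
#' @param false_alarms Set `FALSE` to skip the false-alarm pass.
#' @return A `detectability_tally` data frame, one row per affix:
#'   `affix`, `position`, `n_genuine`, `n_hits`, `n_misses`,
#'   `n_false_alarms`, plus list columns `hits`, `misses`,
#'   `false_alarm_words` with the word lists.
#' @export
run_detectability <- function(joined, affixes, attested = NULL,
                              rules = default_spelling_rules(),
                              max_depth = 6, false_alarms = TRUE) {
  affixes <- as_affix_table(affixes)
  stopifnot(nrow(affixes) > 0)
  if (is.null(attested)) attested <- joined$words$word
  attested <- as_attested(attested)
  ann <- joined$words[joined$words$annotated, , drop = FALSE]
  ann <- ann[order(ann$word), , drop = FALSE] # iteration-order invariance

  rows <- vector("list", nrow(affixes))
  for (i in seq_len(nrow(affixes))) {
    form <- affixes$form[i]
    pos <- affixes$position[i]
    genuine <- vapply(
      ann$units, morph_contains_affix, logical(1),
      affix = form, position = pos
    )
    gw <- ann$word[genuine]
    detected <- vapply(gw, function(w) {
      detect_affix_in_word(w, form, pos, affixes, attested, rules, max_depth)
    }, logical(1), USE.NAMES = FALSE)
    fa_words <- character()
    if (false_alarms) {
      pool <- if (pos == "prefix") {
        ann$word[ann$n_prefixes == 0]
      } else {
        ann$word[ann$n_suffixes == 0]
      }
      fa <- vapply(pool, function(w) {
        strip_once(w, form, pos, attested, rules)$detected
      }, logical(1), USE.NAMES = FALSE)
      fa_words <- pool[fa]
    }
    rows[[i]] <- data.frame(
      affix = form, position = pos,
      n_genuine = length(gw),
      n_hits = sum(detected),
      n_misses = sum(!detected),
      n_false_alarms = length(fa_words),
      stringsAsFactors = FALSE
    )
    rows[[i]]$hits <- list(gw[detected])
    rows[[i]]$misses <- list(gw[!detected])
    rows[[i]]$false_alarm_words <- list(fa_words)
  }
  tally <- do.call(rbind, rows)
  rownames(tally) <- NULL
  class(tally) <- c("detectability_tally", "data.frame")
  tally
}

#' Summarize a detectability tally
#'
#' Adds, per affix, the number of *identifiable* words (hits plus false
#' alarms: everything in which the affix pattern strips to an attested
#' stem, correctly or not), the percentage of those that are misleading
#' false alarms, and the percentage of genuine words detected. Percentages
#' are reported to the whole percent.
#'
#' @param tally A `detectability_tally` from [run_detectability()].
#' @return Data frame with columns `affix`, `position`, `n_genuine`,
#'   `n_hits`, `n_misses`, `n_false_alarms`, `n_identifiable`,
#'   `pct_false_alarm`, `pct_detected`.
#' @export
detectability_summary <- function(tally) {
  out <- as.data.frame(tally)[c(
    "affix", "position", "n_genuine", "n_hits", "n_misses",
    "n_false_alarms"
  )]
  out$n_identifiable <- out$n_hits + out$n_false_alarms
  out$pct_false_alarm <- ifelse(
    out$n_identifiable > 0,
    round(100 * out$n_false_alarms / out$n_identifiable), NA_integer_
  )
  out$pct_detected <- ifelse(
    out$n_genuine > 0,
    round(100 * out$n_hits / out$n_genuine), NA_integer_
  )
  out
}
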