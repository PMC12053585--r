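VOWELS <- c("a", "e", "i", "o", "u")

first_char <- function(x) substr(x, 1, 1)
last_char <- function(x) substr(x, nchar(x), nchar(x))
drop_last <- function(x) substr(x, 1, nchar(x) - 1)

# "y" behaves as a vowel at a suffix juncture (sun + -y -> sunny), so
# suffixes starting with it license the vowel-initial alterations.
is_vowel_initial <- function(affix) first_char(affix) %in% c(VOWELS, "y")

#' Construct a spelling-reversal rule
#'
#' A rule describes one orthographic alteration that derivational
#' affixation can apply at a morpheme juncture, in the *reversal*
#' direction used during stripping: given the residual letter string left
#' after an affix has been detached, `transform` proposes a candidate
#' stem, and `invert` maps an attested stem back to the residual (used for
#' reconstruction and by the synthetic generator's forward direction).
#'
#' @param name Rule identifier (e.g. `"e_restore"`).
#' @param position Where the rule may fire: `"suffix"`, `"prefix"` or
#'   `"both"`.
#' @param condition Function of the affix form returning `TRUE` when the
#'   rule is applicable to that affix (e.g. vowel-initial suffixes only).
#' @param transform Function mapping a residual string to a candidate stem,
#'   or `NA_character_` when the rule does not apply to that residual.
#' @param invert Function mapping the attested stem back to the residual.
#' @return A `spelling_rule` object.
#' @export
spelling_rule <- function(name, position = c("suffix", "prefix", "both"),
                          condition = function(affix) TRUE,
                          transform, invert) {
  position <- match.arg(position)
  stopifnot(is.function(condition), is.function(transform), is.function(invert))
  structure(
    list(
      name = name, position = position, condition = condition,
      transform = transform, invert = invert
    ),
    class = "spelling_rule"
  )
}

#' Default spelling-reversal rule set
#'
#' Four rules, tried in this order when looking for an attested stem:
#'
#' * `identity` - the residual itself (always present, always first);
#' * `e_restore` - restores a silent final *e* dropped before a
#'   vowel-initial suffix (*adorable* - *-able* -> *ador* -> *adore*);
#' * `undouble` - collapses a final doubled consonant produced before a
#'   vowel-initial suffix (*sunny* - *-y* -> *sunn* -> *sun*);
#' * `y_restore` - restores a stem-final *y* changed to *i* before a
#'   suffix (*happiness* - *-ness* -> *happi* -> *happy*).
#'
#' Prefixes attach by plain concatenation, so only the identity rule fires
#' on the prefix side. The set is pluggable: pass your own list of
#' [spelling_rule()] objects to the stripping functions.
#'
#' @return List of `spelling_rule` objects.
#' @export
default_spelling_rules <- function() {
  list(
    spelling_rule("identity", "both",
      transform = function(residual) residual,
      invert = function(stem) stem
    ),
    spelling_rule("e_restore", "suffix",
      condition = is_vowel_initial,
      transform = function(residual) paste0(residual, "e"),
      invert = function(stem) {
        if (last_char(stem) != "e") {
          stop("e_restore invert: stem does not end in 'e'", call. = FALSE)
        }
        drop_last(stem)
      }
    ),
    spelling_rule("undouble", "suffix",
      condition = is_vowel_initial,
      transform = function(residual) {
        n <- nchar(residual)
        if (n < 2) {
          return(NA_character_)
        }
        a <- substr(residual, n - 1, n - 1)
        b <- substr(residual, n, n)
        if (a == b && !(b %in% VOWELS)) drop_last(residual) else NA_character_
      },
      invert = function(stem) paste0(stem, last_char(stem))
    ),
    spelling_rule("y_restore", "suffix",
      transform = function(residual) {
        if (last_char(residual) == "i") {
          paste0(drop_last(residual), "y")
        } else {
          NA_character_
        }
      },
      invert = function(stem) {
        if (last_char(stem) != "y") {
          stop("y_restore invert: stem does not end in 'y'", call. = FALSE)
        }
        paste0(drop_last(stem), "i")
      }
    )
  )
}

rule_by_name <- function(rules, name) {
  for (r in rules) if (r$name == name) return(r)
  stop("unknown spelling rule: ", name, call. = FALSE)
}
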