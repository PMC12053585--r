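---
title: "Quantifying morphological exposure and orthographic affix detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological exposure and orthographic affix detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bookmorph)
```

## The problem

Readers of English learn derivational morphemes (*un-*, *-ness*, *-able*,
...) largely from print: affixes rarely occur in isolation, so their
meanings must be inferred from the complex words that contain them. How
much usable morphological information a book corpus actually offers
depends on three things that dictionary counts conflate:

1. **Exposure** - how many distinct words carry each affix (type
   frequency), how often those words recur (token frequency), and how
   widely they are spread across individual books (dispersion).
2. **Detectability** - whether the affix can be recovered from spelling
   alone. *teacher* segments transparently into *teach* + *-er*, but
   *depend* leaves the bound stem *pend*, which is not an English word:
   without etymological knowledge the prefix is invisible.
3. **Pseudo-affixation** - spellings that invite a spurious parse:
   *corner* looks like *corn* + *-er* but is etymologically simple. Such
   false alarms dilute whatever signal an affix provides.

`bookmorph` implements this whole accounting pipeline: it joins a
per-age-band word-frequency lexicon with an etymological annotation
table, computes the exposure statistics, selects a common-affix
inventory, and runs an orthography-only stripping algorithm that
classifies every word, per affix, as a **hit** (genuinely affixed and
detectable), a **miss** (genuinely affixed, not detectable), or a
**false alarm** (etymologically affix-free, yet strippable).

## The stripping algorithm

For a target affix the engine checks that the orthographic pattern sits
at the required position (word start for prefixes, word end for
suffixes), detaches it, and asks whether the residual letter string - or
a spelling-rule transformation of it - is *attested*, i.e. occurs in the
lexicon word list. The attested dictionary deliberately includes proper
names, interjections and coinages: the analysis models what a reader
could take to be a word, not what a curated dictionary sanctions
(*aaargh* - *a-* + *aargh* is a legitimate false alarm precisely because
*aargh* is also in the lexicon).

Affixation alters spelling at the morpheme juncture, so stripping must
reverse those alterations. The default rule set
(`default_spelling_rules()`) contains, in priority order:

| rule        | applies to | reversal                                         | example |
|-------------|------------|--------------------------------------------------|---------|
| `identity`  | both sides | residual unchanged                               | *teacher* -> *teach* |
| `e_restore` | vowel-initial suffixes | append silent *e*                    | *adorable* -> *adore* |
| `undouble`  | vowel-initial suffixes | collapse doubled final consonant     | *sunny* -> *sun* |
| `y_restore` | suffixes   | final *i* -> *y*                                 | *happiness* -> *happy* |

A suffix beginning with *y* counts as vowel-initial (*sun* + *-y* ->
*sunny*). The set is pluggable; richer curriculum-style rule lists can
be passed to every stripping function. The first attested candidate in
rule-priority order wins - a deterministic tie-break the data cannot
decide.

Multi-affix words are handled recursively (`segment_recursive()`):
suffixes are tried before prefixes, longest pattern first (so *-ly* is
tried before *-y* and *soundlessly* parses as *sound* + *-less* + *-ly*
rather than through a spurious *-y*), and the algorithm recurses on the
attested stem of the first successful strip until nothing strips or
`max_depth` (default 6, safely above the deepest plausible English
derivation) is reached. Every strip must produce a stem strictly
shorter than its word, which bounds the recursion by the word length; a
corollary is that a silent *e* is never restored after a single-letter
suffix, since the restored stem would be as long as the word.

Two numerical contracts are worth stating explicitly:

* **Reconstruction.** Each segmentation records the rule used at every
  step, and `reconstruct_segmentation()` re-applies the forward
  alterations to rebuild the original word exactly. This is tested for
  every segmentation the suite produces.
* **Detection semantics.** `detect_affix_in_word()` answers an
  *existential* question: is there any sequence of attested strips that
  exposes the target affix? This makes the answer independent of the
  (essentially arbitrary) order in which affixes are tried, and it
  coincides by construction with the exhaustive enumeration oracle
  (`brute_force_oracle()`) used for validation. The greedy canonical
  parse reported by `segment_recursive()` is one member of the oracle's
  set; on unambiguous words the two notions agree, and the package
  chose the order-independent one for tallying because per-affix counts
  should not depend on a tie-break.

False alarms use a **single-step** strip, no recursion: every canonical
pseudo-affixed example (*corner*, *army*, *forty*, *aaargh*) is a
one-step parse, and recursing through already-spurious stems would
compound speculation. The false-alarm pool for a position is the set of
annotated words with *zero* etymological affixes at that position
(words may carry affixes on the other side).

## Exposure statistics and the affix inventory

All corpus statistics run on the annotated subset of the joined lexicon
(words lacking an annotation are excluded from every statistic) and
within an age band on the words with nonzero band frequency. A word is
*morphologically complex* when it has at least one derivational affix
or at least two roots; unaffixed compounds (*snowman*) are complex but
participate in neither the prefix nor the suffix analyses. Percentages
are reported to the whole percent, with counts always retained
alongside, and every percentage is recomputed from its own counts in
the tests.

The common-affix inventory (`select_common_affixes()`) keeps an affix
when it appears in at least 1% of affixed word *types* - prefixes
measured against distinct prefixed words, suffixes against distinct
suffixed words, ties at exactly the threshold counting as meeting it -
in **every** band. Affixes that clear the bar in some bands only are
reported separately as the pre-exclusion candidate set together with
their failing bands, so both readings of the criterion are available.
Affix identity follows the annotation source's canonical form:
allomorphs (*com-*/*con-*/*cor-* under *co-*) are grouped by the
annotations, while the stripping engine matches exactly one
orthographic pattern per affix - the canonical spelling - which is
itself one driver of low detectability for affixes with many variant
forms.

## The synthetic generator

Real lexicon/annotation databases are large downloads, so the package
ships a generator (`generate_lexicon()`) that emulates the statistical
structure the analysis assumes and carries gold tags for every word:

* free stems (emitted as entries) and bound stems (never emitted);
* affixed words realized with the forward spelling alterations
  (`realize_surface_form()`);
* injected pseudo-affixed words: an attested carrier word plus an affix
  string, tagged monomorphemic in gold;
* Zipfian token frequencies (exponent 1 by default, so the most common
  word is about twice as frequent as the second) scaled to a token
  total, and book dispersion by uniform multinomial token assignment.

Attachment counts are exact combinatorial draws rather than Bernoulli
trials, so recovery is exact: with no bound stems every affix's hit
rate is 1; with a bound fraction *b* it is exactly 1 - *b*; recovered
false alarms equal the injected pseudo counts. Three construction
details make this hold *by design* rather than with high probability:
stems are generated to avoid affix-pattern boundaries (no stem starts
with an inventory prefix or ends with an inventory suffix), affix forms
are chosen so no pattern nests inside another at the same position, and
a post-pass regenerates any bound-stem surface whose strip candidates
collide with an attested entry. The default configuration
(`synth_config()`) fixes the study conditions at about 2,100 distinct
words - 1,200 free stems, nine affixes with 810 attachments, 45 pseudo
words - 400 books and 200,000 tokens, a size at which the full pipeline
runs in seconds on one CPU.

What the generator does **not** emulate: English phonotactics beyond
CV-syllable plausibility, semantic content, real frequency spectra
beyond the Zipf law, allomorphic spelling variation, and the annotation
noise of real etymological databases. Passing the synthetic recovery
tests therefore shows the algorithm is *correct*; it does not show that
real-corpus detectability counts are insensitive to the rule set, which
is why counts on real data should be read as estimates.

Multi-band corpora (`generate_multiband()`) draw per-band presence,
frequencies and dispersion over one linked type inventory, which is
what the between-band novelty and per-band threshold statistics need.

## Degenerate inputs and edge cases

Words containing hyphens or apostrophes pass through unmodified and
simply fail pattern checks where punctuation intervenes. Duplicate
lexicon rows merge by summing frequencies and taking the maximum book
count; duplicate annotation rows keep the first parse and report the
rest. An empty intersection in the cross-reference is a valid,
reportable outcome, as is an empty affix tally. Unsegmentable words
return themselves as terminal stems.

## Limitations

The analysis is orthographic by design: no phonology, no semantics, no
etymology inference (etymological truth always comes from the
annotation table). Inflectional variants are matched by exact surface
form only. Neutral/non-neutral affix classification and
distributional-semantic measures of affix meaning consistency are out
of scope.
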