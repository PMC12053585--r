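# bookmorph

Quantifying the derivational morphology that readers encounter in large
book lexicons — and how much of it is actually *visible* in spelling.

English readers are thought to learn affix morphemes (*un-*, *-ness*,
*-er*, ...) mostly from print, but dictionary-based counts of
"morphologically complex" words overstate the learnable signal: many
complex words have **bound stems** that block an orthographic parse
(*depend* → *de-* + *pend*, where *pend* is not a word), while some
simple words invite a spurious one (**pseudo-affixation**: *corner* →
*corn* + *-er*). `bookmorph` is aimed at psycholinguists and corpus
analysts who want to separate those cases at corpus scale.

The package provides:

* **Lexicon I/O** — readers for a per-age-band word-frequency lexicon
  (tokens and book-dispersion counts per band), an etymological
  morphological annotation table (MorphoLex-style `<un<{(lock)>able>}`
  segmentations or a plain `kind:form` dialect), and a reference
  spoken-language lexicon with channel subsets; exact-match
  cross-referencing with coverage accounting.
* **Exposure statistics** — per-band complexity prevalence, token
  frequency and book-dispersion band tables split by word class,
  morphological-structure distributions, reference-corpus gap summaries
  and between-band novelty.
* **Affix inventory** — per-affix type/token tallies and selection of
  the common-affix set (≥ 1% of affixed word types in every band,
  prefixes and suffixes analysed separately).
* **Detectability** — the core algorithm: orthography-only affix
  stripping with spelling-rule reversal (silent-*e* restoration,
  consonant un-doubling, *i*→*y* restoration), recursive multi-affix
  segmentation, and per-affix classification of words as **hits**,
  **misses**, or pseudo-affix **false alarms**, validated against an
  exhaustive enumeration oracle.
* **Synthetic lexicon generator** — seeded corpora with free/bound
  stems, orthographic alterations, injected pseudo words, Zipfian
  frequencies, multinomial book dispersion and gold tags, with exact
  parameter-recovery guarantees.

## Worked example

Segment a multi-affix word against an attested word list:

```r
library(bookmorph)

att  <- c("teach", "teacher", "corn", "corner", "infer", "sun", "sunny",
          "adore", "adorable", "sound", "soundless", "soundlessly")
affs <- data.frame(form = c("ly", "less", "er", "y", "able"),
                   position = "suffix")

segment_recursive("soundlessly", affs, att)[c("suffixes", "stem")]
#> $suffixes
#> [1] "ly"   "less"
#> $stem
#> [1] "sound"
```

Two recursive strips: *soundlessly* → *soundless* + *-ly*, then
*soundless* → *sound* + *-less*. By contrast
`strip_once("infer", "er", "suffix", att)$detected` is `FALSE` (the
residual *inf* is not attested) and `strip_once("corner", "er",
"suffix", att)` succeeds even though *corner* is etymologically simple
— a false alarm.

Run the full pipeline on a seeded synthetic corpus:

```r
cfg    <- synth_config(seed = 1)
corp   <- generate_lexicon(cfg)
corp
#> Synthetic corpus: 2145 words (1200 simple, 574 complex/free,
#>   326 complex/bound, 45 pseudo); seed 1

joined <- cross_reference(corp$entries, corp$gold)
common <- select_common_affixes(joined)
tally  <- run_detectability(joined, common)
detectability_summary(tally)
#>  affix position n_genuine n_hits n_misses n_false_alarms n_identifiable pct_false_alarm pct_detected
#>   over   prefix        60     30       30              3             33               9           50
#>     re   prefix       100     50       50              5             55               9           50
#>     un   prefix       120     60       60              6             66               9           50
#>   able   suffix       120     84       36              6             90               7           70
#>    ish   suffix        80     56       24              4             60               7           70
#>   ment   suffix        90     63       27              4             67               6           70
#>   ness   suffix       150    105       45              8            113               7           70
#>    ous   suffix        80     56       24              4             60               7           70
#>      y   suffix       100     70       30              5             75               7           70
```

Reading the table: for the suffix *-ness*, 150 words genuinely contain
it; 105 strip to an attested stem (hits, 70%), 45 have bound stems and
cannot be parsed from spelling (misses), and 8 further words merely
*look* *-ness*-suffixed (false alarms), so 7% of the 113 apparent
carriers are misleading. The generator attached half of each prefix's
and 30% of each suffix's words to bound stems, and the algorithm
recovers exactly those rates — and exactly the injected pseudo counts.

`run_pipeline()` drives the same stages from a configuration list or
YAML file and writes the TSV tables plus a run manifest.

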