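# sublexr

Type-weighted sound–spelling consistency and frequency norms for English,
computed from any phoneme–grapheme aligned lexicon — for psycholinguists
studying reading and spelling who need positional consistency measures for
real words, pseudowords, and misspellings alike.

## What it computes

English spelling–sound mappings are probabilistic: word-final [S] is read
/z/ in some words (HIS, PLEASE) and /s/ in others (GAS, LEASE). `sublexr`
quantifies such regularities from a corpus of aligned words. For a grapheme
G mapped to a phoneme P in a given within-word position,

    reading consistency   p(P | G) = n(G → P) / n(G)
    spelling consistency  p(G | P) = n(G → P) / n(P)
    phonographeme frequency        = n(G → P)

where `n(·)` counts corpus entries containing the unit in that position,
each lexical entry weighted once (type weighting, never token frequency).
The shared numerator `n(G → P)` is the frequency of the *phonographeme* —
the direction-neutral pairing of one grapheme with one phoneme. Five further
measures (phoneme, grapheme and phonographeme log10 frequencies plus the two
consistencies) are available at a coarser grain, the syllable **onset**
(initial consonant cluster) and **rime** (vowel plus following consonants).

The machinery behind the measures:

- **Maximum Onset Principle syllabification** of pronunciations, with an
  attested-onset whitelist deciding phonotactic legality
  (`mop_syllabify()`, `is_legal_onset()`); /lɑbstəɹ/ parses LOB-STER, not
  LO-BSTER or LOBS-TER.
- **Both-ends position coding**: word-initial, syllable-initial,
  syllable-medial, syllable-final, word-final — so the PP of HA-PPY is
  syllable-initial but never word-initial (`assign_positions()`).
- **One grapheme per phoneme**, with no "silent letters": WEIGH is
  [W]→/w/ + [EIGH]→/eɪ/. Discontinuous silent-E graphemes (A_E in BAKE),
  non-linear final E's realizing /ə/ or /ʌ/ (MUSCLE, ONE), and the X
  cluster exception (X→/ks/, pinned to the earlier syllable, TAX-I) are
  modeled explicitly.
- **Automatic alignment** of a spelling to its pronunciation against a
  corpus-derived grapheme inventory (`auto_align()`), with a held-out
  generalization diagnostic (`evaluate_generalization()`).
- A **synthetic-lexicon generator** with an independent brute-force
  counting oracle for testing (`generate_synthetic_corpus()`,
  `oracle_counts()`).

Mappings are written in a plain-text notation, e.g.
`M>m|U>ʌ-S>s|C>k|E~ə|L>l` for MUSCLE (`>` maps, `|` separates segments,
`-` marks syllable boundaries, `~` marks a non-linear E, `_` a silent-E
gap).

## Worked example

```r
library(sublexr)
words  <- read_corpus(demo_lexicon_path())
tables <- build_count_tables(words)        # type-weighted, position-keyed

reading_consistency(tables, "S", "z", "word_final")
#> [1] 0.5238095
```

So 52.4% of demonstration-lexicon entries with word-final [S] read it /z/.
Scoring the pseudoword BLEASE under the reading /bliz/:

```r
w <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>z")
score_word(w, tables, "phonographeme")$summary[1, ]
#>               measure      mean       min max      sum n_defined n_undefined
#> 1 reading_consistency 0.8809524 0.5238095   1 3.523810         4           0
```

Each of B→/b/, L→/l/, EA_E→/i/ is the sole attested reading of its
grapheme in its position (consistency 1); word-final S→/z/ contributes
0.524, for a mean of 0.881. The preference between /bliz/ and /blis/
reverses across grains: /bliz/ wins segment by segment (0.881 vs 0.869)
because word-final S is more often /z/, but at the onset/rime grain the
rime -EASE is more often read /is/:

```r
blis <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>s")
compare_pronunciations(list(w, blis), tables, "onset_rime")
#>   pronunciation            mapping     value rank
#> 2          blis B>b|L>l|EA_E>i|S>s 0.7857143    1
#> 1          bliz B>b|L>l|EA_E>i|S>z 0.7142857    2
```

A command-line wrapper covers the same ground
(`system.file("cli", "sublex.R", package = "sublexr")`):

```sh
Rscript sublex.R build  --corpus lexicon.tsv --out tables/
Rscript sublex.R score  --tables tables/ --queries queries.tsv
Rscript sublex.R search --tables tables/ --measure grapheme_freq --op ">=" --value 2
Rscript sublex.R diag   --corpus lexicon.tsv
```

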