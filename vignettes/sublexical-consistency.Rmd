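---
title: "Methods: positional sound–spelling consistency from an aligned lexicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional sound-spelling consistency from an aligned lexicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sublexr)
```

## The model

`sublexr` treats sublexical knowledge of English spelling–sound mappings as
experience-dependent: the strength of a mapping is estimated from how often
it is encountered across lexical entries, not from a prescriptive rule set.
Two grain sizes are measured. At the fine grain, the unit is the
*phonographeme* — one grapheme (one or more letters functioning as the
orthographic counterpart of a single phoneme) paired with that phoneme. At
the coarse grain, the units are the syllable *onset* (initial consonant
cluster) and *rime* (nucleus plus coda). For a unit in a position,

- reading consistency is the conditional probability of the phonological
  side given the orthographic side, `p(P | G)`;
- spelling consistency is the converse, `p(G | P)`;
- frequency measures are the raw type counts (and their `log10`).

Both consistencies share one numerator — the joint count of the pairing —
because an encounter with a word exercises the mapping in both directions
at once. All counting is type-weighted: each lexical entry counts once,
regardless of its usage frequency. Token weighting is deliberately not
implemented.

### Assumptions

- Pronunciations are inputs, taken at face value (no text-to-phoneme
  generation, no dialect normalization such as a cot–caught merger, no
  stress or prosody). Words with several accepted pronunciations enter as
  separate records sharing a spelling (`pron_id` distinguishes them).
- Every grapheme maps to exactly one phoneme; there are no "silent
  letters", only graphemes whose pronunciation differs from their letters
  (WEIGH = [W]→/w/ + [EIGH]→/eɪ/). The single exception is the letter X,
  the one English grapheme that can represent a consonant *cluster*
  (/ks/, /gz/, /kʃ/, /gʒ/; the admissible set is a plain-text config).
- Morphology is invisible: syllabification routinely crosses morpheme
  boundaries (EATER parses EA-TER, not EAT-ER), and no morphological
  information ever informs a measure.

## Parsing and position coding

Pronunciations are syllabified by the Maximum Onset Principle: intervocalic
consonants go to the following syllable's onset unless that onset would be
phonotactically illegal, in which case the smallest offending prefix stays
in the preceding coda. Legality is decided by an explicit whitelist of
attested English onsets (`inst/extdata/onsets_en.txt`, editable, one onset
per line) rather than by a sonority computation: prose sonority hierarchies
leave too many cluster judgments open (nasal-medial clusters, /s/-cluster
exceptions), and a closed list is reproducible and swappable for other
dialects. Sonority ranks are still carried in the phoneme inventory for
diagnostics. Syllabic consonants are not represented; final /əl/-type
sequences are schwa plus consonant.

Degenerate inputs: a vowel-less phoneme string is an error (nothing to
syllabify); a word-*initial* consonant run that is itself an illegal onset
(loanwords, onomatopoeia) is retained as the first onset and flagged with a
warning rather than rejected, since initial position leaves no earlier coda
to absorb it.

Positions are coded by a both-ends scheme with five categories —
word-initial, syllable-initial, syllable-medial, syllable-final,
word-final — applied in that priority order, so the first and last segments
of a word always take the word-anchored codes. This distinguishes mappings
that occur syllable-initially but never word-initially (PP in HA-PPY). A
single-segment word (the word A) is coded word-initial; the choice is
arbitrary but fixed, and such words are flagged. At the coarse grain,
onsets are word-initial or syllable-initial and rimes word-final or
syllable-final; every monosyllable's rime is word-final.

Three orthographic conventions require non-linear bookkeeping:

- **Silent-E graphemes** are discontinuous (A_E in BAKE): the grapheme
  takes the position of its head letters and the trailing E contributes no
  separate segment.
- **Non-linear E's** are word-final E's that *are* a vowel, /ə/ or /ʌ/,
  whose phonological order precedes the adjacent consonant (MUSCLE /mʌskəl/
  maps the /ə/ onto the E; contrast MUSSEL, whose /əl/ maps linearly onto
  EL). In the mapping notation they are written at their phonological slot
  with `~`.
- **The letter X** straddles syllables under the MOP (/tæk.si/); the whole
  X segment is pinned to the earlier syllable, parsing TAX-I, so its /ks/
  stays in the earlier rime and no /ks/-initial onset unit is emitted.

## Automatic alignment

`auto_align()` searches all segmentations of a spelling into graphemes
attested in a corpus-derived inventory whose concatenated phonemes equal
the pronunciation, treating silent-E, non-linear-E and X transitions
specially, then discards candidates using a mapping in a position where it
is unattested. Among the survivors it maximizes the product of inventory
attestation counts; remaining ties go to the parse with fewer segments
(grapheme parsimony), then to longer graphemes earlier in the word, then to
notation order — a fixed, deterministic cascade. The count-product score is
this package's convention: corpus-building work of this kind specifies
inventory parsimony but not how a single word's parse is chosen among
attested alternatives, and favoring well-attested mappings is the natural
experience-dependent choice. Failures return the furthest letter/phoneme
indices reached, the information needed to extend the inventory or annotate
manually.

The held-out diagnostic (`evaluate_generalization()`) holds out every
k-th record (k = 5 by default), rebuilds the inventory from the rest, and
reports the fraction of held-out records that auto-align — a measure of how
well a corpus generalizes to unseen words. On the small bundled
demonstration lexicon this rate is modest by construction: many of its
records are the sole carriers of a grapheme, so holding them out removes
the only evidence for their mappings. The rate is informative at realistic
corpus sizes, and rises already on a few hundred synthetic words (see
`scripts/acceptance.R`).

## Counting modes

The defining ratios read "number of words with …", but a word can contain
the same (unit, position) key twice with different mappings, and counting
*words* then breaks normalization: the consistencies of a grapheme's
alternatives need not sum to 1. The default mode therefore counts
*instances* (every occurrence), which guarantees `Σ p(P|G) = 1` exactly and
makes the marginal tables equal the sums of the joint table. A `words` mode
(each record increments a key at most once) is provided for literal
fidelity, and all tests of published values try both. Counts are stored
unsmoothed: zero means unattested, and measures over unattested
denominators are *undefined* (`NA`), never zero — undefineds are data,
excluded from summaries and tallied in `n_undefined`.

Log frequencies use base 10, undefined at count zero; `+1` smoothing is
deliberately off by default for transparency. Word summaries (mean, min,
max, sum) run over defined values only. Syllables without onsets contribute
no onset unit at all — neither a zero nor an undefined — so OOSH-type words
simply have fewer units. When two alternative parses of one pseudoword are
compared (`compare_pronunciations()`), undefined summaries rank last and
ties share a rank.

## The synthetic-lexicon generator

`generate_synthetic_corpus()` builds random aligned mini-lexicons for
testing. It draws phonemes from the real inventory and onsets from the real
whitelist (so position-restriction logic is exercised), and plants the
structural phenomena at configurable per-word rates: multi-letter and
doubled graphemes (never word-initial), discontinuous silent-E finals,
non-linear-E finals (consonant + /ə/ + /l/ spelled C-L-E), X clusters
(word-final, or vowel-flanked so the cluster straddles a boundary), and
homograph duplicates (same spelling, one mapping's phoneme swapped to an
alternative its grapheme supports). Default rates (0.12 silent-E, 0.08
non-linear-E, 0.06 X, 0.06 homograph, syllable counts 1–3 at 0.50/0.35/0.15)
are set once so that a modest corpus exercises every special-case code path
several times over; they are not calibrated to English.

What the generator does *not* emulate — realistic rime inventories, Zipfian
type frequencies, orthographic neighborhoods, stress — bounds what passing
tests show: they establish that counting, position coding and the measure
algebra are exact on structurally representative input, not that any value
generalizes to real English. Real-corpus claims require a real corpus.

Ground truth for tests comes from `oracle_counts()`, a deliberately naive
nested-loop counter with its own independent position-coding and
onset/rime derivation, kept separate from the production table builder so
that the two can disagree. The central test compares them key-by-key,
exactly, across many random corpora in both counting modes.

## Numerical and testing choices

All comparisons of counts are exact integer identities; consistency
normalization is asserted to `1e-12` (pure floating-point ratios of small
integers). The test suite runs at desk scale by design: 50 random corpora
of 20–80 words for the oracle property, 100–200 random phoneme strings for
the syllabification properties, and a 300-word synthetic lexicon for the
generalization rate in the acceptance script — sizes chosen so the full
suite completes in about a minute while every code path is exercised many
times.

One published figure leaves its averaging ambiguous (which of two phoneme
assignments a mean was computed over); the reproduction test therefore
checks both assignments and both counting modes and accepts a match under
any, recording the configuration. The composite onset/rime mean averages
over emitted units only (absent onsets excluded), consistent with the
treatment of onset-less syllables above.

## Limitations

- Consistency values depend entirely on the corpus supplied; the bundled
  117-word demonstration lexicon yields illustrative values only.
- The full published corpus is deposited externally and not
  redistributable here; the reproduction test for its printed values runs
  only when a local copy is supplied via `options(sublexr.osf_corpus=)`.
- The toolkit scores *given* parses; it assigns no probability to the
  parse itself (A-DANE versus A-DA-NE is the user's choice).
- Non-linear E handling covers the adjacent-consonant inversion (MUSCLE,
  ONE); the rarer two-consonant inversion (ONCE) is outside the model.
- One grapheme–phoneme alignment per (spelling, pronunciation) record;
  alternative alignments of the same pair are separate queries, not a
  distribution.
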