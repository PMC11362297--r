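Package: sublexr
Title: Sublexical Sound-Spelling Consistency and Frequency Measures for English
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A corpus-statistics engine for quantifying the regularity of English
    sound-spelling mappings. Parses phoneme-grapheme aligned lexicons, syllabifies
    pronunciations by the Maximum Onset Principle, assigns both-ends positional codes,
    and computes type-weighted frequency and bidirectional consistency measures
    (reading consistency p(P|G) and spelling consistency p(G|P)) at the phonographeme
    and onset/rime grain for any real word or pseudoword mapping. Includes an
    automatic letter-to-phoneme aligner driven by a corpus-derived grapheme inventory,
    a synthetic-lexicon generator with an independent counting oracle for testing,
    and a command-line interface for building tables, scoring words, and searching
    units by measure predicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
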