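# Mapping notation, automatic alignment, position coding, onset/rime units.

test_that("mapping notation parses the canonical records", {
  w <- parse_mapping_notation("WEIGH", "W>w|EIGH>eɪ")
  expect_length(w$segments, 2L)
  expect_identical(word_phonemes(w), c("w", "eɪ"))

  one <- parse_mapping_notation("ONE", "O>w|E~ʌ|N>n")
  expect_identical(word_phonemes(one), c("w", "ʌ", "n"))   # non-linear order
  expect_true(one$segments[[3]]$nonlinear)                 # E is last segment
  expect_identical(one$segments[[3]]$notation, "E")

  rogue <- parse_mapping_notation("ROGUE", "R>ɹ|O_E>oʊ|GU>g")
  expect_length(rogue$segments, 3L)
  expect_true(is_discontinuous(rogue$segments[[2]]$notation))

  muscle <- parse_mapping_notation("MUSCLE", "M>m|U>ʌ-S>s|C>k|E~ə|L>l")
  expect_identical(word_phonemes(muscle), c("m", "ʌ", "s", "k", "ə", "l"))
})

test_that("notation round-trips bit-exactly over every fixture record", {
  df <- demo_records()
  for (r in seq_len(nrow(df))) {
    w <- parse_mapping_notation(df$spelling[r], df$mapping[r],
                                pron_id = as.integer(df$pron_id[r]))
    expect_identical(format_mapping_notation(w), df$mapping[r])
    expect_identical(paste(word_phonemes(w), collapse = ""),
                     df$pronunciation[r])
  }
})

test_that("malformed records yield structured validation errors", {
  expect_error(parse_mapping_notation("CAT", "C>k|A>æ"), "spell")
  expect_error(parse_mapping_notation("CAT", "C>k|A>æ|T>t|S>s"), "spell")
  expect_error(parse_mapping_notation("STS", "S>s|T>t|S>s"), "no vowel")
  expect_error(parse_mapping_notation("CAT", "C>k||T>t"), "empty segment")
  expect_error(parse_mapping_notation("CAT", "C>k|A>æ|T>"), "malformed")
  # notated boundary contradicting the MOP
  expect_error(parse_mapping_notation("HAPPY", "H>h|A>æ|PP>p-Y>i"),
               "inconsistent with MOP")
  # two-phoneme segments only for X
  expect_error(segment("QU", c("k", "w")), "graphemes containing X")
})

test_that("auto-alignment recovers the attested parses", {
  inv <- demo_inventory()
  guess <- auto_align("GUESS", "gɛs", inv)
  expect_identical(format_mapping_notation(guess), "GU>g|E>ɛ|SS>s")

  taxi <- auto_align("TAXI", "tæksi", inv)
  expect_identical(format_mapping_notation(taxi), "T>t|A>æ|X>ks-I>i")
  expect_identical(taxi$seg_syllable, c(1L, 1L, 1L, 2L))  # X in syllable 1

  muscle <- auto_align("MUSCLE", "mʌskəl", inv)
  expect_true(muscle$segments[[6]]$nonlinear)
  expect_identical(muscle$segments[[6]]$phonemes, "ə")

  cat_ <- auto_align("CAT", "kæt", inv)
  expect_identical(format_mapping_notation(cat_), "C>k|A>æ|T>t")
})

test_that("auto-alignment failures report the furthest-reached indices", {
  inv <- demo_inventory()
  fail <- auto_align("QUIZ", "kwɪz", inv)   # Q unattested in the demo corpus
  expect_s3_class(fail, "sublex_align_failure")
  expect_false(fail$success)
  expect_identical(fail$furthest_letters, 0L)
  # positionally inadmissible: PP never occurs word-initially
  fail2 <- auto_align("PPAT", "pæt", inv)
  expect_s3_class(fail2, "sublex_align_failure")
})

test_that("alignment soundness: successful alignments cover letters and
           phonemes exactly", {
  inv <- demo_inventory()
  for (w in demo_words()[seq(1, 117, by = 7)]) {
    res <- auto_align(w$spelling, word_phonemes(w), inv)
    expect_s3_class(res, "sublex_word")
    expect_identical(res$spelling, w$spelling)
    expect_identical(word_phonemes(res), word_phonemes(w))
  }
})

test_that("positions follow the five-category both-ends scheme", {
  happy <- parse_mapping_notation("HAPPY", "H>h|A>æ-PP>p|Y>i")
  expect_identical(happy$positions,
                   c("word_initial", "syllable_final", "syllable_initial",
                     "word_final"))
  # the demo corpus attests PP only away from the word edge
  expect_false(inventory_admits(demo_inventory(), "PP", "p", "word_initial"))
  expect_true(inventory_admits(demo_inventory(), "PP", "p",
                               "syllable_initial"))

  mono <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>s")
  expect_identical(mono$positions[3], "syllable_medial")   # EA_E mid-syllable
  di <- parse_mapping_notation("BLEASE", "B>b|L>l|EA>i-S>s|E>eɪ")
  expect_identical(di$positions[5], "word_final")          # final E
  expect_identical(di$positions[4], "syllable_initial")

  a <- assign_positions(aligned_word("A", list(segment("A", "eɪ"))))
  expect_identical(a$positions, "word_initial")            # single segment
  expect_true("single_segment" %in% a$flags)
})

test_that("onset/rime units carry the two-way position codes", {
  blease <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>z")
  or <- derive_onset_rime_units(blease)
  expect_identical(or$type, c("onset", "rime"))
  expect_identical(or$grapheme, c("BL", "EASE"))
  expect_identical(or$phoneme, c("bl", "iz"))
  expect_identical(or$position, c("onset_word_initial", "rime_word_final"))

  adane <- parse_mapping_notation("ADANE", "A>æ-D>d|A_E>eɪ|N>n")
  or2 <- derive_onset_rime_units(adane)
  expect_identical(or2$grapheme, c("A", "D", "ANE"))
  expect_identical(or2$phoneme, c("æ", "d", "eɪn"))
  expect_identical(or2$position, c("rime_syllable_final",
                                   "onset_syllable_initial",
                                   "rime_word_final"))

  taxi <- parse_mapping_notation("TAXI", "T>t|A>æ|X>ks-I>i")
  or3 <- derive_onset_rime_units(taxi)
  # the X cluster stays in the earlier syllable's rime; no /ks/ onset unit
  expect_identical(or3$grapheme[or3$type == "rime"], c("AX", "I"))
  expect_identical(or3$phoneme[or3$type == "rime"], c("æks", "i"))
  expect_false(any(or3$type == "onset" & or3$syllable == 2))

  oosh <- assign_positions(aligned_word("OOSH", list(segment("OO", "u"),
                                                     segment("SH", "ʃ"))))
  or4 <- derive_onset_rime_units(oosh)
  expect_identical(or4$type, "rime")     # no onset unit is emitted
})

test_that("every syllable yields exactly one rime and every segment one
           position", {
  for (w in demo_words()) {
    expect_false(any(is.na(w$positions)))
    expect_true(all(w$positions %in% c("word_initial", "syllable_initial",
                                       "syllable_medial", "syllable_final",
                                       "word_final")))
    or <- derive_onset_rime_units(w)
    expect_identical(sum(or$type == "rime"), max(w$seg_syllable))
    expect_true(all(table(or$syllable[or$type == "onset"]) <= 1))
  }
})

test_that("inventory closure: every corpus segment is in the corpus-built
           inventory", {
  inv <- demo_inventory()
  for (w in demo_words()) {
    for (k in seq_along(w$segments)) {
      s <- w$segments[[k]]
      expect_true(inventory_admits(inv, s$notation,
                                   paste(s$phonemes, collapse = ""),
                                   w$positions[k]))
    }
  }
})

test_that("inventory TSV export/import round-trips", {
  inv <- demo_inventory()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_inventory(inv, path)
  inv2 <- read_inventory(path)
  expect_identical(as.data.frame(inv)[order(inv$grapheme, inv$phoneme), ],
                   as.data.frame(inv2)[order(inv2$grapheme, inv2$phoneme), ],
                   ignore_attr = TRUE)
})
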