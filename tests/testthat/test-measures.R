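# The consistency and frequency measures, word scoring, pronunciation ranking.

test_that("a sole mapping has consistency 1 and a split is a proper ratio", {
  tab <- demo_tables()
  # CK -> /k/ is the only pronunciation of word-final CK in the demo corpus
  expect_identical(reading_consistency(tab, "CK", "k", "word_final"), 1)
  # word-final S splits between /s/ and /z/
  s_s <- reading_consistency(tab, "S", "s", "word_final")
  s_z <- reading_consistency(tab, "S", "z", "word_final")
  expect_equal(s_s + s_z, 1)
  expect_true(s_z > s_s)     # the demo corpus has a /z/ majority, like English
  # unattested grapheme/position: undefined, not zero
  expect_true(is.na(reading_consistency(tab, "ZZ", "z", "word_final")))
  expect_true(is.na(spelling_consistency(tab, "GE", "ʒ", "word_final")))
  expect_error(reading_consistency(tab, "S", "s", "nowhere"),
               "unknown position")
})

test_that("phonographeme frequency is direction-symmetric and ties the
           consistency to the marginal", {
  tab <- demo_tables()
  mt <- measure_table(tab, "phonographeme")
  for (r in seq_len(nrow(mt))) {
    f1 <- phonographeme_frequency(tab, mt$grapheme[r], mt$phoneme[r],
                                  mt$position[r])
    expect_identical(f1, mt$phonographeme_freq[r])
    # p(P|G) * grapheme frequency recovers the joint count exactly
    expect_equal(mt$reading_consistency[r] * mt$grapheme_freq[r], f1)
    expect_equal(mt$spelling_consistency[r] * mt$phoneme_freq[r], f1)
  }
})

test_that("consistency normalizes to 1 over alternatives in instances mode", {
  for (grain in c("phonographeme", "onset_rime")) {
    mt <- measure_table(demo_tables(), grain)
    gkeys <- if (grain == "phonographeme") c("grapheme", "position") else
      c("type", "grapheme", "position")
    pkeys <- if (grain == "phonographeme") c("phoneme", "position") else
      c("type", "phoneme", "position")
    rsum <- aggregate(mt$reading_consistency, mt[gkeys], sum)
    expect_true(all(abs(rsum$x - 1) < 1e-12))
    ssum <- aggregate(mt$spelling_consistency, mt[pkeys], sum)
    expect_true(all(abs(ssum$x - 1) < 1e-12))
  }
})

test_that("unit and log frequencies query the marginals", {
  tab <- demo_tables()
  expect_identical(unit_frequency(tab, "grapheme", "PP", "syllable_initial"),
                   2L)   # HAPPY, APPLE
  expect_identical(log_frequency(tab, "grapheme", "RH", "word_initial"), 0)
  expect_true(is.na(log_frequency(tab, "grapheme", "RH", "word_final")))
  expect_identical(unit_frequency(tab, "grapheme", "EASE", "rime_word_final"),
                   7L)   # the -EASE family
  expect_identical(unit_frequency(tab, "phoneme", "iz", "rime_word_final"),
                   4L)   # PLEASE TEASE EASE CHEESE
})

test_that("scoring a word yields per-segment measures and summaries over
           defined values only", {
  tab <- demo_tables()
  w <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>z")
  sc <- score_word(w, tab, "phonographeme")
  expect_identical(nrow(sc$units), 4L)
  rc <- sc$units$reading_consistency
  expect_true(all(rc >= 0 & rc <= 1, na.rm = TRUE))
  direct <- mean(rc, na.rm = TRUE)
  expect_equal(score_summary(sc, "reading_consistency", "mean"), direct)
  expect_equal(score_summary(sc, "reading_consistency", "min"),
               min(rc, na.rm = TRUE))
  # onset/rime grain of the same word has one onset + one rime unit
  sc2 <- score_word(w, tab, "onset_rime")
  expect_identical(nrow(sc2$units), 2L)

  # a wholly unattested pseudoword: all summaries undefined, all units tallied
  zz <- assign_positions(aligned_word("VOYZZ", list(
    segment("V", "v"), segment("OY", "ɔɪ"), segment("ZZ", "z"))))
  sc3 <- score_word(zz, tab, "phonographeme")
  row <- sc3$summary[sc3$summary$measure == "reading_consistency", ]
  expect_true(is.na(row$mean))
  expect_identical(row$n_undefined, 3L)
  expect_identical(row$n_defined, 0L)
})

test_that("pronunciation ranking reverses across grains for BLEASE-type
           items, matching direct means", {
  tab <- demo_tables()
  bliz <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>z")
  blis <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>s")
  for (grain in c("phonographeme", "onset_rime")) {
    cmp <- compare_pronunciations(list(bliz, blis), tab, grain)
    means <- vapply(list(bliz, blis), function(w)
      score_summary(score_word(w, tab, grain)), 0)
    expect_identical(cmp$value[cmp$rank == 1],
                     max(means))
  }
  # the demo corpus is built so the preference reverses across grains, the
  # hallmark dissociation between segment-level and rime-level regularity
  pg <- compare_pronunciations(list(bliz, blis), tab, "phonographeme")
  or <- compare_pronunciations(list(bliz, blis), tab, "onset_rime")
  expect_identical(pg$pronunciation[pg$rank == 1], "bliz")
  expect_identical(or$pronunciation[or$rank == 1], "blis")
})

test_that("ranking handles single candidates, ties and undefineds", {
  tab <- demo_tables()
  w <- parse_mapping_notation("CAT", "C>k|A>æ|T>t")
  expect_identical(compare_pronunciations(list(w), tab)$rank, 1L)
  expect_error(compare_pronunciations(list(), tab), "empty")
  expect_error(compare_pronunciations(
    list(w, parse_mapping_notation("COT", "C>k|O>ɑ|T>t")), tab),
    "share one spelling")
  # identical candidates tie at rank 1
  w2 <- parse_mapping_notation("CAT", "C>k|A>æ|T>t", pron_id = 2L)
  cmp <- compare_pronunciations(list(w, w2), tab)
  expect_identical(cmp$rank, c(1L, 1L))
  # an unattested candidate ranks last
  zz <- assign_positions(aligned_word("CAT", list(
    segment("C", "tʃ"), segment("A", "ɔɪ"), segment("T", "ð"))))
  cmp2 <- compare_pronunciations(list(w, zz), tab)
  expect_identical(cmp2$rank[cmp2$pronunciation == "tʃɔɪð"], 2L)
})

test_that("adding a word never decreases a phonographeme frequency", {
  words <- demo_words()
  tab <- build_count_tables(words)
  plus <- build_count_tables(c(words, list(
    parse_mapping_notation("SEAT", "S>s|EA>i|T>t"))))
  mt <- measure_table(tab, "phonographeme")
  for (r in seq(1, nrow(mt), by = 11)) {
    expect_true(phonographeme_frequency(plus, mt$grapheme[r], mt$phoneme[r],
                                        mt$position[r]) >=
                  mt$phonographeme_freq[r])
  }
  expect_identical(
    phonographeme_frequency(plus, "EA", "i", "syllable_medial"),
    phonographeme_frequency(tab, "EA", "i", "syllable_medial") + 1L)
})
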