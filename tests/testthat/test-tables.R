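# Position-keyed type-weighted count tables.

three_word_corpus <- function() {
  list(parse_mapping_notation("ROGUE", "R>ɹ|O_E>oʊ|GU>g"),
       parse_mapping_notation("GUESS", "GU>g|E>ɛ|SS>s"),
       parse_mapping_notation("GONE", "G>g|O_E>ɔ|N>n"))
}

test_that("direct counts: shared word-initial mapping counted per record", {
  words <- list(parse_mapping_notation("CAT", "C>k|A>æ|T>t"),
                parse_mapping_notation("COT", "C>k|O>ɑ|T>t"))
  tab <- build_count_tables(words)
  expect_identical(phonographeme_frequency(tab, "C", "k", "word_initial"), 2L)
  expect_identical(phonographeme_frequency(tab, "C", "s", "word_initial"), 0L)
  expect_identical(tab$n_words, 2L)
})

test_that("ROGUE, GUESS and GONE share a minimal grapheme inventory", {
  tab <- build_count_tables(three_word_corpus())
  # the parsimonious parse: GU and O_E are reused across the three words, so
  # no GUE, UE or O_UE grapheme is ever needed; E carries GUESS's /ɛ/
  expect_setequal(unique(tab$phonographeme$grapheme),
                  c("R", "O_E", "GU", "E", "SS", "G", "N"))
  expect_false(any(c("GUE", "UE", "O_UE") %in% tab$phonographeme$grapheme))
})

test_that("duplicate (spelling, pron_id) records are rejected", {
  w <- parse_mapping_notation("CAT", "C>k|A>æ|T>t")
  expect_error(build_count_tables(list(w, w)), "duplicate")
  # same spelling, distinct pron_id is a homograph and is fine
  w2 <- parse_mapping_notation("CAT", "C>k|A>æ|T>t", pron_id = 2L)
  expect_identical(build_count_tables(list(w, w2))$n_words, 2L)
})

test_that("merging disjoint builds equals building the concatenation", {
  words <- demo_words()
  a <- build_count_tables(words[1:50])
  b <- build_count_tables(words[51:length(words)])
  merged <- merge_tables(a, b)
  full <- build_count_tables(words)
  for (nm in c("phonographeme", "grapheme", "phoneme", "or_joint",
               "or_grapheme", "or_phoneme")) {
    expect_identical(merged[[nm]], full[[nm]])
  }
  expect_identical(merged$n_words, full$n_words)
  # merging never decreases a key
  expect_true(all(merge(a$phonographeme, merged$phonographeme,
                        by = c("grapheme", "phoneme", "position"),
                        suffixes = c("_a", "_m"))$count_m >=
                  merge(a$phonographeme, merged$phonographeme,
                        by = c("grapheme", "phoneme", "position"),
                        suffixes = c("_a", "_m"))$count_a))
})

test_that("mode mismatch refuses to merge", {
  words <- demo_words()
  a <- build_count_tables(words[1:10], mode = "instances")
  b <- build_count_tables(words[11:20], mode = "words")
  expect_error(merge_tables(a, b), "counting modes")
})

test_that("counts are invariant to corpus record order", {
  words <- demo_words()
  set.seed(99)
  shuffled <- words[sample(seq_along(words))]
  expect_identical(build_count_tables(words)$phonographeme,
                   build_count_tables(shuffled)$phonographeme)
  expect_identical(build_count_tables(words)$or_joint,
                   build_count_tables(shuffled)$or_joint)
})

test_that("words-mode counts never exceed instances-mode counts", {
  corp <- generate_synthetic_corpus(synth_spec(seed = 11, n_words = 80))
  ti <- build_count_tables(corp$words, mode = "instances")
  tw <- build_count_tables(corp$words, mode = "words")
  for (nm in c("phonographeme", "grapheme", "phoneme", "or_joint")) {
    keys <- setdiff(names(ti[[nm]]), "count")
    m <- merge(tw[[nm]], ti[[nm]], by = keys, suffixes = c("_w", "_i"))
    expect_identical(nrow(m), nrow(tw[[nm]]))   # same attested keys
    expect_true(all(m$count_w <= m$count_i))
  }
})

test_that("marginal identities hold exactly in instances mode", {
  tab <- demo_tables()
  pg <- tab$phonographeme
  gsum <- aggregate(count ~ grapheme + position, pg, sum)
  m <- merge(gsum, tab$grapheme, by = c("grapheme", "position"))
  expect_identical(nrow(m), nrow(tab$grapheme))
  expect_true(all(m$count.x == m$count.y))
  psum <- aggregate(count ~ phoneme + position, pg, sum)
  m2 <- merge(psum, tab$phoneme, by = c("phoneme", "position"))
  expect_true(all(m2$count.x == m2$count.y))
  # same at the onset/rime grain
  osum <- aggregate(count ~ type + grapheme + position, tab$or_joint, sum)
  m3 <- merge(osum, tab$or_grapheme, by = c("type", "grapheme", "position"))
  expect_true(all(m3$count.x == m3$count.y))
})

test_that("tables artifact round-trips through TSV", {
  tab <- build_count_tables(three_word_corpus(), version = "v-test")
  dir <- withr::local_tempdir()
  write_tables(tab, dir)
  tab2 <- read_tables(dir)
  expect_identical(tab2$phonographeme, tab$phonographeme)
  expect_identical(tab2$n_words, tab$n_words)
  expect_identical(tab2$mode, tab$mode)
  expect_identical(tab2$version, "v-test")
})
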