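# Shared fixtures: the bundled demonstration lexicon, parsed once per run.

.demo_cache <- new.env(parent = emptyenv())

demo_words <- function() {
  if (is.null(.demo_cache$words)) {
    .demo_cache$words <- read_corpus(demo_lexicon_path())
  }
  .demo_cache$words
}

demo_tables <- function(mode = "instances") {
  key <- paste0("tables_", mode)
  if (is.null(.demo_cache[[key]])) {
    .demo_cache[[key]] <- build_count_tables(demo_words(), mode = mode)
  }
  .demo_cache[[key]]
}

demo_inventory <- function() {
  if (is.null(.demo_cache$inv)) {
    .demo_cache$inv <- build_inventory(demo_words())
  }
  .demo_cache$inv
}

# raw mapping strings of the demo lexicon (for round-trip tests)
demo_records <- function() {
  df <- utils::read.delim(demo_lexicon_path(), comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character")
  df
}

# random phoneme strings containing at least one vowel
random_phoneme_strings <- function(n, seed, min_len = 2L, max_len = 8L) {
  set.seed(seed)
  inv <- phoneme_inventory()
  vowels <- inv$symbol[inv$klass == "vowel"]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(min_len:max_len, 1L)
    ph <- sample(inv$symbol, len, replace = TRUE)
    if (!any(ph %in% vowels)) ph[sample(len, 1L)] <- sample(vowels, 1L)
    out[[i]] <- ph
  }
  out
}

# naive count-and-divide measure check for one joint key of a table set
naive_measure_check <- function(tables, grain = "phonographeme") {
  if (grain == "phonographeme") {
    joint <- tables$phonographeme; gm <- tables$grapheme; pm <- tables$phoneme
    gsel <- function(r) gm$grapheme == joint$grapheme[r] &
      gm$position == joint$position[r]
    psel <- function(r) pm$phoneme == joint$phoneme[r] &
      pm$position == joint$position[r]
  } else {
    joint <- tables$or_joint; gm <- tables$or_grapheme; pm <- tables$or_phoneme
    gsel <- function(r) gm$type == joint$type[r] &
      gm$grapheme == joint$grapheme[r] & gm$position == joint$position[r]
    psel <- function(r) pm$type == joint$type[r] &
      pm$phoneme == joint$phoneme[r] & pm$position == joint$position[r]
  }
  data.frame(
    reading = joint$count / vapply(seq_len(nrow(joint)),
                                   function(r) sum(gm$count[gsel(r)]), 0),
    spelling = joint$count / vapply(seq_len(nrow(joint)),
                                    function(r) sum(pm$count[psel(r)]), 0),
    freq = joint$count)
}
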