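# Both-ends position coding at the phonographeme and onset/rime grain.

PHONOGRAPHEME_POSITIONS <- c("word_initial", "syllable_initial",
                             "syllable_medial", "syllable_final",
                             "word_final")
ONSET_RIME_POSITIONS <- c("onset_word_initial", "onset_syllable_initial",
                          "rime_word_final", "rime_syllable_final")

#' Assign both-ends position codes to the segments of a word
#'
#' Five-category scheme anchored to the word's ends: the first segment of the
#' word is `word_initial` and the last `word_final`; the first segment of a
#' non-initial syllable is `syllable_initial`, the last segment of a non-final
#' syllable `syllable_final`; everything else is `syllable_medial`. A
#' discontinuous silent-E grapheme takes the position of its head letters. A
#' single-segment word is coded `word_initial` (and flagged).
#'
#' @param word a `sublex_word`.
#' @return the word with its `positions` field filled in.
#' @export
#' @examples
#' w <- parse_mapping_notation("HAPPY", "H>h|A>æ-PP>p|Y>i")
#' w$positions   # PP is syllable_initial, not word_initial
assign_positions <- function(word) {
  stopifnot(inherits(word, "sublex_word"))
  n <- length(word$segments)
  syl <- word$seg_syllable
  n_syl <- max(syl)
  pos <- character(n)
  for (i in seq_len(n)) {
    first_of_syl <- i == 1L || syl[i] != syl[i - 1L]
    last_of_syl <- i == n || syl[i] != syl[i + 1L]
    pos[i] <- if (i == 1L) {
      "word_initial"
    } else if (i == n) {
      "word_final"
    } else if (first_of_syl && syl[i] > 1L) {
      "syllable_initial"
    } else if (last_of_syl && syl[i] < n_syl) {
      "syllable_final"
    } else {
      "syllable_medial"
    }
  }
  word$positions <- pos
  if (n == 1L) word$flags <- union(word$flags, "single_segment")
  word
}

# phonological start index of each segment (into word_phonemes(word))
segment_phoneme_starts <- function(segments) {
  ord <- phonological_order(segments)
  lens <- vapply(segments, function(s) length(s$phonemes), 0L)
  starts_in_ord <- cumsum(c(1L, lens[ord]))[seq_along(ord)]
  starts <- integer(length(segments))
  starts[ord] <- starts_in_ord
  starts
}

# orthographic letter string of a subset of segments (trailing silent E
# inserted after the next segment when that segment is in the subset,
# otherwise kept as the "_E" notation)
unit_grapheme_string <- function(segments) {
  out <- character(0)
  pending <- FALSE
  for (seg in segments) {
    out <- c(out, grapheme_head(seg$notation))
    if (pending) {
      out <- c(out, "E")
      pending <- FALSE
    }
    if (is_discontinuous(seg$notation)) pending <- TRUE
  }
  s <- paste(out, collapse = "")
  if (pending) s <- paste0(s, "_E")
  s
}

#' Decompose a word into onset and rime units
#'
#' Per syllable, emits one onset unit (absent when the syllable has no onset
#' consonants) and exactly one rime unit (nucleus plus coda), each carrying
#' its grapheme string, phoneme string, and onset/rime position code. Onsets
#' are `onset_word_initial` (first syllable) or `onset_syllable_initial`;
#' rimes are `rime_word_final` (last syllable, including all monosyllables)
#' or `rime_syllable_final`. The phonemes of an X cluster stay in the earlier
#' syllable's rime.
#'
#' @param word a position-assigned `sublex_word`.
#' @return a data.frame with columns `syllable`, `type` (`onset`/`rime`),
#'   `grapheme`, `phoneme`, `position`.
#' @export
#' @examples
#' w <- parse_mapping_notation("BLEASE", "B>b|L>l|EA_E>i|S>z")
#' derive_onset_rime_units(w)
derive_onset_rime_units <- function(word) {
  stopifnot(inherits(word, "sublex_word"))
  segs <- word$segments
  syl <- word$seg_syllable
  n_syl <- max(syl)
  starts <- segment_phoneme_starts(segs)
  rows <- list()
  for (s in seq_len(n_syl)) {
    idx <- which(syl == s)                       # orthographic order
    # nucleus: the (unique) vowel-bearing segment of the syllable
    vowelful <- idx[vapply(segs[idx], function(g) any(is_vowel(g$phonemes)),
                           TRUE)]
    nucleus_start <- starts[vowelful]
    # phonological role: onset segments are those whose phonemes all precede
    # the nucleus vowel in phonological time
    onset_idx <- idx[starts[idx] < nucleus_start]
    rime_idx <- idx[starts[idx] >= nucleus_start]
    if (length(onset_idx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        syllable = s, type = "onset",
        grapheme = unit_grapheme_string(segs[onset_idx]),
        phoneme = paste(unlist(lapply(
          segs[onset_idx][order(starts[onset_idx])],
          function(g) g$phonemes)), collapse = ""),
        position = if (s == 1L) "onset_word_initial"
                   else "onset_syllable_initial",
        stringsAsFactors = FALSE)
    }
    rime_phon_order <- rime_idx[order(starts[rime_idx])]
    rows[[length(rows) + 1L]] <- data.frame(
      syllable = s, type = "rime",
      grapheme = unit_grapheme_string(segs[rime_idx]),
      phoneme = paste(unlist(lapply(segs[rime_phon_order],
                                    function(g) g$phonemes)), collapse = ""),
      position = if (s == n_syl) "rime_word_final" else "rime_syllable_final",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
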