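# Aligned words: spelling/pronunciation pairs decomposed into ordered
# phoneme-grapheme segments with syllable spans and position codes.

GRAPHEME_RE <- "^[A-Z]+(_E)?$"

is_discontinuous <- function(notation) grepl("_", notation, fixed = TRUE)

grapheme_head <- function(notation) sub("_E$", "", notation)

#' Construct an aligned segment
#'
#' One phoneme-grapheme pairing within a word: a grapheme (possibly
#' discontinuous, e.g. `"A_E"`) mapped to one phoneme -- or to two phonemes in
#' the single exceptional case of X-graphemes representing a consonant cluster
#' (/ks/, /gz/, ...). A `nonlinear` segment is a word-final E realizing /ə/ or
#' /ʌ/ whose phonological order precedes the adjacent consonant (as in MUSCLE
#' or ONE).
#'
#' @param notation grapheme notation: uppercase letters, with `_E` marking a
#'   discontinuous silent-E grapheme (e.g. `"EA_E"`).
#' @param phonemes character vector of phoneme symbols (length 1; length 2
#'   only for X-cluster graphemes).
#' @param nonlinear logical.
#' @return an object of class `sublex_segment`.
#' @export
segment <- function(notation, phonemes, nonlinear = FALSE) {
  if (!grepl(GRAPHEME_RE, notation)) {
    stop("invalid grapheme notation: \"", notation, "\"", call. = FALSE)
  }
  phonemes <- tokenize_phonemes(phonemes)
  check_phonemes(phonemes)
  if (!length(phonemes) %in% 1:2) {
    stop("a segment maps to one phoneme (two only for X clusters)",
         call. = FALSE)
  }
  if (length(phonemes) == 2L && !grepl("X", notation, fixed = TRUE)) {
    stop("two-phoneme segments are only admissible for graphemes containing X",
         call. = FALSE)
  }
  if (length(phonemes) == 2L && !x_cluster_ok(phonemes)) {
    stop("/", paste(phonemes, collapse = ""),
         "/ is not an admissible X cluster", call. = FALSE)
  }
  if (nonlinear && !(notation == "E" && phonemes[1] %in% c("ə", "ʌ"))) {
    stop("non-linear segments must be the grapheme E mapping to /ə/ or /ʌ/",
         call. = FALSE)
  }
  structure(list(notation = notation, phonemes = phonemes,
                 nonlinear = nonlinear),
            class = "sublex_segment")
}

#' Admissible X clusters
#'
#' The phoneme clusters a grapheme containing the letter X may represent,
#' read from an editable plain-text table.
#'
#' @param path optional alternative config file.
#' @return list of character vectors.
#' @export
x_clusters <- function(path = NULL) {
  parse_file <- function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lapply(lines[nzchar(lines)], function(l) strsplit(l, "\\s+")[[1]])
  }
  if (is.null(path)) {
    if (is.null(.sublexr_env$xclusters)) {
      .sublexr_env$xclusters <- parse_file(config_path("x_clusters.txt"))
    }
    return(.sublexr_env$xclusters)
  }
  parse_file(path)
}

x_cluster_ok <- function(phonemes) {
  key <- paste(phonemes, collapse = " ")
  key %in% vapply(x_clusters(), paste, "", collapse = " ")
}

# order of segments in phonological time: orthographic order with each
# non-linear E swapped before its (orthographically preceding) consonant
phonological_order <- function(segments) {
  ord <- seq_along(segments)
  for (k in seq_along(segments)) {
    if (isTRUE(segments[[k]]$nonlinear) && k > 1L) {
      ord[c(k - 1L, k)] <- ord[c(k, k - 1L)]
    }
  }
  ord
}

# spelling implied by the segments (inserting trailing E's of discontinuous
# graphemes after the following grapheme)
reconstruct_spelling <- function(segments) {
  out <- character(0)
  pending <- FALSE
  for (seg in segments) {
    if (pending && is_discontinuous(seg$notation)) {
      stop("overlapping discontinuous graphemes", call. = FALSE)
    }
    out <- c(out, grapheme_head(seg$notation))
    if (pending) {
      out <- c(out, "E")
      pending <- FALSE
    }
    if (is_discontinuous(seg$notation)) pending <- TRUE
  }
  if (pending) {
    stop("discontinuous grapheme has no following grapheme to host its E",
         call. = FALSE)
  }
  paste(out, collapse = "")
}

#' Construct an aligned word
#'
#' Builds and validates the central data structure: a spelling decomposed into
#' ordered phoneme-grapheme segments (orthographic order) together with the
#' partition of segments into syllables. Validation asserts that the segments
#' reproduce the spelling exactly, that the phonemes in phonological order
#' (honoring non-linear inversions and X clusters) form the pronunciation,
#' that every syllable bears exactly one vowel, and (optionally) that the
#' syllable spans agree with Maximum-Onset-Principle syllabification of the
#' pronunciation with the X-to-earlier-syllable override.
#'
#' @param spelling uppercase letter string.
#' @param segments list of [segment()] objects in orthographic order.
#' @param seg_syllable integer vector: syllable index of each segment. If
#'   `NULL`, spans are derived from MOP syllabification.
#' @param pron_id integer distinguishing multiple pronunciations of one
#'   spelling.
#' @param check_mop assert MOP consistency of the spans (default `TRUE`).
#' @return an object of class `sublex_word` with `positions` unset (see
#'   [assign_positions()]).
#' @export
aligned_word <- function(spelling, segments, seg_syllable = NULL,
                         pron_id = 1L, check_mop = TRUE) {
  stopifnot(is.character(spelling), length(spelling) == 1L)
  spelling <- toupper(spelling)
  if (!all(vapply(segments, inherits, TRUE, "sublex_segment"))) {
    stop("segments must be a list of sublex_segment objects", call. = FALSE)
  }
  rec <- reconstruct_spelling(segments)
  if (rec != spelling) {
    stop("segments spell \"", rec, "\", not \"", spelling, "\"",
         call. = FALSE)
  }
  nl <- vapply(segments, function(s) isTRUE(s$nonlinear), TRUE)
  if (any(nl) && (sum(nl) > 1L || which(nl) != length(segments))) {
    stop("a non-linear E must be the single word-final segment", call. = FALSE)
  }
  ph <- word_phonemes_from_segments(segments)
  mop_syl <- derived_seg_syllable(segments)
  if (is.null(seg_syllable)) {
    seg_syllable <- mop_syl
  } else {
    seg_syllable <- as.integer(seg_syllable)
    if (length(seg_syllable) != length(segments)) {
      stop("seg_syllable must have one entry per segment", call. = FALSE)
    }
    if (check_mop && !identical(seg_syllable, mop_syl)) {
      stop("syllable spans of \"", spelling,
           "\" are inconsistent with MOP syllabification (expected ",
           paste(mop_syl, collapse = ","), ", got ",
           paste(seg_syllable, collapse = ","), ")", call. = FALSE)
    }
  }
  if (is.unsorted(seg_syllable) || seg_syllable[1L] != 1L ||
      any(diff(unique(seg_syllable)) != 1L)) {
    stop("seg_syllable must partition segments into consecutive syllables",
         call. = FALSE)
  }
  # exactly one vowel-bearing segment per syllable
  vowelful <- vapply(segments, function(s) any(is_vowel(s$phonemes)), TRUE)
  for (s in unique(seg_syllable)) {
    nv <- sum(vowelful[seg_syllable == s])
    if (nv != 1L) {
      stop("syllable ", s, " of \"", spelling, "\" has ", nv,
           " vowel-bearing segments (needs exactly 1)", call. = FALSE)
    }
  }
  structure(list(spelling = spelling, segments = segments,
                 seg_syllable = seg_syllable,
                 positions = rep(NA_character_, length(segments)),
                 pron_id = as.integer(pron_id),
                 flags = character(0)),
            class = "sublex_word")
}

word_phonemes_from_segments <- function(segments) {
  unlist(lapply(segments[phonological_order(segments)],
                function(s) s$phonemes))
}

#' Pronunciation of an aligned word
#'
#' Phonemes in phonological order (non-linear E's precede their adjacent
#' consonant; X clusters expand to their two phonemes).
#'
#' @param word a `sublex_word`.
#' @return character vector of phoneme symbols.
#' @export
word_phonemes <- function(word) {
  stopifnot(inherits(word, "sublex_word"))
  word_phonemes_from_segments(word$segments)
}

# syllable index per segment from MOP syllabification of the pronunciation,
# with the X-cluster override (X segments pinned to the earlier syllable)
derived_seg_syllable <- function(segments) {
  ord <- phonological_order(segments)
  lens <- vapply(segments, function(s) length(s$phonemes), 0L)
  ph <- word_phonemes_from_segments(segments)
  ph_syl <- phoneme_syllable_map(ph)
  # phonological index range of each segment
  starts <- cumsum(c(1L, lens[ord]))[seq_along(ord)]
  seg_syl <- integer(length(segments))
  for (k in seq_along(ord)) {
    seg <- ord[k]
    idx <- starts[k]:(starts[k] + lens[seg] - 1L)
    seg_syl[seg] <- min(ph_syl[idx])  # X override: earlier syllable wins
  }
  seg_syl
}
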