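# The mapping notation: a plain-text serialization of phoneme-grapheme
# alignments.
#
# A mapping string lists `GRAPHEME>phoneme` pairs in phonological order,
# separated by `|`, with syllable boundaries marked `-`. A non-linear E is
# written `E~phoneme` (it appears at its phonological slot, before the
# consonant that orthographically precedes it). Discontinuous silent-E
# graphemes carry an underscore (`A_E`), and X clusters write both phonemes
# (`X>ks`). Examples:
#   WEIGH   W>w|EIGH>eɪ
#   ONE     O>w|E~ʌ|N>n
#   ROGUE   R>ɹ|O_E>oʊ|GU>g
#   MUSCLE  M>m|U>ʌ|S>s-C>k|E~ə|L>l
#   TAXI    T>t|A>æ|X>ks-I>i

#' Parse a mapping-notation record into an aligned word
#'
#' @param spelling the word's spelling.
#' @param mapping the mapping string (see package notation; `>` separates a
#'   grapheme from its phoneme(s), `|` separates segments, `-` marks syllable
#'   boundaries, `~` marks a non-linear E, `_` marks the silent-E gap).
#' @param pron_id integer distinguishing multiple pronunciations.
#' @param check_mop assert that the notated syllable boundaries agree with
#'   MOP syllabification (with the X override).
#' @return a validated `sublex_word` (positions assigned).
#' @export
#' @examples
#' w <- parse_mapping_notation("WEIGH", "W>w|EIGH>eɪ")
#' word_phonemes(w)
parse_mapping_notation <- function(spelling, mapping, pron_id = 1L,
                                   check_mop = TRUE) {
  stopifnot(is.character(mapping), length(mapping) == 1L)
  syl_chunks <- strsplit(mapping, "-", fixed = TRUE)[[1]]
  if (!length(syl_chunks) || any(!nzchar(trimws(syl_chunks)))) {
    stop("empty syllable span in mapping \"", mapping, "\"", call. = FALSE)
  }
  segs <- list()
  syl_of <- integer(0)
  for (s in seq_along(syl_chunks)) {
    toks <- strsplit(syl_chunks[s], "|", fixed = TRUE)[[1]]
    if (!length(toks) || any(!nzchar(trimws(toks)))) {
      stop("empty segment in syllable ", s, " of mapping \"", mapping, "\"",
           call. = FALSE)
    }
    for (tok in toks) {
      tok <- trimws(tok)
      nonlinear <- grepl("~", tok, fixed = TRUE)
      sep <- if (nonlinear) "~" else ">"
      parts <- strsplit(tok, sep, fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
        stop("malformed segment token \"", tok, "\" in mapping \"", mapping,
             "\"", call. = FALSE)
      }
      segs <- c(segs, list(segment(parts[1], tokenize_phonemes(parts[2]),
                                   nonlinear = nonlinear)))
      syl_of <- c(syl_of, s)
    }
  }
  # notation order is phonological; restore orthographic order by moving each
  # non-linear E after the consonant segment that follows it in notation
  ord <- seq_along(segs)
  for (k in seq_along(segs)) {
    if (isTRUE(segs[[k]]$nonlinear)) {
      if (k == length(segs)) {
        stop("non-linear E must be followed by its consonant segment in \"",
             mapping, "\"", call. = FALSE)
      }
      ord[c(k, k + 1L)] <- ord[c(k + 1L, k)]
    }
  }
  word <- aligned_word(spelling, segs[ord], seg_syllable = syl_of[ord],
                       pron_id = pron_id, check_mop = check_mop)
  assign_positions(word)
}

#' Serialize an aligned word to mapping notation
#'
#' Inverse of [parse_mapping_notation()]: `format_mapping_notation(
#' parse_mapping_notation(s, m))` reproduces `m` bit-exactly.
#'
#' @param word a `sublex_word`.
#' @return the mapping string.
#' @export
format_mapping_notation <- function(word) {
  stopifnot(inherits(word, "sublex_word"))
  ord <- phonological_order(word$segments)
  toks <- vapply(ord, function(i) {
    seg <- word$segments[[i]]
    sep <- if (isTRUE(seg$nonlinear)) "~" else ">"
    paste0(seg$notation, sep, paste(seg$phonemes, collapse = ""))
  }, "")
  syl <- word$seg_syllable[ord]
  out <- toks[1L]
  if (length(toks) > 1L) {
    for (k in 2L:length(toks)) {
      out <- paste0(out, if (syl[k] != syl[k - 1L]) "-" else "|", toks[k])
    }
  }
  out
}

#' @export
print.sublex_word <- function(x, ...) {
  cat(x$spelling, " /", paste(word_phonemes(x), collapse = ""), "/",
      if (x$pron_id != 1L) paste0(" (pron ", x$pron_id, ")"), "\n", sep = "")
  cat("  ", format_mapping_notation(x), "\n", sep = "")
  if (!all(is.na(x$positions))) {
    cat("  positions: ", paste(x$positions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
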