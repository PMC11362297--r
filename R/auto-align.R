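# Automatic phoneme-grapheme alignment: a search over segmentations of the
# spelling into inventory graphemes whose concatenated phonemes equal the
# pronunciation, handling discontinuous silent-E graphemes, non-linear E's
# and X clusters as special transitions.

#' Automatically align a spelling to its pronunciation
#'
#' Enumerates all segmentations of `spelling` into graphemes attested in
#' `inventory` whose phonemes concatenate (in phonological order) to
#' `phonemes`, then keeps alignments whose every segment is positionally
#' admissible, and returns the best-scoring one. Scoring maximizes the
#' product of inventory attestation counts of the used mappings; remaining
#' ties are broken by fewest segments (parsimony), then by preferring longer
#' graphemes earlier in the word.
#'
#' @param spelling uppercase letter string.
#' @param phonemes phoneme symbol vector or single IPA string.
#' @param inventory a `sublex_inventory`.
#' @param max_alignments safety cap on enumerated complete alignments.
#' @return on success, a position-assigned `sublex_word` with attribute
#'   `n_alignments` (number of admissible candidates); on failure, an object
#'   of class `sublex_align_failure` reporting the furthest-reached letter
#'   and phoneme indices.
#' @export
#' @examples
#' \dontrun{
#' inv <- build_inventory(read_corpus(demo_lexicon_path()))
#' auto_align("GUESS", "gɛs", inv)
#' }
auto_align <- function(spelling, phonemes, inventory,
                       max_alignments = 500L) {
  stopifnot(inherits(inventory, "sublex_inventory"))
  spelling <- toupper(spelling)
  ph <- tokenize_phonemes(phonemes)
  if (!nzchar(spelling) || length(ph) == 0L) {
    stop("spelling and pronunciation must be non-empty", call. = FALSE)
  }
  letters_ <- strsplit(spelling, "")[[1]]
  n_l <- length(letters_)
  n_p <- length(ph)

  inv <- as.data.frame(inventory)
  inv$head <- grapheme_head(inv$grapheme)
  inv$head_len <- nchar(inv$head)
  inv$ph_tokens <- lapply(inv$phoneme, tokenize_phonemes)
  inv$n_ph <- lengths(inv$ph_tokens)
  cons <- !vapply(inv$ph_tokens, function(p) any(is_vowel(p)), TRUE)

  furthest <- c(0L, 0L)
  results <- list()
  seen_dead <- new.env(parent = emptyenv())  # memo of states with no completion

  # i / j: letters / phonemes consumed; pending: a silent E awaits insertion
  # after the next (single consonant) grapheme
  recurse <- function(i, j, pending, segs) {
    if (length(results) >= max_alignments) return(invisible(NULL))
    if (i > furthest[1L] || (i == furthest[1L] && j > furthest[2L])) {
      furthest <<- c(i, j)
    }
    if (i == n_l && j == n_p && !pending) {
      results[[length(results) + 1L]] <<- segs
      return(invisible(NULL))
    }
    key <- paste(i, j, pending)
    if (!is.null(seen_dead[[key]])) return(invisible(NULL))
    produced <- length(results)

    rest <- substring(spelling, i + 1L)
    for (e in seq_len(nrow(inv))) {
      kind <- inv$kind[e]
      hd <- inv$head[e]
      hlen <- inv$head_len[e]
      toks <- inv$ph_tokens[[e]]
      if (kind != "nonlinearE") {
        # the E of a non-linear segment is not at the letter cursor (its
        # consonant comes first orthographically), so only linear kinds are
        # guarded by a head-letter match here
        if (hlen == 0L || hlen > n_l - i) next
        if (substr(rest, 1L, hlen) != hd) next
      }
      if (kind == "normal") {
        if (j + inv$n_ph[e] > n_p) next
        if (!identical(ph[(j + 1L):(j + inv$n_ph[e])], toks)) next
        seg <- segment(inv$grapheme[e], toks)
        if (pending) {
          # the grapheme bridging a silent-E gap is one consonant grapheme
          if (!cons[e] || inv$n_ph[e] != 1L) next
          if (i + hlen + 1L > n_l || letters_[i + hlen + 1L] != "E") next
          recurse(i + hlen + 1L, j + 1L, FALSE, c(segs, list(seg)))
        } else {
          recurse(i + hlen, j + inv$n_ph[e], FALSE, c(segs, list(seg)))
        }
      } else if (kind == "xcluster") {
        if (pending) next
        if (j + 2L > n_p) next
        if (!identical(ph[(j + 1L):(j + 2L)], toks)) next
        recurse(i + hlen, j + 2L, FALSE,
                c(segs, list(segment(inv$grapheme[e], toks))))
      } else if (kind == "silentE") {
        if (pending) next
        if (j + 1L > n_p || !identical(ph[j + 1L], toks[1L])) next
        recurse(i + hlen, j + 1L, TRUE,
                c(segs, list(segment(inv$grapheme[e], toks))))
      } else if (kind == "nonlinearE") {
        # word-final pattern [C][E] realizing /ə|ʌ/ + consonant, with the
        # vowel phonologically first; C is any normal consonant entry
        if (pending) next
        if (j + 2L != n_p) next
        if (!identical(ph[j + 1L], toks[1L])) next
        ccand <- which(inv$kind == "normal" & cons & inv$n_ph == 1L)
        for (ce in ccand) {
          clen <- inv$head_len[ce]
          if (i + clen + 1L != n_l) next
          if (substr(rest, 1L, clen) != inv$head[ce]) next
          if (letters_[n_l] != "E") next
          if (!identical(ph[j + 2L], inv$ph_tokens[[ce]][1L])) next
          recurse(n_l, n_p, FALSE,
                  c(segs, list(segment(inv$grapheme[ce],
                                       inv$ph_tokens[[ce]])),
                    list(segment("E", toks[1L], nonlinear = TRUE))))
        }
      }
    }
    if (length(results) == produced && length(results) < max_alignments) {
      seen_dead[[key]] <- TRUE
    }
    invisible(NULL)
  }
  recurse(0L, 0L, FALSE, list())

  if (!length(results)) {
    return(structure(list(spelling = spelling, phonemes = ph, success = FALSE,
                          furthest_letters = furthest[1L],
                          furthest_phonemes = furthest[2L]),
                     class = "sublex_align_failure"))
  }

  # build candidate words; drop positionally inadmissible or unsyllabifiable
  candidates <- list()
  for (segs in results) {
    w <- tryCatch(assign_positions(aligned_word(spelling, segs)),
                  error = function(e) NULL)
    if (is.null(w)) next
    ok <- all(vapply(seq_along(w$segments), function(k) {
      s <- w$segments[[k]]
      inventory_admits(inventory, s$notation,
                       paste(s$phonemes, collapse = ""), w$positions[k])
    }, TRUE))
    if (ok) candidates[[length(candidates) + 1L]] <- w
  }
  if (!length(candidates)) {
    return(structure(list(spelling = spelling, phonemes = ph, success = FALSE,
                          furthest_letters = furthest[1L],
                          furthest_phonemes = furthest[2L],
                          reason = "no positionally admissible alignment"),
                     class = "sublex_align_failure"))
  }

  score_of <- function(w) {
    sum(vapply(w$segments, function(s) {
      hit <- inv$grapheme == s$notation &
        inv$phoneme == paste(s$phonemes, collapse = "")
      log(max(inv$count[hit]))
    }, 0))
  }
  scores <- vapply(candidates, score_of, 0)
  nseg <- vapply(candidates, function(w) length(w$segments), 0L)
  # tie-break key: longer graphemes earlier (compare per-segment head lengths)
  lenkey <- vapply(candidates, function(w) {
    paste(sprintf("%02d", 99L - nchar(vapply(w$segments,
                                             function(s) s$notation, ""))),
          collapse = "")
  }, "")
  mapkey <- vapply(candidates, format_mapping_notation, "")
  o <- order(-scores, nseg, lenkey, mapkey)
  best <- candidates[[o[1L]]]
  attr(best, "n_alignments") <- length(candidates)
  best
}

#' @export
print.sublex_align_failure <- function(x, ...) {
  cat("<alignment failure> ", x$spelling, " /",
      paste(x$phonemes, collapse = ""), "/: reached letter ",
      x$furthest_letters, "/", nchar(x$spelling), ", phoneme ",
      x$furthest_phonemes, "/", length(x$phonemes), "\n", sep = "")
  if (!is.null(x$reason)) cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
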