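# Syllabification by the Maximum Onset Principle and onset phonotactics.

#' The attested-onset whitelist
#'
#' English onset legality is decided by an explicit whitelist of attested
#' onsets (including /s/-clusters), read from an editable plain-text file
#' (one onset per line, phonemes space-separated, `#` comments). The empty
#' onset is always legal.
#'
#' @param path optional path to an alternative whitelist file.
#' @return a list of character vectors, one per attested onset.
#' @export
onset_whitelist <- function(path = NULL) {
  parse_file <- function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    lapply(lines, function(l) strsplit(l, "\\s+")[[1]])
  }
  if (is.null(path)) {
    if (is.null(.sublexr_env$onsets)) {
      .sublexr_env$onsets <- parse_file(config_path("onsets_en.txt"))
    }
    return(.sublexr_env$onsets)
  }
  parse_file(path)
}

onset_keys <- function(whitelist = onset_whitelist()) {
  vapply(whitelist, paste, "", collapse = " ")
}

#' Test whether a consonant cluster is a legal English onset
#'
#' Returns `TRUE` iff the cluster is a permissible English syllable onset
#' according to the attested-onset whitelist. The empty cluster is legal
#' (vowel-initial syllables exist).
#'
#' @param cluster character vector of consonant phoneme symbols (possibly
#'   empty), or a single unsegmented IPA string.
#' @param whitelist onset whitelist, as returned by [onset_whitelist()].
#' @return a single logical.
#' @export
#' @examples
#' is_legal_onset(c("s", "t"))   # TRUE: /s/ can precede /t/
#' is_legal_onset(c("b", "s"))   # FALSE: /b/ cannot precede /s/
#' is_legal_onset(character())   # TRUE: empty onset
is_legal_onset <- function(cluster, whitelist = onset_whitelist()) {
  cluster <- tokenize_phonemes(cluster)
  if (length(cluster) == 0L) return(TRUE)
  check_phonemes(cluster)
  if (any(is_vowel(cluster))) {
    stop("onset cluster must contain only consonants", call. = FALSE)
  }
  paste(cluster, collapse = " ") %in% onset_keys(whitelist)
}

#' Construct a syllable
#'
#' A syllable has consonants (optionally) in the onset, exactly one vowel in
#' the nucleus, and consonants (optionally) in the coda. The rime is the
#' nucleus plus the coda by construction.
#'
#' @param onset,nucleus,coda character vectors of phoneme symbols; `nucleus`
#'   must be a single vowel.
#' @return an object of class `sublex_syllable`.
#' @export
syllable <- function(onset = character(), nucleus, coda = character()) {
  check_phonemes(c(onset, nucleus, coda))
  if (length(nucleus) != 1L || !is_vowel(nucleus)) {
    stop("nucleus must be exactly one vowel phoneme", call. = FALSE)
  }
  if ((length(onset) && any(is_vowel(onset))) ||
      (length(coda) && any(is_vowel(coda)))) {
    stop("onset and coda must contain only consonants", call. = FALSE)
  }
  structure(list(onset = onset, nucleus = nucleus, coda = coda),
            class = "sublex_syllable")
}

#' @export
print.sublex_syllable <- function(x, ...) {
  cat("/", paste(c(x$onset, x$nucleus, x$coda), collapse = ""), "/\n", sep = "")
  invisible(x)
}

syllable_phonemes <- function(syl) c(syl$onset, syl$nucleus, syl$coda)

#' Syllabify a pronunciation by the Maximum Onset Principle
#'
#' Splits a phoneme sequence into syllables, assigning each intervocalic
#' consonant run so that the longest phonotactically legal suffix of the run
#' becomes the next syllable's onset and the remainder the previous syllable's
#' coda. The number of syllables equals the number of vowels, and
#' concatenating the syllables reproduces the input.
#'
#' A word-initial consonant run that is itself an illegal onset (loanwords,
#' edge cases) is retained as the first onset and flagged via the
#' `"illegal_initial_onset"` attribute.
#'
#' @param phonemes character vector of phoneme symbols, or a single IPA
#'   string (tokenized with [tokenize_phonemes()]).
#' @param whitelist onset whitelist.
#' @return a list of `sublex_syllable` objects; attribute
#'   `illegal_initial_onset` is `TRUE` if the word-initial cluster is not a
#'   legal onset.
#' @export
#' @examples
#' mop_syllabify("lɑbstəɹ")  # LOB-STER, not LO-BSTER or LOBS-TER
#' mop_syllabify("hæpi")     # HA-PPY
mop_syllabify <- function(phonemes, whitelist = onset_whitelist()) {
  ph <- tokenize_phonemes(phonemes)
  check_phonemes(ph)
  vowels <- which(is_vowel(ph))
  if (length(vowels) == 0L) {
    stop("cannot syllabify: pronunciation contains no vowel", call. = FALSE)
  }
  n_syl <- length(vowels)
  # onset start index for each syllable (index into ph of first onset phoneme)
  starts <- integer(n_syl)
  starts[1L] <- 1L
  if (n_syl > 1L) {
    for (k in seq_len(n_syl - 1L)) {
      run <- if (vowels[k] + 1L <= vowels[k + 1L] - 1L) {
        (vowels[k] + 1L):(vowels[k + 1L] - 1L)
      } else integer(0)
      # longest legal suffix of the run becomes the next onset
      pick <- vowels[k + 1L]  # empty onset fallback
      if (length(run)) {
        for (s in run) {      # earliest start = longest onset
          if (is_legal_onset(ph[s:run[length(run)]], whitelist)) {
            pick <- s
            break
          }
        }
      }
      starts[k + 1L] <- pick
    }
  }
  ends <- c(starts[-1L] - 1L, length(ph))
  syls <- vector("list", n_syl)
  for (k in seq_len(n_syl)) {
    idx <- starts[k]:ends[k]
    v <- vowels[k]
    syls[[k]] <- syllable(
      onset = ph[idx[idx < v]],
      nucleus = ph[v],
      coda = ph[idx[idx > v]]
    )
  }
  init <- syls[[1L]]$onset
  attr(syls, "illegal_initial_onset") <-
    length(init) > 0L && !is_legal_onset(init, whitelist)
  if (isTRUE(attr(syls, "illegal_initial_onset"))) {
    warning("word-initial cluster /", paste(init, collapse = ""),
            "/ is not a legal English onset; retained as first onset",
            call. = FALSE)
  }
  syls
}

#' Split a syllable into onset and rime
#'
#' The rime is the concatenation of the vowel in the nucleus and any following
#' consonants in the coda; the onset may be empty, the rime never is.
#'
#' @param syl a `sublex_syllable`.
#' @return a list with character vectors `onset` and `rime`.
#' @export
#' @examples
#' split_onset_rime(syllable(c("b", "l"), "i", "s"))
split_onset_rime <- function(syl) {
  stopifnot(inherits(syl, "sublex_syllable"))
  list(onset = syl$onset, rime = c(syl$nucleus, syl$coda))
}

# syllable index of each phoneme, per MOP
phoneme_syllable_map <- function(phonemes, whitelist = onset_whitelist()) {
  syls <- suppressWarnings(mop_syllabify(phonemes, whitelist))
  rep(seq_along(syls), vapply(syls, function(s) length(syllable_phonemes(s)), 0L))
}
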