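# Synthetic aligned mini-lexicons with known ground truth, and an
# independent brute-force counting oracle. The generator draws from the real
# phoneme inventory and onset whitelist so position-restriction logic is
# exercised; it makes no attempt to match real-English distributional
# statistics.

# phoneme -> candidate graphemes used by the generator
GEN_CONS <- list(
  p = c("P", "PP"), b = "B", t = c("T", "TT"), d = "D",
  k = c("K", "CK"), g = "G", s = c("S", "SS"), z = "Z",
  f = c("F", "FF", "PH"), m = "M", n = c("N", "NN"), l = c("L", "LL"),
  "ɹ" = "R", "ʃ" = "SH", "tʃ" = "CH", h = "H"
)
GEN_VOWELS <- list(
  "æ" = "A", "ɛ" = c("E", "EA"), "ɪ" = "I",
  "ɑ" = "O", "ʌ" = "U", i = c("EE", "EA"), u = "OO",
  "eɪ" = "AI", "oʊ" = "OA"
)
GEN_SILENT <- c("eɪ" = "A_E", "oʊ" = "O_E")
# doubled letters and CK never occur word-initially
GEN_NOT_INITIAL <- c("PP", "TT", "SS", "FF", "NN", "LL", "CK")
# grapheme -> alternative phonemes, for homograph mutation
GEN_ALTERNATES <- list(
  EA = c("i", "ɛ"), S = c("s", "z"), CH = c("tʃ", "k"),
  OO = c("u", "ʊ")
)

#' Specification for a synthetic lexicon
#'
#' Describes the structure of a randomly generated aligned mini-lexicon:
#' its size, the syllable-count distribution, and the per-word rates of the
#' structural phenomena of English spelling the generator emulates
#' (multi-letter graphemes, discontinuous silent-E graphemes, non-linear E's,
#' X clusters, homograph duplication). Identical seeds reproduce identical
#' corpora.
#'
#' @param seed integer RNG seed.
#' @param n_words number of base words (>= 1).
#' @param p_multi_letter probability that a consonant/vowel picks a
#'   multi-letter grapheme variant where one exists.
#' @param p_silent_e probability that a word is given a final silent-E
#'   pattern (vowel + single consonant + E, e.g. A_E).
#' @param p_nonlinear_e probability of appending a non-linear-E final
#'   syllable (consonant + /ə/ + /l/ spelled C-L-E).
#' @param p_x probability of appending an X cluster (/ks/), half the time
#'   followed by a vowel so the cluster straddles a syllable boundary.
#' @param p_homograph probability of duplicating a word with an altered
#'   pronunciation (same spelling, new `pron_id`).
#' @param syllable_dist probabilities of 1, 2, ... syllables.
#' @return an object of class `sublex_synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_words = 100L, p_multi_letter = 0.25,
                       p_silent_e = 0.12, p_nonlinear_e = 0.08, p_x = 0.06,
                       p_homograph = 0.06,
                       syllable_dist = c(0.5, 0.35, 0.15)) {
  probs <- c(p_multi_letter, p_silent_e, p_nonlinear_e, p_x, p_homograph,
             syllable_dist)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (p_silent_e + p_nonlinear_e + p_x > 1) {
    stop("feature probabilities must sum to at most 1", call. = FALSE)
  }
  if (n_words < 1L) stop("n_words must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_words = as.integer(n_words),
                 p_multi_letter = p_multi_letter, p_silent_e = p_silent_e,
                 p_nonlinear_e = p_nonlinear_e, p_x = p_x,
                 p_homograph = p_homograph,
                 syllable_dist = syllable_dist / sum(syllable_dist)),
            class = "sublex_synth_spec")
}

# onsets from the whitelist composed solely of generator consonants
gen_onset_pool <- function() {
  pool <- Filter(function(o) all(o %in% names(GEN_CONS)), onset_whitelist())
  pool[lengths(pool) <= 2L]
}

gen_pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# one random base word: phoneme sequence + per-phoneme generation plan
gen_one_word <- function(spec, onset_pool) {
  n_syl <- sample(seq_along(spec$syllable_dist), 1L,
                  prob = spec$syllable_dist)
  feature <- sample(c("none", "silentE", "nonlinearE", "x"), 1L,
                    prob = c(1 - spec$p_silent_e - spec$p_nonlinear_e -
                               spec$p_x,
                             spec$p_silent_e, spec$p_nonlinear_e, spec$p_x))
  coda_pool <- c("p", "t", "d", "k", "g", "s", "z", "m", "n", "l", "f")
  ph <- character(0)
  for (s in seq_len(n_syl)) {
    if (stats::runif(1) < 0.85) ph <- c(ph, onset_pool[[gen_pick(
      seq_along(onset_pool))]])
    ph <- c(ph, gen_pick(names(GEN_VOWELS)))
    p_coda <- if (s == n_syl) 0.6 else 0.25
    if (stats::runif(1) < p_coda) ph <- c(ph, gen_pick(coda_pool))
  }
  silent <- FALSE; nonlin <- FALSE; x_at <- NA_integer_
  if (feature == "silentE") {
    # force final pattern: silent-E vowel + exactly one coda consonant
    vowels_at <- which(ph %in% names(GEN_VOWELS))
    last_v <- vowels_at[length(vowels_at)]
    ph <- c(ph[seq_len(last_v - 1L)], gen_pick(names(GEN_SILENT)),
            gen_pick(c("t", "d", "k", "s", "m", "n", "l")))
    silent <- TRUE
  } else if (feature == "nonlinearE") {
    ph <- c(ph, gen_pick(c("t", "d", "k", "s", "p", "b", "f", "m")),
            "ə", "l")
    nonlin <- TRUE
  } else if (feature == "x") {
    # append /ks/ after a vowel; half the time a further vowel follows so the
    # cluster straddles a syllable boundary (X pinned to earlier syllable)
    vowels_at <- which(ph %in% names(GEN_VOWELS))
    ph <- ph[seq_len(vowels_at[length(vowels_at)])]
    x_at <- length(ph) + 1L
    ph <- c(ph, "k", "s")
    if (stats::runif(1) < 0.5) ph <- c(ph, "ɪ")
  }
  list(ph = ph, silent = silent, nonlin = nonlin, x_at = x_at)
}

# turn a generation plan into an aligned word (segments in orthographic order)
gen_build_word <- function(plan, spec) {
  ph <- plan$ph
  segs <- list()
  i <- 1L
  n <- length(ph)
  first_seg <- TRUE
  pick_grapheme <- function(options, initial) {
    if (initial) options <- setdiff(options, GEN_NOT_INITIAL)
    if (length(options) > 1L && stats::runif(1) < spec$p_multi_letter) {
      multi <- options[nchar(options) > 1L]
      if (length(multi)) return(gen_pick(multi))
    }
    options[which.max(nchar(options) == 1L)][1L]
  }
  while (i <= n) {
    if (!is.na(plan$x_at) && i == plan$x_at) {
      segs <- c(segs, list(segment("X", c("k", "s"))))
      i <- i + 2L
    } else if (plan$nonlin && i == n - 1L) {
      # phonemes ə, l -> orthographic L then non-linear E (appended last)
      segs <- c(segs, list(segment("L", "l")),
                list(segment("E", "ə", nonlinear = TRUE)))
      # reorder below expects the non-linear E already last; phoneme order is
      # handled by phonological_order()
      i <- i + 2L
    } else if (plan$silent && ph[i] %in% names(GEN_SILENT) && i == n - 1L) {
      segs <- c(segs, list(segment(GEN_SILENT[[ph[i]]], ph[i])))
      i <- i + 1L
    } else if (ph[i] %in% names(GEN_VOWELS)) {
      segs <- c(segs, list(segment(pick_grapheme(GEN_VOWELS[[ph[i]]],
                                                 first_seg), ph[i])))
      i <- i + 1L
    } else {
      segs <- c(segs, list(segment(pick_grapheme(GEN_CONS[[ph[i]]],
                                                 first_seg), ph[i])))
      i <- i + 1L
    }
    first_seg <- FALSE
  }
  aligned_word(reconstruct_spelling(segs), segs)
}

#' Generate a synthetic aligned corpus with ground-truth tables
#'
#' Generates `spec$n_words` base words (plus homograph duplicates), each a
#' valid aligned word, and returns ground-truth count tables computed during
#' generation by the independent brute-force oracle ([oracle_counts()]),
#' never by [build_count_tables()].
#'
#' @param spec a [synth_spec()].
#' @return list with `words` (position-assigned `sublex_word` list) and
#'   `truth` (oracle `sublex_tables`, instances mode).
#' @export
generate_synthetic_corpus <- function(spec) {
  stopifnot(inherits(spec, "sublex_synth_spec"))
  onset_pool <- gen_onset_pool()
  if (!length(onset_pool)) stop("degenerate generator alphabet", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  words <- list()
  seen <- character(0)   # spelling#pronunciation
  pron_of <- list()      # spelling -> number of pronunciations so far
  add_word <- function(w) {
    key <- paste(w$spelling, paste(word_phonemes(w), collapse = ""),
                 sep = "#")
    if (key %in% seen) return(FALSE)
    nprev <- if (is.null(pron_of[[w$spelling]])) 0L else pron_of[[w$spelling]]
    w$pron_id <- nprev + 1L
    pron_of[[w$spelling]] <<- nprev + 1L
    seen <<- c(seen, key)
    words[[length(words) + 1L]] <<- assign_positions(w)
    TRUE
  }
  tries <- 0L
  while (length(unique(vapply(words, function(w) w$spelling, ""))) <
         spec$n_words && tries < spec$n_words * 50L) {
    tries <- tries + 1L
    w <- tryCatch(gen_build_word(gen_one_word(spec, onset_pool), spec),
                  error = function(e) NULL)
    if (is.null(w)) next
    if (!add_word(w)) next
    if (stats::runif(1) < spec$p_homograph) {
      hw <- gen_mutate_homograph(w)
      if (!is.null(hw)) add_word(hw)
    }
  }
  list(words = words, truth = oracle_counts(words))
}

# same spelling, one segment's phoneme swapped to an alternative the
# grapheme supports
gen_mutate_homograph <- function(w) {
  cand <- which(vapply(w$segments, function(s)
    s$notation %in% names(GEN_ALTERNATES) && !isTRUE(s$nonlinear), TRUE))
  for (k in cand) {
    seg <- w$segments[[k]]
    alts <- setdiff(GEN_ALTERNATES[[seg$notation]],
                    paste(seg$phonemes, collapse = ""))
    for (alt in alts) {
      segs2 <- w$segments
      segs2[[k]] <- segment(seg$notation, alt)
      hw <- tryCatch(aligned_word(w$spelling, segs2),
                     error = function(e) NULL)
      if (!is.null(hw)) return(hw)
    }
  }
  NULL
}

# ---- the brute-force oracle -------------------------------------------------

# naive position coding, written independently of assign_positions()
oracle_positions <- function(w) {
  n <- length(w$segments)
  syl <- w$seg_syllable
  out <- character(n)
  for (i in seq_len(n)) {
    if (i == 1L) out[i] <- "word_initial"
    else if (i == n) out[i] <- "word_final"
    else if (syl[i] != syl[i - 1L] && syl[i] > 1L) out[i] <- "syllable_initial"
    else if (syl[i] != syl[i + 1L] && syl[i] < max(syl)) out[i] <-
        "syllable_final"
    else out[i] <- "syllable_medial"
  }
  out
}

# naive onset/rime unit listing, written independently of
# derive_onset_rime_units()
oracle_or_units <- function(w) {
  segs <- w$segments
  n <- length(segs)
  # phonological order: the (word-final) non-linear E comes right before the
  # segment that precedes it orthographically
  ord <- seq_len(n)
  if (n >= 2L && isTRUE(segs[[n]]$nonlinear)) ord <- c(seq_len(n - 2L), n,
                                                       n - 1L)
  rows <- list()
  for (s in seq_len(max(w$seg_syllable))) {
    in_syl <- ord[w$seg_syllable[ord] == s]       # phonological order
    vow <- vapply(segs[in_syl], function(g) any(is_vowel(g$phonemes)), TRUE)
    nucleus_at <- which(vow)[1L]
    onset <- in_syl[seq_len(nucleus_at - 1L)]
    rime <- in_syl[nucleus_at:length(in_syl)]
    glue_letters <- function(idx) {
      idx <- sort(idx)                            # orthographic order
      out <- ""
      pend <- FALSE
      for (g in segs[idx]) {
        out <- paste0(out, grapheme_head(g$notation))
        if (pend) { out <- paste0(out, "E"); pend <- FALSE }
        if (is_discontinuous(g$notation)) pend <- TRUE
      }
      if (pend) out <- paste0(out, "_E")
      out
    }
    glue_phonemes <- function(idx) paste(unlist(lapply(segs[idx],
      function(g) g$phonemes)), collapse = "")
    if (length(onset)) {
      rows[[length(rows) + 1L]] <- c("onset", glue_letters(onset),
        glue_phonemes(onset),
        if (s == 1L) "onset_word_initial" else "onset_syllable_initial")
    }
    rows[[length(rows) + 1L]] <- c("rime", glue_letters(rime),
      glue_phonemes(rime),
      if (s == max(w$seg_syllable)) "rime_word_final"
      else "rime_syllable_final")
  }
  m <- do.call(rbind, rows)
  data.frame(type = m[, 1], grapheme = m[, 2], phoneme = m[, 3],
             position = m[, 4], stringsAsFactors = FALSE)
}

#' Brute-force count tables (the test oracle)
#'
#' Naive nested-loop enumeration of every unit occurrence in the corpus,
#' intentionally simple and implemented separately from
#' [build_count_tables()] so the two can be compared in tests.
#'
#' @param words list of `sublex_word` objects.
#' @param mode `"instances"` or `"words"`.
#' @return a `sublex_tables`.
#' @export
oracle_counts <- function(words, mode = c("instances", "words")) {
  mode <- match.arg(mode)
  tally <- list(phonographeme = list(), grapheme = list(), phoneme = list(),
                or_joint = list(), or_grapheme = list(), or_phoneme = list())
  bump <- function(tab, key, seen_keys) {
    if (mode == "words" && key %in% seen_keys[[tab]]) return(seen_keys)
    prev <- tally[[tab]][[key]]
    tally[[tab]][[key]] <<- if (is.null(prev)) 1L else prev + 1L
    seen_keys[[tab]] <- c(seen_keys[[tab]], key)
    seen_keys
  }
  for (w in words) {
    seen <- list(phonographeme = character(), grapheme = character(),
                 phoneme = character(), or_joint = character(),
                 or_grapheme = character(), or_phoneme = character())
    pos <- oracle_positions(w)
    for (i in seq_along(w$segments)) {
      g <- w$segments[[i]]$notation
      p <- paste(w$segments[[i]]$phonemes, collapse = "")
      seen <- bump("phonographeme", paste(g, p, pos[i], sep = "\t"), seen)
      seen <- bump("grapheme", paste(g, pos[i], sep = "\t"), seen)
      seen <- bump("phoneme", paste(p, pos[i], sep = "\t"), seen)
    }
    or <- oracle_or_units(w)
    for (i in seq_len(nrow(or))) {
      seen <- bump("or_joint", paste(or$type[i], or$grapheme[i],
                                     or$phoneme[i], or$position[i],
                                     sep = "\t"), seen)
      seen <- bump("or_grapheme", paste(or$type[i], or$grapheme[i],
                                        or$position[i], sep = "\t"), seen)
      seen <- bump("or_phoneme", paste(or$type[i], or$phoneme[i],
                                       or$position[i], sep = "\t"), seen)
    }
  }
  shape <- function(tab, cols) {
    keys <- names(tally[[tab]])
    m <- if (length(keys)) do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    out <- as.data.frame(if (is.null(m)) matrix(character(), 0, length(cols))
                         else m, stringsAsFactors = FALSE)
    names(out) <- cols
    out$count <- if (length(keys)) unlist(tally[[tab]], use.names = FALSE)
                 else integer()
    dtout <- as.data.table(out)
    setorderv(dtout, cols)
    as.data.frame(dtout)
  }
  out <- list(
    phonographeme = shape("phonographeme", c("grapheme", "phoneme",
                                             "position")),
    grapheme = shape("grapheme", c("grapheme", "position")),
    phoneme = shape("phoneme", c("phoneme", "position")),
    or_joint = shape("or_joint", c("type", "grapheme", "phoneme",
                                   "position")),
    or_grapheme = shape("or_grapheme", c("type", "grapheme", "position")),
    or_phoneme = shape("or_phoneme", c("type", "phoneme", "position")),
    n_words = length(words), mode = mode, version = "oracle")
  class(out) <- "sublex_tables"
  out
}
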