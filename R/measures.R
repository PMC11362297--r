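# The ten measures: reading consistency p(P|G), spelling consistency p(G|P),
# phoneme / grapheme / phonographeme frequency (and their log10 forms), each
# at the phonographeme and the onset/rime grain.

position_grain <- function(position) {
  if (position %in% PHONOGRAPHEME_POSITIONS) return("phonographeme")
  if (position %in% ONSET_RIME_POSITIONS) return("onset_rime")
  stop("unknown position code: \"", position, "\"", call. = FALSE)
}

or_type_of_position <- function(position) {
  if (startsWith(position, "onset_")) "onset" else "rime"
}

lookup_count <- function(tab, keys) {
  hit <- rep(TRUE, nrow(tab))
  for (k in names(keys)) hit <- hit & tab[[k]] == keys[[k]]
  if (!any(hit)) 0L else sum(tab$count[hit])
}

joint_count <- function(tables, grapheme, phoneme, position) {
  if (position_grain(position) == "phonographeme") {
    lookup_count(tables$phonographeme,
                 list(grapheme = grapheme, phoneme = phoneme,
                      position = position))
  } else {
    lookup_count(tables$or_joint,
                 list(type = or_type_of_position(position),
                      grapheme = grapheme, phoneme = phoneme,
                      position = position))
  }
}

#' Reading consistency p(P|G)
#'
#' The proportion of corpus entries containing `grapheme` in `position` in
#' which it maps to `phoneme`: the joint (phonographeme) count divided by the
#' grapheme count. Undefined (`NA`, not zero) when the grapheme is unattested
#' in that position. The position code selects the grain: a five-category
#' phonographeme code queries phonographeme tables, an onset/rime code the
#' onset/rime tables.
#'
#' @param tables a `sublex_tables`.
#' @param grapheme grapheme notation (phonographeme grain) or orthographic
#'   unit string (onset/rime grain).
#' @param phoneme phoneme string (concatenated symbols).
#' @param position a position code.
#' @return a probability in `[0, 1]`, or `NA` if undefined.
#' @export
reading_consistency <- function(tables, grapheme, phoneme, position) {
  num <- joint_count(tables, grapheme, phoneme, position)
  den <- if (position_grain(position) == "phonographeme") {
    lookup_count(tables$grapheme,
                 list(grapheme = grapheme, position = position))
  } else {
    lookup_count(tables$or_grapheme,
                 list(type = or_type_of_position(position),
                      grapheme = grapheme, position = position))
  }
  if (den == 0L) NA_real_ else num / den
}

#' Spelling consistency p(G|P)
#'
#' The proportion of corpus entries containing `phoneme` in `position` in
#' which it is spelled with `grapheme`. Undefined (`NA`) when the phoneme is
#' unattested in that position.
#'
#' @inheritParams reading_consistency
#' @return a probability in `[0, 1]`, or `NA` if undefined.
#' @export
spelling_consistency <- function(tables, grapheme, phoneme, position) {
  num <- joint_count(tables, grapheme, phoneme, position)
  den <- if (position_grain(position) == "phonographeme") {
    lookup_count(tables$phoneme,
                 list(phoneme = phoneme, position = position))
  } else {
    lookup_count(tables$or_phoneme,
                 list(type = or_type_of_position(position),
                      phoneme = phoneme, position = position))
  }
  if (den == 0L) NA_real_ else num / den
}

#' Phonographeme frequency
#'
#' The number of corpus entries with `grapheme` mapped to `phoneme` in
#' `position`: the shared numerator of both consistency measures, and
#' direction-independent by construction (the frequency of G -> P equals that
#' of P -> G). Returns 0 for unattested mappings.
#'
#' @inheritParams reading_consistency
#' @return a non-negative integer count.
#' @export
phonographeme_frequency <- function(tables, grapheme, phoneme, position) {
  joint_count(tables, grapheme, phoneme, position)
}

#' Positional unit frequency (and its log)
#'
#' Marginal count of a single-sided unit in a position: with a phonographeme
#' position code, `unit = "grapheme"` or `"phoneme"` queries the grapheme /
#' phoneme marginals; with an onset/rime position code the same `unit` choice
#' selects the orthographic or phonological marginal of the onset/rime unit.
#' `log_frequency` is `log10` of the count and is undefined (`NA`) for count
#' zero (no smoothing by default).
#'
#' @param tables a `sublex_tables`.
#' @param unit `"grapheme"` or `"phoneme"` (the side of the unit).
#' @param key the unit string.
#' @param position a position code (either grain).
#' @return a count (`unit_frequency`) or a log10 count (`log_frequency`).
#' @export
unit_frequency <- function(tables, unit = c("grapheme", "phoneme"), key,
                           position) {
  unit <- match.arg(unit)
  if (position_grain(position) == "phonographeme") {
    tab <- tables[[unit]]
    lookup_count(tab, setNames(list(key, position), c(unit, "position")))
  } else {
    tab <- tables[[paste0("or_", unit)]]
    lookup_count(tab, setNames(list(or_type_of_position(position), key,
                                    position),
                               c("type", unit, "position")))
  }
}

#' @rdname unit_frequency
#' @export
log_frequency <- function(tables, unit = c("grapheme", "phoneme"), key,
                          position) {
  n <- unit_frequency(tables, unit, key, position)
  if (n == 0L) NA_real_ else log10(n)
}

MEASURE_NAMES <- c("reading_consistency", "spelling_consistency",
                   "phonographeme_freq", "grapheme_freq", "phoneme_freq",
                   "lg_phonographeme_freq", "lg_grapheme_freq",
                   "lg_phoneme_freq")

#' Score a word or pseudoword against the corpus tables
#'
#' Computes every applicable measure for each segment (phonographeme grain)
#' or each onset/rime unit of a word, plus word-level summaries (mean, min,
#' max, sum) over the defined values. Unattested units yield undefined
#' measures (`NA`), which are data, not errors: they are excluded from
#' summaries and tallied in `n_undefined`. The word need not be in the
#' corpus -- pseudowords and misspellings are scored identically.
#'
#' @param word an aligned, position-assigned `sublex_word`.
#' @param tables a `sublex_tables`.
#' @param grain `"phonographeme"` or `"onset_rime"`.
#' @return an object of class `sublex_scores`: list with `units` (one row per
#'   segment/unit with all measures), `summary` (one row per measure with
#'   `mean`, `min`, `max`, `sum`, `n_defined`, `n_undefined`), `grain`,
#'   `spelling`.
#' @export
score_word <- function(word, tables,
                       grain = c("phonographeme", "onset_rime")) {
  grain <- match.arg(grain)
  stopifnot(inherits(word, "sublex_word"), inherits(tables, "sublex_tables"))
  if (all(is.na(word$positions))) word <- assign_positions(word)
  if (grain == "phonographeme") {
    units <- data.frame(
      unit = vapply(word$segments, function(s) s$notation, ""),
      grapheme = vapply(word$segments, function(s) s$notation, ""),
      phoneme = vapply(word$segments, function(s)
        paste(s$phonemes, collapse = ""), ""),
      position = word$positions, stringsAsFactors = FALSE)
  } else {
    or <- derive_onset_rime_units(word)
    units <- data.frame(unit = paste(or$type, or$grapheme, sep = ":"),
                        grapheme = or$grapheme, phoneme = or$phoneme,
                        position = or$position, stringsAsFactors = FALSE)
  }
  n <- nrow(units)
  m <- matrix(NA_real_, n, length(MEASURE_NAMES),
              dimnames = list(NULL, MEASURE_NAMES))
  for (i in seq_len(n)) {
    g <- units$grapheme[i]; p <- units$phoneme[i]; pos <- units$position[i]
    pgf <- phonographeme_frequency(tables, g, p, pos)
    gf <- unit_frequency(tables, "grapheme", g, pos)
    pf <- unit_frequency(tables, "phoneme", p, pos)
    m[i, "reading_consistency"] <- reading_consistency(tables, g, p, pos)
    m[i, "spelling_consistency"] <- spelling_consistency(tables, g, p, pos)
    m[i, "phonographeme_freq"] <- if (pgf == 0L) NA_real_ else pgf
    m[i, "grapheme_freq"] <- if (gf == 0L) NA_real_ else gf
    m[i, "phoneme_freq"] <- if (pf == 0L) NA_real_ else pf
    m[i, "lg_phonographeme_freq"] <- if (pgf == 0L) NA_real_ else log10(pgf)
    m[i, "lg_grapheme_freq"] <- if (gf == 0L) NA_real_ else log10(gf)
    m[i, "lg_phoneme_freq"] <- if (pf == 0L) NA_real_ else log10(pf)
  }
  units <- cbind(units, as.data.frame(m))
  summ <- do.call(rbind, lapply(MEASURE_NAMES, function(nm) {
    v <- m[, nm]
    def <- v[!is.na(v)]
    data.frame(measure = nm,
               mean = if (length(def)) mean(def) else NA_real_,
               min = if (length(def)) min(def) else NA_real_,
               max = if (length(def)) max(def) else NA_real_,
               sum = if (length(def)) sum(def) else NA_real_,
               n_defined = length(def), n_undefined = sum(is.na(v)),
               stringsAsFactors = FALSE)
  }))
  structure(list(spelling = word$spelling, grain = grain, units = units,
                 summary = summ),
            class = "sublex_scores")
}

#' @export
print.sublex_scores <- function(x, digits = 3, ...) {
  cat("<sublex_scores> ", x$spelling, " (", x$grain, " grain)\n", sep = "")
  print(x$units, digits = digits)
  cat("summary:\n")
  print(x$summary, digits = digits)
  invisible(x)
}

#' Get one summary value from a score set
#'
#' @param scores a `sublex_scores`.
#' @param measure one of the measure names (see [score_word()]).
#' @param summary `"mean"`, `"min"`, `"max"` or `"sum"`.
#' @return a single number (`NA` if no unit had a defined value).
#' @export
score_summary <- function(scores, measure = "reading_consistency",
                          summary = c("mean", "min", "max", "sum")) {
  summary <- match.arg(summary)
  stopifnot(inherits(scores, "sublex_scores"))
  row <- scores$summary[scores$summary$measure == measure, ]
  if (nrow(row) != 1L) stop("unknown measure: ", measure, call. = FALSE)
  row[[summary]]
}

#' Rank alternative pronunciations of one spelling
#'
#' Scores each candidate aligned word and ranks them (stable, descending) by
#' the chosen summary of the chosen measure. Candidates with an undefined
#' summary rank last; ties share a rank.
#'
#' @param candidates list of `sublex_word` objects sharing one spelling.
#' @param tables a `sublex_tables`.
#' @param grain `"phonographeme"` or `"onset_rime"`.
#' @param measure,summary see [score_summary()].
#' @return a data.frame with `pronunciation`, `mapping`, `value`, `rank`,
#'   ordered best first.
#' @export
compare_pronunciations <- function(candidates, tables,
                                   grain = c("phonographeme", "onset_rime"),
                                   measure = "reading_consistency",
                                   summary = "mean") {
  grain <- match.arg(grain)
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  sp <- unique(vapply(candidates, function(w) w$spelling, ""))
  if (length(sp) != 1L) {
    stop("all candidates must share one spelling (got: ",
         paste(sp, collapse = ", "), ")", call. = FALSE)
  }
  vals <- vapply(candidates, function(w)
    score_summary(score_word(w, tables, grain), measure, summary), 0)
  # descending rank, NA last, ties equal (min) rank
  key <- ifelse(is.na(vals), -Inf, vals)
  rk <- integer(length(vals))
  for (i in seq_along(vals)) rk[i] <- 1L + sum(key > key[i])
  out <- data.frame(
    pronunciation = vapply(candidates, function(w)
      paste(word_phonemes(w), collapse = ""), ""),
    mapping = vapply(candidates, format_mapping_notation, ""),
    value = vals, rank = rk, stringsAsFactors = FALSE)
  out[order(out$rank, out$pronunciation), , drop = FALSE]
}
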