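# Vectorized measure computation over every attested key of a table set;
# backs the search/lookup interface and the normalization property tests.

#' All measures for every attested joint key
#'
#' Computes reading consistency, spelling consistency and the three
#' frequencies (plus log10 forms) for every attested (grapheme, phoneme,
#' position) key at the requested grain, by joining the joint table with its
#' marginals. Deterministic row order.
#'
#' @param tables a `sublex_tables`.
#' @param grain `"phonographeme"` or `"onset_rime"`.
#' @return a data.frame with key columns (`type` at onset/rime grain,
#'   `grapheme`, `phoneme`, `position`) and the eight measure columns.
#' @export
measure_table <- function(tables, grain = c("phonographeme", "onset_rime")) {
  grain <- match.arg(grain)
  if (grain == "phonographeme") {
    joint <- as.data.table(tables$phonographeme)
    gmarg <- as.data.table(tables$grapheme)
    pmarg <- as.data.table(tables$phoneme)
    gkeys <- c("grapheme", "position")
    pkeys <- c("phoneme", "position")
  } else {
    joint <- as.data.table(tables$or_joint)
    gmarg <- as.data.table(tables$or_grapheme)
    pmarg <- as.data.table(tables$or_phoneme)
    gkeys <- c("type", "grapheme", "position")
    pkeys <- c("type", "phoneme", "position")
  }
  setnames(joint, "count", "phonographeme_freq")
  setnames(gmarg, "count", "grapheme_freq")
  setnames(pmarg, "count", "phoneme_freq")
  out <- merge(joint, gmarg, by = gkeys, all.x = TRUE, sort = FALSE)
  out <- merge(out, pmarg, by = pkeys, all.x = TRUE, sort = FALSE)
  out[, `:=`(
    reading_consistency = phonographeme_freq / grapheme_freq,
    spelling_consistency = phonographeme_freq / phoneme_freq,
    lg_phonographeme_freq = log10(phonographeme_freq),
    lg_grapheme_freq = log10(grapheme_freq),
    lg_phoneme_freq = log10(phoneme_freq)
  )]
  keycols <- if (grain == "phonographeme") {
    c("grapheme", "phoneme", "position")
  } else {
    c("type", "grapheme", "phoneme", "position")
  }
  setcolorder(out, c(keycols, "reading_consistency", "spelling_consistency",
                     "phonographeme_freq", "grapheme_freq", "phoneme_freq",
                     "lg_phonographeme_freq", "lg_grapheme_freq",
                     "lg_phoneme_freq"))
  setorderv(out, keycols)
  as.data.frame(out)
}
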