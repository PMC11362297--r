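# Position-keyed, type-weighted count tables of phonemes, graphemes,
# phonographemes, onsets and rimes.

# one row per unit occurrence in one word, both grains
word_occurrences <- function(word) {
  if (all(is.na(word$positions))) word <- assign_positions(word)
  pg <- data.table(
    grapheme = vapply(word$segments, function(s) s$notation, ""),
    phoneme = vapply(word$segments, function(s)
      paste(s$phonemes, collapse = ""), ""),
    position = word$positions)
  or <- as.data.table(derive_onset_rime_units(word))[
    , .(type, grapheme, phoneme, position)]
  list(pg = pg, or = or)
}

#' Build count tables from an aligned corpus
#'
#' Type-weighted counts: every corpus record contributes irrespective of its
#' token frequency. In `instances` mode (default) each occurrence of a
#' (unit, position) key counts once, which guarantees that consistency values
#' normalize (sum to 1 over alternatives); in `words` mode a record increments
#' each key at most once, matching a literal "number of words with ..."
#' reading of the defining ratios.
#'
#' @param words list of `sublex_word` objects (homographs as separate records
#'   with distinct `pron_id`).
#' @param mode `"instances"` or `"words"`.
#' @param version corpus version tag stored with the tables.
#' @return an object of class `sublex_tables`: a list of count data.frames
#'   (`phonographeme`, `grapheme`, `phoneme`, `or_joint`, `or_grapheme`,
#'   `or_phoneme`) plus `n_words`, `mode`, `version`.
#' @export
build_count_tables <- function(words, mode = c("instances", "words"),
                               version = "unversioned") {
  mode <- match.arg(mode)
  stopifnot(length(words) > 0L)
  ids <- vapply(words, function(w) paste(w$spelling, w$pron_id, sep = "#"), "")
  if (anyDuplicated(ids)) {
    stop("duplicate (spelling, pron_id) records: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  occs <- lapply(words, word_occurrences)
  pg <- rbindlist(lapply(seq_along(occs), function(k)
    cbind(occs[[k]]$pg, word = k)))
  or <- rbindlist(lapply(seq_along(occs), function(k)
    cbind(occs[[k]]$or, word = k)))

  count_tab <- function(dt, keys) {
    if (mode == "words") dt <- unique(dt, by = c("word", keys))
    out <- dt[, .(count = .N), by = keys]
    setorderv(out, keys)
    as.data.frame(out)
  }
  out <- list(
    phonographeme = count_tab(pg, c("grapheme", "phoneme", "position")),
    grapheme = count_tab(pg, c("grapheme", "position")),
    phoneme = count_tab(pg, c("phoneme", "position")),
    or_joint = count_tab(or, c("type", "grapheme", "phoneme", "position")),
    or_grapheme = count_tab(or, c("type", "grapheme", "position")),
    or_phoneme = count_tab(or, c("type", "phoneme", "position")),
    n_words = length(words),
    mode = mode,
    version = version
  )
  class(out) <- "sublex_tables"
  out
}

#' @export
print.sublex_tables <- function(x, ...) {
  cat("<sublex_tables> ", x$n_words, " words (", x$mode, " mode, version ",
      x$version, ")\n", sep = "")
  cat("  phonographemes: ", nrow(x$phonographeme),
      " keys; graphemes: ", nrow(x$grapheme),
      " keys; phonemes: ", nrow(x$phoneme), " keys\n", sep = "")
  cat("  onset/rime joint keys: ", nrow(x$or_joint), "\n", sep = "")
  invisible(x)
}

TABLE_NAMES <- c("phonographeme", "grapheme", "phoneme",
                 "or_joint", "or_grapheme", "or_phoneme")

#' Merge two sets of count tables
#'
#' Key-wise sum of all tables; `n_words` is additive. Both inputs must use
#' the same counting mode. Merging tables built on disjoint corpora equals
#' building on the concatenated corpus.
#'
#' @param a,b `sublex_tables` objects.
#' @return a `sublex_tables` object.
#' @export
merge_tables <- function(a, b) {
  stopifnot(inherits(a, "sublex_tables"), inherits(b, "sublex_tables"))
  if (a$mode != b$mode) {
    stop("cannot merge tables with different counting modes (",
         a$mode, " vs ", b$mode, ")", call. = FALSE)
  }
  out <- list()
  for (nm in TABLE_NAMES) {
    keys <- setdiff(names(a[[nm]]), "count")
    dt <- rbindlist(list(as.data.table(a[[nm]]), as.data.table(b[[nm]])))
    dt <- dt[, .(count = sum(count)), by = keys]
    setorderv(dt, keys)
    out[[nm]] <- as.data.frame(dt)
  }
  out$n_words <- a$n_words + b$n_words
  out$mode <- a$mode
  out$version <- if (identical(a$version, b$version)) a$version else
    paste(a$version, b$version, sep = "+")
  class(out) <- "sublex_tables"
  out
}

#' Write / read a tables artifact
#'
#' Writes one TSV per table (deterministic sort order, UTF-8, LF endings)
#' plus a `meta.tsv` with `n_words`, `mode` and `version`, into a directory.
#'
#' @param tables a `sublex_tables`.
#' @param dir directory path (created if absent).
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "sublex_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in TABLE_NAMES) {
    write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8",
                eol = "\n")
  }
  meta <- data.frame(key = c("n_words", "mode", "version"),
                     value = c(tables$n_words, tables$mode, tables$version))
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(dir)
}

#' @rdname write_tables
#' @export
read_tables <- function(dir) {
  out <- list()
  for (nm in TABLE_NAMES) {
    out[[nm]] <- read.delim(file.path(dir, paste0(nm, ".tsv")),
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  meta <- read.delim(file.path(dir, "meta.tsv"), stringsAsFactors = FALSE,
                     fileEncoding = "UTF-8")
  out$n_words <- as.integer(meta$value[meta$key == "n_words"])
  out$mode <- meta$value[meta$key == "mode"]
  out$version <- meta$value[meta$key == "version"]
  class(out) <- "sublex_tables"
  out
}
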