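# Corpus file interface: UTF-8 TSV with header
#   spelling  pronunciation  mapping  pron_id
# mapping in the package's notation; `#` comment lines ignored. Records with
# an empty mapping are auto-aligned against a grapheme inventory.

#' Read an aligned corpus from TSV
#'
#' @param path corpus file (UTF-8 TSV, columns `spelling`, `pronunciation`,
#'   `mapping`, `pron_id`; `#` comments ignored).
#' @param inventory optional `sublex_inventory` used to auto-align records
#'   whose `mapping` column is empty.
#' @param on_error `"stop"` (default) or `"skip"`; skipped rows are reported
#'   in the `errors` attribute (data.frame with `line`, `spelling`,
#'   `message`).
#' @return list of position-assigned `sublex_word` objects, with attribute
#'   `errors`.
#' @export
read_corpus <- function(path, inventory = NULL,
                        on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8", colClasses = "character")
  needed <- c("spelling", "pronunciation", "mapping", "pron_id")
  if (!all(needed %in% names(df))) {
    stop("corpus file lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  words <- list()
  errs <- list()
  for (r in seq_len(nrow(df))) {
    w <- tryCatch({
      pid <- if (nzchar(df$pron_id[r])) as.integer(df$pron_id[r]) else 1L
      if (nzchar(df$mapping[r])) {
        w <- parse_mapping_notation(df$spelling[r], df$mapping[r],
                                    pron_id = pid)
        # cross-check the pronunciation column when present
        if (nzchar(df$pronunciation[r])) {
          want <- tokenize_phonemes(df$pronunciation[r])
          got <- word_phonemes(w)
          if (!identical(want, got)) {
            stop("mapping yields /", paste(got, collapse = ""),
                 "/ but pronunciation column says /",
                 paste(want, collapse = ""), "/", call. = FALSE)
          }
        }
        w
      } else {
        if (is.null(inventory)) {
          stop("record has no mapping and no inventory was supplied",
               call. = FALSE)
        }
        w <- auto_align(df$spelling[r],
                        tokenize_phonemes(df$pronunciation[r]), inventory)
        if (inherits(w, "sublex_align_failure")) {
          stop("auto-alignment failed (reached letter ", w$furthest_letters,
               ", phoneme ", w$furthest_phonemes, ")", call. = FALSE)
        }
        w$pron_id <- pid
        w
      }
    }, error = function(e) e)
    if (inherits(w, "error")) {
      if (on_error == "stop") {
        stop("corpus row ", r, " (", df$spelling[r], "): ",
             conditionMessage(w), call. = FALSE)
      }
      errs[[length(errs) + 1L]] <- data.frame(
        line = r, spelling = df$spelling[r],
        message = conditionMessage(w), stringsAsFactors = FALSE)
    } else {
      words[[length(words) + 1L]] <- w
    }
  }
  attr(words, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), spelling = character(),
               message = character(), stringsAsFactors = FALSE)
  words
}

#' Write an aligned corpus to TSV
#'
#' @param words list of `sublex_word` objects.
#' @param path output file.
#' @export
write_corpus <- function(words, path) {
  df <- data.frame(
    spelling = vapply(words, function(w) w$spelling, ""),
    pronunciation = vapply(words, function(w)
      paste(word_phonemes(w), collapse = ""), ""),
    mapping = vapply(words, format_mapping_notation, ""),
    pron_id = vapply(words, function(w) w$pron_id, 0L),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))),
             con, useBytes = FALSE, sep = "\n")
  invisible(path)
}

#' Path to the bundled demonstration lexicon
#'
#' A small hand-curated aligned lexicon of common English words, shipped for
#' examples and tests. It is a demonstration corpus, not a published norm
#' set; measures computed from it illustrate the machinery, not
#' population-scale English statistics.
#'
#' @return file path.
#' @export
demo_lexicon_path <- function() config_path("demo_lexicon.tsv")
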