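# Phoneme inventory: loading, tokenization, classification.

#' Read a plain-text configuration table
#'
#' Reads a tab-separated config file shipped with the package (or a user
#' replacement), ignoring `#` comment lines. Used for the phoneme inventory
#' and the ARPAbet translation table.
#'
#' @param path file path.
#' @return a data.frame.
#' @keywords internal
read_config_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

config_path <- function(file) {
  p <- system.file("extdata", file, package = "sublexr")
  if (!nzchar(p)) stop("configuration file not found: ", file)
  p
}

#' The phoneme inventory
#'
#' Returns the closed phoneme inventory used throughout the package: IPA-based
#' symbols (diphthongs, affricates and rhotic vowels as single tokens), the
#' vowel/consonant class, the manner of articulation, and an ordinal sonority
#' rank (stop < fricative < nasal < liquid < glide < vowel). The inventory is
#' read from an editable plain-text file so alternative dialect inventories can
#' be swapped in.
#'
#' @param path optional path to an alternative inventory file (tab-separated,
#'   `#` comments; columns `symbol`, `klass`, `manner`, `sonority`).
#' @return a data.frame with one row per phoneme.
#' @export
#' @examples
#' head(phoneme_inventory())
phoneme_inventory <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.sublexr_env$phonemes)) {
      .sublexr_env$phonemes <- read_config_tsv(config_path("phonemes_en.tsv"))
    }
    return(.sublexr_env$phonemes)
  }
  read_config_tsv(path)
}

phoneme_symbols <- function() phoneme_inventory()$symbol

check_phonemes <- function(symbols) {
  bad <- setdiff(symbols, phoneme_symbols())
  if (length(bad)) {
    stop("unknown phoneme symbol(s): ", paste0("/", bad, "/", collapse = ", "),
         call. = FALSE)
  }
  invisible(symbols)
}

#' Is each phoneme a vowel?
#'
#' @param symbols character vector of phoneme symbols.
#' @return logical vector.
#' @export
is_vowel <- function(symbols) {
  inv <- phoneme_inventory()
  check_phonemes(symbols)
  inv$klass[match(symbols, inv$symbol)] == "vowel"
}

#' Sonority rank of phonemes
#'
#' Ordinal sonority rank (stop < fricative < nasal < liquid < glide < vowel),
#' retained for diagnostics; onset legality is decided by the attested-onset
#' whitelist, not by sonority (see [is_legal_onset()]).
#'
#' @param symbols character vector of phoneme symbols.
#' @return integer vector of ranks.
#' @export
sonority <- function(symbols) {
  inv <- phoneme_inventory()
  check_phonemes(symbols)
  inv$sonority[match(symbols, inv$symbol)]
}

#' Tokenize an IPA pronunciation string
#'
#' Splits a string like `"lɑbstəɹ"` into inventory phoneme tokens by greedy
#' longest match, so that digraph symbols (/tʃ/, /eɪ/, ...) come out as single
#' tokens. Stress marks and whitespace are stripped.
#'
#' @param x a single pronunciation string (or a character vector already split
#'   into tokens, which is validated and returned as is).
#' @return character vector of phoneme symbols.
#' @export
#' @examples
#' tokenize_phonemes("lɑbstəɹ")
#' tokenize_phonemes("tʃeɪn")
tokenize_phonemes <- function(x) {
  if (length(x) > 1L) {
    check_phonemes(x)
    return(x)
  }
  if (length(x) == 0L || !nzchar(x)) return(character())
  x <- gsub("[ˈˌ'` .]", "", x)  # stress marks, spaces, dots
  syms <- phoneme_symbols()
  maxlen <- max(nchar(syms))
  chars <- strsplit(x, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      if (cand %in% syms) {
        out <- c(out, cand)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("unknown phoneme symbol at position ", i, " of \"", x, "\": \"",
           chars[i], "\"", call. = FALSE)
    }
  }
  out
}

#' Translate ARPAbet pronunciations to the IPA inventory
#'
#' Converts CMU-dictionary-style symbols (e.g. `"L AA1 B S T ER0"`) to the
#' package's IPA tokens. Lexical stress digits are stripped; the unstressed
#' vowels `AH0`/`ER0` map to the reduced vowels /ə/ and /ɚ/.
#'
#' @param x a single space-separated ARPAbet string or a character vector of
#'   ARPAbet tokens.
#' @return character vector of IPA phoneme symbols.
#' @export
#' @examples
#' arpabet_to_ipa("L AA1 B S T ER0")
arpabet_to_ipa <- function(x) {
  if (is.null(.sublexr_env$arpabet)) {
    .sublexr_env$arpabet <- read_config_tsv(config_path("arpabet_ipa.tsv"))
  }
  tab <- .sublexr_env$arpabet
  toks <- if (length(x) == 1L) strsplit(trimws(x), "\\s+")[[1]] else x
  toks <- toupper(toks)
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    hit <- match(tok, tab$arpabet)                 # exact (stress-aware) first
    if (is.na(hit)) hit <- match(sub("[0-9]$", "", tok), tab$arpabet)
    if (is.na(hit)) stop("unknown ARPAbet symbol: ", tok, call. = FALSE)
    out[i] <- tab$ipa[hit]
  }
  out
}
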