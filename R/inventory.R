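# The grapheme inventory: the attested (phoneme, grapheme, position) mapping
# set used to drive automatic alignment.

segment_kind <- function(seg) {
  if (isTRUE(seg$nonlinear)) return("nonlinearE")
  if (is_discontinuous(seg$notation)) return("silentE")
  if (length(seg$phonemes) == 2L) return("xcluster")
  "normal"
}

#' Build a grapheme inventory from an aligned corpus
#'
#' Collects every attested (phoneme, grapheme) pairing over the corpus with
#' the set of positions it occurs in and its attestation count (number of
#' segment occurrences). Position restrictions are thereby honored downstream:
#' e.g. a corpus in which PP only ever occurs syllable-initially yields an
#' inventory in which PP is not admissible word-initially.
#'
#' @param words list of position-assigned `sublex_word` objects.
#' @return a data.frame of class `sublex_inventory` with columns `phoneme`,
#'   `grapheme`, `kind`, `positions` (comma-separated), `count`.
#' @export
build_inventory <- function(words) {
  stopifnot(length(words) > 0L)
  rows <- lapply(words, function(w) {
    if (all(is.na(w$positions))) w <- assign_positions(w)
    data.table(
      phoneme = vapply(w$segments, function(s) paste(s$phonemes, collapse = ""), ""),
      grapheme = vapply(w$segments, function(s) s$notation, ""),
      kind = vapply(w$segments, segment_kind, ""),
      position = w$positions
    )
  })
  dt <- rbindlist(rows)
  inv <- dt[, .(positions = paste(sort(unique(position)), collapse = ","),
                count = .N),
            by = .(phoneme, grapheme, kind)]
  setorder(inv, grapheme, phoneme, kind)
  out <- as.data.frame(inv)
  attr(out, "version") <- "corpus-derived"
  class(out) <- c("sublex_inventory", "data.frame")
  out
}

inventory_positions <- function(inv) {
  strsplit(inv$positions, ",", fixed = TRUE)
}

#' Is a mapping admissible in a given position?
#'
#' @param inventory a `sublex_inventory`.
#' @param grapheme grapheme notation.
#' @param phoneme phoneme string (concatenated symbols).
#' @param position a phonographeme position code, or `NULL` to test bare
#'   attestation.
#' @return a single logical.
#' @export
inventory_admits <- function(inventory, grapheme, phoneme, position = NULL) {
  hit <- inventory$grapheme == grapheme & inventory$phoneme == phoneme
  if (!any(hit)) return(FALSE)
  if (is.null(position)) return(TRUE)
  any(vapply(inventory_positions(inventory)[hit],
             function(p) position %in% p, TRUE))
}

#' Write / read an inventory as TSV
#'
#' Plain-text export with one row per (phoneme, grapheme) mapping: columns
#' `phoneme`, `grapheme`, `kind`, `positions`, `count`; deterministic order.
#'
#' @param inventory a `sublex_inventory`.
#' @param path file path.
#' @export
write_inventory <- function(inventory, path) {
  write.table(as.data.frame(inventory), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("phoneme", "grapheme", "kind", "positions", "count")
  if (!all(needed %in% names(out))) {
    stop("inventory file lacks columns: ",
         paste(setdiff(needed, names(out)), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("sublex_inventory", "data.frame")
  out
}

#' @export
print.sublex_inventory <- function(x, ...) {
  cat("<sublex_inventory> ", nrow(x), " phoneme-grapheme mappings, ",
      length(unique(x$grapheme)), " graphemes\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
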