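#' Default phonetic-segment vowel inventory
#'
#' Segment symbols treated as vowel nuclei when parsing pronunciations.
#' The set is a broad-coverage Swedish-style X-SAMPA inventory (long vowels
#' carry a trailing colon). Every function that inspects pronunciations takes
#' a `vowels` argument so the inventory can be swapped for other transcription
#' schemes.
#'
#' @return Character vector of vowel segment symbols.
#' @export
pran_vowels <- function() {
  c(
    "i:", "I", "e:", "e", "E:", "E", "{:", "{", "a", "A:",
    "o:", "O", "u:", "U", "u0", "}:", "y:", "Y", "2:", "9",
    "@", "au", "eu"
  )
}

#' Construct a word-initial fragment (WIF) key
#'
#' A WIF is the competition unit of the analysis: an ordered sequence of
#' phonetic segments ending in the first (stressed) vowel, paired with a word
#' accent (1 or 2). Two WIFs with identical segments but different accents are
#' distinct keys.
#'
#' @param segments Character vector of segment symbols; the last (and only the
#'   last) must be a vowel.
#' @param accent Word accent, 1 or 2.
#' @param vowels Vowel inventory, see [pran_vowels()].
#' @return An object of class `wif_key`: a list with elements `segments`,
#'   `accent` and the canonical string `id` (segments joined by spaces, then
#'   `"|"` and the accent, e.g. `"b o:|1"`).
#' @export
wif_key <- function(segments, accent, vowels = pran_vowels()) {
  segments <- as.character(segments)
  if (length(segments) < 1L) {
    stop("a WIF needs at least one segment", call. = FALSE)
  }
  accent <- as.integer(accent)
  if (length(accent) != 1L || is.na(accent) || !accent %in% c(1L, 2L)) {
    stop("WIF accent must be 1 or 2", call. = FALSE)
  }
  is_v <- segments %in% vowels
  if (!is_v[length(segments)]) {
    stop("last WIF segment must be a vowel: ", segments[length(segments)],
      call. = FALSE
    )
  }
  if (any(is_v[-length(segments)])) {
    stop("a WIF ends at its first vowel; found an earlier vowel in: ",
      paste(segments, collapse = " "),
      call. = FALSE
    )
  }
  structure(
    list(segments = segments, accent = accent, id = wif_id(segments, accent)),
    class = "wif_key"
  )
}

#' Canonical WIF id string
#'
#' @param segments Character vector of segment symbols.
#' @param accent Word accent (1 or 2).
#' @return Character scalar, e.g. `"b o:|1"`.
#' @export
wif_id <- function(segments, accent) {
  paste0(paste(segments, collapse = " "), "|", accent)
}

#' Parse a WIF id string back into segments and accent
#'
#' @param id Character vector of WIF ids as produced by [wif_id()].
#' @return Data frame with columns `wif` (the id), `wif_segments`
#'   (space-joined segments) and `accent` (integer).
#' @export
parse_wif_id <- function(id) {
  bar <- regexpr("\\|[12]$", id)
  if (any(bar < 0L)) {
    stop(
      "not a WIF id (expected '<segments>|<accent>'): ",
      paste(id[bar < 0L], collapse = ", "),
      call. = FALSE
    )
  }
  data.frame(
    wif = id,
    wif_segments = substr(id, 1L, bar - 1L),
    accent = as.integer(substr(id, bar + 1L, nchar(id))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.wif_key <- function(x, ...) {
  cat(
    "<wif_key> ", paste(x$segments, collapse = " "),
    " (accent ", x$accent, ")\n",
    sep = ""
  )
  invisible(x)
}
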