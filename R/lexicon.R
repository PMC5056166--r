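#' Parse a whitespace-tokenized pronunciation string
#'
#' The pronunciation dialect is a whitespace-separated token stream: segment
#' symbols, the accent-stress markers `"1` / `"2` (accent-1 or accent-2
#' primary stress, attaching to the immediately following vowel token), and
#' `$` (syllable boundary, validated but otherwise ignored). At most one
#' stress marker per pronunciation.
#'
#' @param pron Pronunciation string, e.g. `'b "2 o: t $ h u: s'`.
#' @param vowels Vowel inventory; see [pran_vowels()].
#' @return List with elements `segments` (character vector, markers and
#'   boundaries removed), `stress_index` (1-based index into `segments` of the
#'   primary-stressed vowel, `NA` if unstressed), `accent` (integer 1/2 or
#'   `NA`) and `syllable_count` (number of vowel-nucleus segments).
#' @examples
#' parse_pronunciation('f "1 I s k')
#' @export
parse_pronunciation <- function(pron, vowels = pran_vowels()) {
  if (length(pron) != 1L || is.na(pron)) {
    stop_malformed("pronunciation must be a single string")
  }
  tokens <- strsplit(trimws(pron), "[ \t]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  segments <- character(0)
  stress_index <- NA_integer_
  accent <- NA_integer_
  pending <- NA_integer_ # accent of a marker awaiting its vowel
  for (tok in tokens) {
    if (tok %in% c("\"1", "\"2")) {
      if (!is.na(accent) || !is.na(pending)) {
        stop_malformed("more than one stress marker in: ", pron)
      }
      pending <- if (tok == "\"1") 1L else 2L
    } else if (tok == "$") {
      next
    } else {
      segments <- c(segments, tok)
      if (!is.na(pending)) {
        if (!tok %in% vowels) {
          stop_malformed(
            "stress marker not followed by a vowel token ('", tok,
            "') in: ", pron
          )
        }
        stress_index <- length(segments)
        accent <- pending
        pending <- NA_integer_
      }
    }
  }
  if (!is.na(pending)) {
    stop_malformed("stress marker at end of pronunciation: ", pron)
  }
  list(
    segments = segments,
    stress_index = stress_index,
    accent = accent,
    syllable_count = sum(segments %in% vowels)
  )
}

stop_malformed <- function(...) {
  stop(structure(
    class = c("pran_malformed_pronunciation", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Parse a delimited pronunciation lexicon
#'
#' Reads a full-form lexicon stored as delimited text (default delimiter
#' `";"`, as in multi-field lexicon dumps), one entry per line. `column_map`
#' selects which 1-based fields hold the orthography, the word-class tag and
#' the pronunciation; all other fields are ignored, so the same reader works
#' for minimal 4-field files and for wide many-field exports.
#'
#' Malformed lines (fewer fields than `column_map` requires, or an invalid
#' pronunciation) are skipped and tallied in the parse report attached as
#' attribute `"parse_report"`.
#'
#' @param path Path to the lexicon file (UTF-8).
#' @param column_map Named list with 1-based field indices `orthography`,
#'   `word_class`, `pronunciation`.
#' @param delimiter Field delimiter, default `";"`.
#' @param vowels Vowel inventory; see [pran_vowels()].
#' @return A `pran_lexicon` data frame with one row per parsed entry and
#'   columns `orthography`, `word_class`, `pron` (raw string), `segments`
#'   (list column), `stress_index`, `accent`, `syllable_count`, `frequency`
#'   (0 until [apply_frequency_filter()] attaches corpus counts) and `wif`
#'   (canonical WIF id, `NA` for entries without an initial-stress WIF).
#' @export
parse_lexicon <- function(path,
                          column_map = list(
                            orthography = 1L, word_class = 2L,
                            pronunciation = 4L
                          ),
                          delimiter = ";",
                          vowels = pran_vowels()) {
  if (!file.exists(path)) {
    stop("cannot read lexicon file: ", path, call. = FALSE)
  }
  needed <- c("orthography", "word_class", "pronunciation")
  if (!all(needed %in% names(column_map))) {
    stop(
      "column_map must name fields: ",
      paste(setdiff(needed, names(column_map)), collapse = ", "),
      call. = FALSE
    )
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  max_field <- max(unlist(column_map[needed]))

  n_short <- 0L
  n_badpron <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], delimiter, fixed = TRUE)[[1]]
    if (length(fields) < max_field) {
      n_short <- n_short + 1L
      next
    }
    pron <- fields[[column_map$pronunciation]]
    parsed <- tryCatch(
      parse_pronunciation(pron, vowels = vowels),
      pran_malformed_pronunciation = function(e) NULL
    )
    if (is.null(parsed)) {
      n_badpron <- n_badpron + 1L
      next
    }
    rows[[i]] <- list(
      orthography = fields[[column_map$orthography]],
      word_class = fields[[column_map$word_class]],
      pron = pron,
      parsed = parsed
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]

  entries <- data.frame(
    orthography = vapply(rows, `[[`, character(1), "orthography"),
    word_class = vapply(rows, `[[`, character(1), "word_class"),
    pron = vapply(rows, `[[`, character(1), "pron"),
    stringsAsFactors = FALSE
  )
  if (nrow(entries)) {
    entries$segments <- I(lapply(rows, function(r) r$parsed$segments))
    entries$stress_index <-
      vapply(rows, function(r) r$parsed$stress_index, integer(1))
    entries$accent <- vapply(rows, function(r) r$parsed$accent, integer(1))
    entries$syllable_count <-
      vapply(rows, function(r) r$parsed$syllable_count, integer(1))
  } else {
    entries$segments <- I(list())
    entries$stress_index <- integer(0)
    entries$accent <- integer(0)
    entries$syllable_count <- integer(0)
  }
  entries$frequency <- rep(0L, nrow(entries))
  entries$wif <- entry_wif_ids(entries, vowels = vowels)

  if (n_short + n_badpron > 0L) {
    warning(
      "skipped ", n_short + n_badpron, " malformed lexicon line(s) (",
      n_short, " with too few fields, ", n_badpron,
      " with malformed pronunciations)",
      call. = FALSE
    )
  }
  structure(
    entries,
    class = c("pran_lexicon", "data.frame"),
    parse_report = list(
      n_lines = length(lines),
      n_parsed = nrow(entries),
      n_skipped = n_short + n_badpron,
      n_short_lines = n_short,
      n_malformed_pron = n_badpron
    )
  )
}

# Vectorised WIF extraction over a lexicon data frame: the WIF exists only
# when the entry carries an accent and its stressed vowel is the first vowel.
entry_wif_ids <- function(entries, vowels = pran_vowels()) {
  n <- nrow(entries)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  for (i in seq_len(n)) {
    si <- entries$stress_index[[i]]
    ac <- entries$accent[[i]]
    if (is.na(si) || is.na(ac)) next
    segs <- entries$segments[[i]]
    before <- segs[seq_len(si - 1L)]
    if (any(before %in% vowels)) next # stress not on the first vowel
    out[[i]] <- wif_id(segs[seq_len(si)], ac)
  }
  out
}

#' Extract the word-initial fragment of a lexicon entry
#'
#' Returns the entry's segments from the word onset up to and including the
#' stressed vowel, paired with the entry's word accent. Entries without a
#' stress/accent marking, or whose stress falls on a non-initial vowel
#' (initial-syllable stress is required for a WIF), yield `NULL`.
#'
#' @param entry One row of a [parse_lexicon()] data frame, or a list with
#'   elements `segments`, `stress_index`, `accent`.
#' @param vowels Vowel inventory.
#' @return A [wif_key()] or `NULL`.
#' @export
extract_wif <- function(entry, vowels = pran_vowels()) {
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1L)
    entry <- list(
      segments = entry$segments[[1L]],
      stress_index = entry$stress_index[[1L]],
      accent = entry$accent[[1L]]
    )
  }
  si <- entry$stress_index
  ac <- entry$accent
  if (is.na(si) || is.na(ac)) return(NULL)
  segs <- entry$segments
  if (any(segs[seq_len(si - 1L)] %in% vowels)) return(NULL)
  wif_key(segs[seq_len(si)], ac, vowels = vowels)
}

#' Read a word-frequency table
#'
#' Two-column delimited text: orthography and non-negative corpus count.
#' Lookups of unlisted words return 0.
#'
#' @param path Path to the frequency file.
#' @param min_frequency Inclusion threshold used by
#'   [apply_frequency_filter()]; default 2 (words occurring at least twice in
#'   the corpus).
#' @param delimiter Field delimiter, default tab.
#' @return A `pran_freq_table` data frame with columns `orthography`, `count`
#'   and attribute `min_frequency`.
#' @export
read_frequency_table <- function(path, min_frequency = 2L, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("cannot read frequency file: ", path, call. = FALSE)
  }
  d <- utils::read.delim(path,
    sep = delimiter, header = FALSE,
    col.names = c("orthography", "count"),
    colClasses = c("character", "integer"),
    quote = "", fileEncoding = "UTF-8"
  )
  if (any(d$count < 0L)) stop("negative corpus count", call. = FALSE)
  frequency_table(d, min_frequency)
}

#' Build a frequency table from a data frame
#'
#' @param counts Data frame with columns `orthography` and `count`.
#' @param min_frequency Inclusion threshold, default 2.
#' @return A `pran_freq_table` data frame.
#' @export
frequency_table <- function(counts, min_frequency = 2L) {
  stopifnot(all(c("orthography", "count") %in% names(counts)))
  structure(
    data.frame(
      orthography = as.character(counts$orthography),
      count = as.integer(counts$count),
      stringsAsFactors = FALSE
    ),
    class = c("pran_freq_table", "data.frame"),
    min_frequency = as.integer(min_frequency)
  )
}

#' Look up corpus frequencies (0 for unlisted words)
#'
#' @param freq A `pran_freq_table`.
#' @param words Character vector of orthographies.
#' @return Integer vector of counts, 0 where unlisted.
#' @export
frequency_of <- function(freq, words) {
  idx <- match(words, freq$orthography)
  out <- freq$count[idx]
  out[is.na(out)] <- 0L
  out
}

#' Apply the corpus-frequency inclusion filter to a lexicon
#'
#' Attaches each entry's corpus count and keeps exactly the entries whose
#' orthography reaches the threshold (frequency >= `min_frequency`), in their
#' original order. A threshold of 0 is the identity filter.
#'
#' @param entries A [parse_lexicon()] data frame.
#' @param freq A frequency table ([read_frequency_table()]).
#' @param min_frequency Threshold; defaults to the table's own
#'   `min_frequency` attribute.
#' @return The filtered lexicon with the `frequency` column populated.
#' @export
apply_frequency_filter <- function(entries, freq, min_frequency = NULL) {
  if (is.null(min_frequency)) {
    min_frequency <- attr(freq, "min_frequency")
  }
  min_frequency <- as.integer(min_frequency)
  if (is.na(min_frequency) || min_frequency < 0L) {
    stop("min_frequency must be a non-negative integer", call. = FALSE)
  }
  entries$frequency <- frequency_of(freq, entries$orthography)
  out <- entries[entries$frequency >= min_frequency, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default competitor-set constraints
#'
#' The analysis restricts competitors to polysyllabic nouns with
#' initial-syllable stress; these toggles reproduce or relax that.
#'
#' @param word_class Word-class tag competitors must carry (`NULL` to ignore).
#' @param polysyllabic Require at least two vowel nuclei.
#' @param initial_stress Require primary stress on the first vowel (always
#'   true of any entry that has a WIF at all; kept as an explicit toggle).
#' @return Named list of constraints.
#' @export
pran_constraints <- function(word_class = "NN", polysyllabic = TRUE,
                             initial_stress = TRUE) {
  list(
    word_class = word_class,
    polysyllabic = polysyllabic,
    initial_stress = initial_stress
  )
}

# Logical index of entries satisfying the constraint set.
constraint_mask <- function(entries, constraints) {
  keep <- rep(TRUE, nrow(entries))
  if (!is.null(constraints$word_class)) {
    keep <- keep & entries$word_class %in% constraints$word_class
  }
  if (isTRUE(constraints$polysyllabic)) {
    keep <- keep & entries$syllable_count >= 2L
  }
  if (isTRUE(constraints$initial_stress)) {
    # entries with a WIF necessarily have initial stress; others are excluded
    keep <- keep & !is.na(entries$wif)
  }
  keep
}

#' Count the lexical competitors of a WIF
#'
#' The competitor count of a WIF is the number of lexicon entries (word
#' forms) whose own word-initial fragment equals the query — same segment
#' sequence and same word accent — and that satisfy the constraint set.
#' The carrier word itself is part of its cohort, so an attested WIF always
#' counts at least 1. Homographic entries (same orthography, different
#' pronunciation lines) count once per form.
#'
#' @param wif A [wif_key()], a canonical WIF id string, or anything accepted
#'   by [parse_wif_id()].
#' @param entries Lexicon entries, already frequency-filtered.
#' @param constraints See [pran_constraints()].
#' @return Non-negative integer count (0 when the WIF is unattested).
#' @export
count_competitors <- function(wif, entries, constraints = pran_constraints()) {
  id <- if (inherits(wif, "wif_key")) wif$id else as.character(wif)
  stopifnot(length(id) == 1L)
  keep <- constraint_mask(entries, constraints)
  sum(!is.na(entries$wif) & entries$wif == id & keep)
}

#' Competitor counts, log-competition and z-scores for a WIF set
#'
#' Computes, for each queried WIF, its competitor count under the constraint
#' set, the log-transformed count, and the z-score of the log count
#' standardized over exactly the supplied WIF set (sample SD, n-1
#' denominator). Rows are sorted by WIF key (segments, then accent) so output
#' is deterministic. z-scores are invariant to the log base.
#'
#' @param wifs Character vector of WIF ids, a list of [wif_key()]s, or a data
#'   frame with columns `wif_segments` and `accent`.
#' @param entries Frequency-filtered lexicon entries.
#' @param constraints See [pran_constraints()].
#' @param log_base Base of the log transform, default `exp(1)`.
#' @return Data frame (class `competition_table`) with columns `wif`,
#'   `wif_segments`, `accent`, `count`, `log_count`, `z_log_count`, `group`
#'   (`"unassigned"` until [median_split()] is applied).
#' @export
competition_table <- function(wifs, entries,
                              constraints = pran_constraints(),
                              log_base = exp(1)) {
  ids <- wif_ids_of(wifs)
  if (!length(ids)) stop("no WIFs supplied", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicated WIFs supplied", call. = FALSE)

  keep <- constraint_mask(entries, constraints)
  tab <- table(entries$wif[keep & !is.na(entries$wif)])
  counts <- as.integer(tab[ids])
  counts[is.na(counts)] <- 0L
  if (any(counts == 0L)) {
    stop(
      "WIF(s) not attested in the lexicon under the constraints: ",
      paste(ids[counts == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  out <- parse_wif_id(ids)
  out$count <- counts
  out$log_count <- log(counts, base = log_base)
  out$z_log_count <- zscore_or_zero(out$log_count)
  out$group <- rep("unassigned", nrow(out))
  out <- out[order(out$wif_segments, out$accent), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("competition_table", "data.frame")
  out
}

wif_ids_of <- function(wifs) {
  if (is.character(wifs)) {
    wifs
  } else if (is.data.frame(wifs)) {
    if ("wif" %in% names(wifs)) {
      wifs$wif
    } else {
      paste0(wifs$wif_segments, "|", wifs$accent)
    }
  } else if (is.list(wifs)) {
    vapply(
      wifs,
      function(w) if (inherits(w, "wif_key")) w$id else as.character(w),
      character(1)
    )
  } else {
    stop("cannot interpret `wifs`", call. = FALSE)
  }
}

# Sample-SD z-score; all-equal input degenerates to zeros with a warning
# rather than NaN so edge-case fixtures stay runnable.
zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (length(x) < 2L || is.na(s) || s == 0) {
    warning("zero variance when z-scoring; returning zeros",
      call. = FALSE
    )
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Ratio of mean continuations: accent 2 over accent 1
#'
#' Over the WIF inventory induced by the (constrained) lexicon, computes the
#' mean competitor count of accent-2 WIFs divided by that of accent-1 WIFs.
#' In Swedish-like lexicons, productive compounding inflates accent-2
#' continuations, putting this ratio near an order of magnitude.
#'
#' @param entries Frequency-filtered lexicon entries.
#' @param constraints See [pran_constraints()].
#' @return Positive real ratio.
#' @export
accent_continuation_ratio <- function(entries,
                                      constraints = pran_constraints()) {
  keep <- constraint_mask(entries, constraints)
  ids <- entries$wif[keep & !is.na(entries$wif)]
  if (!length(ids)) stop("no WIFs attested under the constraints", call. = FALSE)
  tab <- table(ids)
  acc <- as.integer(sub("^.*\\|", "", names(tab)))
  m1 <- mean(tab[acc == 1L])
  m2 <- mean(tab[acc == 2L])
  if (!length(tab[acc == 1L]) || is.na(m1) || m1 == 0) {
    stop("no accent-1 WIFs attested; ratio undefined", call. = FALSE)
  }
  if (!length(tab[acc == 2L])) {
    stop("no accent-2 WIFs attested; ratio undefined", call. = FALSE)
  }
  unname(m2 / m1)
}

#' Write / read a competition table as tab-separated text
#'
#' @param x A [competition_table()] data frame.
#' @param path Output path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_competition_table <- function(x, path) {
  utils::write.table(
    x[, c("wif", "wif_segments", "accent", "count", "log_count",
          "z_log_count", "group")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_competition_table
#' @export
read_competition_table <- function(path) {
  d <- utils::read.delim(path,
    sep = "\t", quote = "", stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"
  )
  class(d) <- c("competition_table", "data.frame")
  d
}
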