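# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
    normal.kind = "Inversion", sample.kind = "Rejection"
  )
  force(code)
}

#' Configuration for the synthetic lexicon generator
#'
#' Defaults state the lexical world the analysis assumes: each word-initial
#' fragment occurs with both word accents; accent-1 WIFs average 24.8
#' continuations and accent-2 WIFs 248.5 (a roughly 10x accent asymmetry
#' driven by productive compounding). Competitor counts are right-skewed
#' (log-normal, rounded, floored at 1), matching SDs on the order of the
#' means. Distractor entries are constructed to fail exactly one competitor
#' filter each: wrong word class, non-initial stress, monosyllabic, or
#' corpus frequency below threshold.
#'
#' @param seed RNG seed.
#' @param n_wifs Number of distinct segment fragments (each paired with both
#'   accents), default 26.
#' @param mean_continuations Named numeric, mean competitor count per accent,
#'   defaults `c(accent1 = 24.8, accent2 = 248.5)`.
#' @param dispersion Log-normal sdlog of competitor counts, default 0.7.
#' @param consonants,vowels Segment alphabet.
#' @param distractor_rates Named proportions (relative to the number of
#'   qualifying entries) of distractor entries per failure mode:
#'   `word_class`, `stress`, `monosyllabic`, `frequency`.
#' @param n_malformed Number of deliberately corrupt lines appended to the
#'   lexicon file (skipped by the parser), default 0.
#' @return List of class `lexicon_sim_config`.
#' @export
lexicon_sim_config <- function(seed = 1L,
                               n_wifs = 26L,
                               mean_continuations = c(
                                 accent1 = 24.8, accent2 = 248.5
                               ),
                               dispersion = 0.7,
                               consonants = c(
                                 "b", "d", "f", "g", "h", "j", "k", "l",
                                 "m", "n", "p", "r", "s", "t", "v"
                               ),
                               vowels = c(
                                 "a", "A:", "e:", "E", "i:", "I",
                                 "o:", "O", "u:", "U", "y:", "2:"
                               ),
                               distractor_rates = c(
                                 word_class = 0.05, stress = 0.05,
                                 monosyllabic = 0.05, frequency = 0.05
                               ),
                               n_malformed = 0L) {
  stopifnot(
    n_wifs >= 1L, all(mean_continuations > 0), dispersion >= 0,
    all(distractor_rates >= 0), all(distractor_rates <= 1),
    n_malformed >= 0L
  )
  structure(
    list(
      seed = as.integer(seed), n_wifs = as.integer(n_wifs),
      mean_continuations = mean_continuations, dispersion = dispersion,
      consonants = consonants, vowels = vowels,
      distractor_rates = distractor_rates,
      n_malformed = as.integer(n_malformed)
    ),
    class = "lexicon_sim_config"
  )
}

#' Generate a synthetic pronunciation lexicon with known competitor counts
#'
#' Constructs (rather than samples away) entries, so realized competitor
#' counts equal the recorded ground truth exactly: for every fragment x
#' accent WIF a target count is drawn and exactly that many qualifying
#' polysyllabic noun entries with initial-syllable stress and corpus
#' frequency >= 2 are emitted. Distractor entries each violate exactly one
#' filter. Output files are parseable by [parse_lexicon()] /
#' [read_frequency_table()]; identical seeds give byte-identical files.
#'
#' The lexicon file has six `;`-separated fields
#' (orthography; word class; lemma; pronunciation; morphology; source) read
#' with the default `column_map` of [parse_lexicon()]. Frequency-distractor
#' words with corpus count 0 are omitted from the frequency file so the
#' unlisted-word lookup path is exercised.
#'
#' @param config A [lexicon_sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `lexicon_file`, `frequency_file`, `truth_file`, `truth`
#'   (data frame `wif`, `wif_segments`, `accent`, `count`), `distractors`
#'   (data frame `orthography`, `type`), `n_entries` (total lexicon lines
#'   excluding malformed), `n_malformed`, and `config`.
#' @export
simulate_lexicon <- function(config = lexicon_sim_config(),
                             dir = tempfile("pran_lex")) {
  stopifnot(inherits(config, "lexicon_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    frag <- draw_fragments(config)
    n_wifs <- config$n_wifs

    meanlog <- log(config$mean_continuations) - config$dispersion^2 / 2
    counts <- list(
      `1` = pmax(1L, as.integer(round(stats::rlnorm(
        n_wifs, meanlog[["accent1"]], config$dispersion
      )))),
      `2` = pmax(1L, as.integer(round(stats::rlnorm(
        n_wifs, meanlog[["accent2"]], config$dispersion
      ))))
    )

    lex_lines <- character(0)
    freq_orth <- character(0)
    freq_count <- integer(0)
    truth <- vector("list", 2L * n_wifs)

    for (a in c(1L, 2L)) {
      for (w in seq_len(n_wifs)) {
        cnt <- counts[[as.character(a)]][w]
        orth <- sprintf("w%02da%dx%03d", w, a, seq_len(cnt))
        pron <- qualifying_pron(frag[[w]], a, cnt, config)
        freqs <- 2L + stats::rnbinom(cnt, size = 1, mu = 48)
        lex_lines <- c(lex_lines, lexicon_line(orth, "NN", pron))
        freq_orth <- c(freq_orth, orth)
        freq_count <- c(freq_count, freqs)
        truth[[(a - 1L) * n_wifs + w]] <- data.frame(
          wif = wif_id(frag[[w]], a),
          wif_segments = paste(frag[[w]], collapse = " "),
          accent = a,
          count = cnt,
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- do.call(rbind, truth)
    n_qual <- sum(truth$count)

    distract <- make_distractors(frag, config, n_qual)
    lex_lines <- c(lex_lines, distract$lines)
    freq_orth <- c(freq_orth, distract$freq_orth)
    freq_count <- c(freq_count, distract$freq_count)

    if (config$n_malformed > 0L) {
      lex_lines <- c(
        lex_lines,
        sprintf("corrupt%03d;NN", seq_len(config$n_malformed))
      )
    }

    lexicon_file <- file.path(dir, "lexicon.txt")
    frequency_file <- file.path(dir, "frequency.tsv")
    truth_file <- file.path(dir, "competitor_truth.tsv")
    writeLines(lex_lines, lexicon_file, useBytes = TRUE)
    writeLines(
      paste(freq_orth, freq_count, sep = "\t"),
      frequency_file,
      useBytes = TRUE
    )
    utils::write.table(truth, truth_file,
      sep = "\t", quote = FALSE,
      row.names = FALSE, fileEncoding = "UTF-8"
    )
    list(
      lexicon_file = lexicon_file,
      frequency_file = frequency_file,
      truth_file = truth_file,
      truth = truth,
      distractors = distract$truth,
      n_entries = length(lex_lines) - config$n_malformed,
      n_malformed = config$n_malformed,
      config = config
    )
  })
}

# n_wifs distinct CV / CCV fragments (list of segment vectors).
draw_fragments <- function(config) {
  cons <- config$consonants
  vow <- config$vowels
  cv <- expand.grid(c1 = cons, v = vow,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  ccv <- expand.grid(c1 = cons, c2 = cons, v = vow,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  ccv <- ccv[ccv$c1 != ccv$c2, , drop = FALSE]
  pool <- c(
    lapply(seq_len(nrow(cv)), function(i) c(cv$c1[i], cv$v[i])),
    lapply(seq_len(nrow(ccv)), function(i) c(ccv$c1[i], ccv$c2[i], ccv$v[i]))
  )
  if (config$n_wifs > length(pool)) {
    stop("segment alphabet too small for ", config$n_wifs,
      " distinct fragments",
      call. = FALSE
    )
  }
  pool[sample.int(length(pool), config$n_wifs)]
}

# Pronunciations of n qualifying entries carrying fragment `frag` with
# accent `a`: marker on the first vowel, plus a second syllable.
qualifying_pron <- function(frag, a, n, config) {
  marked <- paste(
    c(utils::head(frag, -1L), paste0("\"", a), utils::tail(frag, 1L)),
    collapse = " "
  )
  cont_c <- sample(config$consonants, n, replace = TRUE)
  cont_v <- sample(config$vowels, n, replace = TRUE)
  final <- ifelse(
    stats::runif(n) < 0.5,
    sample(config$consonants, n, replace = TRUE),
    ""
  )
  trimws(paste(marked, "$", cont_c, cont_v, final))
}

lexicon_line <- function(orth, pos, pron) {
  paste(orth, pos, orth, pron, "SIN-IND", "syn", sep = ";")
}

make_distractors <- function(frag, config, n_qual) {
  rates <- config$distractor_rates
  types <- c("word_class", "stress", "monosyllabic", "frequency")
  n_per <- stats::setNames(
    as.integer(round(rates[types] * n_qual)), types
  )
  n_per[is.na(n_per)] <- 0L
  lines <- character(0)
  freq_orth <- character(0)
  freq_count <- integer(0)
  truth <- list()
  for (ty in types) {
    n <- n_per[[ty]]
    if (n == 0L) next
    wi <- sample.int(config$n_wifs, n, replace = TRUE)
    acc <- sample(c(1L, 2L), n, replace = TRUE)
    orth <- sprintf("d_%s_%03d", substr(ty, 1L, 4L), seq_len(n))
    cont_c <- sample(config$consonants, n, replace = TRUE)
    cont_v <- sample(config$vowels, n, replace = TRUE)
    pron <- character(n)
    pos <- rep("NN", n)
    fq <- 2L + stats::rnbinom(n, size = 1, mu = 48)
    for (i in seq_len(n)) {
      f <- frag[[wi[i]]]
      marked <- paste(
        c(utils::head(f, -1L), paste0("\"", acc[i]), utils::tail(f, 1L)),
        collapse = " "
      )
      pron[i] <- switch(ty,
        # correct structure, wrong word class
        word_class = paste(marked, "$", cont_c[i], cont_v[i]),
        # stress/accent marker on the second vowel, not the first
        stress = paste(
          paste(f, collapse = " "), "$", cont_c[i],
          paste0("\"", acc[i]), cont_v[i]
        ),
        # single syllable: fragment plus a coda consonant only
        monosyllabic = paste(marked, cont_c[i]),
        # qualifying structure but corpus frequency below threshold
        frequency = paste(marked, "$", cont_c[i], cont_v[i])
      )
    }
    if (ty == "word_class") pos <- rep("VB", n)
    if (ty == "frequency") {
      fq <- rep(c(0L, 1L), length.out = n)
    }
    lines <- c(lines, lexicon_line(orth, pos, pron))
    # frequency 0 means "unlisted": omit from the frequency file
    keep <- fq > 0L
    freq_orth <- c(freq_orth, orth[keep])
    freq_count <- c(freq_count, fq[keep])
    truth[[ty]] <- data.frame(
      orthography = orth, type = ty, stringsAsFactors = FALSE
    )
  }
  list(
    lines = lines,
    freq_orth = freq_orth,
    freq_count = freq_count,
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(orthography = character(0), type = character(0))
  )
}
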