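# Independent oracles and fixture builders. These re-derive expected values
# by routes separate from the package implementation: explicit double loops
# for competitor counting, stats::aov() Error-strata fits for the
# repeated-measures ANOVA, and nested-loop averaging for ERPs.

# --- lexicon oracles ---------------------------------------------------------

# WIF of one entry, re-derived from first principles: the fragment exists only
# when the stressed vowel is the entry's first vowel.
oracle_wif <- function(segments, stress_index, accent,
                       vowels = pran_vowels()) {
  if (is.na(stress_index) || is.na(accent)) {
    return(NA_character_)
  }
  vow_pos <- which(segments %in% vowels)
  if (!length(vow_pos) || vow_pos[1] != stress_index) {
    return(NA_character_)
  }
  paste0(
    paste(segments[seq_len(stress_index)], collapse = " "), "|", accent
  )
}

# Brute-force competitor count: scan every entry, apply each constraint
# explicitly, compare re-derived WIFs.
oracle_count <- function(id, entries, word_class = "NN",
                         polysyllabic = TRUE, vowels = pran_vowels()) {
  n <- 0L
  for (i in seq_len(nrow(entries))) {
    if (!is.null(word_class) && entries$word_class[i] != word_class) next
    if (polysyllabic && sum(entries$segments[[i]] %in% vowels) < 2L) next
    w <- oracle_wif(
      entries$segments[[i]], entries$stress_index[i], entries$accent[i],
      vowels
    )
    if (!is.na(w) && w == id) n <- n + 1L
  }
  n
}

# Random lexicon lines in the 6-field layout: random segment strings with a
# stress marker inserted before a randomly chosen vowel (80% of lines).
random_lexicon_lines <- function(n, seed) {
  set.seed(seed)
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vows <- c("a", "e:", "i:", "o:", "u:", "E", "I", "O")
  vapply(seq_len(n), function(i) {
    len <- sample(2:6, 1)
    toks <- ifelse(runif(len) < 0.45, sample(vows, len, replace = TRUE),
      sample(cons, len, replace = TRUE)
    )
    vpos <- which(toks %in% vows)
    if (length(vpos) && runif(1) < 0.8) {
      at <- sample(vpos, 1)
      toks <- append(toks, paste0("\"", sample(1:2, 1)), after = at - 1L)
    }
    pos <- sample(c("NN", "NN", "NN", "VB", "JJ"), 1)
    paste(paste0("word", i), pos, paste0("lemma", i),
      paste(toks, collapse = " "), "X", "Y",
      sep = ";"
    )
  }, character(1))
}

random_lexicon <- function(n, seed) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(random_lexicon_lines(n, seed), path)
  suppressWarnings(parse_lexicon(path))
}

# --- ANOVA oracle ------------------------------------------------------------

# Independent repeated-measures ANOVA via stats::aov() with Error strata.
aov_oracle <- function(data, dv, subject, factors) {
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  rhs <- paste(factors, collapse = "*")
  fml <- stats::as.formula(
    paste(dv, "~", rhs, "+ Error(", subject, "/(", rhs, "))")
  )
  sm <- summary(stats::aov(fml, data = d))
  rows <- list()
  for (stratum in sm) {
    tb <- stratum[[1]]
    rn <- trimws(rownames(tb))
    res <- which(rn == "Residuals")
    for (r in which(!rn %in% c("Residuals"))) {
      if (is.na(tb$`F value`[r])) next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", rn[r]),
        df_num = tb$Df[r],
        df_den = tb$Df[res],
        F = tb$`F value`[r],
        p = tb$`Pr(>F)`[r],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Random balanced within-subjects cell means.
random_cells <- function(n_subj, levels_per_factor, seed) {
  set.seed(seed)
  fls <- lapply(seq_along(levels_per_factor), function(i) {
    paste0("f", i, "_", seq_len(levels_per_factor[i]))
  })
  names(fls) <- paste0("f", seq_along(levels_per_factor))
  g <- expand.grid(
    c(list(subject = paste0("s", seq_len(n_subj))), fls),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  g$mean_amplitude <- rnorm(nrow(g))
  g
}

# --- ERP fixtures ------------------------------------------------------------

# Small epoch set with explicit ids; fill is a function(s, i, c, t_ms) or a
# constant.
toy_epochs <- function(ns = 2, ni = 2, nc = 2, times = seq(-200, 280, 40),
                       channels = NULL, items = NULL, fill = 0) {
  if (is.null(channels)) channels <- paste0("CH", seq_len(nc))
  if (is.null(items)) items <- paste0("b o:|", rep_len(1:2, ni), "#", seq_len(ni))
  subjects <- paste0("S", seq_len(ns))
  amp <- array(0, c(ns, ni, nc, length(times)))
  if (is.function(fill)) {
    for (s in seq_len(ns)) {
      for (i in seq_len(ni)) {
        for (cc in seq_len(nc)) {
          amp[s, i, cc, ] <- vapply(times, function(t) fill(s, i, cc, t),
            numeric(1)
          )
        }
      }
    }
  } else {
    amp[] <- fill
  }
  epoch_set(amp, times, channels, subjects, items)
}

# Nested-loop item-ERP oracle: subject-wise mean over surviving items of a
# WIF, then unweighted mean over contributing subjects.
oracle_item_erp <- function(epochs, wif, channel, time) {
  ci <- match(channel, epochs$channels)
  ti <- match(time, epochs$times)
  per_subj <- c()
  for (s in seq_along(epochs$subjects)) {
    vals <- c()
    for (i in seq_along(epochs$items)) {
      if (epochs$item_wif[[i]] != wif) next
      if (epochs$rejected[s, i]) next
      vals <- c(vals, epochs$amplitudes[s, i, ci, ti])
    }
    if (length(vals)) per_subj <- c(per_subj, mean(vals))
  }
  mean(per_subj)
}

# Qualifying-entry mask under the default constraints (noun, polysyllabic,
# has an initial-stress WIF).
constraint_ids <- function(lex) {
  !is.na(lex$wif) & lex$word_class == "NN" & lex$syllable_count >= 2L
}

# One-row parsed lexicon built from a pronunciation string.
parse_lexicon_line_fixture <- function(pron, orth = "extra", pos = "NN") {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(paste(orth, pos, "l", pron, "x", "y", sep = ";"), path)
  parse_lexicon(path)
}
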