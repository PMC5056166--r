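test_that("parse_pronunciation handles stress markers, accents and syllables", {
  p <- parse_pronunciation('f "1 I s k')
  expect_identical(p$segments, c("f", "I", "s", "k"))
  expect_identical(p$stress_index, 2L)
  expect_identical(p$accent, 1L)
  expect_identical(p$syllable_count, 1L)

  p <- parse_pronunciation('b "2 o: t $ h u: s')
  expect_identical(p$segments, c("b", "o:", "t", "h", "u:", "s"))
  expect_identical(p$stress_index, 2L)
  expect_identical(p$accent, 2L)
  expect_identical(p$syllable_count, 2L)

  p <- parse_pronunciation("k a t")
  expect_true(is.na(p$accent))
  expect_true(is.na(p$stress_index))
  expect_identical(p$syllable_count, 1L)
})

test_that("malformed pronunciations raise dedicated errors", {
  expect_error(
    parse_pronunciation('"1 s a'),
    class = "pran_malformed_pronunciation"
  )
  expect_error(
    parse_pronunciation('b "1 a t "2 u'),
    class = "pran_malformed_pronunciation"
  )
  expect_error(
    parse_pronunciation('b a "1'),
    class = "pran_malformed_pronunciation"
  )
})

test_that("parse_lexicon maps fields, skips malformed lines and reports", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    'båt;NN;båt;b "1 o: t;SIN;x',
    'fisk;NN;fisk;f "1 I s k;SIN;x',
    "short;NN", # too few fields
    'bad;NN;bad;b "1 s a;SIN;x' # marker not before a vowel
  ), path)
  expect_warning(lex <- parse_lexicon(path), "skipped 2")
  expect_equal(nrow(lex), 2L)
  expect_identical(lex$orthography, c("båt", "fisk"))
  expect_identical(lex$segments[[1]], c("b", "o:", "t"))
  expect_identical(lex$stress_index[1], 2L)
  expect_identical(lex$accent[1], 1L)
  expect_identical(lex$wif[1], "b o:|1")
  rep <- attr(lex, "parse_report")
  expect_equal(rep$n_parsed, 2L)
  expect_equal(rep$n_skipped, 2L)
  expect_equal(rep$n_short_lines, 1L)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  lex0 <- parse_lexicon(empty)
  expect_equal(nrow(lex0), 0L)
  expect_equal(attr(lex0, "parse_report")$n_parsed, 0L)
  expect_equal(attr(lex0, "parse_report")$n_skipped, 0L)

  expect_error(parse_lexicon(file.path(tempdir(), "nope.txt")), "cannot read")
})

test_that("extract_wif returns the fragment up to the stressed first vowel", {
  e <- list(segments = c("b", "o:", "t"), stress_index = 2L, accent = 1L)
  w <- extract_wif(e)
  expect_s3_class(w, "wif_key")
  expect_identical(w$segments, c("b", "o:"))
  expect_identical(w$id, "b o:|1")

  # stress on the second vowel: no WIF
  e2 <- list(segments = c("b", "a", "n", "a", "n"), stress_index = 4L,
    accent = 2L)
  expect_null(extract_wif(e2))

  # unaccented entry: no WIF
  e3 <- list(segments = c("k", "a", "t"), stress_index = NA_integer_,
    accent = NA_integer_)
  expect_null(extract_wif(e3))
})

test_that("wif_key validates its invariants and ids round-trip", {
  expect_error(wif_key(c("b", "o:"), 3), "accent")
  expect_error(wif_key(c("b", "s"), 1), "vowel")
  expect_error(wif_key(c("a", "o:"), 1), "earlier vowel")
  k <- wif_key(c("s", "t", "A:"), 2)
  parsed <- parse_wif_id(k$id)
  expect_identical(parsed$wif_segments, "s t A:")
  expect_identical(parsed$accent, 2L)
  expect_error(parse_wif_id("b o:"), "not a WIF id")
})

test_that("frequency filter keeps exactly the words at/above threshold", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    'a;NN;a;a "1 a b a;x;y', 'b;NN;b;b "1 a b a;x;y',
    'c;NN;c;k "1 a b a;x;y', 'd;NN;d;d "1 a b a;x;y'
  ), path)
  lex <- parse_lexicon(path)
  ft <- frequency_table(
    data.frame(orthography = c("a", "b", "c"), count = c(5L, 2L, 1L)),
    min_frequency = 2L
  )
  expect_identical(frequency_of(ft, c("a", "d")), c(5L, 0L)) # d unlisted -> 0
  kept <- apply_frequency_filter(lex, ft)
  expect_identical(kept$orthography, c("a", "b"))
  expect_identical(kept$frequency, c(5L, 2L))
  # threshold 0 is the identity
  all_kept <- apply_frequency_filter(lex, ft, min_frequency = 0L)
  expect_identical(all_kept$orthography, lex$orthography)
})

test_that("frequency-filter survivors match an independent scan and shrink with threshold", {
  lex <- random_lexicon(500, seed = 42)
  set.seed(43)
  counts <- data.frame(
    orthography = lex$orthography,
    count = rpois(nrow(lex), 3)
  )
  ft <- frequency_table(counts, min_frequency = 2L)
  kept <- apply_frequency_filter(lex, ft)
  brute <- lex$orthography[counts$count[match(lex$orthography,
    counts$orthography)] >= 2L]
  expect_identical(kept$orthography, brute)
  sizes <- vapply(0:5, function(thr) {
    nrow(apply_frequency_filter(lex, ft, min_frequency = thr))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0L))
  expect_equal(sizes[1], nrow(lex))
})

test_that("count_competitors enumerates a toy cohort correctly", {
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- c(
    sprintf('a1w%d;NN;l;b "1 o: t %s a;x;y', 1:3, c("k", "l", "m")),
    sprintf('a2w%d;NN;l;b "2 o: s %s a;x;y', 1:5, c("k", "l", "m", "n", "p")),
    'vb1;VB;l;b "1 o: t a;x;y', # wrong class
    'mono;NN;l;b "1 o: t;x;y', # monosyllabic
    'late;NN;l;b o: t "1 a;x;y' # non-initial stress
  )
  writeLines(lines, path)
  lex <- parse_lexicon(path)
  expect_equal(count_competitors("b o:|1", lex), 3L)
  expect_equal(count_competitors("b o:|2", lex), 5L)
  # relaxing one constraint readmits the matching excluded entry
  expect_equal(
    count_competitors("b o:|1", lex, pran_constraints(word_class = NULL)),
    4L
  )
  expect_equal(
    count_competitors("b o:|1", lex, pran_constraints(polysyllabic = FALSE)),
    4L
  )
  # empty lexicon
  empty <- lex[0, , drop = FALSE]
  expect_equal(count_competitors("b o:|1", empty), 0L)
})

test_that("counts equal a brute-force double loop on random lexicons", {
  lex <- random_lexicon(2000, seed = 7)
  wifs <- unique(lex$wif[!is.na(lex$wif)])
  set.seed(8)
  query <- sample(wifs, min(40L, length(wifs)))
  for (id in query) {
    expect_identical(
      count_competitors(id, lex),
      oracle_count(id, lex),
      info = id
    )
  }
})

test_that("adding one qualifying entry increments exactly one count", {
  lex <- random_lexicon(300, seed = 21)
  wifs <- sort(unique(lex$wif[constraint_ids(lex)]))
  target <- wifs[[1]]
  before <- vapply(wifs, count_competitors, integer(1), entries = lex)
  seg <- strsplit(sub("\\|.*$", "", target), " ")[[1]]
  acc <- sub("^.*\\|", "", target)
  pron <- paste(
    c(head(seg, -1), paste0("\"", acc), tail(seg, 1), "t", "a"),
    collapse = " "
  )
  extra <- parse_lexicon_line_fixture(pron)
  grown <- rbind(lex, extra)
  after <- vapply(wifs, count_competitors, integer(1), entries = grown)
  expect_equal(after[[target]], before[[target]] + 1L)
  expect_identical(after[names(after) != target], before[names(before) != target])
})

test_that("accent-specific counts partition the accent-blind count", {
  lex <- random_lexicon(1500, seed = 33)
  segs <- unique(sub("\\|.*$", "", lex$wif[!is.na(lex$wif)]))
  mask <- constraint_ids(lex)
  for (sg in segs[seq_len(min(20, length(segs)))]) {
    blind <- sum(sub("\\|.*$", "", lex$wif[mask]) == sg, na.rm = TRUE)
    c1 <- count_competitors(paste0(sg, "|1"), lex)
    c2 <- count_competitors(paste0(sg, "|2"), lex)
    expect_equal(c1 + c2, blind, info = sg)
  }
})

test_that("competition_table: z closed forms, degeneracy, determinism", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    sprintf('w%d;NN;l;b "1 o: k%d a;x;y', 1:10, 1:10),
    sprintf('v%d;NN;l;s "2 A: k%d a;x;y', 1:100, rep(1:10, 10))
  ), path)
  lex <- parse_lexicon(path)
  tab <- competition_table(c("b o:|1", "s A:|2"), lex)
  expect_identical(tab$count, c(10L, 100L))
  # two points: z = +-1/sqrt(2) under the sample-SD convention
  expect_equal(tab$z_log_count, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # rows sorted by WIF key
  expect_identical(tab$wif, c("b o:|1", "s A:|2"))
  # unattested WIF is an explicit error naming it
  expect_error(
    competition_table(c("b o:|1", "p u:|1"), lex),
    "p u:\\|1"
  )
  # degenerate all-equal counts: warning and zero z
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    'x1;NN;l;b "1 o: t a;x;y',
    'x2;NN;l;s "2 A: t a;x;y'
  ), path2)
  lex2 <- parse_lexicon(path2)
  expect_warning(
    tab2 <- competition_table(c("b o:|1", "s A:|2"), lex2),
    "zero variance"
  )
  expect_identical(tab2$z_log_count, c(0, 0))
})

test_that("z-scored log-competition is invariant to the log base", {
  lex <- random_lexicon(1200, seed = 9)
  wifs <- sort(unique(lex$wif[constraint_ids(lex)]))
  wifs <- wifs[seq_len(min(30, length(wifs)))]
  t_ln <- competition_table(wifs, lex, log_base = exp(1))
  t_10 <- competition_table(wifs, lex, log_base = 10)
  expect_lt(max(abs(t_ln$z_log_count - t_10$z_log_count)), 1e-12)
  expect_false(isTRUE(all.equal(t_ln$log_count, t_10$log_count)))
})

test_that("accent continuation ratio recovers enumerated and symmetric cases", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    sprintf('r1w%d;NN;l;b "1 o: k a;x;y', 1:3),
    sprintf('r2w%d;NN;l;b "2 o: k a;x;y', 1:33)
  ), path)
  lex <- parse_lexicon(path)
  expect_equal(accent_continuation_ratio(lex), 11)

  # mirror-symmetric lexicon: ratio exactly 1
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    sprintf('m1w%d;NN;l;s "1 A: k a;x;y', 1:4),
    sprintf('m2w%d;NN;l;s "2 A: k a;x;y', 1:4)
  ), path2)
  expect_equal(accent_continuation_ratio(parse_lexicon(path2)), 1)

  # accent 1 absent: undefined
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines('q1;NN;l;s "2 A: k a;x;y', path3)
  expect_error(accent_continuation_ratio(parse_lexicon(path3)), "undefined")
})

test_that("competition tables round-trip through TSV", {
  lex <- random_lexicon(800, seed = 5)
  wifs <- sort(unique(lex$wif[constraint_ids(lex)]))[1:10]
  tab <- competition_table(wifs, lex)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_competition_table(tab, path)
  back <- read_competition_table(path)
  expect_identical(back$wif, tab$wif)
  expect_identical(back$count, tab$count)
  expect_equal(back$z_log_count, tab$z_log_count, tolerance = 1e-12)
})
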