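test_that("median split halves ranked counts with deterministic tie-breaks", {
  rec <- data.frame(wif = paste0("w", 1:4, "|1"), count = c(1L, 2L, 3L, 4L))
  sp <- median_split(rec)
  expect_identical(
    sp$assignment$group[order(sp$assignment$count)],
    c("low", "low", "high", "high")
  )
  expect_equal(sp$summary$mean_count, c(1.5, 3.5))

  # boundary ties resolved by lexicographic WIF key, sizes stay 2/2
  rec2 <- data.frame(
    wif = c("d|1", "a|1", "c|1", "b|1"), count = c(5L, 5L, 5L, 9L)
  )
  sp2 <- median_split(rec2)
  expect_equal(as.vector(table(sp2$assignment$group)[c("low", "high")]),
    c(2L, 2L))
  # the two lexicographically smallest tied keys go low
  expect_setequal(
    sp2$assignment$wif[sp2$assignment$group == "low"], c("a|1", "c|1")
  )

  # every low count <= every high count (random fixture, vs sort-and-halve)
  set.seed(99)
  rec3 <- data.frame(
    wif = sprintf("w%02d|%d", 1:52, rep(1:2, 26)),
    count = rpois(52, 60)
  )
  sp3 <- median_split(rec3)
  lo <- sp3$assignment$count[sp3$assignment$group == "low"]
  hi <- sp3$assignment$count[sp3$assignment$group == "high"]
  expect_equal(length(lo), 26L)
  expect_true(max(lo) <= min(hi))
  expect_setequal(lo, sort(rec3$count)[1:26])

  expect_error(median_split(rec3[1, ]), "at least 2")
})

test_that("repeated-measures ANOVA matches the aov() oracle", {
  designs <- list(
    list(n_subj = 18, levels = c(2)),
    list(n_subj = 18, levels = c(2, 3)),
    list(n_subj = 10, levels = c(2, 3, 2)),
    list(n_subj = 6, levels = c(3, 3))
  )
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    cells <- random_cells(d$n_subj, d$levels, seed = 1000 + k)
    mine <- rm_anova(cells,
      dv = "mean_amplitude", factors = paste0("f", seq_along(d$levels))
    )
    orc <- aov_oracle(cells, "mean_amplitude", "subject",
      paste0("f", seq_along(d$levels))
    )
    m <- merge(mine, orc, by = "effect", suffixes = c("", ".orc"))
    expect_equal(nrow(m), nrow(mine))
    expect_equal(m$F, m$F.orc, tolerance = 1e-8)
    expect_equal(m$p, m$p.orc, tolerance = 1e-8)
    expect_identical(m$df_num, m$df_num.orc)
    expect_identical(m$df_den, m$df_den.orc)
    # partial eta^2 identity from (F, dfs)
    expect_equal(
      m$partial_eta_sq,
      (m$df_num * m$F) / (m$df_num * m$F + m$df_den),
      tolerance = 1e-10
    )
  }
})

test_that("ANOVA df bookkeeping reproduces the published design shapes", {
  # 18 subjects, 2 x 3 x 2 design: (1,17) and (2,34) patterns
  cells <- random_cells(18, c(2, 3, 2), seed = 4)
  a <- rm_anova(cells, factors = c("f1", "f2", "f3"))
  expect_equal(a$df_den[a$effect == "f1"], 17L)
  expect_equal(a$df_num[a$effect == "f2"], 2L)
  expect_equal(a$df_den[a$effect == "f2"], 34L)
  expect_equal(a$df_den[a$effect == "f2 x f3"], 34L)
  # 20 subjects: (1,19), (2,38)
  cells2 <- random_cells(20, c(2, 3), seed = 5)
  a2 <- rm_anova(cells2, factors = c("f1", "f2"))
  expect_equal(a2$df_den[a2$effect == "f1"], 19L)
  expect_equal(a2$df_den[a2$effect == "f2"], 38L)
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  cells <- random_cells(8, c(2, 2), seed = 6)
  cells$mean_amplitude <- 3.14 # identical everywhere
  a <- rm_anova(cells, factors = c("f1", "f2"))
  expect_true(all(a$F == 0))
  expect_true(all(a$partial_eta_sq == 0))

  cells2 <- random_cells(8, c(2, 2), seed = 7)
  expect_error(
    rm_anova(cells2[-1, ], factors = c("f1", "f2")),
    "one observation per subject"
  )
  one <- random_cells(1, c(2, 2), seed = 8)
  expect_error(rm_anova(one, factors = c("f1", "f2")), "2 subjects")
})

test_that("Greenhouse-Geisser epsilon is logged, bounded, not applied", {
  cells <- random_cells(12, c(3, 2), seed = 9)
  a <- rm_anova(cells, factors = c("f1", "f2"))
  eps <- a$gg_epsilon[a$effect == "f1"]
  expect_true(eps >= 1 / 2 - 1e-12 && eps <= 1 + 1e-12) # bounds for k = 3
  expect_true(is.na(a$gg_epsilon[a$effect == "f2"])) # 1-df effect
  # uncorrected dfs are reported regardless of epsilon
  expect_equal(a$df_den[a$effect == "f1"], 22L)
})

test_that("ROI-subset follow-ups collapse factors correctly", {
  set.seed(12)
  lay <- montage("exp1_3")
  rois <- unique(lay[, c("roi", "antpost", "laterality")])
  g <- expand.grid(
    subject = paste0("s", 1:10), group = c("low", "high"),
    roi = rois$roi, stringsAsFactors = FALSE
  )
  g <- merge(g, rois, by = "roi")
  g$mean_amplitude <- rnorm(nrow(g))

  # subset = all ROIs reproduces the omnibus ANOVA
  full <- subset_anova(g, unique(g$roi),
    factors = c("group", "antpost", "laterality")
  )
  cells <- aggregate(
    mean_amplitude ~ subject + group + antpost + laterality, g, mean
  )
  omni <- rm_anova(cells, factors = c("group", "antpost", "laterality"))
  m <- merge(full, omni, by = "effect", suffixes = c("", ".omni"))
  expect_equal(m$F, m$F.omni, tolerance = 1e-10)

  # collapsing to one laterality x one antpost leaves only the group factor
  lc <- subset_anova(g, "left central",
    factors = c("group", "antpost", "laterality")
  )
  expect_identical(attr(lc, "factors"), "group")
  expect_equal(lc$df_num, 1L)
  expect_equal(lc$df_den, 9L)

  # two left ROIs: group x antpost survives, laterality collapses
  l2 <- subset_anova(g, c("left central", "left posterior"),
    factors = c("group", "antpost", "laterality")
  )
  expect_setequal(attr(l2, "factors"), c("group", "antpost"))

  expect_error(subset_anova(g, character(0), factors = "group"), "empty")
  expect_error(subset_anova(g, "nope", factors = "group"), "absent")
})

test_that("amplitude standardization uses study constants or self-scaling", {
  # study constants: the study-mean amplitude maps to z = 0, and an
  # amplitude one SD above (-1.53 with mean -2.44, SD 0.91) maps to z = +1
  expect_equal(
    standardize_amplitudes(-2.44, study_mean = -2.44, study_sd = 0.91)[1], 0
  )
  expect_equal(
    standardize_amplitudes(-1.53, study_mean = -2.44, study_sd = 0.91)[1], 1
  )
  # self-standardized records have mean 0, sample SD 1
  set.seed(13)
  rec <- data.frame(mean_amplitude = rnorm(40, -2, 1.5))
  z <- standardize_amplitudes(rec)
  expect_equal(mean(z$z_amplitude), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_amplitude), 1, tolerance = 1e-12)
  expect_error(standardize_amplitudes(rep(1, 5)), "SD must be positive")
})

test_that("standardized regression identities hold", {
  set.seed(14)
  x <- rnorm(52)
  y <- 0.4 * x + rnorm(52)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  fit <- pran_regression(zy, zx)
  # single-predictor standardized slope = Pearson r; R^2 = r^2
  r <- cor(x, y)
  est <- fit$coefficients$estimate[fit$coefficients$term == "z_competition"]
  expect_equal(est, r, tolerance = 1e-12)
  expect_equal(fit$r_squared, r^2, tolerance = 1e-12)
  expect_equal(fit$df_model, 1L)
  expect_equal(fit$df_residual, 50L)

  # affine rescaling of the raw variables leaves the slope unchanged
  x2 <- 7 - 3 * x
  zx2 <- (x2 - mean(x2)) / sd(x2)
  fit2 <- pran_regression(zy, zx2)
  est2 <- fit2$coefficients$estimate[fit2$coefficients$term == "z_competition"]
  expect_equal(abs(est2), abs(r), tolerance = 1e-12)

  # exact linear data recover the generating slope with R^2 = 1
  y0 <- 0.387 * zx
  fit0 <- suppressWarnings(pran_regression(y0, zx)) # lm warns on exact fit
  expect_equal(
    fit0$coefficients$estimate[fit0$coefficients$term == "z_competition"],
    0.387,
    tolerance = 1e-12
  )
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)
})

test_that("one-tailed competition test and two-tailed covariate test", {
  set.seed(15)
  n <- 60
  zc <- rnorm(n)
  zf <- rnorm(n)
  zy <- 0.3 * zc + rnorm(n)
  fit <- pran_regression(zy, zc, zf)
  co <- fit$coefficients
  tc <- co$t[co$term == "z_competition"]
  expect_equal(
    co$p[co$term == "z_competition"],
    pt(tc, fit$df_residual, lower.tail = FALSE),
    tolerance = 1e-12
  )
  tf <- co$t[co$term == "z_frequency"]
  expect_equal(
    co$p[co$term == "z_frequency"],
    2 * pt(-abs(tf), fit$df_residual),
    tolerance = 1e-12
  )
  # a strong negative slope must NOT look significant one-tailed positive
  zy_neg <- -0.8 * zc + 0.2 * rnorm(n)
  fit_neg <- pran_regression(zy_neg, zc)
  expect_gt(
    fit_neg$coefficients$p[fit_neg$coefficients$term == "z_competition"],
    0.99
  )

  expect_error(pran_regression(zy[1:3], zc[1:3], zf[1:3]), "too few")
  expect_error(pran_regression(zy, rep(1, n)), "constant predictor")
})
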