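#' Median split of WIFs into low/high competition groups
#'
#' WIFs are ranked by raw competitor count; the lower half is assigned to the
#' low-competition group and the upper half to the high group (with odd n the
#' high group receives the extra record). Ties at the boundary are broken
#' deterministically by lexicographic WIF key. Group summaries report means
#' and SDs of the raw counts.
#'
#' @param records Data frame with columns `wif` and `count` (e.g. a
#'   [competition_table()]).
#' @return Object of class `median_split`: list with `assignment` (columns
#'   `wif`, `count`, `group`) and `summary` (per-group n, mean, SD of raw
#'   counts).
#' @export
median_split <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) {
    stop("median split needs at least 2 records", call. = FALSE)
  }
  ord <- order(records$count, records$wif)
  n_low <- n %/% 2L
  group <- rep("high", n)
  group[ord[seq_len(n_low)]] <- "low"
  assignment <- data.frame(
    wif = records$wif,
    count = records$count,
    group = group,
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(c("low", "high"), function(g) {
    x <- assignment$count[assignment$group == g]
    data.frame(
      group = g, n = length(x),
      mean_count = mean(x), sd_count = stats::sd(x),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(assignment = assignment, summary = summ),
    class = "median_split"
  )
}

#' @export
print.median_split <- function(x, ...) {
  cat("<median_split>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fully-crossed within-subjects (repeated-measures) ANOVA
#'
#' Balanced univariate repeated-measures ANOVA on cell means: one observation
#' per subject per factor cell. Every effect is tested against its own
#' effect-by-subject interaction. Degrees of freedom are reported uncorrected
#' (integer); the Greenhouse-Geisser epsilon of each multi-df effect is
#' computed and included for inspection but not applied. Partial eta squared
#' is `SS_effect / (SS_effect + SS_error)`, identical to
#' `df_num * F / (df_num * F + df_den)`.
#'
#' Sums of squares use the closed-form balanced-design decomposition
#' (inclusion-exclusion over marginal-total squares), so the decomposition is
#' exact and independent of model-fitting code.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column (mean amplitude).
#' @param subject Name of the subject-id column.
#' @param factors Character vector of within-subject factor column names.
#' @return Object of class `pran_anova`: data frame with columns `effect`,
#'   `df_num`, `df_den`, `F`, `p`, `partial_eta_sq`, `gg_epsilon`.
#' @export
rm_anova <- function(data, dv = "mean_amplitude", subject = "subject",
                     factors) {
  stopifnot(all(c(dv, subject, factors) %in% names(data)))
  if (!length(factors)) stop("no factors supplied", call. = FALSE)
  y <- as.numeric(data[[dv]])
  if (anyNA(y)) stop("missing cell means (no imputation)", call. = FALSE)
  subj <- factor(data[[subject]])
  if (nlevels(subj) < 2L) stop("need at least 2 subjects", call. = FALSE)
  fs <- lapply(data[factors], factor)
  names(fs) <- factors
  for (f in factors) {
    if (nlevels(fs[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  cell <- interaction(c(list(subj), fs), drop = FALSE)
  tab <- table(cell)
  if (any(tab != 1L)) {
    stop(
      "design must have exactly one observation per subject per cell (",
      sum(tab == 0L), " missing, ", sum(tab > 1L), " replicated)",
      call. = FALSE
    )
  }
  N <- length(y)
  all_f <- c(fs, list(.subject = subj))

  # U(S) = sum over margin cells of (cell total)^2 / (obs per cell)
  u_of <- function(which_names) {
    if (!length(which_names)) {
      return(sum(y)^2 / N)
    }
    g <- interaction(all_f[which_names], drop = FALSE)
    s <- tapply(y, g, sum)
    s[is.na(s)] <- 0
    sum(s^2) / (N / nlevels(g))
  }
  ss_of <- function(term_names) {
    k <- length(term_names)
    ss <- 0
    for (m in 0:k) {
      subs <- if (m == 0L) list(character(0)) else
        utils::combn(term_names, m, simplify = FALSE)
      for (s in subs) ss <- ss + (-1)^(k - m) * u_of(s)
    }
    ss
  }

  effects <- unlist(
    lapply(seq_along(factors), function(m) {
      utils::combn(factors, m, simplify = FALSE)
    }),
    recursive = FALSE
  )
  n_subj <- nlevels(subj)
  rows <- lapply(effects, function(term) {
    ss_eff <- ss_of(term)
    ss_err <- ss_of(c(term, ".subject"))
    df_num <- prod(vapply(fs[term], nlevels, integer(1)) - 1L)
    df_den <- df_num * (n_subj - 1L)
    ss_eff <- max(ss_eff, 0) # guard tiny negative rounding residue
    ss_err <- max(ss_err, 0)
    f_val <- if (ss_eff == 0) 0 else (ss_eff / df_num) / (ss_err / df_den)
    if (!is.finite(f_val)) f_val <- 0
    p <- stats::pf(f_val, df_num, df_den, lower.tail = FALSE)
    peta <- if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
    data.frame(
      effect = paste(term, collapse = " x "),
      df_num = df_num, df_den = df_den,
      F = f_val, p = p,
      partial_eta_sq = peta,
      gg_epsilon = gg_epsilon(y, subj, fs[term]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_subjects") <- n_subj
  class(out) <- c("pran_anova", "data.frame")
  out
}

# Greenhouse-Geisser (Box) epsilon for an effect, computed from the
# double-centered covariance of the per-subject cell means; NA for 1-df
# effects, where sphericity is not at issue.
gg_epsilon <- function(y, subj, term_factors) {
  k <- prod(vapply(term_factors, nlevels, integer(1)))
  if (k <= 2L) return(NA_real_)
  g <- interaction(term_factors, drop = FALSE)
  m <- tapply(y, list(subj, g), mean)
  v <- stats::cov(m)
  vc <- sweep(v, 1L, rowMeans(v))
  vc <- sweep(vc, 2L, colMeans(vc))
  tr <- sum(diag(vc))
  denom <- (k - 1) * sum(vc^2)
  if (denom <= 0) return(NA_real_)
  unname(tr^2 / denom)
}

#' @export
print.pran_anova <- function(x, digits = 4, ...) {
  cat("<repeated-measures ANOVA> n_subjects =", attr(x, "n_subjects"), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Follow-up ANOVA on a subset of ROIs
#'
#' Restricts subject-resolved windowed amplitude records to a subset of ROIs,
#' averages into subject x cell means over the factors that still vary (a
#' factor reduced to one level is dropped), and applies [rm_anova()]. Used
#' for simple-effects follow-ups such as "Competitors at left-central
#' channels".
#'
#' @param records Subject-resolved amplitude records with columns `subject`,
#'   `roi` and the candidate factor columns.
#' @param rois Character vector of ROI names to keep (non-empty).
#' @param dv Dependent-variable column name.
#' @param factors Candidate factor columns, in design order (e.g.
#'   `c("group", "antpost", "laterality")`).
#' @param subject Subject column name.
#' @return A [rm_anova()] table; attribute `"factors"` lists the factors
#'   retained after subsetting.
#' @export
subset_anova <- function(records, rois, dv = "mean_amplitude",
                         factors, subject = "subject") {
  if (!length(rois)) stop("empty ROI subset", call. = FALSE)
  bad <- setdiff(rois, unique(records$roi))
  if (length(bad)) {
    stop("ROI(s) absent from records: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  d <- records[records$roi %in% rois, , drop = FALSE]
  keep <- factors[vapply(
    factors,
    function(f) length(unique(d[[f]])) > 1L, logical(1)
  )]
  if (!length(keep)) {
    stop("no factor varies within the ROI subset", call. = FALSE)
  }
  agg <- stats::aggregate(
    d[[dv]],
    by = c(
      list(subject = d[[subject]]),
      lapply(keep, function(f) d[[f]])
    ),
    FUN = mean, na.rm = TRUE # subjects may have lost all epochs of a WIF
  )
  names(agg) <- c(subject, keep, dv)
  out <- rm_anova(agg, dv = dv, subject = subject, factors = keep)
  attr(out, "factors") <- keep
  out
}

#' Standardize amplitudes to z-scores
#'
#' Converts windowed mean amplitudes to z-scores using the study-wide mean
#' and SD. When `study_mean` / `study_sd` are not supplied they are computed
#' from the records themselves (sample SD).
#'
#' @param records Data frame with a `mean_amplitude` column, or a numeric
#'   vector.
#' @param study_mean,study_sd Optional standardization constants in
#'   microvolts (`study_sd` must be positive).
#' @return The records with a `z_amplitude` column added (or, for vector
#'   input, the z-scored vector). The constants used are attached as
#'   attribute `"standardization"`.
#' @export
standardize_amplitudes <- function(records, study_mean = NULL,
                                   study_sd = NULL) {
  x <- if (is.data.frame(records)) records$mean_amplitude else
    as.numeric(records)
  if (is.null(study_mean)) study_mean <- mean(x)
  if (is.null(study_sd)) study_sd <- stats::sd(x)
  if (is.na(study_sd) || study_sd <= 0) {
    stop("study SD must be positive", call. = FALSE)
  }
  z <- (x - study_mean) / study_sd
  std <- c(mean = study_mean, sd = study_sd)
  if (is.data.frame(records)) {
    records$z_amplitude <- z
    attr(records, "standardization") <- std
    records
  } else {
    attr(z, "standardization") <- std
    z
  }
}

#' Standardized regression of PrAN amplitude on lexical competition
#'
#' Ordinary least squares with intercept on z-scored variables. The
#' directional hypothesis is fixed a priori: windowed amplitude becomes less
#' negative as competition rises, i.e. the slope of z-amplitude on
#' z-log-competition is positive, so the competition coefficient is tested
#' one-tailed in the positive direction. The optional lexical-frequency
#' covariate is tested two-tailed. With a single predictor the standardized
#' slope equals the Pearson correlation and R-squared equals its square.
#'
#' @param z_amplitude Numeric vector of z-scored windowed amplitudes.
#' @param z_competition Numeric vector of z-scored log competitor counts.
#' @param z_frequency Optional numeric vector of z-scored log corpus
#'   frequencies.
#' @return Object of class `pran_regression`: list with `coefficients`
#'   (term, estimate, std_error, t, p, tail), `f_statistic`, `df_model`,
#'   `df_residual`, `p_model`, `r_squared`, `n`.
#' @export
pran_regression <- function(z_amplitude, z_competition, z_frequency = NULL) {
  d <- data.frame(z_amplitude = z_amplitude, z_competition = z_competition)
  if (!is.null(z_frequency)) d$z_frequency <- z_frequency
  if (anyNA(d)) stop("missing values in regression inputs", call. = FALSE)
  p <- ncol(d) - 1L
  n <- nrow(d)
  if (n <= p + 1L) {
    stop("too few observations (n = ", n, ") for ", p, " predictor(s)",
      call. = FALSE
    )
  }
  for (v in names(d)[-1L]) {
    if (stats::sd(d[[v]]) == 0) {
      stop("constant predictor: ", v, call. = FALSE)
    }
  }
  fml <- if (is.null(z_frequency)) {
    z_amplitude ~ z_competition
  } else {
    z_amplitude ~ z_competition + z_frequency
  }
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- rownames(ct)
  df_res <- fit$df.residual
  tail <- ifelse(terms == "z_competition", "one-sided (positive)",
    "two-sided"
  )
  pvals <- ifelse(
    terms == "z_competition",
    stats::pt(ct[, "t value"], df_res, lower.tail = FALSE),
    ct[, "Pr(>|t|)"]
  )
  coefs <- data.frame(
    term = terms,
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    t = unname(ct[, "t value"]),
    p = unname(pvals),
    tail = tail,
    stringsAsFactors = FALSE
  )
  fstat <- unname(sm$fstatistic)
  structure(
    list(
      coefficients = coefs,
      f_statistic = fstat[1L],
      df_model = as.integer(fstat[2L]),
      df_residual = as.integer(fstat[3L]),
      p_model = stats::pf(fstat[1L], fstat[2L], fstat[3L],
        lower.tail = FALSE
      ),
      r_squared = sm$r.squared,
      n = n
    ),
    class = "pran_regression"
  )
}

#' @export
print.pran_regression <- function(x, digits = 4, ...) {
  b <- x$coefficients
  slope <- b$estimate[b$term == "z_competition"]
  cat(
    "<standardized regression> PrAN = ",
    formatC(slope, digits = 3, format = "f"),
    " (lexical competition)\n",
    "F(", x$df_model, ",", x$df_residual, ") = ",
    formatC(x$f_statistic, digits = digits, format = "g"),
    ", p = ", formatC(x$p_model, digits = 3, format = "g"),
    ", R^2 = ", formatC(x$r_squared, digits = 3, format = "f"),
    ", n = ", x$n, "\n",
    sep = ""
  )
  print.data.frame(b, digits = digits, row.names = FALSE)
  invisible(x)
}
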