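#' Experiment analysis configuration
#'
#' Three shipped presets encode the montages, analysis windows and ROI
#' subsets of the three PrAN datasets:
#' \describe{
#'   \item{`exp1`}{12-channel montage (`exp1_3`), window 136-280 ms;
#'     follow-up ANOVAs at left channels, left central and left posterior;
#'     regression over left central + left posterior ROIs.}
#'   \item{`exp2`}{54-channel montage (`exp2`), window 136-280 ms; follow-up
#'     at left-lateralized sites; regression over the three left ROIs.}
#'   \item{`exp3`}{12-channel montage, later window 220-280 ms; follow-up and
#'     regression over left anterior + left central.}
#' }
#' All analysis choices are data, not code: any field can be overridden via
#' `...`.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param ... Named overrides of any config field.
#' @return List of class `experiment_config` with fields `experiment`,
#'   `montage_id`, `analysis_window`, `baseline_window` (default
#'   `c(-200, 0)`), `rejection_threshold` (100 microvolts), `min_frequency`
#'   (2), `anova_factors`, `followup_subsets` (named list of ROI-name
#'   vectors), `regression_rois`, `standardize_mean` / `standardize_sd`
#'   (`NULL` = compute from the data), `column_map`, `delimiter`.
#' @export
experiment_config <- function(experiment = c("exp1", "exp2", "exp3"), ...) {
  experiment <- match.arg(experiment)
  base <- list(
    experiment = experiment,
    baseline_window = c(-200, 0),
    rejection_threshold = 100,
    min_frequency = 2L,
    anova_factors = c("group", "antpost", "laterality"),
    standardize_mean = NULL,
    standardize_sd = NULL,
    column_map = list(
      orthography = 1L, word_class = 2L, pronunciation = 4L
    ),
    delimiter = ";"
  )
  preset <- switch(experiment,
    exp1 = list(
      montage_id = "exp1_3",
      analysis_window = c(136, 280),
      followup_subsets = list(
        "left channels" = c(
          "left anterior", "left central", "left posterior"
        ),
        "left central" = "left central",
        "left posterior" = "left posterior"
      ),
      regression_rois = c("left central", "left posterior")
    ),
    exp2 = list(
      montage_id = "exp2",
      analysis_window = c(136, 280),
      followup_subsets = list(
        "left channels" = c(
          "left anterior", "left central", "left posterior"
        )
      ),
      regression_rois = c(
        "left anterior", "left central", "left posterior"
      )
    ),
    exp3 = list(
      montage_id = "exp1_3",
      analysis_window = c(220, 280),
      followup_subsets = list(
        "left anterior + central" = c("left anterior", "left central")
      ),
      regression_rois = c("left anterior", "left central")
    )
  )
  cfg <- utils::modifyList(c(base, preset), list(...))
  stopifnot(
    cfg$analysis_window[1] < cfg$analysis_window[2],
    cfg$baseline_window[1] < cfg$baseline_window[2],
    cfg$rejection_threshold > 0
  )
  layout <- montage(cfg$montage_id)
  named <- unique(c(unlist(cfg$followup_subsets), cfg$regression_rois))
  bad <- setdiff(named, unique(layout$roi))
  if (length(bad)) {
    stop("config names ROI(s) absent from montage: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(cfg, class = "experiment_config")
}

# Stable hash of a config (or any R object) for run manifests.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Compute a competition table from lexicon and frequency files
#'
#' Orchestrates the lexicon stage: parse the pronunciation lexicon, attach
#' corpus frequencies and apply the inclusion threshold, then score the
#' queried WIFs (or, by default, every WIF attested under the constraints).
#' Optionally attaches a per-WIF `log_frequency` covariate: the log corpus
#' frequency of the supplied stimulus word, or — when no stimuli are given —
#' the log mean corpus frequency of the WIF's competitor cohort.
#'
#' @param lexicon_path Path to the lexicon file.
#' @param frequency_path Path to the word-frequency file.
#' @param config An [experiment_config()].
#' @param wifs Optional WIF query set (ids, [wif_key()]s or data frame);
#'   default all attested WIFs.
#' @param stimuli Optional data frame with columns `wif` and `orthography`
#'   naming the stimulus word carrying each WIF.
#' @param out Optional path: write the competition table as TSV.
#' @return List with `table` (the [competition_table()] plus `log_frequency`)
#'   and `log` (parse/filter counts and the config hash).
#' @export
run_competition <- function(lexicon_path, frequency_path,
                            config = experiment_config("exp1"),
                            wifs = NULL, stimuli = NULL, out = NULL) {
  entries <- parse_lexicon(lexicon_path,
    column_map = config$column_map, delimiter = config$delimiter
  )
  report <- attr(entries, "parse_report")
  freq <- read_frequency_table(frequency_path,
    min_frequency = config$min_frequency
  )
  kept <- apply_frequency_filter(entries, freq)
  constraints <- pran_constraints()
  if (is.null(wifs)) {
    wifs <- sort(unique(kept$wif[constraint_mask(kept, constraints) &
      !is.na(kept$wif)]))
  }
  tab <- competition_table(wifs, kept, constraints = constraints)

  if (!is.null(stimuli)) {
    stopifnot(all(c("wif", "orthography") %in% names(stimuli)))
    idx <- match(tab$wif, stimuli$wif)
    if (anyNA(idx)) {
      stop("stimuli missing for WIF(s): ",
        paste(tab$wif[is.na(idx)], collapse = ", "),
        call. = FALSE
      )
    }
    f <- frequency_of(freq, stimuli$orthography[idx])
    tab$log_frequency <- log(pmax(f, 1L))
  } else {
    mask <- constraint_mask(kept, pran_constraints())
    cohort <- tapply(kept$frequency[mask], kept$wif[mask], mean)
    tab$log_frequency <- log(pmax(unname(cohort[tab$wif]), 1))
  }

  if (!is.null(out)) write_competition_table(tab, out)
  list(
    table = tab,
    log = list(
      n_lines = report$n_lines,
      n_parsed = report$n_parsed,
      n_skipped = report$n_skipped,
      n_after_frequency_filter = nrow(kept),
      n_wifs = nrow(tab),
      config_hash = config_hash(unclass(config))
    )
  )
}

#' Run the windowed-amplitude statistics on epochs + competition table
#'
#' The full inferential recipe: baseline correction, artifact rejection,
#' item averaging, windowed ROI reduction; then (in order) the median-split
#' group summary, the omnibus repeated-measures ANOVA
#' (Competitors x Antpost x Laterality), the configured ROI-subset follow-up
#' ANOVAs, the two-predictor standardized regression (competition +
#' frequency, long format over WIF x regression-ROI observations, competition
#' tested one-tailed) and the single-predictor regression on ROI-averaged
#' per-WIF amplitudes.
#'
#' @param epochs An [epoch_set()] or a path to a long-format epoch file.
#' @param competition A [competition_table()] (with optional `log_frequency`
#'   column) or a path to one written by [write_competition_table()].
#' @param config An [experiment_config()].
#' @return Object of class `pran_report`: list with `split`, `anova_omnibus`,
#'   `anova_followups`, `regression_full`, `regression_simple`,
#'   `amplitudes` (per-WIF ROI-averaged records) and `manifest`.
#' @export
run_analysis <- function(epochs, competition,
                         config = experiment_config("exp1")) {
  layout <- montage(config$montage_id)
  if (is.character(epochs)) epochs <- load_epochs(epochs, layout = layout)
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(competition)) {
    competition <- read_competition_table(competition)
  }

  wif_epochs <- sort(unique(unname(epochs$item_wif)))
  wif_comp <- sort(unique(competition$wif))
  if (!setequal(wif_epochs, wif_comp)) {
    stop(
      "WIF sets differ between epochs and competition table; ",
      "only in epochs: {",
      paste(setdiff(wif_epochs, wif_comp), collapse = ", "),
      "}; only in competition table: {",
      paste(setdiff(wif_comp, wif_epochs), collapse = ", "), "}",
      call. = FALSE
    )
  }

  epochs <- baseline_correct(epochs, config$baseline_window)
  epochs <- reject_artifacts(epochs, config$rejection_threshold)
  erps <- item_erps(epochs)

  subj_rec <- window_roi_amplitudes(erps, layout, config$analysis_window,
    per_subject = TRUE
  )
  grand_rec <- window_roi_amplitudes(erps, layout, config$analysis_window)

  split <- median_split(competition)
  grp <- stats::setNames(split$assignment$group, split$assignment$wif)
  subj_rec$group <- factor(unname(grp[subj_rec$wif]),
    levels = c("low", "high")
  )
  grand_rec$group <- factor(unname(grp[grand_rec$wif]),
    levels = c("low", "high")
  )

  cells <- stats::aggregate(
    mean_amplitude ~ subject + group + antpost + laterality,
    data = subj_rec, FUN = mean
  )
  omnibus <- rm_anova(cells,
    dv = "mean_amplitude", subject = "subject",
    factors = intersect(config$anova_factors, names(cells))
  )
  followups <- lapply(config$followup_subsets, function(rois) {
    subset_anova(subj_rec, rois,
      dv = "mean_amplitude",
      factors = config$anova_factors
    )
  })

  z_comp <- stats::setNames(competition$z_log_count, competition$wif)
  reg_rec <- grand_rec[grand_rec$roi %in% config$regression_rois, ,
    drop = FALSE
  ]
  reg_rec <- standardize_amplitudes(reg_rec,
    study_mean = config$standardize_mean,
    study_sd = config$standardize_sd
  )
  reg_full <- NULL
  if ("log_frequency" %in% names(competition)) {
    lf <- stats::setNames(competition$log_frequency, competition$wif)
    zf <- zscore_or_zero(unname(lf[reg_rec$wif]))
    reg_full <- pran_regression(
      reg_rec$z_amplitude,
      unname(z_comp[reg_rec$wif]),
      z_frequency = zf
    )
  }

  by_wif <- stats::aggregate(
    mean_amplitude ~ wif, data = reg_rec, FUN = mean
  )
  by_wif <- standardize_amplitudes(by_wif,
    study_mean = config$standardize_mean,
    study_sd = config$standardize_sd
  )
  reg_simple <- pran_regression(
    by_wif$z_amplitude, unname(z_comp[by_wif$wif])
  )

  manifest <- list(
    experiment = config$experiment,
    config_hash = config_hash(unclass(config)),
    package_version = as.character(utils::packageVersion("pranr")),
    n_subjects = length(epochs$subjects),
    n_wifs = length(wif_comp),
    n_rejected_epochs = sum(epochs$rejected),
    n_obs_regression_full = if (is.null(reg_full)) NA_integer_ else
      reg_full$n,
    n_obs_regression_simple = reg_simple$n
  )
  structure(
    list(
      split = split,
      anova_omnibus = omnibus,
      anova_followups = followups,
      regression_full = reg_full,
      regression_simple = reg_simple,
      amplitudes = by_wif,
      manifest = manifest
    ),
    class = "pran_report"
  )
}

#' @export
print.pran_report <- function(x, ...) {
  m <- x$manifest
  cat(
    "== PrAN analysis report (", m$experiment, ") ==\n",
    m$n_subjects, " subjects, ", m$n_wifs, " WIFs, ",
    m$n_rejected_epochs, " epoch(s) rejected\n\n",
    sep = ""
  )
  cat("-- Median split (raw competitor counts) --\n")
  print(x$split$summary, row.names = FALSE)
  cat("\n-- Omnibus ANOVA --\n")
  print(x$anova_omnibus)
  for (nm in names(x$anova_followups)) {
    cat("\n-- Follow-up:", nm, "--\n")
    print(x$anova_followups[[nm]])
  }
  if (!is.null(x$regression_full)) {
    cat("\n-- Regression: competition + frequency (WIF x ROI) --\n")
    print(x$regression_full)
  }
  cat("\n-- Regression: competition only (ROI-averaged) --\n")
  print(x$regression_simple)
  cat("\nconfig hash:", m$config_hash, "\n")
  invisible(x)
}
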