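#' Configuration for the synthetic ERP epoch generator
#'
#' Defaults state the measurement world of the windowed-amplitude analysis:
#' 18 subjects on the 12-channel two-electrode-per-ROI montage, epochs
#' spanning -200..280 ms around F0 onset at 250 Hz, and a windowed effect in
#' 136-280 ms whose standardized slope on z-scored log competition is the
#' `beta` of the generating model. The effect is injected as a boxcar inside
#' the analysis window only (the statistics read nothing but windowed means),
#' with a left-lateralized topography.
#'
#' Noise layers: per-trace baseline drift (removed by baseline correction),
#' per-sample noise, a per-subject offset (absorbed by the regression
#' intercept), and a per-item offset — the item offset is the noise that
#' survives averaging, so by default `item_sd` is tuned to
#' `study_sd * sqrt(1 - beta^2)`, which makes the population standardized
#' slope equal `beta` and the single-predictor R-squared equal `beta^2`
#' (about 0.09-0.16 for the slopes of interest).
#'
#' @param seed RNG seed.
#' @param n_subjects Number of subjects, default 18.
#' @param montage_id `"exp1_3"` or `"exp2"`.
#' @param sampling_rate Hz, default 250 (4 ms steps).
#' @param epoch_span `(start_ms, end_ms)` of each epoch, default
#'   `c(-200, 280)`.
#' @param beta Generating standardized slope of z-amplitude on
#'   z-log-competition, default 0.387.
#' @param study_mean,study_sd Mean and SD (microvolts) of the windowed
#'   amplitude the generator targets, defaults -2.44 and 0.91.
#' @param roi_gain Optional named numeric of per-ROI gains on the competition
#'   effect; default 1 on left ROIs, 0.25 on mid, 0 on right.
#' @param subject_sd,item_sd,sample_sd,drift_sd Noise SDs in microvolts;
#'   `item_sd = NULL` applies the tuning above.
#' @param artifact_rate Proportion of epochs receiving an injected
#'   above-threshold spike, default 0.02.
#' @param artifact_amplitude Spike magnitude in microvolts, default 150.
#' @param window Analysis window `(start_ms, end_ms)` gating the injected
#'   effect, default `c(136, 280)`.
#' @return List of class `erp_sim_config`.
#' @export
erp_sim_config <- function(seed = 1L, n_subjects = 18L,
                           montage_id = c("exp1_3", "exp2"),
                           sampling_rate = 250,
                           epoch_span = c(-200, 280),
                           beta = 0.387,
                           study_mean = -2.44, study_sd = 0.91,
                           roi_gain = NULL,
                           subject_sd = 1.5, item_sd = NULL,
                           sample_sd = 5, drift_sd = 2,
                           artifact_rate = 0.02,
                           artifact_amplitude = 150,
                           window = c(136, 280)) {
  montage_id <- match.arg(montage_id)
  stopifnot(
    n_subjects >= 2L, sampling_rate > 0,
    length(epoch_span) == 2L, epoch_span[1] < epoch_span[2],
    study_sd > 0, subject_sd >= 0, sample_sd >= 0, drift_sd >= 0,
    artifact_rate >= 0, artifact_rate <= 1, artifact_amplitude > 0,
    length(window) == 2L, window[1] < window[2]
  )
  if (is.null(item_sd)) {
    item_sd <- study_sd * sqrt(max(0, 1 - beta^2))
  }
  stopifnot(item_sd >= 0)
  structure(
    list(
      seed = as.integer(seed), n_subjects = as.integer(n_subjects),
      montage_id = montage_id, sampling_rate = sampling_rate,
      epoch_span = epoch_span, beta = beta,
      study_mean = study_mean, study_sd = study_sd,
      roi_gain = roi_gain, subject_sd = subject_sd, item_sd = item_sd,
      sample_sd = sample_sd, drift_sd = drift_sd,
      artifact_rate = artifact_rate,
      artifact_amplitude = artifact_amplitude,
      window = window
    ),
    class = "erp_sim_config"
  )
}

#' Default effect topography for a montage
#'
#' @param layout A [montage()] data frame.
#' @return Named numeric gain per ROI: 1 for left ROIs, 0.25 for mid,
#'   0 for right.
#' @export
default_roi_gain <- function(layout) {
  rois <- unique(layout[, c("roi", "laterality")])
  gain <- ifelse(rois$laterality == "left", 1,
    ifelse(rois$laterality == "mid", 0.25, 0)
  )
  stats::setNames(gain, rois$roi)
}

#' Simulate ERP epochs carrying a lexical-competition effect
#'
#' Generates a dense [epoch_set()] with one item per competition record
#' (item label = WIF id). Amplitude of sample t in epoch (subject s, item i,
#' channel c):
#' baseline drift(s,i,c) + sample noise, plus — for t inside the analysis
#' window only — `study_mean + study_sd * beta * z_i * gain(c) +
#' subject_offset(s) + item_offset(i)`, where `z_i` is the record's
#' z-scored log competitor count. Artifacts are injected as single
#' above-threshold spikes into a recorded set of epochs.
#'
#' @param config An [erp_sim_config()].
#' @param competition Data frame with columns `wif` and `z_log_count`
#'   (e.g. a [competition_table()]).
#' @param file Optional path; if given the epochs are also written with
#'   [write_epochs()].
#' @return List with `epochs` (an `epoch_set`), `truth` (list: `beta`,
#'   `subject_offsets`, `item_offsets`, `artifacts` data frame with columns
#'   `subject`/`item`, `roi_gain`, `item_sd`) and `config`.
#' @export
simulate_epochs <- function(config, competition, file = NULL) {
  stopifnot(inherits(config, "erp_sim_config"))
  if (!all(c("wif", "z_log_count") %in% names(competition))) {
    stop("competition records must carry `wif` and `z_log_count`",
      call. = FALSE
    )
  }
  layout <- montage(config$montage_id)
  gain_roi <- config$roi_gain
  if (is.null(gain_roi)) gain_roi <- default_roi_gain(layout)
  miss <- setdiff(unique(layout$roi), names(gain_roi))
  if (length(miss)) {
    stop("roi_gain missing ROI(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  channels <- layout$channel
  gain_ch <- unname(gain_roi[layout$roi])

  step <- 1000 / config$sampling_rate
  times <- seq(config$epoch_span[1], config$epoch_span[2], by = step)
  tidx <- which(times >= config$window[1] & times <= config$window[2])
  if (!length(tidx)) {
    stop("analysis window contains no samples at this sampling rate",
      call. = FALSE
    )
  }

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  items <- competition$wif
  z <- competition$z_log_count
  ns <- length(subjects)
  ni <- length(items)
  nc <- length(channels)
  nt <- length(times)

  with_seed(config$seed, {
    subj_off <- stats::rnorm(ns, 0, config$subject_sd)
    item_off <- stats::rnorm(ni, 0, config$item_sd)
    amp <- array(
      stats::rnorm(ns * ni * nc * nt, 0, config$sample_sd),
      dim = c(ns, ni, nc, nt)
    )
    drift <- stats::rnorm(ns * ni * nc, 0, config$drift_sd)
    amp <- amp + drift # recycles over samples: constant per trace

    eff <- config$study_mean +
      subj_off + # recycles over items and channels
      rep(item_off, each = ns) + # recycles over channels
      config$study_sd * config$beta * outer(rep(1, ns), outer(z, gain_ch))
    amp[, , , tidx] <- amp[, , , tidx] + c(eff)

    hit <- which(stats::runif(ns * ni) < config$artifact_rate)
    artifacts <- data.frame(
      subject = subjects[(hit - 1L) %% ns + 1L],
      item = items[(hit - 1L) %/% ns + 1L],
      stringsAsFactors = FALSE
    )
    if (length(hit)) {
      ci <- sample.int(nc, length(hit), replace = TRUE)
      ti <- sample.int(nt, length(hit), replace = TRUE)
      sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
      s_i <- (hit - 1L) %% ns + 1L
      i_i <- (hit - 1L) %/% ns + 1L
      amp[cbind(s_i, i_i, ci, ti)] <- sgn * config$artifact_amplitude
    }

    epochs <- epoch_set(amp, times, channels, subjects, items)
    if (!is.null(file)) write_epochs(epochs, file)
    list(
      epochs = epochs,
      truth = list(
        beta = config$beta,
        subject_offsets = stats::setNames(subj_off, subjects),
        item_offsets = stats::setNames(item_off, items),
        artifacts = artifacts,
        roi_gain = gain_roi,
        item_sd = config$item_sd
      ),
      config = config
    )
  })
}
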