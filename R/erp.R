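#' Construct an epoch set
#'
#' Container for epoched EEG: a dense subject x item x channel x sample
#' amplitude array (microvolts), time-locked so that 0 ms is the F0 (pitch)
#' onset of the stimulus. Items map to WIF ids; by convention an item label is
#' either a WIF id itself (e.g. `"b o:|1"`) or a WIF id with a `#k` suffix for
#' multiple items sharing a fragment (pooled before averaging).
#'
#' @param amplitudes 4-d numeric array `(subject, item, channel, sample)`.
#' @param times Numeric vector of sample times in ms (strictly increasing,
#'   uniform spacing).
#' @param channels Character vector of 10-20-system channel labels.
#' @param subjects Character vector of subject ids.
#' @param items Character vector of item labels.
#' @param item_wif Optional character vector mapping each item to a WIF id;
#'   defaults to the item labels with any `#k` suffix stripped.
#' @param rejected Optional logical subject x item matrix of rejected epochs.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(amplitudes, times, channels, subjects, items,
                      item_wif = NULL, rejected = NULL) {
  stopifnot(
    is.array(amplitudes), length(dim(amplitudes)) == 4L,
    dim(amplitudes)[1] == length(subjects),
    dim(amplitudes)[2] == length(items),
    dim(amplitudes)[3] == length(channels),
    dim(amplitudes)[4] == length(times)
  )
  if (is.unsorted(times, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (length(times) > 2L) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6) {
      stop("non-uniform time grid", call. = FALSE)
    }
  }
  if (is.null(item_wif)) item_wif <- sub("#.*$", "", items)
  stopifnot(length(item_wif) == length(items))
  names(item_wif) <- items
  if (is.null(rejected)) {
    rejected <- matrix(FALSE, length(subjects), length(items))
  }
  stopifnot(
    is.logical(rejected),
    nrow(rejected) == length(subjects), ncol(rejected) == length(items)
  )
  structure(
    list(
      amplitudes = amplitudes,
      times = as.numeric(times),
      channels = as.character(channels),
      subjects = as.character(subjects),
      items = as.character(items),
      item_wif = item_wif,
      rejected = rejected
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(
    "<epoch_set> ", length(x$subjects), " subjects x ", length(x$items),
    " items x ", length(x$channels), " channels x ", length(x$times),
    " samples [", min(x$times), ", ", max(x$times), "] ms; ",
    sum(x$rejected), " epoch(s) rejected\n",
    sep = ""
  )
  invisible(x)
}

#' Load epochs from a long-format delimited file
#'
#' Expects columns `subject`, `item`, `channel`, `time_ms`, `amplitude_uv`.
#' The table must be dense: every subject x item x channel x time cell present
#' exactly once (no imputation is performed). Times must lie on a uniform
#' grid.
#'
#' @param path Path to a TSV/CSV file.
#' @param layout Optional montage data frame (see [montage()]); channel labels
#'   not present in the montage raise an error naming them.
#' @param delimiter Field delimiter, default tab.
#' @return An [epoch_set()].
#' @export
load_epochs <- function(path, layout = NULL, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("cannot read epoch file: ", path, call. = FALSE)
  }
  d <- utils::read.delim(path,
    sep = delimiter, quote = "", stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"
  )
  need <- c("subject", "item", "channel", "time_ms", "amplitude_uv")
  if (!all(need %in% names(d))) {
    stop(
      "epoch file lacks column(s): ",
      paste(setdiff(need, names(d)), collapse = ", "),
      call. = FALSE
    )
  }
  subjects <- sort(unique(as.character(d$subject)))
  items <- sort(unique(as.character(d$item)))
  times <- sort(unique(as.numeric(d$time_ms)))
  if (!is.null(layout)) {
    unknown <- setdiff(unique(d$channel), layout$channel)
    if (length(unknown)) {
      stop(
        "unknown channel label(s) not in montage: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    channels <- intersect(layout$channel, unique(d$channel))
  } else {
    channels <- sort(unique(as.character(d$channel)))
  }
  if (length(times) > 2L) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6) {
      stop("non-uniform time grid in epoch file", call. = FALSE)
    }
  }
  dims <- c(length(subjects), length(items), length(channels), length(times))
  idx <- cbind(
    match(as.character(d$subject), subjects),
    match(as.character(d$item), items),
    match(as.character(d$channel), channels),
    match(as.numeric(d$time_ms), times)
  )
  if (anyDuplicated(idx)) {
    stop("duplicated (subject, item, channel, time) cells in epoch file",
      call. = FALSE
    )
  }
  amp <- array(NA_real_, dims)
  amp[idx] <- d$amplitude_uv
  miss <- which(is.na(amp), arr.ind = TRUE)
  if (nrow(miss)) {
    m <- miss[1L, ]
    stop(
      "missing cell in epoch file: subject=", subjects[m[1]],
      " item=", items[m[2]], " channel=", channels[m[3]],
      " time_ms=", times[m[4]],
      call. = FALSE
    )
  }
  epoch_set(amp, times, channels, subjects, items)
}

#' Write an epoch set as long-format tab-separated text
#'
#' Amplitudes are written with 17 significant digits so a write/load round
#' trip reproduces values exactly.
#'
#' @param epochs An [epoch_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  g <- expand.grid(
    subject = epochs$subjects, item = epochs$items,
    channel = epochs$channels, time_ms = epochs$times,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$amplitude_uv <- formatC(as.vector(epochs$amplitudes),
    digits = 17, format = "g"
  )
  utils::write.table(g, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Baseline-correct every epoch
#'
#' Subtracts from each (subject, item, channel) trace its mean over the
#' pre-stimulus baseline interval, so that post-correction baseline means are
#' zero. The default interval is the 200 ms preceding F0 onset.
#'
#' @param epochs An [epoch_set()].
#' @param baseline Length-2 numeric `(start_ms, end_ms)`, inclusive; must be
#'   covered by the sampled range.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(length(baseline) == 2L, baseline[1] < baseline[2])
  tms <- epochs$times
  if (baseline[1] < min(tms) || baseline[2] > max(tms)) {
    stop("baseline interval outside sampled range", call. = FALSE)
  }
  idx <- which(tms >= baseline[1] & tms <= baseline[2])
  if (!length(idx)) {
    stop("baseline interval contains no samples", call. = FALSE)
  }
  nt <- length(tms)
  m <- matrix(epochs$amplitudes, ncol = nt)
  base <- rowMeans(m[, idx, drop = FALSE])
  epochs$amplitudes <- array(m - base, dim = dim(epochs$amplitudes))
  epochs
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' Marks as rejected every (subject, item) epoch in which any channel or
#' sample magnitude strictly exceeds the threshold (default the conventional
#' +-100 microvolts). Rejection accumulates: already-rejected epochs stay
#' rejected. A per-subject rejection log is attached as attribute
#' `"rejection_log"`.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Positive scalar in microvolts, default 100.
#' @return The `epoch_set` with an updated `rejected` mask.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  ns <- length(epochs$subjects)
  ni <- length(epochs$items)
  m <- matrix(abs(epochs$amplitudes) > threshold, nrow = ns * ni)
  viol <- matrix(rowSums(m) > 0L, ns, ni)
  epochs$rejected <- epochs$rejected | viol
  log <- data.frame(
    subject = epochs$subjects,
    n_rejected = rowSums(epochs$rejected),
    stringsAsFactors = FALSE
  )
  attr(epochs, "rejection_log") <- log
  epochs
}

#' Average epochs into per-WIF ERPs
#'
#' Two-stage averaging, following conventional grand-averaging: within each
#' subject, the unrejected epochs of all items sharing a WIF are averaged;
#' the subject ERPs are then averaged across subjects, unweighted. WIFs with
#' no surviving epochs anywhere are dropped with a warning; subjects who lost
#' every epoch of a WIF simply do not contribute to that WIF's grand average.
#'
#' @param epochs An [epoch_set()] (typically baseline-corrected and
#'   artifact-screened).
#' @return Object of class `item_erps`: list with `grand` (wif x channel x
#'   sample array), `by_subject` (subject x wif x channel x sample array,
#'   `NA` where a subject has no surviving epochs), `wifs`, `channels`,
#'   `times`.
#' @export
item_erps <- function(epochs) {
  wifs <- sort(unique(unname(epochs$item_wif)))
  ns <- length(epochs$subjects)
  nc <- length(epochs$channels)
  nt <- length(epochs$times)
  by_subject <- array(
    NA_real_, c(ns, length(wifs), nc, nt),
    dimnames = list(epochs$subjects, wifs, NULL, NULL)
  )
  for (w in seq_along(wifs)) {
    its <- which(unname(epochs$item_wif) == wifs[[w]])
    for (s in seq_len(ns)) {
      ok <- its[!epochs$rejected[s, its]]
      if (!length(ok)) next
      if (length(ok) == 1L) {
        by_subject[s, w, , ] <- epochs$amplitudes[s, ok, , ]
      } else {
        sl <- epochs$amplitudes[s, ok, , , drop = FALSE]
        by_subject[s, w, , ] <- colMeans(
          matrix(sl, nrow = length(ok)),
          na.rm = FALSE
        )
      }
    }
  }
  dead <- vapply(
    seq_along(wifs),
    function(w) all(is.na(by_subject[, w, 1L, 1L])),
    logical(1)
  )
  if (any(dead)) {
    warning(
      "WIF(s) with no surviving epochs excluded: ",
      paste(wifs[dead], collapse = ", "),
      call. = FALSE
    )
    wifs <- wifs[!dead]
    by_subject <- by_subject[, !dead, , , drop = FALSE]
  }
  grand <- colMeans(by_subject, na.rm = TRUE, dims = 1L)
  structure(
    list(
      grand = grand,
      by_subject = by_subject,
      wifs = wifs,
      channels = epochs$channels,
      times = epochs$times
    ),
    class = "item_erps"
  )
}

#' Windowed region-of-interest mean amplitudes
#'
#' Averages an ERP over the channels of each region of interest and the
#' samples inside the analysis window (both endpoints inclusive), yielding
#' one record per WIF x ROI — the dependent variable of all downstream
#' statistics. With `per_subject = TRUE` the subject-resolved averages are
#' returned instead (one record per subject x WIF x ROI), as needed by the
#' repeated-measures ANOVA.
#'
#' @param erps An [item_erps()] object.
#' @param rois Montage data frame with columns `roi`, `antpost`, `laterality`,
#'   `channel` (see [montage()]); may be a subset of ROIs.
#' @param window Length-2 numeric `(start_ms, end_ms)`.
#' @param per_subject Return subject-resolved records?
#' @return Data frame with columns (`subject`,) `wif`, `accent`, `roi`,
#'   `antpost`, `laterality`, `mean_amplitude`, `window_start`, `window_end`.
#' @export
window_roi_amplitudes <- function(erps, rois, window, per_subject = FALSE) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  tidx <- which(erps$times >= window[1] & erps$times <= window[2])
  if (!length(tidx)) {
    stop("analysis window contains no samples", call. = FALSE)
  }
  roi_names <- unique(rois$roi)
  acc <- parse_wif_id(erps$wifs)$accent
  nw <- length(erps$wifs)
  out <- vector("list", length(roi_names))
  for (r in seq_along(roi_names)) {
    rdef <- rois[rois$roi == roi_names[[r]], , drop = FALSE]
    cidx <- match(rdef$channel, erps$channels)
    if (anyNA(cidx)) {
      stop(
        "ROI '", roi_names[[r]], "' channel(s) absent from data: ",
        paste(rdef$channel[is.na(cidx)], collapse = ", "),
        call. = FALSE
      )
    }
    if (per_subject) {
      ns <- dim(erps$by_subject)[1]
      sl <- erps$by_subject[, , cidx, tidx, drop = FALSE]
      vals <- rowMeans(matrix(sl, nrow = ns * nw)) # NA if subject lost the WIF
      rec <- data.frame(
        subject = rep(dimnames(erps$by_subject)[[1]], times = nw),
        wif = rep(erps$wifs, each = ns),
        accent = rep(acc, each = ns),
        roi = roi_names[[r]],
        antpost = rdef$antpost[1L],
        laterality = rdef$laterality[1L],
        mean_amplitude = vals,
        stringsAsFactors = FALSE
      )
    } else {
      sl <- erps$grand[, cidx, tidx, drop = FALSE]
      vals <- rowMeans(matrix(sl, nrow = nw))
      rec <- data.frame(
        wif = erps$wifs,
        accent = acc,
        roi = roi_names[[r]],
        antpost = rdef$antpost[1L],
        laterality = rdef$laterality[1L],
        mean_amplitude = vals,
        stringsAsFactors = FALSE
      )
    }
    out[[r]] <- rec
  }
  out <- do.call(rbind, out)
  out$window_start <- window[1]
  out$window_end <- window[2]
  rownames(out) <- NULL
  out
}
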