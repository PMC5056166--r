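#' Electrode montages and regions of interest
#'
#' Two ROI layouts are shipped as plain-text configs under `extdata`:
#' \describe{
#'   \item{`exp1_3`}{6 ROIs of 2 channels each — left/right anterior
#'     (F7, F3 / F4, F8), central (T7, C3 / C4, T8) and posterior
#'     (P7, P3 / P4, P8). Laterality has levels left/right.}
#'   \item{`exp2`}{9 ROIs of 6 channels each, crossing Antpost
#'     (anterior/central/posterior) with Laterality (left/mid/right) on a
#'     denser cap.}
#' }
#'
#' @param id Montage id, `"exp1_3"` or `"exp2"`.
#' @return Data frame with columns `roi`, `antpost`, `laterality`, `channel`.
#' @export
montage <- function(id = c("exp1_3", "exp2")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0("montage_", id, ".tsv"),
    package = "pranr", mustWork = TRUE
  )
  d <- utils::read.delim(path,
    sep = "\t", quote = "", stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$channel)) {
    stop("montage ROIs must be disjoint", call. = FALSE)
  }
  d
}

#' ROI subset of a montage
#'
#' @param layout A [montage()] data frame.
#' @param rois Character vector of ROI names to keep.
#' @return The subsetted montage data frame.
#' @export
montage_subset <- function(layout, rois) {
  bad <- setdiff(rois, unique(layout$roi))
  if (length(bad)) {
    stop("unknown ROI(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- layout[layout$roi %in% rois, , drop = FALSE]
  rownames(out) <- NULL
  out
}
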