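# Behavioural read-outs from segmentation masks: total open-polyp surface
# area per frame, the frame-differencing activity index, normalisation,
# percent expansion and the absolute derivative.

#' Per-frame open-polyp surface area
#'
#' @param masks List of segmentation masks (integer class matrices), one per
#'   frame.
#' @return Integer vector of open-polyp pixel counts, one per frame.
#' @export
open_area_series <- function(masks) {
  abort_if(length(masks) < 1, "need at least one mask")
  vapply(masks, function(m) sum(m == CLASS_OPEN_POLYP), integer(1))
}

#' Polyp activity index between two consecutive frames
#'
#' Counts pixels whose open-polyp membership differs between the two masks
#' (the symmetric difference of the open-polyp pixel sets). A polyp that
#' only waves its tentacles while keeping the same open surface contributes
#' nothing: identical open sets give a null difference.
#'
#' @param mask_curr,mask_prev Segmentation masks of equal dimensions.
#' @return Non-negative integer changed-pixel count.
#' @export
activity_index <- function(mask_curr, mask_prev) {
  abort_if(!all(dim(mask_curr) == dim(mask_prev)),
           "mask dimensions differ (%s vs %s)",
           paste(dim(mask_curr), collapse = "x"),
           paste(dim(mask_prev), collapse = "x"))
  sum((mask_curr == CLASS_OPEN_POLYP) != (mask_prev == CLASS_OPEN_POLYP))
}

#' Activity index over a mask sequence
#'
#' The index is undefined at the first frame (reported as `NA`), then one
#' value per consecutive frame pair.
#'
#' @param masks List of segmentation masks.
#' @return Numeric vector, length equal to the number of frames; `NA` first.
#' @export
activity_index_series <- function(masks) {
  abort_if(length(masks) < 1, "need at least one mask")
  n <- length(masks)
  out <- rep(NA_real_, n)
  if (n > 1) {
    for (t in 2:n) out[t] <- activity_index(masks[[t]], masks[[t - 1]])
  }
  out
}

#' Normalise an open-area series by its maximum
#'
#' Divides every value by the series maximum (the maximum polyp expansion of
#' that experiment), giving values in \[0, 1\] with the maximum exactly 1.
#'
#' @param open_area Non-negative numeric series.
#' @return Numeric series in \[0, 1\].
#' @export
normalize_activity <- function(open_area) {
  abort_if(length(open_area) < 1, "series is empty")
  abort_if(any(open_area < 0), "open areas must be non-negative")
  m <- max(open_area)
  abort_if(m == 0, "all-zero series: no expansion to normalise by")
  open_area / m
}

#' Percent polyp expansion relative to calibration references
#'
#' Linear rescaling between the contracted (`closed_ref`) and fully expanded
#' (`open_ref`) reference areas, clipped to \[0, 100\]. References are
#' typically taken from calibration frames: the all-closed start of an
#' experiment and the observed maximum.
#'
#' @param open_area Numeric series of open areas (px).
#' @param closed_ref Area at full contraction (>= 0).
#' @param open_ref Area at full expansion (> `closed_ref`).
#' @return Percent series in \[0, 100\].
#' @export
percent_expansion <- function(open_area, closed_ref, open_ref) {
  abort_if(closed_ref < 0, "closed_ref must be >= 0")
  abort_if(open_ref <= closed_ref, "open_ref must exceed closed_ref")
  clip(100 * (open_area - closed_ref) / (open_ref - closed_ref), 0, 100)
}

#' Absolute first difference of an activity curve
#'
#' The per-step magnitude of change (increase or decrease) in polyp
#' expansion; length one less than the input.
#'
#' @param series Numeric series.
#' @return Non-negative numeric series of length `length(series) - 1`.
#' @export
activity_derivative <- function(series) {
  abort_if(length(series) < 2, "need at least two samples")
  abs(diff(series))
}

#' Camera pixel resolution
#'
#' Physical size of one pixel given the real imaged width and the frame
#' width, reported to 2 significant figures (e.g. 104 mm over 736 px gives
#' 140 um per pixel).
#'
#' @param real_width_mm Imaged width in mm (> 0).
#' @param width_px Frame width in pixels (> 0).
#' @return Micrometres per pixel, 2 significant figures.
#' @export
pixel_resolution <- function(real_width_mm, width_px) {
  abort_if(real_width_mm <= 0 || width_px <= 0,
           "width and pixel count must be positive")
  signif(1000 * real_width_mm / width_px, 2)
}

#' Assemble an activity table from a mask sequence
#'
#' Convenience wrapper combining the open-area series, the activity index,
#' maximum-normalised activity and percent expansion into one data frame.
#'
#' @param masks List of segmentation masks.
#' @param time_s Frame timestamps in seconds (default 20 s spacing, i.e. 3
#'   frames/min).
#' @param closed_ref,open_ref Percent-expansion references; defaults are the
#'   series minimum and maximum (calibration-frame convention).
#' @return Data frame with `frame`, `time_s`, `open_area_px`,
#'   `activity_index_px`, `normalized`, `percent_expansion`.
#' @export
activity_table <- function(masks, time_s = (seq_along(masks) - 1) * 20,
                           closed_ref = NULL, open_ref = NULL) {
  area <- open_area_series(masks)
  if (is.null(closed_ref)) closed_ref <- min(area)
  if (is.null(open_ref)) open_ref <- max(area)
  data.frame(
    frame = seq_along(masks),
    time_s = time_s,
    open_area_px = area,
    activity_index_px = activity_index_series(masks),
    normalized = normalize_activity(area),
    percent_expansion = percent_expansion(area, closed_ref, open_ref)
  )
}
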