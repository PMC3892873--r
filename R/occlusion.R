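#' Detect lower-body occlusion and switch tracking modes
#'
#' State machine over a per-frame depth profile (mean depth of the upper and
#' lower body regions): when the lower-body mean depth drops below the
#' upper-body depth by more than `delta` for at least `hold` consecutive
#' frames — a closer object, such as furniture, is covering the legs — the
#' tracker switches to the seated (upper-body-only) mode; when the
#' difference returns within `delta` for `hold` consecutive frames it
#' switches back. A frame with no lower-body depth at all (fully occluded)
#' counts as occluded. The debounce makes the mode stream piecewise
#' constant: single-frame flickers never switch modes.
#'
#' @param profile A data frame with columns `frame`, `upper_mean_depth`,
#'   `lower_mean_depth` (meters; `lower_mean_depth` may be NA when the
#'   region is empty).
#' @param delta Depth-drop threshold in meters (default 0.3).
#' @param hold Consecutive frames required to switch (default 3).
#' @return A tibble with columns `frame`, `occluded` (raw per-frame signal)
#'   and `mode` (`"default"` / `"seated"`).
#' @export
detect_occlusion <- function(profile, delta = 0.3, hold = 3) {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("frame", "upper_mean_depth", "lower_mean_depth") %in%
                  names(profile)))
  occ <- is.na(profile$lower_mean_depth) |
    profile$lower_mean_depth < profile$upper_mean_depth - delta
  n <- length(occ)
  mode <- character(n)
  state <- "default"
  run <- 0L
  for (i in seq_len(n)) {
    mode[i] <- state  # a completed hold switches the mode from the NEXT frame
    opposite <- if (state == "default") occ[i] else !occ[i]
    run <- if (opposite) run + 1L else 0L
    if (run >= hold) {
      state <- if (state == "default") "seated" else "default"
      run <- 0L
    }
  }
  tibble::tibble(frame = profile$frame, occluded = occ, mode = mode)
}

#' Depth profile from a raster depth image
#'
#' Raster-input path for occlusion detection: depth values inside the
#' skeleton bounding box are averaged separately above and below the
#' HIP_CENTER row, giving the upper- and lower-body mean depths of one
#' frame.
#'
#' @param depth A numeric matrix of depth values in meters (rows are image
#'   rows, top first); NA for no-return pixels.
#' @param bbox Bounding box as `c(row_min, row_max, col_min, col_max)`.
#' @param hip_row Image row of the HIP_CENTER joint (the upper/lower split).
#' @param frame Frame index to record.
#' @return A one-row depth-profile tibble.
#' @export
depth_profile_from_image <- function(depth, bbox, hip_row, frame = 1L) {
  rows <- bbox[1]:bbox[2]
  cols <- bbox[3]:bbox[4]
  sub <- depth[rows, cols, drop = FALSE]
  upper <- sub[rows <= hip_row - bbox[1] + 1, , drop = FALSE]
  lower <- sub[rows > hip_row - bbox[1] + 1, , drop = FALSE]
  mean_or_na <- function(m) {
    v <- m[is.finite(m)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  tibble::tibble(frame = as.integer(frame),
                 upper_mean_depth = mean_or_na(upper),
                 lower_mean_depth = mean_or_na(lower))
}
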