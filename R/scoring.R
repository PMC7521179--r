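#' Parameters of the pixel scoring pipeline
#'
#' The pipeline estimates the background as the mean intensity over a
#' centered rectangle covering `rect_fraction` of each image dimension,
#' subtracts it (clipping residuals below 0), applies the linear contrast map
#' `v * alpha + beta` (clipping to \[0, 255\]), and marks a pixel positive when
#' the result is at least `pixel_threshold`.  The score of a well is the
#' count of positive pixels.
#'
#' The defaults are neutral: `alpha = 1`, `beta = 0` leave residual
#' intensities untouched, and `pixel_threshold = 50` (on the 8-bit scale)
#' separates bright reporter patches from a dim organoid body in typical
#' images.  16-bit input is rescaled to the 8-bit range (division by 257)
#' before the pipeline so the threshold has one meaning across bit depths.
#'
#' @param rect_fraction fraction in (0, 1] of each image dimension covered by
#'   the background rectangle; default 0.8.
#' @param alpha contrast gain, > 0.
#' @param beta contrast offset.
#' @param pixel_threshold per-pixel positivity cutoff in (0, 255].
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(rect_fraction = 0.8, alpha = 1, beta = 0,
                           pixel_threshold = 50) {
  if (!is.numeric(rect_fraction) || length(rect_fraction) != 1L ||
      rect_fraction <= 0 || rect_fraction > 1)
    stop_validation("rect_fraction must lie in (0, 1], got %s", rect_fraction)
  if (!is.numeric(alpha) || alpha <= 0)
    stop_validation("alpha must be positive, got %s", alpha)
  if (!is.numeric(beta) || length(beta) != 1L)
    stop_validation("beta must be a single number")
  if (!is.numeric(pixel_threshold) || pixel_threshold <= 0 ||
      pixel_threshold > 255)
    stop_validation("pixel_threshold must lie in (0, 255], got %s",
                    pixel_threshold)
  structure(list(rect_fraction = rect_fraction, alpha = alpha, beta = beta,
                 pixel_threshold = pixel_threshold, positive_value = 255),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf(
    "<scoring_params rect_fraction=%g alpha=%g beta=%g pixel_threshold=%g>\n",
    x$rect_fraction, x$alpha, x$beta, x$pixel_threshold))
  invisible(x)
}

# rows/cols of the centered background rectangle for one dimension.
# Size is round-half-away-from-zero of fraction*dim, at least 1; when the
# leftover margin is odd the extra row/column goes to the bottom/right.
central_span <- function(dim, fraction) {
  size <- max(1L, as.integer(round_half_up(fraction * dim)))
  offset <- (dim - size) %/% 2L
  seq.int(offset + 1L, offset + size)
}

#' Estimate the background intensity of a well image
#'
#' The arithmetic mean of the pixels inside a centered axis-aligned rectangle
#' whose height and width are `rect_fraction` of the image's.  The organoid
#' sits in the middle of the well, so a rectangle covering most of the frame
#' averages mostly dark background plus the dim organoid body, giving a
#' per-image background level that tracks illumination differences between
#' wells.
#'
#' @param image a [well_image()] or a plain numeric matrix.
#' @param rect_fraction fraction in (0, 1] of each dimension.
#' @return the mean intensity (native scale of the input).
#' @examples
#' m <- matrix(0, 10, 10); m[c(1, 10), c(1, 10)] <- 100
#' estimate_background(m, 0.8)  # corners excluded -> 0
#' @export
estimate_background <- function(image, rect_fraction = 0.8) {
  px <- if (inherits(image, "well_image")) image$pixels else image
  if (!is.matrix(px)) stop_validation("image must be a matrix or well_image")
  if (rect_fraction <= 0 || rect_fraction > 1)
    stop_validation("rect_fraction must lie in (0, 1], got %s", rect_fraction)
  rows <- central_span(nrow(px), rect_fraction)
  cols <- central_span(ncol(px), rect_fraction)
  mean(px[rows, cols])
}

# 16-bit images are mapped onto the 8-bit scale so that pixel_threshold and
# the 255 saturation constant mean the same thing at either depth.
pipeline_pixels <- function(image) {
  if (inherits(image, "well_image")) {
    if (image$bit_depth == 16L) image$pixels / 257 else image$pixels
  } else image
}

#' Run the scoring pipeline and return the binary positivity mask
#'
#' Per pixel: subtract the estimated background (clip below at 0), apply the
#' linear contrast map `v * alpha + beta` (clip to \[0, 255\]), and set the
#' mask to 255 where the result reaches `pixel_threshold`, else 0.  All
#' arithmetic is floating point; only the mask is integer.
#'
#' @param image a [well_image()] or numeric matrix (8-bit scale if a matrix).
#' @param params a [scoring_params()].
#' @return integer matrix of 0/255 with the input's dimensions.
#' @export
apply_pipeline <- function(image, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  px <- pipeline_pixels(image)
  bg <- estimate_background(px, params$rect_fraction)
  v <- px - bg
  v[v < 0] <- 0
  v <- v * params$alpha + params$beta
  v[v < 0] <- 0
  v[v > 255] <- 255
  mask <- matrix(0L, nrow(px), ncol(px))
  mask[v >= params$pixel_threshold] <- 255L
  mask
}

#' Score one well: count of positive pixels
#'
#' Runs [apply_pipeline()] and counts mask pixels at 255.  The count is the
#' well's *score*, a proxy for the reporter-positive projected area in
#' pixels.
#'
#' @inheritParams apply_pipeline
#' @return an object of class `organoid_score`: `plate_id`, `well_id`,
#'   `score`, `background` (8-bit scale), `area_px`, `height`, `width`,
#'   `params_used`.
#' @export
compute_score <- function(image, params = scoring_params()) {
  mask <- apply_pipeline(image, params)
  px <- pipeline_pixels(image)
  structure(list(
    plate_id   = if (inherits(image, "well_image")) image$plate_id else "",
    well_id    = if (inherits(image, "well_image")) image$well_id else "",
    score      = sum(mask == 255L),
    background = estimate_background(px, params$rect_fraction),
    area_px    = length(px),
    height     = nrow(mask),
    width      = ncol(mask),
    params_used = params
  ), class = "organoid_score")
}

#' @export
print.organoid_score <- function(x, ...) {
  cat(sprintf("<organoid_score %s/%s score=%d background=%.2f (%dx%d px)>\n",
              x$plate_id, x$well_id, x$score, x$background, x$height, x$width))
  invisible(x)
}

#' Score every imaged well of a plate
#'
#' @param plate a `plate_set` from [discover_plate()] or [generate_plate()].
#' @param params a [scoring_params()].
#' @return data frame with one row per imaged well: plate_id, well_id, score,
#'   background, height, width.
#' @export
score_plate <- function(plate, params = scoring_params()) {
  stopifnot(inherits(plate, "plate_set"))
  as_score_table(lapply(plate$wells, compute_score, params = params))
}

#' Convert a score to a fraction of organoid projected area
#'
#' @param score non-negative pixel count.
#' @param organoid_area_px projected area of the organoid in pixels (> 0);
#'   how it was measured is up to the caller (it is not produced by the
#'   scoring pipeline).
#' @return `score / organoid_area_px`; values above 1 are returned as-is
#'   with a warning.
#' @export
score_to_area_fraction <- function(score, organoid_area_px) {
  if (!is.numeric(organoid_area_px) || any(organoid_area_px <= 0))
    stop_validation("organoid_area_px must be positive")
  if (any(score < 0)) stop_validation("score must be non-negative")
  frac <- score / organoid_area_px
  if (any(frac > 1))
    warning("score exceeds organoid area; fraction > 1 reported as-is")
  frac
}
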