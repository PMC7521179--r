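#' In-memory well image
#'
#' A `well_image` is a 2-D intensity matrix tagged with its plate/well
#' identity, channel label and native bit depth.  Pixel coordinates are
#' row-major with the origin at the top-left; intensities are kept at native
#' scale (`0 .. 2^bit_depth - 1`).
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param plate_id plate identifier string.
#' @param well_id well coordinate, row letter A-H plus column 1-12; both
#'   zero-padded ("A01") and bare ("A1") forms are accepted and canonicalized
#'   to the bare form.
#' @param bit_depth 8 or 16.
#' @param channel free-text channel label (e.g. "green").
#' @return an object of class `well_image`.
#' @examples
#' img <- well_image(matrix(0, 16, 16), plate_id = "P1", well_id = "B07")
#' img$well_id  # "B7"
#' @export
well_image <- function(pixels, plate_id = "", well_id = "A1",
                       bit_depth = 8L, channel = "mono") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_validation("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_validation("zero-sized image (dims %d x %d)", nrow(pixels), ncol(pixels))
  if (!bit_depth %in% c(8L, 16L))
    stop_validation("bit_depth must be 8 or 16, got %s", bit_depth)
  maxval <- 2^bit_depth - 1
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > maxval)
    stop_validation("pixel intensities outside [0, %d]", maxval)
  structure(list(
    pixels    = pixels,
    height    = nrow(pixels),
    width     = ncol(pixels),
    bit_depth = as.integer(bit_depth),
    plate_id  = as.character(plate_id),
    well_id   = normalize_well_id(well_id),
    channel   = as.character(channel)
  ), class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  cat(sprintf("<well_image %s/%s  %dx%d  %d-bit  channel=%s>\n",
              x$plate_id, x$well_id, x$height, x$width, x$bit_depth, x$channel))
  invisible(x)
}

#' Normalize a 96-well coordinate
#'
#' Accepts zero-padded ("A01") and bare ("A1") well ids, upper- or lower-case,
#' and returns the canonical bare form ("A1").  Invalid coordinates raise a
#' validation error.
#'
#' @param well_id character vector of well ids.
#' @return character vector of canonical ids (row A-H, column 1-12).
#' @export
normalize_well_id <- function(well_id) {
  w <- toupper(trimws(as.character(well_id)))
  m <- regmatches(w, regexec("^([A-H])0?([1-9]|1[0-2])$", w))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop_validation("invalid well id(s): %s", paste(w[bad], collapse = ", "))
  vapply(m, function(g) paste0(g[2], g[3]), "")
}

#' @rdname normalize_well_id
#' @return `well_to_rowcol()`: a two-column integer matrix (row 1-8 = A-H,
#'   column 1-12).
#' @export
well_to_rowcol <- function(well_id) {
  w <- normalize_well_id(well_id)
  cbind(row = match(substr(w, 1, 1), LETTERS[1:8]),
        col = as.integer(substring(w, 2)))
}

#' @rdname normalize_well_id
#' @return `all_wells()`: the 96 canonical well ids in plate order
#'   (A1..A12, B1..B12, ...).
#' @export
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}
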