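#' Read a single well image from TIFF or PNG
#'
#' Reads 8- or 16-bit grayscale or RGB TIFF, or 8-bit PNG.  Multi-channel
#' images are reduced to one channel according to `channel`; the default is
#' the green plane, the usual home of GFP-class reporters.  Pixel values are
#' returned at native scale (integers in `0 .. 2^bit_depth - 1`).
#'
#' @param path file path (.tif/.tiff/.png).
#' @param channel for RGB input, one of "red", "green", "blue"; ignored for
#'   grayscale images.
#' @param plate_id,well_id identity to stamp on the result; when `NULL` they
#'   are parsed from the file name as `<plate>_<well>`.
#' @return a [well_image()].
#' @export
read_well_image <- function(path, channel = "green",
                            plate_id = NULL, well_id = NULL) {
  if (!file.exists(path))
    stop_io("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      tif  = ,
      tiff = tiff::readTIFF(path, as.is = TRUE, info = TRUE),
      png  = png::readPNG(path),
      stop_validation("unsupported image format '.%s' for '%s'", ext, path)
    ),
    error = function(e) {
      if (inherits(e, "organoidscreen_validation_error")) stop(e)
      stop_io("failed to read '%s': %s", path, conditionMessage(e))
    }
  )
  if (length(arr) == 0L || is.null(dim(arr)) || any(dim(arr)[1:2] == 0L))
    stop_validation("zero-sized image in '%s'", path)
  bps_attr <- attr(arr, "bits.per.sample")
  attributes(arr) <- list(dim = dim(arr))   # drop TIFF metadata attributes

  if (ext == "png") {
    bit_depth <- 8L
    # readPNG scales to [0,1]; recover 8-bit integer codes
    arr <- round(arr * 255)
  } else {
    bit_depth <- if (is.null(bps_attr)) 8L else as.integer(bps_attr[1])
    if (!bit_depth %in% c(8L, 16L))
      stop_validation("unsupported TIFF bit depth %d in '%s'", bit_depth, path)
  }

  if (length(dim(arr)) == 3L) {
    idx <- match(match.arg(channel, c("red", "green", "blue")),
                 c("red", "green", "blue"))
    if (dim(arr)[3] < idx)
      stop_validation("image '%s' has %d channels; cannot select %s",
                      path, dim(arr)[3], channel)
    arr <- arr[, , idx]
    # multi-channel TIFFs come back normalized to [0,1] regardless of as.is
    if (ext != "png" && !is.integer(arr))
      arr <- round(arr * (2^bit_depth - 1))
  }

  if (is.null(plate_id) || is.null(well_id)) {
    stem <- tools::file_path_sans_ext(basename(path))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    if (is.null(plate_id))
      plate_id <- if (length(parts) >= 2L)
        paste(parts[-length(parts)], collapse = "_") else ""
    if (is.null(well_id))
      well_id <- if (length(parts) >= 2L) parts[length(parts)] else "A1"
  }
  well_image(arr, plate_id = plate_id, well_id = well_id,
             bit_depth = bit_depth, channel = channel)
}

# Turn a "{plate}_{well}.{ext}" style template into a regex with capture
# groups named by the placeholders.
pattern_to_regex <- function(pattern) {
  if (!grepl("{plate}", pattern, fixed = TRUE) ||
      !grepl("{well}", pattern, fixed = TRUE))
    stop_validation("filename pattern must contain {plate} and {well} placeholders")
  rx <- gsub("([][(){}+*^$|\\\\?.])", "\\\\\\1", pattern)
  rx <- sub("\\\\\\{plate\\\\\\}", "(?<plate>.+)", rx)
  rx <- sub("\\\\\\{well\\\\\\}", "(?<well>[A-Ha-h]0?[0-9]{1,2})", rx)
  rx <- sub("\\\\\\{ext\\\\\\}", "(?:tif|tiff|png|TIF|TIFF|PNG)", rx)
  paste0("^", rx, "$")
}

#' Discover the well images of a plate in a directory
#'
#' Matches files against a filename template (default `{plate}_{well}.{ext}`
#' with extensions tif/tiff/png), assigns each to its 96-well coordinate,
#' reads the images, and records the coordinates with no image as missing.
#' Two files resolving to the same well (e.g. "A01" and "A1") are rejected.
#'
#' @param directory folder containing one plate's images.
#' @param pattern filename template with `{plate}`, `{well}` and optionally
#'   `{ext}` placeholders, or a full PCRE with named groups `plate`, `well`.
#' @param channel passed to [read_well_image()].
#' @return a list of class `plate_set`: `plate_id`, `wells` (named list of
#'   [well_image()]s), `missing_wells` (character vector).
#' @export
discover_plate <- function(directory, pattern = "{plate}_{well}.{ext}",
                           channel = "green") {
  if (!dir.exists(directory))
    stop_io("no such directory '%s'", directory)
  rx <- if (grepl("{plate}", pattern, fixed = TRUE))
    pattern_to_regex(pattern) else pattern
  files <- sort(list.files(directory))
  m <- regmatches(files, regexpr(rx, files, perl = TRUE))
  hits <- grepl(rx, files, perl = TRUE)
  if (!any(hits))
    stop_validation("no files in '%s' match pattern '%s'", directory, pattern)
  files <- files[hits]

  caps <- regmatches(files, regexec(rx, files, perl = TRUE))
  # named capture groups: extract by position of names
  parse_one <- function(fname) {
    mm <- regexpr(rx, fname, perl = TRUE)
    st <- attr(mm, "capture.start"); ln <- attr(mm, "capture.length")
    nm <- attr(mm, "capture.names")
    setNames(substring(fname, st, st + ln - 1L), nm)
  }
  info <- t(vapply(files, parse_one, c(plate = "", well = "")))
  wells_raw <- info[, "well"]
  ok <- grepl("^[A-Ha-h]0?([1-9]|1[0-2])$", wells_raw)
  files <- files[ok]; info <- info[ok, , drop = FALSE]
  if (nrow(info) == 0L)
    stop_validation("no files in '%s' carry a valid well coordinate", directory)
  wells <- normalize_well_id(info[, "well"])
  plate_ids <- unique(info[, "plate"])
  if (length(plate_ids) > 1L)
    stop_validation("directory '%s' mixes plates: %s", directory,
                    paste(plate_ids, collapse = ", "))
  dup <- wells[duplicated(wells)]
  if (length(dup) > 0L) {
    culprits <- files[wells %in% dup]
    stop_validation("multiple files map to well(s) %s: %s",
                    paste(unique(dup), collapse = ", "),
                    paste(culprits, collapse = ", "))
  }
  imgs <- lapply(seq_along(files), function(i)
    read_well_image(file.path(directory, files[i]), channel = channel,
                    plate_id = plate_ids, well_id = wells[i]))
  names(imgs) <- wells
  imgs <- imgs[intersect(all_wells(), wells)]   # plate order
  structure(list(
    plate_id      = plate_ids,
    wells         = imgs,
    missing_wells = setdiff(all_wells(), wells)
  ), class = "plate_set")
}

#' @export
print.plate_set <- function(x, ...) {
  cat(sprintf("<plate_set %s: %d wells imaged, %d missing>\n",
              x$plate_id, length(x$wells), length(x$missing_wells)))
  invisible(x)
}

# Coerce a list of organoid_score objects (or a ready data frame) to the
# canonical score table.
as_score_table <- function(results) {
  if (is.data.frame(results)) return(results)
  if (length(results) == 0L)
    return(data.frame(plate_id = character(), well_id = character(),
                      score = integer(), background = numeric(),
                      height = integer(), width = integer(),
                      label = character(), stringsAsFactors = FALSE))
  rows <- lapply(results, function(r) {
    data.frame(plate_id = r$plate_id, well_id = r$well_id,
               score = r$score, background = r$background,
               height = r$height, width = r$width,
               label = if (is.null(r$label)) NA_character_ else r$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-organoid scores to CSV
#'
#' One row per well with plate id, well id, score, estimated background,
#' image dimensions and (if present) the classification label.  Rows are
#' ordered by plate, then row letter, then column number, so repeated runs
#' produce byte-identical files.
#'
#' @param results a data frame from [score_plate()] or a list of
#'   [compute_score()] results.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_scores <- function(results, path) {
  df <- as_score_table(results)
  if (nrow(df) > 0L) {
    rc <- well_to_rowcol(df$well_id)
    df <- df[order(df$plate_id, rc[, "row"], rc[, "col"]), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_io("cannot write scores to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_io("no such scores file '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well_id", "score")
  if (!all(need %in% names(df)))
    stop_validation("scores file '%s' lacks columns: %s", path,
                    paste(setdiff(need, names(df)), collapse = ", "))
  df$well_id <- normalize_well_id(df$well_id)
  df
}
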