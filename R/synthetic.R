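# Synthetic well images with exact pixel-level ground truth.
#
# A well is modelled as a roughly circular dim organoid body on a darker
# background, with zero or more bright circular reporter patches inside the
# body, optional linear illumination gradient, and additive Gaussian noise.
# Disk rasterization is center-in-circle (a pixel belongs to a disk iff
# dx^2 + dy^2 <= r^2 for its integer offsets from the disk center), so
# ground-truth areas are integer-exact and implementation-independent.

#' Specification of one synthetic well image
#'
#' Defaults mimic the scale of a 96-well organoid scan: a 512x512 frame, an
#' organoid of radius 150 px (projected area ~70,700 px), and for positive
#' wells bright patches totalling a few percent of the organoid area —
#' reporter-positive regions are a small fraction of the projected area at
#' the stage where selection happens.
#'
#' @param height,width image dimensions in pixels.
#' @param organoid_radius radius of the organoid disk in pixels; the disk
#'   must fit inside the frame.
#' @param organoid_intensity intensity added inside the organoid body.
#' @param patches list of `list(center = c(row, col), radius, intensity)`
#'   fluorescent patches; centers must lie inside the organoid disk.
#' @param background_level base intensity outside the organoid.
#' @param gradient optional `list(direction = "row"|"column", amplitude)`
#'   linear illumination ramp from 0 to `amplitude` across the image.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units; applied after compositing, before clipping to the bit range).
#' @param bit_depth 8 or 16.
#' @param seed integer governing the well's random stream (noise and, when
#'   `random_patches` is set, patch sampling).
#' @param random_patches instead of explicit `patches`, sample them:
#'   `list(fraction = c(lo, hi), n = candidates, intensity)` draws a total
#'   patch area fraction of the organoid area uniformly from `[lo, hi]`,
#'   a patch count from `n`, and places equal-radius patches uniformly
#'   inside the organoid.
#' @return object of class `synthetic_well_spec`.
#' @export
synthetic_well_spec <- function(height = 512, width = 512,
                                organoid_radius = 150,
                                organoid_intensity = 30,
                                patches = list(),
                                background_level = 10,
                                gradient = NULL,
                                noise_sd = 0,
                                bit_depth = 8L,
                                seed = 1L,
                                random_patches = NULL) {
  if (height < 1 || width < 1) stop_validation("image dimensions must be >= 1")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  cy <- (height + 1L) %/% 2L; cx <- (width + 1L) %/% 2L
  if (cy - organoid_radius < 1 || cy + organoid_radius > height ||
      cx - organoid_radius < 1 || cx + organoid_radius > width)
    stop_validation("organoid disk (radius %g) does not fit in %dx%d image",
                    organoid_radius, height, width)
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    organoid_radius = organoid_radius,
    organoid_intensity = organoid_intensity,
    patches = patches, background_level = background_level,
    gradient = gradient, noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth), seed = as.integer(seed),
    random_patches = random_patches,
    center = c(row = cy, col = cx)
  ), class = "synthetic_well_spec")
  for (p in patches) validate_patch(p, spec)
  spec
}

validate_patch <- function(p, spec) {
  if (is.null(p$center) || length(p$center) != 2L || is.null(p$radius))
    stop_validation("each patch needs center = c(row, col) and radius")
  d2 <- sum((p$center - spec$center)^2)
  if (d2 > spec$organoid_radius^2)
    stop_validation("patch center (%g, %g) lies outside the organoid disk",
                    p$center[1], p$center[2])
  invisible(TRUE)
}

disk_mask <- function(height, width, center, radius) {
  dr <- (seq_len(height) - center[1])^2
  dc <- (seq_len(width) - center[2])^2
  outer(dr, dc, `+`) <= radius^2
}

# uniform integer point in the disk of given radius around center
sample_point_in_disk <- function(center, radius) {
  repeat {
    dr <- sample.int(2L * floor(radius) + 1L, 1L) - floor(radius) - 1L
    dc <- sample.int(2L * floor(radius) + 1L, 1L) - floor(radius) - 1L
    if (dr * dr + dc * dc <= radius^2)
      return(c(center[1] + dr, center[2] + dc))
  }
}

sample_random_patches <- function(spec) {
  rp <- spec$random_patches
  frac <- stats::runif(1, rp$fraction[1], rp$fraction[2])
  k <- if (length(rp$n) == 1L) rp$n else sample(rp$n, 1L)
  organoid_area <- pi * spec$organoid_radius^2
  r <- max(2, round(sqrt(frac * organoid_area / (k * pi))))
  reach <- max(0, spec$organoid_radius - r - 1)
  lapply(seq_len(k), function(i)
    list(center = sample_point_in_disk(spec$center, reach),
         radius = r, intensity = rp$intensity))
}

#' Render a synthetic well image
#'
#' Composites background, optional gradient, organoid body and patches, adds
#' Gaussian noise, clips to the bit range, and rounds to integer intensities.
#' Deterministic given `spec$seed`.  The returned ground truth holds exact
#' rasterized pixel counts: `positive_area_px` is the size of the union of
#' the patch disks, `organoid_area_px` of the organoid disk.
#'
#' @param spec a [synthetic_well_spec()].
#' @param plate_id,well_id identity stamped on the image.
#' @return list with `image` (a [well_image()]) and `truth` (list:
#'   `positive_area_px`, `organoid_area_px`, `label`, `seed`).
#' @export
render_well <- function(spec, plate_id = "SIM", well_id = "A1") {
  stopifnot(inherits(spec, "synthetic_well_spec"))
  with_seed(spec$seed, {
    patches <- if (length(spec$patches) == 0L && !is.null(spec$random_patches))
      sample_random_patches(spec) else spec$patches
    for (p in patches) validate_patch(p, spec)

    h <- spec$height; w <- spec$width
    organoid <- disk_mask(h, w, spec$center, spec$organoid_radius)
    img <- matrix(spec$background_level, h, w)
    if (!is.null(spec$gradient)) {
      g <- spec$gradient
      ramp <- if (g$direction == "row")
        matrix(g$amplitude * (seq_len(h) - 1) / max(1, h - 1), h, w)
      else
        matrix(g$amplitude * (seq_len(w) - 1) / max(1, w - 1), h, w,
               byrow = TRUE)
      img <- img + ramp
    }
    img <- img + spec$organoid_intensity * organoid
    patch_union <- matrix(FALSE, h, w)
    for (p in patches) {
      m <- disk_mask(h, w, p$center, p$radius)
      img <- img + p$intensity * m
      patch_union <- patch_union | m
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
    maxval <- 2^spec$bit_depth - 1
    img[img < 0] <- 0
    img[img > maxval] <- maxval
    img <- round(img)

    list(
      image = well_image(img, plate_id = plate_id, well_id = well_id,
                         bit_depth = spec$bit_depth, channel = "green"),
      truth = list(positive_area_px = sum(patch_union),
                   organoid_area_px = sum(organoid),
                   label = if (length(patches) > 0L) "positive" else "negative",
                   seed = spec$seed)
    )
  })
}

# deterministic per-well seed derived from (plate seed, well index);
# stays below 2^31 (exact in doubles well below 2^53)
derive_well_seed <- function(plate_seed, index) {
  as.integer((abs(plate_seed) * 7919 + index * 104729) %% 2147483647L)
}

#' Generate a synthetic plate with known labels
#'
#' Each of `n_wells` wells (filled in plate order A1..H12) is independently
#' positive with probability `positive_rate`, optionally modulated per
#' column by `edge_gradient` to emulate a spatial edge effect.  Positive
#' wells are rendered from `positive_spec` (which must produce at least one
#' patch), negative wells from `negative_spec` (no patches).  Each well's
#' random stream is derived from `(seed, well index)`, so a plate is
#' reproducible well-by-well.
#'
#' @param plate_id plate identifier.
#' @param n_wells number of wells, 1..96.
#' @param positive_rate probability in \[0, 1\] that a well is positive.
#' @param positive_spec [synthetic_well_spec()] template for positive wells;
#'   defaults to random patches covering 1-10\% of the organoid area at
#'   intensity 120.
#' @param negative_spec template for negative wells (no patches).
#' @param edge_gradient optional length-12 numeric vector of per-column
#'   multipliers on `positive_rate` (capped at probability 1).
#' @param seed plate-level seed.
#' @param render if `FALSE`, skip image rendering and return labels only —
#'   useful for plate-level simulations where only the classification layout
#'   matters.
#' @return object of class `synthetic_plate`: `plate` (a `plate_set`, wells
#'   empty when `render = FALSE`), `truth` (data frame: well_id, label,
#'   positive_area_px, organoid_area_px, seed), `labels` (named vector).
#' @export
generate_plate <- function(plate_id = "SIM1", n_wells = 96,
                           positive_rate = 0.25,
                           positive_spec = NULL, negative_spec = NULL,
                           edge_gradient = NULL, seed = 1L, render = TRUE) {
  if (n_wells < 1 || n_wells > 96)
    stop_validation("n_wells must be in 1..96, got %s", n_wells)
  if (!is.numeric(positive_rate) || positive_rate < 0 || positive_rate > 1)
    stop_validation("positive_rate must lie in [0, 1], got %s", positive_rate)
  if (!is.null(edge_gradient) && length(edge_gradient) != 12L)
    stop_validation("edge_gradient must have one multiplier per column (12)")
  if (is.null(positive_spec))
    positive_spec <- synthetic_well_spec(
      random_patches = list(fraction = c(0.01, 0.10), n = 1:3,
                            intensity = 120))
  if (is.null(negative_spec)) negative_spec <- synthetic_well_spec()

  ids <- all_wells()[seq_len(n_wells)]
  cols <- well_to_rowcol(ids)[, "col"]
  p_col <- if (is.null(edge_gradient)) rep(positive_rate, length(ids))
           else pmin(1, positive_rate * edge_gradient[cols])
  labels <- with_seed(seed, ifelse(stats::runif(length(ids)) < p_col,
                                   "positive", "negative"))
  names(labels) <- ids

  truth <- data.frame(well_id = ids, label = labels,
                      positive_area_px = 0L,
                      organoid_area_px = NA_integer_,
                      seed = vapply(seq_along(ids), derive_well_seed,
                                    integer(1), plate_seed = seed),
                      stringsAsFactors = FALSE, row.names = NULL)
  wells <- list()
  if (render) {
    for (i in seq_along(ids)) {
      spec <- if (labels[i] == "positive") positive_spec else negative_spec
      spec$seed <- truth$seed[i]
      rw <- render_well(spec, plate_id = plate_id, well_id = ids[i])
      wells[[ids[i]]] <- rw$image
      truth$positive_area_px[i] <- rw$truth$positive_area_px
      truth$organoid_area_px[i] <- rw$truth$organoid_area_px
    }
  }
  plate <- structure(list(plate_id = plate_id, wells = wells,
                          missing_wells = setdiff(all_wells(), ids)),
                     class = "plate_set")
  structure(list(plate = plate, truth = truth, labels = labels),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate %s: %d wells (%d positive), %s>\n",
              x$plate$plate_id, nrow(x$truth),
              sum(x$labels == "positive"),
              if (length(x$plate$wells) > 0L) "rendered" else "labels only"))
  invisible(x)
}

#' Draw a labeled score set from parametric distributions
#'
#' Stands in for a manually classified calibration set: negative and
#' positive organoid scores drawn from named families.  Supported families:
#' `lognormal` (`meanlog`, `sdlog`) and `gamma` (`shape`, `rate`).  Default
#' parameters put the negative median near 55 and the positive median near
#' 2000 score units, with heavy right tails, the shape typical of
#' reporter-area scores.
#'
#' @param n_pos,n_neg sample sizes (total >= 1).
#' @param pos_dist,neg_dist `list(family, ...)` distribution specs.
#' @param seed integer seed.
#' @param source provenance string for the resulting set.
#' @return a [labeled_scores()] with positives first.
#' @export
sample_scores <- function(n_pos, n_neg,
                          pos_dist = list(family = "lognormal",
                                          meanlog = 7.6, sdlog = 0.7),
                          neg_dist = list(family = "lognormal",
                                          meanlog = 4, sdlog = 1),
                          seed = 1L, source = "synthetic") {
  if (n_pos + n_neg < 1L) stop_validation("n_pos + n_neg must be >= 1")
  draw <- function(n, d) {
    if (n == 0L) return(numeric(0))
    switch(as.character(d$family),
      lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
      gamma     = stats::rgamma(n, shape = d$shape, rate = d$rate),
      stop_validation("unknown score distribution family '%s'", d$family))
  }
  with_seed(seed, {
    pos <- draw(n_pos, pos_dist)
    neg <- draw(n_neg, neg_dist)
    labeled_scores(c(pos, neg),
                   rep(c("positive", "negative"), c(n_pos, n_neg)),
                   source = source)
  })
}

#' Write a rendered synthetic plate to disk
#'
#' Writes one TIFF per well named `<plate>_<well>.tif` (the default
#' discovery pattern) plus a `<plate>_truth.csv` manifest of the ground
#' truth labels and areas.
#'
#' @param sim a rendered `synthetic_plate` from [generate_plate()].
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_plate <- function(sim, directory) {
  stopifnot(inherits(sim, "synthetic_plate"))
  if (length(sim$plate$wells) == 0L)
    stop_validation("plate was generated with render = FALSE; nothing to write")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop_io("cannot create directory '%s'", directory)
  for (img in sim$plate$wells) {
    path <- file.path(directory,
                      sprintf("%s_%s.tif", img$plate_id, img$well_id))
    maxval <- 2^img$bit_depth - 1
    tiff::writeTIFF(img$pixels / maxval, path,
                    bits.per.sample = img$bit_depth)
  }
  utils::write.csv(sim$truth,
                   file.path(directory,
                             sprintf("%s_truth.csv", sim$plate$plate_id)),
                   row.names = FALSE)
  invisible(directory)
}
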