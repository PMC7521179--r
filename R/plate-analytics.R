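#' Assemble a plate-level result from classified wells
#'
#' Builds the 8x12 grid of labels, the per-well score map, and the summary
#' counts that all batch statistics operate on.  Wells with no entry in
#' `labels` are marked missing and excluded from `n_scored`.
#'
#' @param labels named character vector ("positive"/"negative"), names are
#'   well ids.
#' @param scores optional named numeric vector of scores (same names).
#' @param plate_id plate identifier.
#' @return object of class `plate_result`: `plate_id`, `grid` (8x12
#'   character matrix, dimnames A-H / 1-12, entries positive/negative/
#'   missing), `scores`, `n_positive`, `n_scored`, `positive_fraction`.
#' @export
build_plate_result <- function(labels, scores = NULL, plate_id = "") {
  if (length(labels) > 0L && is.null(names(labels)))
    stop_validation("labels must be named by well id")
  ids <- if (length(labels) > 0L) normalize_well_id(names(labels)) else character(0)
  if (anyDuplicated(ids))
    stop_validation("duplicate well ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad) > 0L)
    stop_validation("labels must be positive/negative, got: %s",
                    paste(bad, collapse = ", "))
  grid <- matrix("missing", 8, 12, dimnames = list(LETTERS[1:8], 1:12))
  if (length(ids) > 0L) {
    rc <- well_to_rowcol(ids)
    grid[rc] <- unname(labels)
  }
  n_pos <- sum(grid == "positive")
  n_scored <- sum(grid != "missing")
  sc <- if (is.null(scores)) numeric(0) else {
    names(scores) <- normalize_well_id(names(scores)); scores
  }
  structure(list(
    plate_id = plate_id, grid = grid, scores = sc,
    n_positive = n_pos, n_scored = n_scored,
    positive_fraction = if (n_scored > 0L) n_pos / n_scored else NA_real_
  ), class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("Plate %s: %d/%d wells positive (fraction %.3f)\n",
              x$plate_id, x$n_positive, x$n_scored,
              x$positive_fraction))
  cat(plate_layout_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text 8x12 layout of a plate
#'
#' `+` positive, `-` negative, `.` missing; one line per plate row A-H.
#'
#' @param plate a `plate_result`.
#' @return character vector of 9 lines (header + 8 rows).
#' @export
plate_layout_text <- function(plate) {
  stopifnot(inherits(plate, "plate_result"))
  sym <- c(positive = "+", negative = "-", missing = ".")
  body <- vapply(1:8, function(r)
    paste0(LETTERS[r], "  ", paste(sym[plate$grid[r, ]], collapse = " ")), "")
  header <- paste0("   ", paste(sprintf("%s", c(1:9, "10", "11", "12")),
                                collapse = " "))
  c(header, body)
}

#' Heatmap of well scores with positive wells circled
#'
#' Mirrors the per-plate quality-control figure: an 8x12 score heatmap with
#' circles around the wells classified positive and dots for missing wells.
#'
#' @param x a `plate_result`.
#' @param ... passed to [graphics::image()].
#' @export
plot.plate_result <- function(x, ...) {
  m <- matrix(NA_real_, 8, 12)
  if (length(x$scores) > 0L) {
    rc <- well_to_rowcol(names(x$scores))
    m[rc] <- as.numeric(x$scores)
  }
  graphics::image(1:12, 1:8, t(m[8:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "column", ylab = "", axes = FALSE,
                  main = paste("Plate", x$plate_id), ...)
  graphics::axis(1, at = 1:12)
  graphics::axis(2, at = 8:1, labels = LETTERS[1:8], las = 1)
  pos <- which(x$grid == "positive", arr.ind = TRUE)
  if (nrow(pos) > 0L)
    graphics::points(pos[, 2], 9 - pos[, 1], cex = 2.4, lwd = 2, col = "green3")
  mis <- which(x$grid == "missing", arr.ind = TRUE)
  if (nrow(mis) > 0L)
    graphics::points(mis[, 2], 9 - mis[, 1], pch = 20, col = "grey60")
  invisible(x)
}

#' Positive counts in the two halves of a plate
#'
#' Splits the plate along one axis and counts positive wells on each side;
#' a systematic imbalance (e.g. wells nearer an incubator door lagging in
#' development) shows up as unequal halves.  Missing wells contribute 0.
#'
#' @param plate a `plate_result`.
#' @param axis "column" (default, columns 1..boundary vs the rest) or "row"
#'   (rows A..boundary vs the rest).
#' @param boundary last column (default 6) or row index (default 4) of the
#'   first half.
#' @return named integer vector `c(half1, half2)`.
#' @export
half_plate_counts <- function(plate, axis = c("column", "row"),
                              boundary = NULL) {
  stopifnot(inherits(plate, "plate_result"))
  axis <- match.arg(axis)
  pos <- plate$grid == "positive"
  if (axis == "column") {
    b <- if (is.null(boundary)) 6L else as.integer(boundary)
    if (b < 1L || b > 11L) stop_validation("column boundary must be in 1..11")
    c(half1 = sum(pos[, 1:b]), half2 = sum(pos[, (b + 1L):12]))
  } else {
    b <- if (is.null(boundary)) 4L else as.integer(boundary)
    if (b < 1L || b > 7L) stop_validation("row boundary must be in 1..7")
    c(half1 = sum(pos[1:b, ]), half2 = sum(pos[(b + 1L):8, ]))
  }
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] with an explicit policy: the exact null
#' distribution is used when both groups have at most 8 observations and the
#' pooled sample has no ties; otherwise the normal approximation with tie and
#' continuity corrections.  `U` is reported for the first group, so swapping
#' the groups maps `U` to `n_a * n_b - U` with the same p-value.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return list with `u_statistic`, `p_value`, `method` ("exact" or
#'   "normal_approx"), `n_a`, `n_b`.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop_validation("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- length(values_a) <= 8L && length(values_b) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # zero-variance pooled sample (all ties)
  list(u_statistic = unname(wt$statistic),
       p_value = min(p, 1),
       method = if (exact) "exact" else "normal_approx",
       n_a = length(values_a), n_b = length(values_b))
}

#' Compare per-plate positive fractions between two groups
#'
#' Each plate contributes one observation (its positive fraction), so the
#' plate — the biological replicate — is the unit of analysis.  Groups are
#' compared with the two-sided Mann-Whitney test; Welch's t-test is reported
#' as an optional secondary check.  With `unit = "organoid"`, per-organoid
#' scores pooled across the plates are compared instead.
#'
#' @param plates_a,plates_b lists of `plate_result` (at least one each).
#' @param group_names length-2 character vector of group labels.
#' @param unit "plate" (positive fractions; default) or "organoid" (scores).
#' @param welch also run Welch's t-test as a labeled secondary output.
#' @return object of class `group_comparison`: group names, the two value
#'   vectors, `u_statistic`, `p_value`, `method`, per-group mean and sample
#'   SD, and optionally `welch_p`.
#' @export
compare_groups <- function(plates_a, plates_b,
                           group_names = c("group_a", "group_b"),
                           unit = c("plate", "organoid"), welch = FALSE) {
  unit <- match.arg(unit)
  if (inherits(plates_a, "plate_result")) plates_a <- list(plates_a)
  if (inherits(plates_b, "plate_result")) plates_b <- list(plates_b)
  if (length(plates_a) == 0L || length(plates_b) == 0L)
    stop_validation("each group needs at least one plate")
  extract <- function(plates) {
    if (unit == "plate")
      vapply(plates, function(p) p$positive_fraction, numeric(1))
    else
      unlist(lapply(plates, function(p) as.numeric(p$scores)))
  }
  a <- extract(plates_a); b <- extract(plates_b)
  if (length(a) == 0L || length(b) == 0L)
    stop_validation("no %s-level values available in one of the groups", unit)
  mw <- mann_whitney(a, b)
  res <- list(group_names = group_names, unit = unit,
              values_a = a, values_b = b,
              u_statistic = mw$u_statistic, p_value = mw$p_value,
              method = mw$method,
              mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b))
  if (welch)
    res$welch_p <- if (length(a) > 1L && length(b) > 1L)
      stats::t.test(a, b)$p.value else NA_real_
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(m, s) sprintf("%.3f +/- %.3f", m, s)
  cat(sprintf(
    "%s (n=%d) %s vs %s (n=%d) %s; Mann-Whitney U=%g, p=%.4g [%s, unit=%s]\n",
    x$group_names[1], length(x$values_a), fmt(x$mean_a, x$sd_a),
    x$group_names[2], length(x$values_b), fmt(x$mean_b, x$sd_b),
    x$u_statistic, x$p_value, x$method, x$unit))
  if (!is.null(x$welch_p))
    cat(sprintf("  secondary Welch t-test: p=%.4g\n", x$welch_p))
  if (length(x$values_a) == 1L && length(x$values_b) == 1L)
    cat("  note: one observation per group; the test is uninformative\n")
  invisible(x)
}
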