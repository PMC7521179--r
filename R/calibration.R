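#' A labeled set of organoid scores
#'
#' Scores of organoids a human has classified as reporter-positive or
#' -negative; the raw material for threshold calibration.
#'
#' @param scores numeric vector of non-negative scores.
#' @param labels parallel character vector of "positive"/"negative".
#' @param source free-text provenance (reporter line, day, batch); stored on
#'   the fitted model and checked when a model is applied elsewhere.
#' @return an object of class `labeled_scores`.
#' @export
labeled_scores <- function(scores, labels, source = "") {
  if (length(scores) != length(labels) || length(scores) < 1L)
    stop_validation("scores and labels must have equal length >= 1")
  labels <- match.arg(as.character(labels), c("positive", "negative"),
                      several.ok = TRUE)
  if (any(!is.finite(scores)) || any(scores < 0))
    stop_validation("scores must be finite and non-negative")
  structure(list(scores = as.numeric(scores), labels = labels,
                 source = as.character(source)),
            class = "labeled_scores")
}

#' @export
print.labeled_scores <- function(x, ...) {
  cat(sprintf("<labeled_scores: %d positive, %d negative%s>\n",
              sum(x$labels == "positive"), sum(x$labels == "negative"),
              if (nzchar(x$source)) paste0("  [", x$source, "]") else ""))
  invisible(x)
}

#' @rdname labeled_scores
#' @param path CSV with columns `score`, `label` (and optional `source`).
#' @export
read_labeled_scores <- function(path, source = "") {
  if (!file.exists(path)) stop_io("no such labeled-score file '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("score", "label") %in% names(df)))
    stop_validation("'%s' must have columns score,label", path)
  labeled_scores(df$score, df$label, source = source)
}

#' Empirical cumulative distribution function as explicit step points
#'
#' `F(x)` = fraction of observations `<= x`, the right-continuous empirical
#' CDF.  Returns both the sorted `(x, F(x))` support points and a callable
#' step function (a thin wrapper over [stats::ecdf()]).
#'
#' @param values non-empty numeric vector.
#' @return list with `points` (data frame `x`, `F`) and `fun` (function).
#' @export
score_ecdf <- function(values) {
  if (length(values) == 0L) stop_validation("ecdf of an empty sample")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  list(points = data.frame(x = x, F = f(x)), fun = f)
}

#' Calibrate a score threshold from labeled negative organoids
#'
#' The threshold is the `ceiling(quantile_level * n)`-th order statistic of
#' the negative scores (the inverse empirical CDF quantile).  With strict
#' classification (positive means score \emph{strictly above} threshold), at
#' most a `1 - quantile_level` fraction of the calibration negatives can
#' exceed the threshold, for every sample size — the estimator makes the
#' contamination bound exact rather than approximate.  Positives in the set
#' play no role in fitting; they are kept for sensitivity reporting.
#'
#' @param labeled a [labeled_scores()] set with at least one negative.
#' @param quantile_level quantile of the negative score distribution used as
#'   the cutoff; default 0.95, i.e. at most 5\% of calibration negatives lie
#'   above the threshold.
#' @return an object of class `threshold_model` with components `threshold`,
#'   `quantile_level`, `n_negatives`, `n_positives`, `ecdf_points` (negative
#'   scores), `sensitivity` (fraction of labeled positives above threshold,
#'   `NA` if none), `source`.
#' @seealso [predict.threshold_model()], [classify()],
#'   [sensitivity_on_labeled()]
#' @examples
#' set.seed(1)
#' cal <- labeled_scores(c(rlnorm(100, 4, 1), rlnorm(40, 7, 0.5)),
#'                       rep(c("negative", "positive"), c(100, 40)))
#' m <- fit_threshold(cal)
#' m
#' predict(m, c(10, 5000))
#' @export
fit_threshold <- function(labeled, quantile_level = 0.95) {
  stopifnot(inherits(labeled, "labeled_scores"))
  if (quantile_level <= 0 || quantile_level >= 1)
    stop_validation("quantile_level must lie in (0, 1), got %s", quantile_level)
  neg <- labeled$scores[labeled$labels == "negative"]
  pos <- labeled$scores[labeled$labels == "positive"]
  if (length(neg) == 0L)
    stop_validation("threshold fitting needs at least one labeled negative")
  n <- length(neg)
  thr <- sort(neg)[ceiling(quantile_level * n)]
  model <- structure(list(
    threshold      = thr,
    quantile_level = quantile_level,
    n_negatives    = n,
    n_positives    = length(pos),
    ecdf_points    = score_ecdf(neg)$points,
    source         = labeled$source
  ), class = "threshold_model")
  model$sensitivity <- if (length(pos) > 0L) mean(pos > thr) else NA_real_
  model
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Score threshold: %g (%.0f%% quantile of %d negative organoids)\n",
              x$threshold, 100 * x$quantile_level, x$n_negatives))
  if (nzchar(x$source)) cat("Calibration source:", x$source, "\n")
  invisible(x)
}

#' @export
summary.threshold_model <- function(object, ...) {
  cat(sprintf("Threshold model (%s)\n",
              if (nzchar(object$source)) object$source else "unlabelled source"))
  cat(sprintf("  threshold        : %g\n", object$threshold))
  cat(sprintf("  quantile level   : %g\n", object$quantile_level))
  cat(sprintf("  negatives used   : %d\n", object$n_negatives))
  cat(sprintf("  positives on file: %d\n", object$n_positives))
  if (!is.na(object$sensitivity))
    cat(sprintf("  sensitivity on labeled positives: %.3f\n",
                object$sensitivity))
  invisible(object)
}

#' @export
coef.threshold_model <- function(object, ...) {
  c(threshold = object$threshold, quantile_level = object$quantile_level)
}

#' Classify scores against a calibrated threshold
#'
#' An organoid is positive iff its score \emph{strictly exceeds} the
#' threshold; ties at the threshold are negative.  This strictness is what
#' makes the calibration-set contamination bound exact.
#'
#' @param object a `threshold_model` from [fit_threshold()].
#' @param newdata numeric scores, a data frame with a `score` column, or a
#'   list of [compute_score()] results.
#' @param ... unused.
#' @return character vector of "positive"/"negative", in input order.
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata$score
       else if (is.list(newdata) && !is.null(newdata[[1]]$score))
         vapply(newdata, `[[`, numeric(1), "score")
       else as.numeric(newdata)
  if (length(s) == 0L) return(character(0))
  ifelse(s > object$threshold, "positive", "negative")
}

#' @rdname predict.threshold_model
#' @param scores scores to classify (same forms as `newdata`).
#' @param model a `threshold_model`.
#' @export
classify <- function(scores, model) predict(model, scores)

#' Sensitivity of a threshold on labeled positives
#'
#' The fraction of labeled positive organoids whose score strictly exceeds
#' the model threshold.  The calibration controls contamination by
#' negatives; this reports the complementary price paid in missed positives.
#'
#' @param labeled a [labeled_scores()] with at least one positive.
#' @param model a `threshold_model`.
#' @return fraction in \[0, 1\].
#' @export
sensitivity_on_labeled <- function(labeled, model) {
  stopifnot(inherits(labeled, "labeled_scores"),
            inherits(model, "threshold_model"))
  pos <- labeled$scores[labeled$labels == "positive"]
  if (length(pos) == 0L)
    stop_validation("sensitivity needs at least one labeled positive")
  mean(pos > model$threshold)
}

#' Plot the calibration ECDF and threshold
#'
#' Draws the empirical CDF of the negative calibration scores, the quantile
#' level, and the fitted threshold.  If a `labeled_scores` set is supplied
#' the positive ECDF is overlaid.
#'
#' @param x a `threshold_model`.
#' @param labeled optional [labeled_scores()] to overlay positives.
#' @param ... passed to [graphics::plot()].
#' @export
plot.threshold_model <- function(x, labeled = NULL, ...) {
  pts <- x$ecdf_points
  graphics::plot(pts$x, pts$F, type = "s", xlab = "score",
                 ylab = "cumulative fraction",
                 main = "Negative-score ECDF and threshold", ...)
  graphics::abline(h = x$quantile_level, lty = 3)
  graphics::abline(v = x$threshold, col = 2, lty = 2)
  if (!is.null(labeled)) {
    pos <- labeled$scores[labeled$labels == "positive"]
    if (length(pos) > 0L) {
      e <- score_ecdf(pos)$points
      graphics::lines(e$x, e$F, type = "s", col = 4)
      graphics::legend("bottomright", c("negative", "positive", "threshold"),
                       col = c(1, 4, 2), lty = c(1, 1, 2), bty = "n")
    }
  }
  invisible(x)
}

#' Serialize / restore a threshold model as JSON
#'
#' @param model a `threshold_model`.
#' @param path JSON file path.
#' @return `write_threshold_model()` the path invisibly;
#'   `read_threshold_model()` the model.
#' @export
write_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  obj <- unclass(model)
  obj$ecdf_points <- as.list(model$ecdf_points)
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_io("cannot write model to '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname write_threshold_model
#' @export
read_threshold_model <- function(path) {
  if (!file.exists(path)) stop_io("no such model file '%s'", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("threshold", "quantile_level", "n_negatives")
  if (!all(need %in% names(obj)))
    stop_validation("'%s' is not a threshold model (missing %s)", path,
                    paste(setdiff(need, names(obj)), collapse = ", "))
  obj$ecdf_points <- as.data.frame(obj$ecdf_points)
  if (is.null(obj$source)) obj$source <- ""
  if (is.null(obj$sensitivity)) obj$sensitivity <- NA_real_
  structure(obj, class = "threshold_model")
}
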