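#' Hold-out absolute prediction error
#'
#' `|actual - predicted|`: non-negative, symmetric, zero only when the two
#' agree.
#'
#' @param actual,predicted finite numeric vectors (recycled to equal length).
#' @return numeric vector of absolute errors.
#' @export
prediction_error <- function(actual, predicted) {
  assert_that(is.numeric(actual) && all(is.finite(actual)),
              "actual must be finite numeric")
  assert_that(is.numeric(predicted) && all(is.finite(predicted)),
              "predicted must be finite numeric")
  abs(actual - predicted)
}

#' Assemble a hold-out validation report
#'
#' Joins actual hold-out ROAVs with per-model predictions, computes the
#' absolute error per compound and model, the mean absolute error per model,
#' and ranks the models by ascending mean error.
#'
#' @param actual named numeric vector: ROAV measured at the hold-out point,
#'   one entry per compound.
#' @param predictions named list (one element per model kind) of named
#'   numeric vectors of predicted ROAVs over the same compounds.
#' @param holdout_x the hold-out abscissa value (annotation only).
#' @return an object of class `"validation_report"`: `rows` (a `data.frame`
#'   in the order of `actual`), `holdout_x`, `mean_error` (named, per model),
#'   `ranking` (model kinds, ascending mean error).
#' @export
build_report <- function(actual, predictions, holdout_x = NA_real_) {
  assert_that(is.numeric(actual) && !is.null(names(actual)),
              "actual must be a named numeric vector")
  assert_that(is.list(predictions) && length(predictions) >= 1 &&
                !is.null(names(predictions)),
              "predictions must be a named list of named numeric vectors")
  cset <- names(actual)
  for (kind in names(predictions)) {
    p <- predictions[[kind]]
    assert_that(is.numeric(p) && !is.null(names(p)),
                "predictions$%s must be a named numeric vector", kind)
    extra <- setdiff(names(p), cset)
    miss <- setdiff(cset, names(p))
    assert_that(length(extra) == 0 && length(miss) == 0,
                "compound sets differ for %s (missing: %s; extra: %s)", kind,
                paste(miss, collapse = ", "), paste(extra, collapse = ", "))
  }
  rows <- data.frame(compound = cset, actual = unname(actual),
                     stringsAsFactors = FALSE)
  for (kind in names(predictions)) {
    pred <- predictions[[kind]][cset]
    rows[[paste0("pred_", tolower(kind))]] <- unname(pred)
    rows[[paste0("err_", tolower(kind))]] <-
      prediction_error(unname(actual), unname(pred))
  }
  mean_error <- vapply(names(predictions), function(kind) {
    mean(rows[[paste0("err_", tolower(kind))]])
  }, numeric(1))
  structure(list(rows = rows, holdout_x = holdout_x,
                 mean_error = mean_error,
                 ranking = names(sort(mean_error))),
            class = "validation_report")
}

#' Run the hold-out verification experiment
#'
#' Fits the requested surrogate models to each compound's training trajectory
#' (training points only), predicts at the hold-out abscissa, and assembles a
#' [build_report()]. A hold-out value that coincides with a training point is
#' refused as leakage.
#'
#' @param training named list of [trajectory_series()], one per compound.
#' @param holdout_x hold-out abscissa; must not be a training point.
#' @param actual named numeric vector of measured hold-out ROAVs over the
#'   same compounds.
#' @param models model kinds to fit (default all three).
#' @param degree PCF degree.
#' @param config CPM configuration.
#' @return a `validation_report`.
#' @export
run_verification <- function(training, holdout_x, actual,
                             models = c("CSI", "PCF", "CPM"), degree = 3L,
                             config = cpm_config()) {
  assert_that(is.list(training) && !is.null(names(training)),
              "training must be a named list of trajectory_series")
  assert_that(is_number(holdout_x), "holdout_x must be a finite number")
  models <- match.arg(models, several.ok = TRUE)
  for (nm in names(training)) {
    ts <- training[[nm]]
    assert_that(inherits(ts, "trajectory_series"),
                "training$`%s` is not a trajectory_series", nm)
    assert_that(!any(abs(ts$x - holdout_x) < 1e-12),
                "hold-out x = %g is a training point of %s (leakage)",
                holdout_x, nm)
  }
  predictions <- lapply(models, function(kind) {
    vapply(training, function(ts) {
      model <- switch(kind,
                      CSI = fit_csi(ts),
                      PCF = fit_pcf(ts, degree = degree),
                      CPM = fit_cpm(ts, config = config))
      predict(model, holdout_x)
    }, numeric(1))
  })
  names(predictions) <- models
  build_report(actual, predictions, holdout_x)
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<validation_report> hold-out at x = %s\n",
              format(x$holdout_x)))
  rows <- x$rows
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round, digits = digits)
  print(rows, row.names = FALSE)
  cat("mean absolute error:",
      paste(sprintf("%s %.3f", names(x$mean_error), x$mean_error),
            collapse = ", "), "\n")
  cat("ranking (best first):", paste(x$ranking, collapse = " < "), "\n")
  invisible(x)
}
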