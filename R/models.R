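#' Squared Spearman rank correlation
#'
#' Monotone-association strength between an index and LNC; ties receive
#' average ranks. Constant input has no defined rank correlation and yields
#' `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return squared Spearman correlation in `[0, 1]` (or `NA`).
#' @export
spearman_rho2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")^2
}

#' Prediction metrics on held-out samples
#'
#' `R^2 = 1 - SS_res / SS_tot` (the predictive coefficient of determination,
#' not a squared correlation), `RMSE` in LNC %, and the squared Spearman
#' correlation between observed and predicted.
#'
#' @param observed,predicted numeric vectors.
#' @return list of class `lnc_metrics` with `r2`, `rmse`, `rho2`, `n`.
#' @export
regression_metrics <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (!length(o)) stop("no complete observation/prediction pairs")
  ss_res <- sum((o - p)^2)
  ss_tot <- sum((o - mean(o))^2)
  structure(list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((o - p)^2)),
                 rho2 = if (length(o) >= 3 && stats::sd(p) > 0)
                   suppressWarnings(spearman_rho2(o, p)) else NA_real_,
                 n = length(o)),
            class = "lnc_metrics")
}

#' @export
print.lnc_metrics <- function(x, ...) {
  cat("R2 = ", format(x$r2, digits = 3), ", RMSE = ",
      format(x$rmse, digits = 3), " %LNC, rho2 = ",
      format(x$rho2, digits = 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Fit a stage-specific LNC ~ vegetation-index model
#'
#' Ordinary least squares of LNC on a single registry index over the
#' calibration samples of a [split_by_replicate()] split; validation metrics
#' are computed on the held-out replicate. Within a growth stage the
#' LNC-chlorophyll relationship is approximately linear, which is why the
#' stage-specific form is linear while no single line fits the whole season.
#'
#' @param split a `data_split`.
#' @param vi_name registry index name (a column of the sample table).
#' @return object of class `lnc_vi_model` with the usual `print`, `coef`,
#'   `predict`, `residuals`, `summary` and `plot` methods.
#' @export
fit_lnc_vi <- function(split, vi_name) {
  stopifnot(inherits(split, "data_split"))
  cal <- split$calibration
  if (!vi_name %in% names(cal)) stop("index column not found: ", vi_name)
  d <- data.frame(lnc = cal$lnc, vi = cal[[vi_name]])
  d <- d[is.finite(d$lnc) & is.finite(d$vi), ]
  if (nrow(d) < 3) stop("need at least 3 calibration samples")
  if (stats::sd(d$vi) == 0) stop("index ", vi_name, " has zero variance")
  fit <- stats::lm(lnc ~ vi, data = d)
  obj <- structure(list(vi_name = vi_name, fit = fit,
                        coefficients = stats::coef(fit),
                        scope = split$scope, stage = split$stage,
                        calibration = regression_metrics(d$lnc, stats::fitted(fit)),
                        calibration_rho2 = suppressWarnings(
                          spearman_rho2(d$vi, d$lnc)),
                        n_cal = nrow(d)),
                   class = "lnc_vi_model")
  obj$validation <- evaluate(obj, split$validation)
  obj
}

#' Evaluate a fitted LNC model on held-out samples
#'
#' @param model a fitted model (`lnc_vi_model`, `lnc_plsr` or `lnc_gpr`).
#' @param validation an `lnc_samples` table.
#' @param ... passed to methods.
#' @return an `lnc_metrics` object.
#' @export
evaluate <- function(model, validation, ...) UseMethod("evaluate")

#' @export
evaluate.lnc_vi_model <- function(model, validation, ...) {
  regression_metrics(validation$lnc, predict(model, validation))
}

#' @export
predict.lnc_vi_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  vi <- if (is.data.frame(newdata)) newdata[[object$vi_name]] else newdata
  as.numeric(stats::predict(object$fit, data.frame(vi = vi)))
}

#' @export
coef.lnc_vi_model <- function(object, ...) object$coefficients

#' @export
residuals.lnc_vi_model <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.lnc_vi_model <- function(object, ...) summary(object$fit, ...)

#' @export
print.lnc_vi_model <- function(x, ...) {
  cat("<lnc_vi_model> LNC ~ ", x$vi_name, " (", x$scope,
      if (!is.null(x$stage)) paste0(": ", x$stage), ", n = ", x$n_cal, ")\n",
      "  LNC = ", format(x$coefficients[1], digits = 4), " + ",
      format(x$coefficients[2], digits = 4), " * ", x$vi_name, "\n",
      "  calibration ", sep = "")
  print(x$calibration)
  if (!is.null(x$validation)) { cat("  validation "); print(x$validation) }
  invisible(x)
}

#' @export
plot.lnc_vi_model <- function(x, split = NULL, ...) {
  d <- x$fit$model
  graphics::plot(d$vi, d$lnc, xlab = x$vi_name, ylab = "LNC (% dry mass)",
                 main = paste("LNC ~", x$vi_name), ...)
  graphics::abline(x$fit, col = "firebrick")
  invisible(x)
}
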