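# extract spectra matrices for the multivariate models; spectra_kind selects
# raw reflectance over 400-900 nm or continuum-removed reflectance 550-750 nm
split_spectra <- function(split, spectra_kind = c("reflectance", "continuum_removed"),
                          lo = NULL, hi = NULL) {
  spectra_kind <- match.arg(spectra_kind)
  wl <- attr(split$calibration, "wavelength")
  prep <- function(samples) {
    X <- attr(samples, "spectra")
    y <- samples$lnc
    ok <- apply(is.finite(X), 1L, all) & is.finite(y)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    if (spectra_kind == "reflectance") {
      lo <- lo %||% 400; hi <- hi %||% 900
      keep <- wl >= lo & wl <= hi
      list(X = X[, keep, drop = FALSE], y = y, wl = wl[keep])
    } else {
      lo <- lo %||% 550; hi <- hi %||% 750
      cr <- t(apply(X, 1L, function(v)
        continuum_removal(v, wl, lo, hi)$values))
      keep <- wl >= lo & wl <= hi
      list(X = cr, y = y, wl = wl[keep])
    }
  }
  cal <- prep(split$calibration)
  val <- prep(split$validation)
  list(X_cal = cal$X, y_cal = cal$y, X_val = val$X, y_val = val$y,
       wavelength = cal$wl, spectra_kind = spectra_kind)
}

# SIMPLS for a univariate response on centered data; returns per-band
# coefficient paths for 1..A components
simpls_paths <- function(Xc, yc, A) {
  p <- ncol(Xc)
  s <- drop(crossprod(Xc, yc))
  Rw <- matrix(0, p, A); Q <- numeric(A); V <- matrix(0, p, A)
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    r <- s
    t_ <- drop(Xc %*% r)
    tn <- sqrt(sum(t_^2))
    if (tn < 1e-12) { A <- a - 1L; break }
    t_ <- t_ / tn; r <- r / tn
    pa <- drop(crossprod(Xc, t_))
    qa <- sum(yc * t_)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    Rw[, a] <- r; Q[a] <- qa; V[, a] <- v
    B[, a] <- Rw[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  }
  list(B = B[, seq_len(max(A, 1L)), drop = FALSE], ncomp = A)
}

#' Partial least squares regression of LNC on spectra
#'
#' Mean-centred univariate PLSR (SIMPLS). The number of latent variables is
#' chosen by leave-one-out cross-validation on the calibration set, taking
#' the count that minimizes the cross-validated RMSE; the per-band regression
#' coefficients of the chosen model are exposed for band-importance profiles.
#'
#' @param split a [split_by_replicate()] split carrying spectra.
#' @param spectra_kind `"reflectance"` (400-900 nm) or `"continuum_removed"`
#'   (550-750 nm).
#' @param max_components upper bound on latent variables considered.
#' @param ncomp fixed latent count, skipping cross-validation.
#' @return object of class `lnc_plsr` with `print`, `coef`, `predict`,
#'   `residuals` and `plot` (coefficient profile) methods.
#' @export
fit_plsr <- function(split, spectra_kind = c("reflectance", "continuum_removed"),
                     max_components = 15L, ncomp = NULL) {
  stopifnot(inherits(split, "data_split"))
  sp <- split_spectra(split, spectra_kind)
  n <- length(sp$y_cal)
  if (n < 5) stop("PLSR needs at least 5 calibration samples")
  A <- min(max_components, n - 2L, ncol(sp$X_cal))
  x_mean <- colMeans(sp$X_cal)
  y_mean <- mean(sp$y_cal)
  Xc <- sweep(sp$X_cal, 2L, x_mean)
  yc <- sp$y_cal - y_mean
  cv_rmse <- NULL
  if (is.null(ncomp)) {
    press <- matrix(NA_real_, n, A)
    for (i in seq_len(n)) {
      Xi <- sp$X_cal[-i, , drop = FALSE]; yi <- sp$y_cal[-i]
      xm <- colMeans(Xi); ym <- mean(yi)
      fit_i <- simpls_paths(sweep(Xi, 2L, xm), yi - ym, A)
      xa <- sp$X_cal[i, ] - xm
      pred <- ym + drop(xa %*% fit_i$B)
      press[i, seq_len(fit_i$ncomp)] <- (sp$y_cal[i] - pred[seq_len(fit_i$ncomp)])^2
    }
    cv_rmse <- sqrt(colMeans(press, na.rm = TRUE))
    ncomp <- which.min(cv_rmse)
  }
  ncomp <- max(1L, min(as.integer(ncomp), A))
  fit <- simpls_paths(Xc, yc, ncomp)
  beta <- fit$B[, min(ncomp, fit$ncomp)]
  obj <- structure(list(ncomp = min(ncomp, fit$ncomp),
                        coefficients = stats::setNames(beta, sp$wavelength),
                        x_mean = x_mean, y_mean = y_mean,
                        wavelength = sp$wavelength,
                        spectra_kind = sp$spectra_kind,
                        cv_rmse = cv_rmse, n_cal = n),
                   class = "lnc_plsr")
  cal_pred <- predict(obj, sp$X_cal)
  obj$residuals <- sp$y_cal - cal_pred
  obj$calibration <- regression_metrics(sp$y_cal, cal_pred)
  obj$validation <- regression_metrics(sp$y_val, predict(obj, sp$X_val))
  obj
}

plsr_matrix <- function(object, newdata) {
  if (is.matrix(newdata)) return(newdata)
  if (inherits(newdata, "lnc_samples")) {
    wl <- attr(newdata, "wavelength")
    X <- attr(newdata, "spectra")
    if (object$spectra_kind == "continuum_removed") {
      lo <- min(object$wavelength); hi <- max(object$wavelength)
      return(t(apply(X, 1L, function(v) continuum_removal(v, wl, lo, hi)$values)))
    }
    keep <- wl >= min(object$wavelength) & wl <= max(object$wavelength)
    return(X[, keep, drop = FALSE])
  }
  stop("newdata must be a spectra matrix or an lnc_samples table")
}

#' @export
predict.lnc_plsr <- function(object, newdata, ...) {
  X <- plsr_matrix(object, newdata)
  object$y_mean + drop(sweep(X, 2L, object$x_mean) %*% object$coefficients)
}

#' @export
coef.lnc_plsr <- function(object, ...) object$coefficients

#' @export
residuals.lnc_plsr <- function(object, ...) object$residuals

#' @export
print.lnc_plsr <- function(x, ...) {
  cat("<lnc_plsr> ", x$ncomp, " latent variable(s), ", length(x$coefficients),
      " bands (", x$spectra_kind, "), n = ", x$n_cal, "\n  calibration ",
      sep = "")
  print(x$calibration)
  cat("  validation ")
  print(x$validation)
  invisible(x)
}

#' @export
plot.lnc_plsr <- function(x, ...) {
  graphics::plot(x$wavelength, x$coefficients, type = "l",
                 xlab = "wavelength (nm)", ylab = "PLSR coefficient",
                 main = paste0("PLSR band importance (", x$ncomp, " LV)"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
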