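# squared-distance contribution per band pair under unit lengthscales:
# K_f = sf2 * exp(-0.5 * sum_b ((x_ib - x_jb) / l_b)^2)
ard_kernel <- function(X1, X2, ell, sf2) {
  A <- sweep(X1, 2L, ell, `/`)
  B <- sweep(X2, 2L, ell, `/`)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sf2 * exp(-0.5 * pmax(d2, 0))
}

# negative log marginal likelihood and analytic gradient in
# theta = c(log ell (p), log sf, log sn)
gpr_nll <- function(theta, X, y) {
  n <- nrow(X); p <- ncol(X)
  ell <- exp(theta[seq_len(p)])
  sf2 <- exp(2 * theta[p + 1L])
  sn2 <- exp(2 * theta[p + 2L]) + 1e-8
  Kf <- ard_kernel(X, X, ell, sf2)
  K <- Kf + diag(sn2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, p + 2L)))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- tcrossprod(alpha) - Kinv          # dNLL/dtheta = -0.5 tr(W dK/dtheta)
  M <- W * Kf
  Xs <- sweep(X, 2L, ell, `/`)
  q <- colSums(Xs * (M %*% Xs))          # diag(Xs' M Xs)
  rx2 <- drop(rowSums(M) %*% Xs^2)
  g_ell <- -(rx2 - q)                    # already includes the 1/l^2 scaling
  g_sf <- -sum(M)                        # -0.5 * tr(W * 2 Kf)
  g_sn <- -sn2 * sum(diag(W))
  list(value = nll, gradient = c(g_ell, g_sf, g_sn))
}

#' Gaussian process regression of LNC on spectra (ARD kernel)
#'
#' Zero-mean GP on per-band standardized spectra with an anisotropic
#' squared-exponential kernel: one lengthscale per band plus signal and noise
#' variances, all fitted by maximizing the log marginal likelihood
#' (L-BFGS-B on log parameters, analytic gradients, fixed-seed multi-start).
#' A band's fitted lengthscale is its relevance measure: the smaller the
#' lengthscale, the more the prediction responds to that band.
#'
#' @param split a [split_by_replicate()] split carrying spectra.
#' @param spectra_kind `"reflectance"` or `"continuum_removed"`.
#' @param n_starts number of optimizer starts.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param noise_var fixed noise variance (on the centred LNC scale), or
#'   `NULL` to fit it.
#' @param seed seed for the multi-start jitter.
#' @return object of class `lnc_gpr`; `$sigma` holds the per-band
#'   lengthscales (ascending rank = descending relevance) and
#'   `band_relevance()` tabulates them.
#' @export
fit_gpr <- function(split, spectra_kind = c("reflectance", "continuum_removed"),
                    n_starts = 3L, maxit = 100L, noise_var = NULL, seed = 1L) {
  stopifnot(inherits(split, "data_split"))
  sp <- split_spectra(split, spectra_kind)
  n <- length(sp$y_cal)
  if (n < 5) stop("GPR needs at least 5 calibration samples")
  p <- ncol(sp$X_cal)
  x_mean <- colMeans(sp$X_cal)
  x_sd <- apply(sp$X_cal, 2L, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  Xs <- sweep(sweep(sp$X_cal, 2L, x_mean), 2L, x_sd, `/`)
  y_mean <- mean(sp$y_cal)
  yc <- sp$y_cal - y_mean
  sd_y <- max(stats::sd(yc), 1e-6)
  fixed_noise <- !is.null(noise_var)
  base_theta <- c(rep(log(sqrt(p)), p), log(sd_y),
                  if (fixed_noise) 0.5 * log(noise_var) else log(0.1 * sd_y))
  obj <- function(theta) {
    if (fixed_noise) theta[p + 2L] <- base_theta[p + 2L]
    gpr_nll(theta, Xs, yc)
  }
  fn <- function(theta) obj(theta)$value
  gr <- function(theta) {
    g <- obj(theta)$gradient
    if (fixed_noise) g[p + 2L] <- 0
    g
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    th <- base_theta
    if (s > 1) {
      th[seq_len(p)] <- th[seq_len(p)] + log(c(0.3, 3, 0.1, 10)[(s - 2L) %% 4L + 1L]) +
        stats::rnorm(p, 0, 0.1)
    }
    th
  }))
  best <- NULL
  converged <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, fn, gr, method = "L-BFGS-B",
                   lower = c(rep(log(1e-3), p), log(1e-4 * sd_y), log(1e-4 * sd_y)),
                   upper = c(rep(log(1e4), p), log(100 * sd_y), log(10 * sd_y)),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop("GPR optimization failed from every start")
  if (!converged)
    warning("GPR marginal-likelihood optimization did not fully converge; ",
            "best-found hyperparameters used")
  theta <- best$par
  if (fixed_noise) theta[p + 2L] <- base_theta[p + 2L]
  ell <- exp(theta[seq_len(p)])
  sf2 <- exp(2 * theta[p + 1L])
  sn2 <- exp(2 * theta[p + 2L]) + 1e-8
  K <- ard_kernel(Xs, Xs, ell, sf2) + diag(sn2, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  out <- structure(list(sigma = stats::setNames(ell, sp$wavelength),
                        signal_var = sf2, noise_var = sn2,
                        x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                        X_train = Xs, alpha = alpha,
                        wavelength = sp$wavelength,
                        spectra_kind = sp$spectra_kind,
                        nll = best$value, converged = converged, n_cal = n),
                   class = "lnc_gpr")
  out$calibration <- regression_metrics(sp$y_cal, predict(out, sp$X_cal))
  out$residuals <- sp$y_cal - predict(out, sp$X_cal)
  out$validation <- regression_metrics(sp$y_val, predict(out, sp$X_val))
  out
}

#' @export
predict.lnc_gpr <- function(object, newdata, ...) {
  X <- plsr_matrix(object, newdata)
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_sd, `/`)
  Ks <- ard_kernel(Xs, object$X_train, object$sigma, object$signal_var)
  object$y_mean + drop(Ks %*% object$alpha)
}

#' Per-band relevance ranking of a fitted GPR model
#'
#' @param object an `lnc_gpr` model.
#' @return data.frame with `wavelength`, `sigma` (lengthscale) and `rank`
#'   (1 = most relevant, i.e. smallest lengthscale).
#' @export
band_relevance <- function(object) {
  stopifnot(inherits(object, "lnc_gpr"))
  data.frame(wavelength = object$wavelength, sigma = as.numeric(object$sigma),
             rank = rank(object$sigma, ties.method = "first"))
}

#' @export
coef.lnc_gpr <- function(object, ...) object$sigma

#' @export
residuals.lnc_gpr <- function(object, ...) object$residuals

#' @export
print.lnc_gpr <- function(x, ...) {
  cat("<lnc_gpr> ARD squared-exponential, ", length(x$sigma), " bands (",
      x$spectra_kind, "), n = ", x$n_cal, "\n  signal var ",
      format(x$signal_var, digits = 3), ", noise var ",
      format(x$noise_var, digits = 3), if (!x$converged) "  [not converged]",
      "\n  calibration ", sep = "")
  print(x$calibration)
  cat("  validation ")
  print(x$validation)
  invisible(x)
}

#' @export
plot.lnc_gpr <- function(x, ...) {
  graphics::plot(x$wavelength, x$sigma, type = "l", log = "y",
                 xlab = "wavelength (nm)", ylab = "ARD lengthscale sigma",
                 main = "GPR band relevance (low sigma = relevant)", ...)
  invisible(x)
}
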