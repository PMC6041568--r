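#' Minimum noise fraction denoising
#'
#' Estimates the noise covariance from single-pixel horizontal shift
#' differences within image rows (consistent with pushbroom acquisition,
#' where along-track neighbours share illumination), whitens the data
#' covariance against it, takes the leading noise-whitened principal
#' components, and inverse-transforms. Component `k` has a whitened-variance
#' eigenvalue of `1 + SNR_k`; by default all components with eigenvalue above
#' `snr_cutoff` are retained.
#'
#' With `k_components` equal to the number of bands the transform is the
#' identity (up to floating point); on a noiseless low-rank cube retaining the
#' true rank reconstructs the input essentially exactly.
#'
#' @param cube a [spectral_cube()] with at least 2 x 2 pixels.
#' @param k_components number of components to keep; `NULL` selects all
#'   components with whitened eigenvalue `> snr_cutoff`.
#' @param snr_cutoff eigenvalue threshold used when `k_components` is `NULL`.
#' @return a denoised [spectral_cube()] of identical shape, with attributes
#'   `k` (components kept) and `eigenvalues`.
#' @export
mnf_denoise <- function(cube, k_components = NULL, snr_cutoff = 2) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  nb <- d[3]
  if (d[1] < 2 || d[2] < 2) stop("MNF needs at least 2 x 2 pixels")
  if (!is.null(k_components) && (k_components < 1 || k_components > nb))
    stop("k_components must lie in 1..", nb)
  X <- cube_pixels(cube)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  # horizontal shift differences within rows: pixel (i, j+1) minus (i, j)
  diffs <- matrix(cube$data[, -1, , drop = FALSE] -
                    cube$data[, -d[2], , drop = FALSE],
                  ncol = nb) / sqrt(2)
  # class boundaries produce large signal differences that would masquerade
  # as noise; keep the smaller-magnitude half (within-patch, noise-dominated)
  if (nrow(diffs) >= 8) {
    mag <- rowSums(diffs^2)
    diffs <- diffs[mag <= stats::quantile(mag, 0.5), , drop = FALSE]
  }
  Sn <- stats::cov(diffs)
  S <- stats::cov(Xc)
  ev <- eigen(Sn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev, 0) || max(ev) == 0)
    warning("noise covariance is singular; ridge regularization applied")
  ridge <- 1e-10 * mean(diag(Sn))
  if (ridge <= 0) ridge <- 1e-12 * max(mean(diag(S)), 1)
  L <- NULL
  for (i in 0:6) {
    L <- tryCatch(t(chol(Sn + ridge * 10^i * diag(nb))), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) stop("noise covariance could not be factorized")
  Linv <- forwardsolve(L, diag(nb))
  A <- Linv %*% S %*% t(Linv)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- if (is.null(k_components)) max(1L, sum(eg$values > snr_cutoff))
       else as.integer(k_components)
  TT <- t(Linv) %*% eg$vectors            # bands x components, scores = Xc %*% TT
  Tinv <- t(eg$vectors) %*% t(L)          # components x bands
  Xhat <- Xc %*% TT[, seq_len(k), drop = FALSE] %*%
    Tinv[seq_len(k), , drop = FALSE]
  Xhat <- sweep(Xhat, 2L, mu, `+`)
  out <- spectral_cube(array(Xhat, dim = d), cube$wavelength,
                       pixel_size_mm = cube$pixel_size_mm, meta = cube$meta)
  attr(out, "k") <- k
  attr(out, "eigenvalues") <- eg$values
  out
}
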