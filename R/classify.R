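#' Per-pixel EVI, PRI and TCARI maps
#'
#' The three indices driving the canopy decision tree, computed per pixel
#' with nearest-band reflectance: EVI (three-band form,
#' `2.5*(R800-R670)/(R800+6*R670-7.5*R470+1)`), PRI
#' (`(R531-R570)/(R531+R570)`) and TCARI
#' (`3*((R700-R670)-0.2*(R700-R550)*(R700/R670))`).
#'
#' @param cube a [spectral_cube()] whose axis covers the nominal bands.
#' @return list of matrices `evi`, `pri`, `tcari`.
#' @export
pixel_index_maps <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  wl <- cube$wavelength
  d <- dim(cube$data)
  B <- function(nm) matrix(cube$data[, , nearest_band(wl, nm)], d[1], d[2])
  r800 <- B(800); r670 <- B(670); r470 <- B(470)
  r531 <- B(531); r570 <- B(570)
  r700 <- B(700); r550 <- B(550)
  list(
    evi = 2.5 * (r800 - r670) / (r800 + 6 * r670 - 7.5 * r470 + 1),
    pri = (r531 - r570) / (r531 + r570),
    tcari = 3 * ((r700 - r670) - 0.2 * (r700 - r550) * (r700 / r670))
  )
}

#' Classification threshold set
#'
#' Cut-offs for the canopy decision tree. The defaults are the published
#' base-resolution values: vegetation requires EVI > 0.45; leaves separate
#' from panicles at PRI > -0.058; sunlit and shaded leaves split at
#' TCARI 0.172 and sunlit and shaded panicles at TCARI 0.241.
#'
#' @param evi,pri,tcari_leaf,tcari_panicle numeric cut-offs.
#' @param stage growth-stage label the set applies to.
#' @param resolution_mm resolution the set applies to.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(evi = 0.45, pri = -0.058, tcari_leaf = 0.172,
                          tcari_panicle = 0.241, stage = NA_character_,
                          resolution_mm = NA_real_) {
  vals <- c(evi, pri, tcari_leaf, tcari_panicle)
  if (any(!is.finite(vals))) stop("thresholds must be finite")
  structure(list(evi = evi, pri = pri, tcari_leaf = tcari_leaf,
                 tcari_panicle = tcari_panicle, stage = stage,
                 resolution_mm = resolution_mm),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> EVI > ", format(x$evi, digits = 4),
      ", PRI > ", format(x$pri, digits = 4),
      ", TCARI leaf ", format(x$tcari_leaf, digits = 4),
      " / panicle ", format(x$tcari_panicle, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Classify pixels into background, leaf and panicle components
#'
#' The decision tree applies the thresholds in order: `EVI <= t_evi` is
#' background; among vegetation, `PRI > t_pri` is leaf and `PRI <= t_pri`
#' panicle; leaves split sunlit/shaded at `TCARI > t_leaf`, panicles at
#' `TCARI > t_panicle`. "Greater than" branches are strict, so ties fall to
#' the background or shaded side.
#'
#' @param cube a [spectral_cube()].
#' @param thresholds a [threshold_set()].
#' @return a [class_map()].
#' @export
classify_pixels <- function(cube, thresholds = threshold_set()) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(thresholds, "threshold_set"))
  m <- pixel_index_maps(cube)
  lab <- classify_from_indices(m$evi, m$pri, m$tcari, thresholds)
  class_map(matrix(lab, dim(cube$data)[1], dim(cube$data)[2]),
            pixel_size_mm = cube$pixel_size_mm,
            stage = cube$meta$stage %||% NA_character_)
}

classify_from_indices <- function(evi, pri, tcari, th) {
  lab <- integer(length(evi))
  veg <- evi > th$evi
  leaf <- veg & pri > th$pri
  pan <- veg & !leaf
  lab[leaf] <- ifelse(tcari[leaf] > th$tcari_leaf, 1L, 2L)
  lab[pan] <- ifelse(tcari[pan] > th$tcari_panicle, 3L, 4L)
  lab
}

#' Green fraction of a classified image
#'
#' The fraction of pixels labelled as vegetation (any non-background class).
#'
#' @param classmap a [class_map()].
#' @param reference flag marking a base-resolution reference record.
#' @return list of class `gf_record` with `gf`, pixel counts, stage,
#'   resolution and the reference flag.
#' @export
green_fraction <- function(classmap, reference = FALSE) {
  stopifnot(inherits(classmap, "class_map"))
  n <- length(classmap)
  nv <- sum(classmap > 0L)
  structure(list(gf = nv / n, n_veg = nv, n_total = n,
                 stage = attr(classmap, "stage"),
                 resolution_mm = attr(classmap, "pixel_size_mm"),
                 reference = reference),
            class = "gf_record")
}

#' @export
print.gf_record <- function(x, ...) {
  cat("<gf_record> GF = ", format(x$gf, digits = 4), " (", x$n_veg, "/",
      x$n_total, " pixels)", if (isTRUE(x$reference)) " [reference]", "\n",
      sep = "")
  invisible(x)
}

#' Class proportions used as the threshold-adaptation reference
#'
#' @param classmap a [class_map()].
#' @return list with `gf` (vegetation / all pixels), `leaf_share` (leaf /
#'   vegetation), `sunlit_leaf_share` (sunlit / leaf) and
#'   `sunlit_panicle_share` (sunlit / panicle; `NA` when no panicles).
#' @export
class_proportions <- function(classmap) {
  stopifnot(inherits(classmap, "class_map"))
  n <- tabulate(as.integer(classmap) + 1L, nbins = 5L)
  veg <- sum(n[2:5]); leaf <- n[2] + n[3]; pan <- n[4] + n[5]
  list(gf = veg / sum(n),
       leaf_share = if (veg > 0) leaf / veg else NA_real_,
       sunlit_leaf_share = if (leaf > 0) n[2] / leaf else NA_real_,
       sunlit_panicle_share = if (pan > 0) n[4] / pan else NA_real_)
}

# bisection on a step function: find t with mean(values > t) ~ target.
# share is non-increasing in t, so the bracket [lo, hi] always holds
# share(lo) >= target >= share(hi); returns the endpoint with the smaller miss.
solve_share_threshold <- function(values, target, default, tol = 0.005,
                                  max_iter = 60L) {
  share <- function(t) mean(values > t)
  if (abs(share(default) - target) <= tol)
    return(list(threshold = default, achieved = share(default), converged = TRUE))
  lo <- min(values) - 1e-9
  hi <- max(values) + 1e-9
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (share(mid) >= target) lo <- mid else hi <- mid
    if (abs(share(mid) - target) <= tol) {
      return(list(threshold = mid, achieved = share(mid), converged = TRUE))
    }
  }
  cand <- c(lo, hi)
  best <- cand[which.min(abs(vapply(cand, share, 0) - target))]
  list(threshold = best, achieved = share(best), converged = FALSE)
}

#' Adapt classification thresholds to a degraded resolution
#'
#' At coarser resolutions mixed pixels pull index values toward the
#' background, so the base-resolution cut-offs misstate the green fraction.
#' Following the green-fraction-matching strategy, three monotone
#' one-dimensional searches run in tree order: the EVI threshold is solved so
#' the green fraction matches the base-resolution reference, then the PRI
#' threshold so the leaf share among vegetation matches, then the two TCARI
#' cut-offs so the sunlit shares match. Each search bisects until the share
#' mismatch is at most `tol` (or 60 iterations); an unreachable target (the
#' share is a step function with steps of 1/n) returns the nearest achievable
#' threshold with a warning.
#'
#' @param x a [spectral_cube()] at the degraded resolution, or a list with
#'   numeric vectors `evi`, `pri`, `tcari` (e.g. pooled over the plots of a
#'   stage).
#' @param reference class proportions from the base-resolution classification,
#'   as returned by [class_proportions()].
#' @param stage growth-stage label recorded in the result.
#' @param defaults starting [threshold_set()]; returned unchanged when it
#'   already reproduces the reference within `tol`.
#' @param tol share-matching tolerance.
#' @param max_iter bisection iteration cap per threshold.
#' @return a [threshold_set()] with attribute `achieved` (the realized
#'   proportions).
#' @export
adapt_thresholds <- function(x, reference, stage = NA_character_,
                             defaults = threshold_set(), tol = 0.005,
                             max_iter = 60L) {
  if (inherits(x, "spectral_cube")) {
    res <- x$pixel_size_mm
    m <- pixel_index_maps(x)
    m <- list(evi = as.numeric(m$evi), pri = as.numeric(m$pri),
              tcari = as.numeric(m$tcari))
  } else {
    stopifnot(is.list(x), all(c("evi", "pri", "tcari") %in% names(x)))
    m <- lapply(x[c("evi", "pri", "tcari")], as.numeric)
    res <- NA_real_
  }
  warn_if <- function(sol, what) {
    if (!sol$converged)
      warning(what, " share target unreachable; nearest achievable threshold",
              " returned (achieved ", round(sol$achieved, 4), ")")
    sol
  }
  s_evi <- warn_if(solve_share_threshold(m$evi, reference$gf, defaults$evi,
                                         tol, max_iter), "green-fraction")
  veg <- m$evi > s_evi$threshold
  achieved <- list(gf = mean(veg))
  t_pri <- defaults$pri
  t_tl <- defaults$tcari_leaf
  t_tp <- defaults$tcari_panicle
  if (any(veg) && is.finite(reference$leaf_share)) {
    s_pri <- warn_if(solve_share_threshold(m$pri[veg], reference$leaf_share,
                                           defaults$pri, tol, max_iter), "leaf")
    t_pri <- s_pri$threshold
    leaf <- veg & m$pri > t_pri
    pan <- veg & !leaf
    achieved$leaf_share <- sum(leaf) / sum(veg)
    if (any(leaf) && is.finite(reference$sunlit_leaf_share)) {
      s_tl <- warn_if(solve_share_threshold(m$tcari[leaf],
                                            reference$sunlit_leaf_share,
                                            defaults$tcari_leaf, tol, max_iter),
                      "sunlit-leaf")
      t_tl <- s_tl$threshold
      achieved$sunlit_leaf_share <- s_tl$achieved
    }
    if (any(pan) && is.finite(reference$sunlit_panicle_share)) {
      s_tp <- warn_if(solve_share_threshold(m$tcari[pan],
                                            reference$sunlit_panicle_share,
                                            defaults$tcari_panicle, tol, max_iter),
                      "sunlit-panicle")
      t_tp <- s_tp$threshold
      achieved$sunlit_panicle_share <- s_tp$achieved
    }
  }
  out <- threshold_set(evi = s_evi$threshold, pri = t_pri, tcari_leaf = t_tl,
                       tcari_panicle = t_tp, stage = stage,
                       resolution_mm = res)
  attr(out, "achieved") <- achieved
  out
}

#' Mean spectrum of a pixel type
#'
#' Per-band arithmetic mean over the pixels of the requested type:
#' `sunlit_leaf`, `shaded_leaf`, `all_leaf` (their union), or `whole_image`
#' (every pixel, vegetation and background). When no pixel of the type
#' exists, the result is a missing-value spectrum with `n = 0`, never a
#' vector of zeros.
#'
#' @param cube a [spectral_cube()].
#' @param classmap the matching [class_map()] (ignored for `whole_image`).
#' @param pixel_type one of `all_leaf`, `sunlit_leaf`, `shaded_leaf`,
#'   `whole_image`.
#' @return object of class `mean_spectrum`: list with `values`, `wavelength`,
#'   `n` (pixel count) and `pixel_type`.
#' @export
mean_spectrum_by_class <- function(cube, classmap, pixel_type = "all_leaf") {
  stopifnot(inherits(cube, "spectral_cube"))
  types <- c("all_leaf", "sunlit_leaf", "shaded_leaf", "whole_image")
  if (!pixel_type %in% types)
    stop("pixel_type must be one of ", paste(types, collapse = ", "))
  px <- cube_pixels(cube)
  if (pixel_type == "whole_image") {
    sel <- rep(TRUE, nrow(px))
  } else {
    stopifnot(inherits(classmap, "class_map"))
    if (!all(dim(classmap) == dim(cube$data)[1:2]))
      stop("classmap shape does not match cube")
    lab <- as.integer(classmap)
    sel <- switch(pixel_type,
                  all_leaf = lab %in% c(1L, 2L),
                  sunlit_leaf = lab == 1L,
                  shaded_leaf = lab == 2L)
  }
  n <- sum(sel)
  vals <- if (n == 0L) rep(NA_real_, ncol(px)) else colMeans(px[sel, , drop = FALSE])
  structure(list(values = vals, wavelength = cube$wavelength, n = n,
                 pixel_type = pixel_type),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat("<mean_spectrum> ", x$pixel_type, ", n = ", x$n, " pixels, ",
      length(x$wavelength), " bands\n", sep = "")
  invisible(x)
}

#' Whole-image spectrum for the coarsest ladder level
#'
#' At the whole-swath resolution a single pixel remains, so no per-class
#' thresholds exist; the spectra of all three leaf pixel types are assigned
#' the average spectrum of every pixel of the base-resolution cropped image.
#'
#' @param base_cube the base-resolution cropped [spectral_cube()].
#' @return a `mean_spectrum` with `pixel_type = "whole_image"`.
#' @export
coarsest_level_spectrum <- function(base_cube) {
  mean_spectrum_by_class(base_cube, NULL, "whole_image")
}
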