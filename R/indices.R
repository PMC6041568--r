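#' Nearest band lookup
#'
#' Index of the band closest to a nominal wavelength, ties broken toward the
#' lower wavelength. Errors if the nearest band is more than `max_dist_nm`
#' away, so an index is never silently computed from a wildly wrong band.
#'
#' @param wavelengths increasing numeric axis, nm.
#' @param target_nm nominal wavelength, nm.
#' @param max_dist_nm maximum tolerated distance, nm.
#' @return integer band index with attribute `distance_nm`.
#' @export
nearest_band <- function(wavelengths, target_nm, max_dist_nm = 10) {
  if (!length(wavelengths)) stop("empty wavelength axis")
  d <- abs(wavelengths - target_nm)
  i <- which.min(d)                       # which.min takes the first (lower) tie
  if (d[i] > max_dist_nm)
    stop("no band within ", max_dist_nm, " nm of ", target_nm,
         " nm (nearest is ", wavelengths[i], " nm)")
  structure(i, distance_nm = d[i])
}

# index definitions: nominal bands and an evaluator over the band getter R(nm)
vi_definitions <- function() {
  list(
    "SR[800,675]" = list(bands = c(800, 675), scale_invariant = TRUE,
      expr = "R800/R675", fn = function(R) R(800) / R(675)),
    "SR[810,560]" = list(bands = c(810, 560), scale_invariant = TRUE,
      expr = "R810/R560", fn = function(R) R(810) / R(560)),
    "SR[750,550]" = list(bands = c(750, 550), scale_invariant = TRUE,
      expr = "R750/R550", fn = function(R) R(750) / R(550)),
    "SR[750,710]" = list(bands = c(750, 710), scale_invariant = TRUE,
      expr = "R750/R710", fn = function(R) R(750) / R(710)),
    "CI_Red-edge" = list(bands = c(800, 720), scale_invariant = TRUE,
      expr = "R800/R720 - 1", fn = function(R) R(800) / R(720) - 1),
    "NDVI" = list(bands = c(800, 670), scale_invariant = TRUE,
      expr = "(R800-R670)/(R800+R670)",
      fn = function(R) (R(800) - R(670)) / (R(800) + R(670))),
    "GNDVI" = list(bands = c(750, 550), scale_invariant = TRUE,
      expr = "(R750-R550)/(R750+R550)",
      fn = function(R) (R(750) - R(550)) / (R(750) + R(550))),
    "ND705" = list(bands = c(750, 705), scale_invariant = TRUE,
      expr = "(R750-R705)/(R750+R705)",
      fn = function(R) (R(750) - R(705)) / (R(750) + R(705))),
    "mND705" = list(bands = c(750, 705, 445), scale_invariant = TRUE,
      expr = "(R750-R705)/(R750+R705-2*R445)",
      fn = function(R) (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445))),
    "mSR705" = list(bands = c(750, 705, 445), scale_invariant = TRUE,
      expr = "(R750-R445)/(R705-R445)",
      fn = function(R) (R(750) - R(445)) / (R(705) - R(445))),
    "MTCI" = list(bands = c(750, 710, 680), scale_invariant = TRUE,
      expr = "(R750-R710)/(R710-R680)",
      fn = function(R) (R(750) - R(710)) / (R(710) - R(680))),
    "PRI" = list(bands = c(531, 570), scale_invariant = TRUE,
      expr = "(R531-R570)/(R531+R570)",
      fn = function(R) (R(531) - R(570)) / (R(531) + R(570))),
    "TCARI" = list(bands = c(700, 670, 550), scale_invariant = FALSE,
      expr = "3*((R700-R670)-0.2*(R700-R550)*(R700/R670))",
      fn = function(R) 3 * ((R(700) - R(670)) -
                              0.2 * (R(700) - R(550)) * (R(700) / R(670)))),
    "OSAVI" = list(bands = c(800, 670), scale_invariant = FALSE,
      expr = "(1+0.16)*(R800-R670)/(R800+R670+0.16)",
      fn = function(R) 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16)),
    "TCARI/OSAVI" = list(bands = c(700, 670, 550, 800), scale_invariant = FALSE,
      expr = "TCARI/OSAVI",
      fn = function(R) {
        tcari <- 3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670)))
        osavi <- 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16)
        tcari / osavi
      }),
    "DCNI" = list(bands = c(720, 700, 670), scale_invariant = FALSE,
      expr = "(R720-R700)/(R700-R670)/(R720-R670+0.03)",
      fn = function(R) (R(720) - R(700)) / (R(700) - R(670)) /
        (R(720) - R(670) + 0.03))
  )
}

#' The registry of 16 published nitrogen-related vegetation indices
#'
#' Simple ratios (SR forms, CI_Red-edge), normalized differences (NDVI,
#' GNDVI, ND705, mND705, mSR705, MTCI, PRI) and combined indices (TCARI,
#' OSAVI, TCARI/OSAVI, DCNI), each defined over nominal wavelengths resolved
#' to the closest available band. DCNI's doubly nested division is evaluated
#' left to right as printed. The `scale_invariant` column documents whether
#' multiplying the spectrum by a positive constant leaves the index unchanged
#' (true for the pure ratio and normalized forms; false for TCARI, OSAVI,
#' their ratio, and DCNI with its +0.03 offset).
#'
#' @return data.frame with columns `name`, `bands` (comma-separated nm),
#'   `expression`, `scale_invariant`.
#' @export
vi_registry <- function() {
  defs <- vi_definitions()
  data.frame(
    name = names(defs),
    bands = vapply(defs, function(d) paste(d$bands, collapse = ","), ""),
    expression = vapply(defs, function(d) d$expr, ""),
    scale_invariant = vapply(defs, function(d) d$scale_invariant, TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compute a vegetation index from a spectrum
#'
#' Nominal wavelengths are resolved with [nearest_band()]; a zero denominator
#' yields `NA` with a warning naming the index rather than an infinity.
#'
#' @param name registered index name (see [vi_registry()]).
#' @param values reflectance vector, or a `mean_spectrum` object.
#' @param wavelength wavelength axis (nm); taken from `values` when it is a
#'   `mean_spectrum`.
#' @return numeric index value (possibly `NA`).
#' @export
compute_vi <- function(name, values, wavelength = NULL) {
  defs <- vi_definitions()
  if (!name %in% names(defs)) stop("unregistered index name: ", name)
  if (inherits(values, "mean_spectrum")) {
    wavelength <- values$wavelength
    values <- values$values
  }
  if (is.null(wavelength)) stop("wavelength axis required")
  R <- function(nm) values[nearest_band(wavelength, nm)]
  v <- defs[[name]]$fn(R)
  if (!is.finite(v)) {
    warning("index ", name, " undefined for this spectrum (zero denominator)")
    return(NA_real_)
  }
  v
}

#' Compute all (or selected) registry indices from a spectrum
#'
#' @param values reflectance vector or `mean_spectrum`.
#' @param wavelength wavelength axis (nm) when `values` is a bare vector.
#' @param names index names; default all 16.
#' @return named numeric vector.
#' @export
compute_vis <- function(values, wavelength = NULL, names = vi_registry()$name) {
  out <- vapply(names, function(nm)
    suppressWarnings(compute_vi(nm, values, wavelength)), numeric(1))
  stats::setNames(out, names)
}

#' Continuum removal over an absorption window
#'
#' Divides the spectrum by its upper convex hull over `[lo, hi]` nm,
#' isolating absorption-feature depth from albedo: values lie in `(0, 1]`
#' and the window endpoints are exactly 1.
#'
#' @param values reflectance vector (positive within the window).
#' @param wavelength wavelength axis, nm.
#' @param lo,hi window bounds, nm (550-750 for the chlorophyll feature).
#' @return object of class `cr_spectrum`: list with `wavelength` and `values`.
#' @export
continuum_removal <- function(values, wavelength, lo = 550, hi = 750) {
  if (inherits(values, "mean_spectrum")) {
    wavelength <- values$wavelength
    values <- values$values
  }
  keep <- wavelength >= lo & wavelength <= hi
  if (sum(keep) < 3) stop("need at least 3 bands in [", lo, ", ", hi, "] nm")
  wl <- wavelength[keep]
  v <- values[keep]
  if (any(v <= 0)) stop("continuum removal requires positive reflectance in the window")
  hull <- upper_hull_values(wl, v)
  out <- v / hull
  out[1] <- 1
  out[length(out)] <- 1
  structure(list(wavelength = wl, values = out), class = "cr_spectrum")
}

# upper convex hull (Andrew's monotone chain) evaluated at every wavelength
upper_hull_values <- function(wl, v) {
  n <- length(wl)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies on or below chord a--i
      if ((wl[i] - wl[a]) * (v[b] - v[a]) <= (wl[b] - wl[a]) * (v[i] - v[a]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  stats::approx(wl[hull], v[hull], xout = wl)$y
}
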