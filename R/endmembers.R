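#' Generate a spectral endmember library for synthetic paddy scenes
#'
#' Builds reflectance endmembers for the seven scene components a nadir view of
#' a paddy plot contains: sunlit and shaded leaves, sunlit and shaded panicles,
#' and the water / soil / duckweed background. Leaf spectra follow a parametric
#' model: a visible baseline joined to a NIR plateau by a logistic red edge,
#' with Gaussian pigment absorption features centred near 450 and 680 nm whose
#' depth scales with a chlorophyll proxy in `[0, 1]`. Shaded spectra multiply
#' the sunlit spectrum by a wavelength-dependent brightness factor that dims
#' the visible region more than the NIR (multiple scattering within the canopy
#' preserves NIR radiance) and slightly deepens the apparent absorption.
#' Panicle spectra have a yellow visible slope so that PRI falls at or below
#' -0.058, the published leaf/panicle cut-off.
#'
#' The seed draws small jitters on the baseline levels so that independent
#' libraries differ slightly, while every endmember stays on the correct side
#' of the published EVI / PRI / TCARI classification thresholds.
#'
#' @param wavelength_grid strictly increasing wavelengths (nm) covering at
#'   least 400-900 nm.
#' @param seed integer RNG seed.
#' @return An object of class `endmember_library`: a list with the wavelength
#'   grid, the model parameters, the default chlorophyll proxy, and `$spectra`,
#'   a role x band matrix of reference spectra evaluated at the default proxy.
#' @seealso [endmember_spectrum()] to evaluate leaf endmembers at a specific
#'   chlorophyll proxy.
#' @export
generate_endmembers <- function(wavelength_grid = seq(400, 900, by = 2), seed = 1L) {
  wl <- as.numeric(wavelength_grid)
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  if (min(wl) > 400 || max(wl) < 900)
    stop("wavelength grid must cover 400-900 nm (got ", min(wl), "-", max(wl), " nm)")
  jits <- with_seed(seed, stats::rnorm(12L, 0, 1))
  jit <- local({ i <- 0L; function(sd) { i <<- i + 1L; jits[i] * sd } })
  pars <- list(
    leaf_vis    = 0.30 + jit(0.006),
    leaf_nir    = 0.55 + jit(0.012),
    edge_nm     = 715 + jit(1.5),
    edge_base   = 700 + jit(1.5),
    edge_shift  = 20,
    edge_width  = 12,
    depth       = 0.78,
    sigma450    = 28,
    sigma680    = 22,
    shade_vis   = 0.33 + jit(0.006),
    shade_nir   = 0.72 + jit(0.012),
    shade_deepen = 1.05,
    pan_lo      = 0.09 + jit(0.003),
    pan_slope   = 7e-4,
    pan_nir     = 0.50 + jit(0.012),
    pan_dip     = 0.65,
    pan_sun_gain = 1.45,
    pan_shade_vis = 0.40,
    pan_shade_nir = 0.80,
    water_lo    = 0.06 + jit(0.003),
    soil_lo     = 0.10 + jit(0.004),
    default_chl = 0.8,
    default_structure = 0.6
  )
  lib <- structure(list(wavelength = wl, pars = pars,
                        default_chl = pars$default_chl),
                   class = "endmember_library")
  roles <- c("sunlit_leaf", "shaded_leaf", "sunlit_panicle", "shaded_panicle",
             "water", "soil", "duckweed")
  lib$spectra <- t(vapply(roles, function(r) endmember_spectrum(lib, r),
                          numeric(length(wl))))
  lib
}

#' Evaluate an endmember spectrum
#'
#' Leaf endmembers depend on the chlorophyll proxy; panicle and background
#' endmembers do not. A chlorophyll proxy of 0 gives a leaf spectrum with zero
#' absorption-feature depth (the bare visible baseline plus red edge).
#'
#' @param library an [`endmember_library`][generate_endmembers].
#' @param role one of `sunlit_leaf`, `shaded_leaf`, `sunlit_panicle`,
#'   `shaded_panicle`, `water`, `soil`, `duckweed`.
#' @param chl chlorophyll proxy in `[0, 1]`; defaults to the library default.
#' @param structure canopy-structure proxy in `[0, 1]` scaling the leaf NIR
#'   plateau (multiple scattering grows with canopy density, so NIR amplitude
#'   rises through the season while the pigment features track chlorophyll);
#'   defaults to the library default (0.6).
#' @return numeric reflectance vector on the library wavelength grid.
#' @export
endmember_spectrum <- function(library, role, chl = NULL, structure = NULL) {
  stopifnot(inherits(library, "endmember_library"))
  wl <- library$wavelength
  p <- library$pars
  if (is.null(chl)) chl <- library$default_chl
  if (is.null(structure)) structure <- p$default_structure
  if (chl < 0 || chl > 1) stop("chlorophyll proxy must lie in [0, 1]")
  if (structure < 0 || structure > 1) stop("structure proxy must lie in [0, 1]")
  logistic <- function(x) 1 / (1 + exp(-x))
  # red edge moves to longer wavelengths as chlorophyll rises
  leaf_edge <- function(c_eff) p$edge_base + p$edge_shift * c_eff
  shade_curve <- function(lo, hi, edge = p$edge_nm)
    lo + (hi - lo) * logistic((wl - edge) / p$edge_width)
  leaf <- function(c_eff) {
    nir_eff <- p$leaf_nir * (0.75 + 0.5 * structure)
    base <- p$leaf_vis + (nir_eff - p$leaf_vis) *
      logistic((wl - leaf_edge(c_eff)) / p$edge_width)
    a <- pmax(exp(-((wl - 450)^2) / (2 * p$sigma450^2)),
              exp(-((wl - 680)^2) / (2 * p$sigma680^2)))
    base * (1 - pmin(0.97, p$depth * c_eff * a))
  }
  panicle <- function() {
    vis <- p$pan_lo + p$pan_slope * (wl - 500)
    top <- p$pan_lo + p$pan_slope * 200          # value held flat past 700 nm
    base <- ifelse(wl <= 700, vis, top) +
      (p$pan_nir - top) * logistic((wl - p$edge_nm) / p$edge_width)
    base * (1 - p$pan_dip * exp(-((wl - 680)^2) / (2 * 20^2)))
  }
  s <- switch(role,
    sunlit_leaf = leaf(chl),
    shaded_leaf = {
      c_eff <- min(1, p$shade_deepen * chl)
      leaf(c_eff) * shade_curve(p$shade_vis, p$shade_nir, leaf_edge(c_eff))
    },
    sunlit_panicle = p$pan_sun_gain * panicle(),
    shaded_panicle = panicle() * shade_curve(p$pan_shade_vis, p$pan_shade_nir),
    water = {
      w <- p$water_lo - 8e-5 * (wl - 400)
      w[wl > 700] <- pmax(0.012, (p$water_lo - 0.024) - 2e-4 * (wl[wl > 700] - 700))
      w
    },
    soil = p$soil_lo + 2.5e-4 * (wl - 400),
    duckweed = 0.07 + 0.05 * exp(-((wl - 555)^2) / (2 * 35^2)) +
      0.08 * logistic((wl - p$edge_nm) / p$edge_width),
    stop("unknown endmember role: ", role)
  )
  pmin(0.99, pmax(0.001, s))
}

#' @export
print.endmember_library <- function(x, ...) {
  cat("<endmember_library> ", nrow(x$spectra), " roles on ",
      length(x$wavelength), " bands (", min(x$wavelength), "-",
      max(x$wavelength), " nm)\n", sep = "")
  invisible(x)
}

#' Growth-stage defaults for the synthetic experiment
#'
#' One row per canonical acquisition stage: early tillering (ET), late
#' tillering (LT), jointing (JT), booting (BT), heading (HD) and filling (FL).
#' Columns give the default stage-mean LNC (% dry mass) of the simulated
#' nitrogen-dilution trajectory, the default green fraction (0.15 at early
#' tillering, rising to 0.9 by booting), the panicle fraction among vegetation
#' (zero before heading), and the stage-specific linear map from LNC to the
#' leaf chlorophyll proxy. The map is distinct for each vegetative stage and
#' shared across the reproductive stages, which is what breaks a single
#' whole-season LNC~VI model: equal chlorophyll (hence equal index values)
#' corresponds to different LNC at different stages.
#'
#' @return data.frame with columns `stage`, `base_lnc`, `green_fraction`,
#'   `panicle_fraction`, `chl_slope`, `chl_intercept`.
#' @export
stage_defaults <- function() {
  data.frame(
    stage = c("ET", "LT", "JT", "BT", "HD", "FL"),
    base_lnc = c(3.9, 3.4, 2.9, 2.4, 2.1, 1.75),
    green_fraction = c(0.15, 0.35, 0.60, 0.85, 0.90, 0.90),
    panicle_fraction = c(0, 0, 0, 0, 0.15, 0.20),
    chl_slope = c(0.18, 0.28, 0.30, 0.30, 0.30, 0.30),
    chl_intercept = c(0.45 - 0.18 * 3.0, 0.45 - 0.28 * 2.3, 0.45 - 0.30 * 1.7,
                      0.38 - 0.30, 0.38 - 0.30, 0.38 - 0.30),
    stringsAsFactors = FALSE
  )
}

# map LNC to the chlorophyll proxy with the stage-specific linear map
lnc_to_chl <- function(lnc, slope, intercept) {
  pmin(1, pmax(0.42, intercept + slope * lnc))
}
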