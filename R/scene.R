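#' Pixel class labels
#'
#' Integer codes used in class maps: 0 = background, 1 = sunlit_leaf,
#' 2 = shaded_leaf, 3 = sunlit_panicle, 4 = shaded_panicle.
#'
#' @return character vector of the five labels, in code order (code 0 first).
#' @export
class_levels <- function() {
  c("background", "sunlit_leaf", "shaded_leaf", "sunlit_panicle", "shaded_panicle")
}

#' Construct a per-pixel class map
#'
#' @param labels integer matrix of class codes 0-4 (see [class_levels()]).
#' @param pixel_size_mm ground pixel size in mm.
#' @param stage growth-stage label, or `NA`.
#' @return object of class `class_map`.
#' @export
class_map <- function(labels, pixel_size_mm = 1.3, stage = NA_character_) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 4L)) stop("class codes must lie in 0..4")
  structure(labels, class = "class_map", pixel_size_mm = pixel_size_mm, stage = stage)
}

#' @export
print.class_map <- function(x, ...) {
  n <- tabulate(as.integer(x) + 1L, nbins = 5L)
  cat("<class_map> ", nrow(x), " x ", ncol(x), " pixels @ ",
      format(attr(x, "pixel_size_mm"), digits = 4), " mm\n", sep = "")
  print(stats::setNames(n, class_levels()))
  invisible(x)
}

#' Scene configuration for the synthetic generator
#'
#' Collects everything [generate_scene()] needs: the growth stage, the target
#' green fraction, the true LNC (% dry mass), the shade and panicle fractions
#' among vegetation, the stage-specific LNC-to-chlorophyll-proxy map, the
#' multiplicative noise level, the spatial clump scale in base pixels, the
#' scene size and base resolution, and the RNG seed. Defaults for the
#' stage-dependent fields come from [stage_defaults()].
#'
#' @param stage one of `"ET"`, `"LT"`, `"JT"`, `"BT"`, `"HD"`, `"FL"`.
#' @param lnc true leaf nitrogen concentration, % dry mass, in `[0.5, 5]`.
#' @param green_fraction target fraction of vegetation pixels in `[0, 1]`.
#' @param shade_fraction fraction of vegetation pixels in shade.
#' @param panicle_fraction fraction of vegetation pixels that are panicle;
#'   must be 0 for vegetative stages (ET, LT, JT, BT).
#' @param chl_slope,chl_intercept stage-specific linear LNC -> chlorophyll map.
#' @param structure canopy-structure proxy in `[0, 1]` passed to the leaf
#'   endmembers (NIR amplitude); defaults to the green fraction, since both
#'   grow with canopy closure.
#' @param noise_sd multiplicative Gaussian noise sd (fraction of reflectance).
#' @param clump_scale spatial correlation scale of the plant pattern, in
#'   base pixels.
#' @param rows,cols scene size in pixels.
#' @param pixel_size_mm base resolution, mm.
#' @param row_spacing_mm planting row spacing, mm (drives the striped layout).
#' @param seed integer RNG seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(stage = "JT", lnc = NULL, green_fraction = NULL,
                         shade_fraction = 0.4, panicle_fraction = NULL,
                         chl_slope = NULL, chl_intercept = NULL,
                         structure = NULL,
                         noise_sd = 0.02, clump_scale = 8,
                         rows = 128L, cols = 128L, pixel_size_mm = 1.3,
                         row_spacing_mm = 300, seed = 1L) {
  sd <- stage_defaults()
  if (!stage %in% sd$stage)
    stop("stage must be one of ", paste(sd$stage, collapse = ", "))
  row <- sd[sd$stage == stage, ]
  if (is.null(lnc)) lnc <- row$base_lnc
  if (is.null(green_fraction)) green_fraction <- row$green_fraction
  if (is.null(panicle_fraction)) panicle_fraction <- row$panicle_fraction
  if (is.null(chl_slope)) chl_slope <- row$chl_slope
  if (is.null(chl_intercept)) chl_intercept <- row$chl_intercept
  if (lnc < 0.5 || lnc > 5) stop("LNC must lie in [0.5, 5] % dry mass")
  if (green_fraction < 0 || green_fraction > 1)
    stop("green fraction must lie in [0, 1]")
  vegetative <- stage %in% c("ET", "LT", "JT", "BT")
  if (vegetative && panicle_fraction > 0)
    stop("panicle fraction must be 0 for vegetative stage ", stage)
  if (shade_fraction < 0 || shade_fraction > 1 ||
      panicle_fraction < 0 || panicle_fraction > 1)
    stop("shade and panicle fractions must lie in [0, 1]")
  if (is.null(structure)) structure <- green_fraction
  if (structure < 0 || structure > 1) stop("structure proxy must lie in [0, 1]")
  structure(list(stage = stage, lnc = lnc, green_fraction = green_fraction,
                 shade_fraction = shade_fraction,
                 panicle_fraction = panicle_fraction,
                 structure = structure,
                 chl_slope = chl_slope, chl_intercept = chl_intercept,
                 noise_sd = noise_sd, clump_scale = clump_scale,
                 rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size_mm = pixel_size_mm,
                 row_spacing_mm = row_spacing_mm, seed = as.integer(seed)),
            class = "scene_config")
}

# separable Gaussian blur with circular boundary; filters columns then rows.
# the kernel is capped so it never exceeds the filtered dimension.
blur_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kern <- function(n) {
    half <- max(1L, min(ceiling(3 * sigma), (n - 1L) %/% 2L))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k / sum(k)
  }
  m <- stats::filter(m, kern(nrow(m)), circular = TRUE)
  t(stats::filter(t(m), kern(ncol(m)), circular = TRUE))
}

# pick exactly n pixels with the highest field values among candidates
top_n_mask <- function(field, candidates, n) {
  idx <- which(candidates)
  if (n > length(idx)) stop("requested more pixels than available")
  sel <- idx[order(field[idx], decreasing = TRUE)[seq_len(n)]]
  out <- logical(length(field))
  out[sel] <- TRUE
  out
}

#' Generate a synthetic hyperspectral paddy scene with ground truth
#'
#' Renders one plot: a spatially clumped vegetation pattern (smooth random
#' field plus a planting-row bias) is thresholded at the exact pixel count
#' matching the target green fraction; vegetation splits into shaded/sunlit
#' and panicle/leaf components via further clumped fields; the background is a
#' water/soil/duckweed mosaic. Each pixel carries the endmember spectrum of
#' its class (leaf endmembers evaluated at the chlorophyll proxy implied by
#' the scene LNC and the stage map), degraded by multiplicative Gaussian noise
#' and a smooth band-correlated baseline wiggle.
#'
#' @param config a [scene_config()].
#' @param library an [`endmember_library`][generate_endmembers].
#' @return list with elements `cube` (a [spectral_cube()]) and `classmap`
#'   (a [class_map()] of true labels).
#' @export
generate_scene <- function(config, library) {
  stopifnot(inherits(config, "scene_config"), inherits(library, "endmember_library"))
  nr <- config$rows; nc <- config$cols
  npix <- nr * nc
  with_seed(config$seed, {
    noise_fields <- replicate(4L, matrix(stats::rnorm(npix), nr, nc), simplify = FALSE)
    veg_field <- blur_field(noise_fields[[1]], config$clump_scale / 2)
    # planting rows stripe across the scan (row) axis, so the middle-half
    # column crop keeps a representative share of every row
    period_px <- max(8, min(nr / 2, config$row_spacing_mm / config$pixel_size_mm))
    bias <- matrix(rep(cos(2 * pi * seq_len(nr) / period_px), times = nc), nr, nc)
    veg_field <- veg_field / max(stats::sd(veg_field), 1e-12) + 0.6 * bias
    if (stats::sd(veg_field) < 1e-9)
      stop("vegetation pattern degenerate: target green fraction unreachable ",
           "at clump scale ", config$clump_scale)

    n_veg <- round_half_up(config$green_fraction * npix)
    veg <- top_n_mask(veg_field, rep(TRUE, npix), n_veg)
    shade_field <- blur_field(noise_fields[[2]], config$clump_scale / 4)
    shaded <- top_n_mask(shade_field, veg, round_half_up(config$shade_fraction * n_veg))
    pan_field <- blur_field(noise_fields[[3]], config$clump_scale / 4)
    panicle <- top_n_mask(pan_field, veg, round_half_up(config$panicle_fraction * n_veg))

    labels <- integer(npix)
    labels[veg & !panicle & !shaded] <- 1L
    labels[veg & !panicle & shaded] <- 2L
    labels[veg & panicle & !shaded] <- 3L
    labels[veg & panicle & shaded] <- 4L

    # background mosaic: mostly standing water, some soil, a little duckweed
    bg_field <- blur_field(noise_fields[[4]], config$clump_scale / 2)
    bg <- !veg
    n_bg <- sum(bg)
    soil_px <- top_n_mask(bg_field, bg, round_half_up(0.2 * n_bg))
    duck_px <- top_n_mask(-bg_field, bg, round_half_up(0.1 * n_bg))
    role <- integer(npix)                       # index into endmember rows
    role[labels == 1L] <- 1L; role[labels == 2L] <- 2L
    role[labels == 3L] <- 3L; role[labels == 4L] <- 4L
    role[bg] <- 5L                              # water
    role[soil_px] <- 6L; role[duck_px & !soil_px] <- 7L

    chl <- lnc_to_chl(config$lnc, config$chl_slope, config$chl_intercept)
    wl <- library$wavelength
    E <- rbind(endmember_spectrum(library, "sunlit_leaf", chl, config$structure),
               endmember_spectrum(library, "shaded_leaf", chl, config$structure),
               library$spectra["sunlit_panicle", ],
               library$spectra["shaded_panicle", ],
               library$spectra["water", ],
               library$spectra["soil", ],
               library$spectra["duckweed", ])
    px <- E[role, , drop = FALSE]
    if (config$noise_sd > 0) {
      px <- px * (1 + matrix(stats::rnorm(length(px), 0, config$noise_sd),
                             nrow(px), ncol(px)))
      # band-correlated smooth baseline wiggle, small random amplitude per pixel
      wig <- stats::filter(stats::rnorm(length(wl)), rep(1 / 15, 15), circular = TRUE)
      wig <- as.numeric(wig) / max(stats::sd(wig), 1e-12)
      amp <- stats::rnorm(npix, 0, 0.25 * config$noise_sd)
      px <- px + outer(amp, wig)
      px <- pmin(1, pmax(0, px))
    }
    cube <- spectral_cube(array(px, dim = c(nr, nc, length(wl))), wl,
                          pixel_size_mm = config$pixel_size_mm,
                          meta = list(stage = config$stage, lnc = config$lnc,
                                      chl = chl, structure = config$structure,
                                      noise_sd = config$noise_sd))
    cm <- class_map(matrix(labels, nr, nc), config$pixel_size_mm, config$stage)
    realized <- sum(labels > 0L) / npix
    if (abs(realized - config$green_fraction) > 0.02)
      stop("realized green fraction ", round(realized, 4),
           " misses target ", config$green_fraction)
    list(cube = cube, classmap = cm)
  })
}

#' Synthesize raw sensor frames from a reflectance cube
#'
#' Inverts the radiometric calibration: per-band digital numbers are generated
#' so that applying [calibrate_reflectance()] recovers the input reflectance
#' (exactly at zero sensor noise). A pixel with reflectance 0 maps to the
#' dark-current level.
#'
#' @param cube a [spectral_cube()] of reflectance.
#' @param panel_reflectance white-panel reflectance in `(0, 1]` (0.99 for a
#'   barium-sulfate panel).
#' @param dark_level dark-current counts per band (scalar or per-band vector).
#' @param noise_sd additive sensor noise sd in counts (0 = noiseless).
#' @param seed RNG seed for the sensor noise.
#' @return a [calibration_frames()] object.
#' @export
generate_dn_frames <- function(cube, panel_reflectance = 0.99, dark_level = 100,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (panel_reflectance <= 0 || panel_reflectance > 1)
    stop("panel reflectance must lie in (0, 1]")
  wl <- cube$wavelength
  nb <- length(wl)
  dark <- rep_len(as.numeric(dark_level), nb)
  # smooth band-dependent system gain (illumination x sensor response), counts
  gain <- 2000 * (0.7 + 0.3 * exp(-((wl - 650)^2) / (2 * 150^2)))
  dn_panel <- dark + gain
  d <- dim(cube$data)
  refl <- matrix(cube$data, d[1] * d[2], nb)
  dn <- sweep(sweep(refl, 2L, gain / panel_reflectance, `*`), 2L, dark, `+`)
  if (noise_sd > 0)
    dn <- dn + with_seed(seed, matrix(stats::rnorm(length(dn), 0, noise_sd),
                                      nrow(dn), ncol(dn)))
  calibration_frames(dn_target = array(dn, dim = d), dn_noise = dark,
                     dn_panel = dn_panel, ref_panel = panel_reflectance,
                     wavelength = wl, pixel_size_mm = cube$pixel_size_mm,
                     meta = cube$meta)
}
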