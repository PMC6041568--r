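#' Crop the central half of the image columns
#'
#' Pushbroom scenes suffer bidirectional-reflectance effects at the swath
#' edges where the view zenith angle is largest; only the central 50% of the
#' columns (centred, floor on odd widths) is kept. Rows and bands are
#' untouched.
#'
#' @param cube a [spectral_cube()] with at least 2 columns.
#' @return the cropped [spectral_cube()].
#' @export
crop_middle_half <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  w <- dim(cube$data)[2]
  if (w < 2) stop("cube must have at least 2 columns")
  keep <- floor(w / 2)
  start <- floor((w - keep) / 2) + 1L
  spectral_cube(cube$data[, start:(start + keep - 1L), , drop = FALSE],
                cube$wavelength, pixel_size_mm = cube$pixel_size_mm,
                meta = cube$meta)
}

#' Build the dyadic spatial-resolution ladder
#'
#' Starting from the full swath, nominal resolutions are `swath / 2^k` rounded
#' half-up to the nearest mm, descending while the rounded value still exceeds
#' the base resolution; the base resolution itself heads the ladder. Each
#' nominal entry carries its integer aggregation factor
#' `N = round(nominal / base)` and the realized resolution `base * N` (the
#' nominal labels are not exact multiples of the base: N = 2 realizes 2.6 mm
#' under the label "2 mm" for a 1.3 mm base). For the default
#' `(base, swath) = (1.3, 450)` the ladder is
#' 1.3, 2, 4, 7, 14, 28, 56, 113, 225, 450 mm - ten levels.
#'
#' The coarsest (whole-swath) entry is not produced by aggregation in the
#' sweep: a single pixel would remain, so the whole-image rule of
#' [coarsest_level_spectrum()] applies there.
#'
#' @param base_mm base resolution, mm.
#' @param swath_mm swath width, mm; must exceed `base_mm`.
#' @return object of class `resolution_ladder`: data.frame with columns
#'   `nominal_mm`, `factor`, `realized_mm`.
#' @export
build_resolution_ladder <- function(base_mm = 1.3, swath_mm = 450) {
  if (base_mm <= 0 || swath_mm <= base_mm)
    stop("need 0 < base_mm < swath_mm")
  nominal <- numeric(0)
  k <- 0
  repeat {
    r <- round_half_up(swath_mm / 2^k)
    if (r <= base_mm) break
    nominal <- c(nominal, r)
    k <- k + 1
  }
  nominal <- c(base_mm, rev(nominal))
  fac <- pmax(1L, as.integer(round_half_up(nominal / base_mm)))
  out <- data.frame(nominal_mm = nominal, factor = fac,
                    realized_mm = base_mm * fac)
  class(out) <- c("resolution_ladder", "data.frame")
  out
}

#' Aggregate a cube over N x N pixel blocks
#'
#' Non-overlapping `N x N` blocks are averaged per band; trailing rows or
#' columns that do not fill a block are dropped (padding would bias edge-block
#' spectra); the pixel size is multiplied by `N`. `N = 1` is the identity.
#'
#' @param cube a [spectral_cube()].
#' @param factor integer aggregation factor `N >= 1`.
#' @return the aggregated [spectral_cube()].
#' @export
aggregate_cube <- function(cube, factor) {
  stopifnot(inherits(cube, "spectral_cube"))
  N <- as.integer(factor)
  if (N < 1) stop("aggregation factor must be >= 1")
  if (N == 1L) return(cube)
  d <- dim(cube$data)
  r2 <- d[1] %/% N; c2 <- d[2] %/% N
  if (r2 < 1 && c2 < 1)
    stop("aggregation factor ", N, " exceeds both image dimensions ",
         d[1], " x ", d[2])
  if (r2 < 1 || c2 < 1)
    stop("aggregation factor ", N, " leaves no complete block along one dimension")
  a <- cube$data[seq_len(r2 * N), seq_len(c2 * N), , drop = FALSE]
  nb <- d[3]
  dim(a) <- c(N, r2, c2 * N * nb)
  s <- colMeans(a)                                   # (r2, N*c2*nb)
  dim(s) <- c(r2, N, c2 * nb)
  s <- aperm(s, c(2, 1, 3))                          # (N, r2, c2*nb)
  dim(s) <- c(N, r2 * c2 * nb)
  out <- colMeans(s)
  dim(out) <- c(r2, c2, nb)
  spectral_cube(out, cube$wavelength,
                pixel_size_mm = cube$pixel_size_mm * N, meta = cube$meta)
}

#' @rdname aggregate_cube
#' @param x a [spectral_cube()] (S3 method for [stats::aggregate()]).
#' @param ... ignored.
#' @export
aggregate.spectral_cube <- function(x, factor, ...) aggregate_cube(x, factor)
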