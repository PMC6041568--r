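#' Construct a spectral cube
#'
#' A `spectral_cube` is the package's in-memory container for a hyperspectral
#' image: a 3-D reflectance array indexed by row x column x band, a wavelength
#' axis in nanometres, the ground pixel size in millimetres, and free-form
#' acquisition metadata (plot id, stage, year, ...).
#'
#' @param data numeric 3-D array, `dim = c(rows, cols, bands)`. A matrix is
#'   accepted for a single-band cube.
#' @param wavelength numeric vector of band-centre wavelengths (nm), strictly
#'   increasing, length equal to `dim(data)[3]`.
#' @param pixel_size_mm positive scalar, ground sampling distance in mm.
#' @param meta named list of acquisition metadata.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelength, pixel_size_mm = 1.3, meta = list()) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x bands array")
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) != dim(data)[3])
    stop("length(wavelength) [", length(wavelength), "] != number of bands [",
         dim(data)[3], "]")
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0))
    stop("wavelength axis must be strictly increasing")
  if (any(dim(data)[1:2] < 1L)) stop("cube must have >= 1 row and column")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L || pixel_size_mm <= 0)
    stop("pixel_size_mm must be a positive scalar")
  structure(list(data = data, wavelength = wavelength,
                 pixel_size_mm = as.numeric(pixel_size_mm), meta = meta),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<spectral_cube> ", d[1], " x ", d[2], " pixels, ", d[3], " bands (",
      min(x$wavelength), "-", max(x$wavelength), " nm), ",
      format(x$pixel_size_mm, digits = 4), " mm/pixel\n", sep = "")
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L, logical(1))
    if (any(keep))
      cat("  meta: ", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                            sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# pixels as an n x bands matrix (row-major pixel order is irrelevant to callers)
cube_pixels <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

round_half_up <- function(x) floor(x + 0.5)

# derive a child RNG seed from a user seed; kept below 2^31
child_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 2048L + (k %% 2048L)

# evaluate expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
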