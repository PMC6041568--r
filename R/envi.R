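#' Write a spectral cube as an ENVI-style header + flat binary pair
#'
#' The header (`<path>.hdr`) is plain text with the standard fields
#' `samples`, `lines`, `bands`, `data type`, `interleave`, `byte order` and
#' the wavelength list in nm; the binary file (`<path>`) holds the values in
#' the declared interleave. Doubles (`data type = 5`) are written by default
#' so that a write/read round trip is bit-identical.
#'
#' @param cube a [spectral_cube()].
#' @param path output binary path; the header gets `.hdr` appended.
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`.
#' @param data_type ENVI data type code: 1 (uint8), 2 (int16), 3 (int32),
#'   4 (float32), 5 (float64) or 12 (uint16).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)                      # lines (rows), samples (cols), bands
  lines <- d[1]; samples <- d[2]; bands <- d[3]
  # reorder the [line, sample, band] array to the on-disk element order,
  # fastest-varying dimension first
  a <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),    # sample, line, band
    bil = aperm(cube$data, c(2, 3, 1)),    # sample, band, line
    bip = aperm(cube$data, c(3, 2, 1)))    # band, sample, line
  spec <- envi_type_spec(data_type)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  vals <- as.vector(a)
  if (spec$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = spec$size, endian = "little")
  hdr <- c("ENVI",
           paste0("description = { ", cube$meta$description %||%
                    "paddyspec spectral cube", " }"),
           paste0("samples = ", samples),
           paste0("lines = ", lines),
           paste0("bands = ", bands),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("pixel size mm = ", format(cube$pixel_size_mm, digits = 10)),
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(format(cube$wavelength, digits = 10, trim = TRUE),
                        collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI-style cube
#'
#' Parses the `.hdr` text header and the flat binary file it describes.
#' Malformed input is rejected with an error naming the offending field:
#' missing dimensions or wavelength list, unsupported data type, or a binary
#' file whose size disagrees with `samples * lines * bands`.
#'
#' @param path the binary path written by [write_cube()] (header at
#'   `<path>.hdr`, or `path` itself may be the header).
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", "", path)
  if (!file.exists(hdr_path)) stop("header file not found: ", hdr_path)
  if (!file.exists(bin_path)) stop("binary file not found: ", bin_path)
  h <- parse_envi_header(hdr_path)
  for (f in c("samples", "lines", "bands"))
    if (is.null(h[[f]])) stop("header missing required field: ", f)
  if (is.null(h$wavelength))
    stop("header missing required field: wavelength")
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  wl <- h$wavelength
  if (length(wl) != bands)
    stop("wavelength list length (", length(wl),
         ") does not match bands (", bands, ")")
  if (identical(tolower(h[["wavelength units"]] %||% "nanometers"), "micrometers"))
    wl <- wl * 1000
  dtype <- as.integer(h[["data type"]] %||% 4L)
  spec <- envi_type_spec(dtype)
  n <- samples * lines * bands
  expected <- n * spec$size
  actual <- file.size(bin_path)
  if (actual != expected)
    stop("binary size mismatch: samples*lines*bands implies ", expected,
         " bytes but file has ", actual, " bytes")
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  interleave <- tolower(h$interleave %||% "bsq")
  a <- switch(interleave,
    bsq = aperm(array(vals, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(bands, samples, lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  px <- suppressWarnings(as.numeric(h[["pixel size mm"]] %||% 1.3))
  spectral_cube(a, wl, pixel_size_mm = px,
                meta = list(description = h$description))
}

#' Write a class map as a single-band labelled ENVI image
#'
#' Class codes are stored as bytes; the header's description documents the
#' code table (see [class_levels()]).
#'
#' @param classmap a [class_map()].
#' @param path output binary path.
#' @return `path`, invisibly.
#' @export
write_classmap <- function(classmap, path) {
  stopifnot(inherits(classmap, "class_map"))
  codes <- paste(seq_along(class_levels()) - 1L, class_levels(),
                 sep = "=", collapse = "; ")
  cube <- spectral_cube(array(as.numeric(classmap), c(dim(classmap), 1L)),
                        wavelength = 0,
                        pixel_size_mm = attr(classmap, "pixel_size_mm"),
                        meta = list(description = paste("class codes:", codes)))
  # wavelength axis is a placeholder; a label image has no spectral meaning
  write_cube(cube, path, interleave = "bsq", data_type = 1L)
}

#' Read a class map written by [write_classmap()]
#' @param path the binary path.
#' @return a [class_map()].
#' @export
read_classmap <- function(path) {
  cube <- read_cube(path)
  class_map(matrix(as.integer(cube$data[, , 1]), dim(cube$data)[1]),
            pixel_size_mm = cube$pixel_size_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

envi_type_spec <- function(code) {
  switch(as.character(code),
    "1" = list(what = "integer", size = 1L, signed = FALSE),
    "2" = list(what = "integer", size = 2L, signed = TRUE),
    "3" = list(what = "integer", size = 4L, signed = TRUE),
    "4" = list(what = "numeric", size = 4L, signed = TRUE),
    "5" = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported data type code: ", code))
}

parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  # join brace-delimited multi-line values
  joined <- character(0)
  buf <- NULL
  for (line in txt) {
    if (is.null(buf)) {
      if (grepl("\\{", line) && !grepl("\\}", line)) buf <- line
      else joined <- c(joined, line)
    } else {
      buf <- paste(buf, line)
      if (grepl("\\}", line)) { joined <- c(joined, buf); buf <- NULL }
    }
  }
  if (!is.null(buf)) stop("unterminated '{' block in header")
  h <- list()
  for (line in joined) {
    if (!grepl("=", line)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (grepl("^\\{", val)) {
      inner <- trimws(gsub("[{}]", "", val))
      if (key %in% c("wavelength", "fwhm"))
        h[[key]] <- as.numeric(strsplit(inner, ",")[[1]])
      else h[[key]] <- inner
    } else h[[key]] <- val
  }
  h
}
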