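test_that("write/read round trip is bit-identical for every interleave", {
  cube <- make_lowrank_cube(seed = 3, nr = 7L, nc = 5L, nb = 11L)
  for (il in c("bil", "bsq", "bip")) {
    path <- file.path(tempdir(), paste0("cube_", il))
    write_cube(cube, path, interleave = il)
    rc <- read_cube(path)
    expect_identical(rc$data, cube$data)
    expect_identical(rc$wavelength, cube$wavelength)
  }
})

test_that("the same cube reads back identically from different interleaves", {
  cube <- make_lowrank_cube(seed = 4, nr = 6L, nc = 9L, nb = 13L)
  p1 <- file.path(tempdir(), "x_bil"); p2 <- file.path(tempdir(), "x_bsq")
  write_cube(cube, p1, "bil"); write_cube(cube, p2, "bsq")
  expect_identical(read_cube(p1)$data, read_cube(p2)$data)
})

test_that("malformed files are rejected with errors naming the field", {
  cube <- make_lowrank_cube(seed = 5, nr = 4L, nc = 4L, nb = 6L)
  path <- file.path(tempdir(), "bad_cube")
  write_cube(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  # declare one band more than the binary holds
  writeLines(sub("bands = 6", "bands = 7", hdr), paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelength list length")
  writeLines(c(sub("bands = 6", "bands = 7", hdr[!grepl("wavelength =", hdr)]),
               paste0("wavelength = { ", paste(1:7, collapse = ", "), " }")),
             paste0(path, ".hdr"))
  expect_error(read_cube(path), "size mismatch")
  writeLines(hdr[!grepl("wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelength")
  writeLines(hdr[!grepl("^samples", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "samples")
})

test_that("calibration follows the worked DN arithmetic and its identities", {
  # (600 - 100) / (1100 - 100) * 0.99 = 0.495
  fr <- calibration_frames(array(600, c(1, 1, 1)), 100, 1100, 0.99,
                           wavelength = 550)
  expect_equal(calibrate_reflectance(fr)$data[1, 1, 1], 0.495)
  # DN_target = DN_panel recovers the panel reflectance; = DN_noise gives 0
  fr2 <- calibration_frames(array(c(1100, 100), c(1, 2, 1)), 100, 1100, 0.99,
                            wavelength = 550)
  out <- calibrate_reflectance(fr2)
  expect_equal(out$data[1, 1, 1], 0.99)
  expect_equal(out$data[1, 2, 1], 0)
})

test_that("calibration is affine in DN_target", {
  wl <- seq(400, 900, 100)
  dn <- array(runif(2 * 3 * 6, 200, 900), c(2, 3, 6))
  fr <- function(x) calibration_frames(x, 100, 1000, 0.99, wavelength = wl)
  base <- calibrate_reflectance(fr(dn))$data
  scaled <- calibrate_reflectance(fr(2 * dn - 100))$data
  expect_equal(scaled, 2 * base, tolerance = 1e-12)
})

test_that("a zero calibration denominator reports the band index", {
  dn <- array(500, c(1, 1, 3))
  expect_error(
    calibrate_reflectance(calibration_frames(dn, c(100, 200, 100),
                                             c(900, 200, 900), 0.99,
                                             wavelength = c(500, 600, 700))),
    "band 2")
})

test_that("spectral subsetting keeps exactly the in-window bands", {
  wl <- seq(360, 1025, by = 2.8)
  cube <- spectral_cube(array(runif(4 * 4 * length(wl)), c(4, 4, length(wl))), wl)
  sub <- subset_spectral(cube, 400, 900)
  expect_true(all(sub$wavelength >= 400 & sub$wavelength <= 900))
  expect_equal(sum(wl >= 400 & wl <= 900), length(sub$wavelength))
  expect_cube_equal(subset_spectral(cube, min(wl), max(wl)), cube)
  one <- subset_spectral(cube, 500, 502)
  expect_equal(dim(one$data)[3], 1L)
  expect_error(subset_spectral(cube, 1100, 1200), "no bands")
})

test_that("MNF reconstructs a noiseless low-rank cube and is identity at full rank", {
  cube <- make_lowrank_cube(seed = 1, nr = 10L, nc = 10L, nb = 51L)
  rec <- suppressWarnings(mnf_denoise(cube, 3))
  expect_lt(max(abs(rec$data - cube$data)) / max(abs(cube$data)), 1e-8)
  full <- suppressWarnings(mnf_denoise(cube, 51))
  expect_lt(max(abs(full$data - cube$data)), 1e-8)
  expect_equal(dim(rec$data), dim(cube$data))
})

test_that("MNF reduces per-band noise on a structured noisy scene", {
  clean <- fix_scene_clean$cube
  noisy_data <- with_seed(99, clean$data *
    (1 + array(stats::rnorm(length(clean$data), 0, 0.02), dim(clean$data))))
  noisy <- spectral_cube(pmin(pmax(noisy_data, 0), 1), clean$wavelength)
  den <- mnf_denoise(noisy, 10)
  per_in <- apply(noisy$data - clean$data, 3, stats::sd)
  per_out <- apply(den$data - clean$data, 3, stats::sd)
  expect_true(all(per_out < per_in))
})

test_that("MNF warns and regularizes on singular noise covariance", {
  cube <- make_lowrank_cube(seed = 2, nr = 6L, nc = 6L, nb = 20L)
  expect_warning(mnf_denoise(cube, 3), "regularization")
})
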