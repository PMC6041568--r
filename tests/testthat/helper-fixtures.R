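# Shared fixtures, built once per test run.

fix_lib <- generate_endmembers(seed = 42L)
fix_wl <- fix_lib$wavelength

# a small noiseless jointing scene used by several files
fix_scene_clean <- generate_scene(
  scene_config(stage = "JT", noise_sd = 0, rows = 48L, cols = 48L, seed = 5L),
  fix_lib)

# random low-rank cube: mixtures of 3 random endmembers, no noise
make_lowrank_cube <- function(seed = 1L, nr = 10L, nc = 10L, nb = 51L) {
  with_seed(seed, {
    E <- matrix(stats::runif(3 * nb, 0.05, 0.8), 3, nb)
    W <- matrix(stats::runif(nr * nc * 3), nr * nc, 3)
    W <- W / rowSums(W)
    spectral_cube(array(W %*% E, c(nr, nc, nb)), seq(400, 900, length.out = nb))
  })
}

# an lnc_samples table with arbitrary spectra/targets, for the multivariate
# model tests (no image pipeline involved)
make_samples <- function(X, y, wl, stage = "JT", year = 1L) {
  n <- nrow(X)
  tab <- data.frame(scene = seq_len(n), year = year, stage = stage,
                    treatment = "t", n_rate = "N1", density = "D1",
                    block = rep(1:3, length.out = n), lnc = y,
                    nominal_mm = 1.3, realized_mm = 1.3,
                    pixel_type = "all_leaf", n_pixels = 10L,
                    stringsAsFactors = FALSE)
  structure(tab, spectra = X, wavelength = wl,
            class = c("lnc_samples", "data.frame"))
}

# split whose targets are a smooth function of a few bands
make_function_split <- function(seed, n = 90L, p = 25L, noise = 0, fn = NULL) {
  if (is.null(fn)) {
    b <- pmax(1L, round(p * c(0.2, 0.48, 0.8)))   # 5, 12, 20 at p = 25
    fn <- function(X) 2 + sin(2 * X[, b[1]]) + X[, b[2]]^2 + 0.8 * X[, b[3]]
  }
  with_seed(seed, {
    X <- matrix(stats::runif(n * p, 0.1, 0.6), n, p)
    y <- fn(X) + stats::rnorm(n, 0, noise)
    wl <- seq(500, 740, length.out = p)
    split_by_replicate(make_samples(X, y, wl), "global")
  })
}

expect_cube_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a$data), dim(b$data))
  expect_lt(max(abs(a$data - b$data)), tol)
  expect_equal(a$wavelength, b$wavelength)
}
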