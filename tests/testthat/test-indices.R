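test_that("nearest band lookup honours ties, distances and the 10 nm guard", {
  wl <- seq(400, 900, by = 2.8)
  i <- nearest_band(wl, 670)
  expect_equal(wl[i], wl[which.min(abs(wl - 670))])
  expect_lte(attr(i, "distance_nm"), 1.4)
  j <- nearest_band(wl, wl[40])
  expect_equal(as.integer(j), 40L)
  expect_equal(attr(j, "distance_nm"), 0)
  expect_error(nearest_band(wl, 915), "10 nm")
  expect_error(nearest_band(numeric(0), 500), "empty")
  # tie broken toward the lower wavelength
  expect_equal(as.integer(nearest_band(c(500, 510), 505)), 1L)
})

test_that("the registry holds exactly the 16 published indices", {
  reg <- vi_registry()
  expect_equal(nrow(reg), 16L)
  expect_setequal(reg$name,
    c("SR[800,675]", "SR[810,560]", "SR[750,550]", "SR[750,710]",
      "CI_Red-edge", "NDVI", "GNDVI", "ND705", "mND705", "mSR705", "MTCI",
      "PRI", "TCARI", "OSAVI", "TCARI/OSAVI", "DCNI"))
})

test_that("index arithmetic matches the printed formulas on simple spectra", {
  wl <- c(445, 470, 531, 550, 560, 570, 670, 675, 680, 700, 705, 710, 720,
          750, 800, 810)
  base <- rep(0.2, length(wl))
  s <- base
  s[wl == 800] <- 0.5; s[wl == 670] <- 0.1
  expect_equal(compute_vi("NDVI", s, wl), 0.4 / 0.6)
  s2 <- base
  s2[wl == 750] <- 0.45; s2[wl == 705] <- 0.15; s2[wl == 445] <- 0.05
  expect_equal(compute_vi("mSR705", s2, wl), 4.0)
  # spectrally flat spectrum: CI is 0 and MTCI's denominator vanishes
  expect_equal(compute_vi("CI_Red-edge", base, wl), 0)
  expect_warning(v <- compute_vi("MTCI", base, wl), "MTCI")
  expect_true(is.na(v))
  expect_error(compute_vi("NOTANINDEX", s, wl), "unregistered")
})

test_that("each registry expression matches an independent transcription", {
  wl <- c(445, 470, 531, 550, 560, 570, 670, 675, 680, 700, 705, 710, 720,
          750, 800, 810)
  R <- function(s, nm) s[which.min(abs(wl - nm))]
  oracle <- list(
    "SR[800,675]" = function(s) R(s, 800) / R(s, 675),
    "SR[810,560]" = function(s) R(s, 810) / R(s, 560),
    "SR[750,550]" = function(s) R(s, 750) / R(s, 550),
    "SR[750,710]" = function(s) R(s, 750) / R(s, 710),
    "CI_Red-edge" = function(s) R(s, 800) / R(s, 720) - 1,
    "NDVI" = function(s) (R(s, 800) - R(s, 670)) / (R(s, 800) + R(s, 670)),
    "GNDVI" = function(s) (R(s, 750) - R(s, 550)) / (R(s, 750) + R(s, 550)),
    "ND705" = function(s) (R(s, 750) - R(s, 705)) / (R(s, 750) + R(s, 705)),
    "mND705" = function(s) (R(s, 750) - R(s, 705)) /
      (R(s, 750) + R(s, 705) - 2 * R(s, 445)),
    "mSR705" = function(s) (R(s, 750) - R(s, 445)) / (R(s, 705) - R(s, 445)),
    "MTCI" = function(s) (R(s, 750) - R(s, 710)) / (R(s, 710) - R(s, 680)),
    "PRI" = function(s) (R(s, 531) - R(s, 570)) / (R(s, 531) + R(s, 570)),
    "TCARI" = function(s) 3 * ((R(s, 700) - R(s, 670)) -
      0.2 * (R(s, 700) - R(s, 550)) * (R(s, 700) / R(s, 670))),
    "OSAVI" = function(s) (1 + 0.16) * (R(s, 800) - R(s, 670)) /
      (R(s, 800) + R(s, 670) + 0.16),
    "TCARI/OSAVI" = function(s) (3 * ((R(s, 700) - R(s, 670)) -
      0.2 * (R(s, 700) - R(s, 550)) * (R(s, 700) / R(s, 670)))) /
      ((1 + 0.16) * (R(s, 800) - R(s, 670)) / (R(s, 800) + R(s, 670) + 0.16)),
    "DCNI" = function(s) (R(s, 720) - R(s, 700)) / (R(s, 700) - R(s, 670)) /
      (R(s, 720) - R(s, 670) + 0.03))
  for (k in 1:20) {
    s <- with_seed(100 + k, stats::runif(length(wl), 0.02, 0.9))
    for (nm in names(oracle))
      expect_equal(compute_vi(nm, s, wl), oracle[[nm]](s), tolerance = 1e-12,
                   label = nm)
  }
})

test_that("scale invariance matches each index's documented behaviour", {
  wl <- c(445, 470, 531, 550, 560, 570, 670, 675, 680, 700, 705, 710, 720,
          750, 800, 810)
  reg <- vi_registry()
  for (k in 1:5) {
    s <- with_seed(200 + k, stats::runif(length(wl), 0.05, 0.7))
    v1 <- compute_vis(s, wl)
    v2 <- compute_vis(2.5 * s, wl)
    for (i in seq_len(nrow(reg))) {
      nm <- reg$name[i]
      if (reg$scale_invariant[i])
        expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-10, label = nm)
      else
        expect_gt(abs(v2[[nm]] - v1[[nm]]), 1e-6, label = nm)
    }
  }
})

test_that("continuum removal has hull semantics", {
  wl <- seq(550, 750, by = 10)
  lin <- 0.2 + 0.001 * (wl - 550)
  cr <- continuum_removal(lin, wl)
  expect_equal(cr$values, rep(1, length(wl)), tolerance = 1e-12)
  # convex absorption dip: interior < 1, minimum at the dip centre
  dip <- 0.4 - 0.25 * exp(-((wl - 660)^2) / (2 * 30^2))
  crd <- continuum_removal(dip, wl)
  expect_equal(crd$values[1], 1)
  expect_equal(crd$values[length(wl)], 1)
  expect_true(all(crd$values[2:(length(wl) - 1)] < 1))
  expect_equal(wl[which.min(crd$values)], 660)
  expect_error(continuum_removal(c(0.2, -0.1, 0.3), c(600, 650, 700)),
               "positive")
  expect_error(continuum_removal(c(0.2, 0.3), c(600, 700)), "3 bands")
})

test_that("continuum removal equals the O(n^2) chord oracle", {
  brute_hull <- function(wl, v) {
    n <- length(wl)
    vapply(seq_len(n), function(i) {
      # the hull at i is the lowest chord that spans i and dominates all points
      best <- Inf
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (wl[a] > wl[i] || wl[b] < wl[i] || a == b) next
        chord <- v[a] + (v[b] - v[a]) * (wl - wl[a]) / (wl[b] - wl[a])
        if (all(v <= chord + 1e-9))
          best <- min(best, chord[i])
      }
      if (is.infinite(best)) v[i] else best
    }, numeric(1))
  }
  for (k in 1:5) {
    wl <- sort(with_seed(300 + k, stats::runif(20, 550, 750)))
    v <- with_seed(400 + k, stats::runif(20, 0.1, 0.6))
    cr <- continuum_removal(v, wl)
    expect_equal(cr$values, v / brute_hull(wl, v), tolerance = 1e-10)
    expect_true(all(cr$values <= 1 + 1e-12))
  }
})
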