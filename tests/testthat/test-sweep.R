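test_that("the tolerance-band rule picks the coarsest near-best resolution", {
  prof <- sensitivity_profile(data.frame(
    nominal_mm = c(1.3, 14, 28, 56), pixel_type = "all_leaf",
    method = "MTCI", scope = "RP", metric = "rho2",
    value = c(0.72, 0.72, 0.71, 0.60)))
  rep <- select_optimal_resolution(prof, "RP", delta = 0.03)
  expect_equal(rep$optimal_mm, 28)
  # strictly increasing and flat profiles both select the coarsest entry
  inc <- prof; inc$value <- c(0.5, 0.6, 0.7, 0.8)
  expect_equal(select_optimal_resolution(sensitivity_profile(inc), "RP")$optimal_mm, 56)
  flat <- prof; flat$value <- rep(0.7, 4)
  expect_equal(select_optimal_resolution(sensitivity_profile(flat), "RP")$optimal_mm, 56)
  # for an error metric, "best" is the minimum
  rms <- prof; rms$metric <- "rmse"; rms$value <- c(0.20, 0.21, 0.22, 0.35)
  expect_equal(select_optimal_resolution(sensitivity_profile(rms), "RP",
                                         delta = 0.03)$optimal_mm, 28)
  expect_error(select_optimal_resolution(prof[1, ], "RP"), "fewer than 2")
})

test_that("profile construction validates its columns", {
  expect_error(sensitivity_profile(data.frame(a = 1)), "missing columns")
})

test_that("a single-resolution sweep equals the direct computation", {
  exp <- generate_experiment(seed = 23, rows = 32L, cols = 32L, noise_sd = 0.01)
  ids <- exp$plots$scene[exp$plots$year == 1 & exp$plots$stage == "JT"]
  samples <- collect_samples(exp, scenes = ids, pixel_types = "all_leaf",
                             vi_names = "CI_Red-edge")
  prof <- run_resolution_sweep(exp, pixel_types = "all_leaf",
                               vi_names = "CI_Red-edge", samples = samples)
  cell <- prof[prof$scope == "JT" & prof$method == "CI_Red-edge", ]
  expect_equal(nrow(cell), 1L)
  d <- samples[samples$pixel_type == "all_leaf", ]
  ok <- is.finite(d[["CI_Red-edge"]])
  expect_equal(cell$value,
               spearman_rho2(d[["CI_Red-edge"]][ok], d$lnc[ok]))
})

test_that("sweeps are deterministic given the experiment seed", {
  lad <- build_resolution_ladder(1.3, 450)[c(1, 4, 6), ]
  run <- function() {
    exp <- generate_experiment(seed = 29, rows = 32L, cols = 32L,
                               noise_sd = 0.02)
    ids <- exp$plots$scene[exp$plots$year == 1 & exp$plots$stage == "LT"]
    samples <- collect_samples(exp, lad, scenes = ids,
                               pixel_types = "all_leaf", vi_names = "MTCI")
    run_resolution_sweep(exp, lad, pixel_types = "all_leaf",
                         vi_names = "MTCI", samples = samples)
  }
  a <- run(); b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("profile cells are reproducible from the cached sample table", {
  exp <- generate_experiment(seed = 31, rows = 32L, cols = 32L, noise_sd = 0.02)
  lad <- build_resolution_ladder(1.3, 450)[c(1, 4), ]
  ids <- exp$plots$scene[exp$plots$year == 1 & exp$plots$stage == "JT"]
  samples <- collect_samples(exp, lad, scenes = ids, pixel_types = "all_leaf",
                             vi_names = "MTCI")
  prof <- run_resolution_sweep(exp, lad, pixel_types = "all_leaf",
                               vi_names = "MTCI", samples = samples)
  cached <- attr(prof, "samples")
  for (r in unique(prof$nominal_mm)) {
    d <- cached[cached$nominal_mm == r & cached$pixel_type == "all_leaf", ]
    ok <- is.finite(d$MTCI)
    expect_equal(prof$value[prof$nominal_mm == r & prof$method == "MTCI"],
                 spearman_rho2(d$MTCI[ok], d$lnc[ok]))
  }
})
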