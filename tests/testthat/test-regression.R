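make_design_samples <- function(seed = 1L, n_per_block = 4L) {
  # small multi-stage sample table exercising the split logic
  with_seed(seed, {
    grid <- expand.grid(block = 1:3, rep = seq_len(n_per_block),
                        stage = c("ET", "LT", "JT", "BT", "HD", "FL"),
                        year = 1:2, stringsAsFactors = FALSE)
    n <- nrow(grid)
    X <- matrix(stats::runif(n * 10, 0.1, 0.7), n, 10)
    s <- make_samples(X, stats::runif(n, 1, 4), seq(500, 900, length.out = 10))
    s$block <- grid$block; s$stage <- grid$stage; s$year <- grid$year
    s
  })
}

test_that("replicate splitting is disjoint, 2:1, and scope-filtered", {
  s <- make_design_samples()
  sp <- split_by_replicate(s, "global")
  expect_equal(nrow(sp$calibration), 2 * nrow(sp$validation))
  expect_length(intersect(sp$calibration$scene, sp$validation$scene), 0)
  expect_true(all(sp$calibration$block %in% 1:2))
  expect_true(all(sp$validation$block == 3))
  rp <- split_by_replicate(s, "reproductive")
  expect_setequal(unique(c(rp$calibration$stage, rp$validation$stage)),
                  c("BT", "HD", "FL"))
  st <- split_by_replicate(s, "stage", stage = "ET", year = 1)
  expect_true(all(st$calibration$stage == "ET" & st$calibration$year == 1))
  veg <- split_by_replicate(s, "vegetative")
  expect_setequal(unique(veg$calibration$stage), c("ET", "LT", "JT"))
  expect_error(split_by_replicate(s, "stage", stage = "XX"), "no samples")
  # held-out block is configurable
  alt <- split_by_replicate(s, "global", validation_block = 1L)
  expect_true(all(alt$validation$block == 1))
})

test_that("spearman rho2 has rank semantics", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman_rho2(x, 2 * x + 1), 1)
  y <- c(3.2, 1.5, 4.8, 2.2, 5.1, 0.7)
  expect_equal(spearman_rho2(x, y), spearman_rho2(exp(x), y))  # rank invariance
  expect_error(spearman_rho2(1:2, 2:3), "3 complete")
  expect_warning(v <- spearman_rho2(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
})

test_that("spearman rho2 matches the direct rank-formula oracle", {
  for (k in 1:10) {
    xy <- with_seed(500 + k, list(x = stats::rnorm(6), y = stats::rnorm(6)))
    rx <- rank(xy$x); ry <- rank(xy$y)
    oracle <- (sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))^2
    expect_equal(spearman_rho2(xy$x, xy$y), oracle, tolerance = 1e-12)
  }
})

test_that("metrics follow their closed forms", {
  obs <- c(2, 3, 4, 5); pred <- c(2.5, 2.5, 4.5, 4.5)
  m <- regression_metrics(obs, pred)
  expect_equal(m$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_equal(m$rmse, sqrt(mean((obs - pred)^2)))
  perfect <- regression_metrics(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  # constant prediction at the validation mean gives R^2 = 0
  expect_equal(regression_metrics(obs, rep(mean(obs), 4))$r2, 0)
})

test_that("a noiseless linear LNC~VI relation validates perfectly", {
  s <- make_design_samples()
  s$NDVI <- 0.1 + 0.2 * s$lnc                  # exact linear index
  sp <- split_by_replicate(s, "global")
  m <- fit_lnc_vi(sp, "NDVI")
  expect_equal(m$validation$r2, 1, tolerance = 1e-10)
  expect_equal(m$validation$rmse, 0, tolerance = 1e-6)
  expect_equal(unname(coef(m)[2]), 5, tolerance = 1e-8)   # inverse slope
  expect_error(fit_lnc_vi(sp, "nope"), "not found")
  s$flat <- 1
  expect_error(fit_lnc_vi(split_by_replicate(s, "global"), "flat"),
               "zero variance")
})

test_that("the generating slope and intercept are recovered across seeds", {
  slopes <- intercepts <- numeric(0)
  for (k in 1:30) {
    s <- make_design_samples(seed = 600 + k)
    vi <- with_seed(700 + k, 0.05 + 0.21 * s$lnc + stats::rnorm(nrow(s), 0, 0.02))
    s$NDVI <- vi
    m <- fit_lnc_vi(split_by_replicate(s, "global"), "NDVI")
    # invert the fitted LNC = a + b VI back to VI = alpha + beta LNC
    slopes <- c(slopes, 1 / coef(m)[2])
    intercepts <- c(intercepts, -coef(m)[1] / coef(m)[2])
  }
  expect_lt(abs(mean(slopes) - 0.21), 2 * stats::sd(slopes))
  expect_lt(abs(mean(intercepts) - 0.05), 2 * stats::sd(intercepts))
  expect_lt(stats::sd(slopes), 0.02)
})

test_that("pure-noise targets rarely reach validation R^2 above 0.2", {
  r2 <- numeric(0)
  for (k in 1:40) {
    s <- with_seed(800 + k, {
      X <- matrix(stats::runif(36 * 5), 36, 5)
      out <- make_samples(X, stats::rnorm(36, 2.5, 0.5),
                          seq(500, 900, length.out = 5))
      out$NDVI <- stats::runif(36)
      out
    })
    m <- fit_lnc_vi(split_by_replicate(s, "global"), "NDVI")
    r2 <- c(r2, m$validation$r2)
  }
  expect_gte(mean(r2 <= 0.2), 0.95)
})

test_that("model methods behave like a classic fitted model object", {
  s <- make_design_samples()
  s$NDVI <- 0.1 + 0.2 * s$lnc + with_seed(1, stats::rnorm(nrow(s), 0, 0.05))
  m <- fit_lnc_vi(split_by_replicate(s, "global"), "NDVI")
  expect_length(coef(m), 2L)
  expect_equal(length(residuals(m)), m$n_cal)
  expect_equal(predict(m, c(0.5, 0.6)),
               unname(coef(m)[1] + coef(m)[2] * c(0.5, 0.6)))
  expect_s3_class(summary(m), "summary.lm")
  expect_output(print(m), "lnc_vi_model")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(m))
})
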