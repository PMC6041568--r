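#' Construct a sensitivity profile table
#'
#' A long table of metric values indexed by resolution, pixel type, method
#' and stage scope. [run_resolution_sweep()] produces these; the constructor
#' mainly validates hand-built profiles.
#'
#' @param df data.frame with at least `nominal_mm`, `pixel_type`, `method`,
#'   `scope`, `metric`, `value`.
#' @return object of class `sensitivity_profile`.
#' @export
sensitivity_profile <- function(df) {
  need <- c("nominal_mm", "pixel_type", "method", "scope", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("profile missing columns: ", paste(miss, collapse = ", "))
  structure(as.data.frame(df), class = c("sensitivity_profile", "data.frame"))
}

#' Sweep the resolution ladder and assemble sensitivity profiles
#'
#' For every ladder entry the pipeline aggregates, adapts thresholds,
#' classifies, extracts class-mean spectra (the whole-image rule applying at
#' entries too coarse to classify) and evaluates the requested models:
#' stage-scope squared Spearman correlations between each representative
#' index and LNC (`method = "vi"`), and global PLSR / GPR validation metrics
#' (`"plsr"`, `"gpr"`). Deterministic given the experiment (whose seed fixes
#' every scene) and `seed` (multi-start jitter of the GPR optimizer).
#'
#' @param experiment a [`rice_experiment`][generate_experiment].
#' @param ladder a [build_resolution_ladder()] table.
#' @param pixel_types leaf pixel types to profile.
#' @param methods subset of `"vi"`, `"plsr"`, `"gpr"`.
#' @param vi_names indices profiled when `"vi"` is requested.
#' @param spectra_kinds spectra inputs for the multivariate methods.
#' @param scopes stage scopes for the VI profiles: vegetative stages get one
#'   scope each, the post-booting stages pool into `"RP"`.
#' @param threshold_scope passed to [collect_samples()].
#' @param samples precomputed [collect_samples()] output (skips the image
#'   pipeline).
#' @param gpr_args list of extra arguments for [fit_gpr()].
#' @param verbose print progress.
#' @return a [sensitivity_profile()] with the sample table in
#'   `attr(, "samples")`.
#' @export
run_resolution_sweep <- function(experiment,
                                 ladder = build_resolution_ladder(
                                   experiment$pixel_size_mm, 450),
                                 pixel_types = c("all_leaf", "sunlit_leaf",
                                                 "shaded_leaf"),
                                 methods = "vi",
                                 vi_names = c("CI_Red-edge", "MTCI", "TCARI/OSAVI"),
                                 spectra_kinds = "reflectance",
                                 scopes = NULL,
                                 threshold_scope = "stage",
                                 samples = NULL,
                                 gpr_args = list(),
                                 verbose = FALSE) {
  stopifnot(inherits(experiment, "rice_experiment"))
  if (is.null(samples))
    samples <- collect_samples(experiment, ladder, pixel_types,
                               threshold_scope = threshold_scope,
                               vi_names = if ("vi" %in% methods) vi_names
                                          else vi_registry()$name[1],
                               verbose = verbose)
  if (is.null(scopes)) {
    veg <- intersect(c("ET", "LT", "JT"), unique(samples$stage))
    scopes <- c(veg, if (any(samples$stage %in% c("BT", "HD", "FL"))) "RP")
  }
  rows <- list()
  push <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  resolutions <- unique(samples[, c("nominal_mm", "realized_mm")])
  resolutions <- resolutions[order(resolutions$nominal_mm), ]
  for (ri in seq_len(nrow(resolutions))) {
    r <- resolutions$nominal_mm[ri]
    for (pt in pixel_types) {
      sub_rt <- samples[samples$nominal_mm == r & samples$pixel_type == pt, ]
      if ("vi" %in% methods) {
        for (sc in scopes) {
          in_scope <- if (sc == "RP") sub_rt$stage %in% c("BT", "HD", "FL")
                      else sub_rt$stage == sc
          d <- sub_rt[in_scope, ]
          for (vi in vi_names) {
            v <- d[[vi]]
            ok <- is.finite(v) & is.finite(d$lnc)
            val <- if (sum(ok) >= 3 && stats::sd(v[ok]) > 0)
              suppressWarnings(spearman_rho2(v[ok], d$lnc[ok])) else NA_real_
            push(nominal_mm = r, realized_mm = resolutions$realized_mm[ri],
                 pixel_type = pt, method = vi, spectra_kind = "vi",
                 scope = sc, metric = "rho2", value = val, n = sum(ok))
          }
        }
      }
      for (mtd in intersect(methods, c("plsr", "gpr"))) {
        for (sk in spectra_kinds) {
          flt <- filter_samples(samples, pt, r)
          res <- tryCatch({
            split <- split_by_replicate(flt, "global")
            fit <- if (mtd == "plsr") fit_plsr(split, sk)
                   else do.call(fit_gpr, c(list(split, sk), gpr_args))
            fit$validation
          }, error = function(e) {
            warning("sweep cell (", r, " mm, ", pt, ", ", mtd, ") failed: ",
                    conditionMessage(e))
            NULL
          })
          push(nominal_mm = r, realized_mm = resolutions$realized_mm[ri],
               pixel_type = pt, method = mtd, spectra_kind = sk,
               scope = "global", metric = "r2",
               value = if (is.null(res)) NA_real_ else res$r2,
               n = if (is.null(res)) 0L else res$n)
          push(nominal_mm = r, realized_mm = resolutions$realized_mm[ri],
               pixel_type = pt, method = mtd, spectra_kind = sk,
               scope = "global", metric = "rmse",
               value = if (is.null(res)) NA_real_ else res$rmse,
               n = if (is.null(res)) 0L else res$n)
        }
      }
    }
  }
  out <- sensitivity_profile(do.call(rbind, rows))
  attr(out, "samples") <- samples
  out
}

#' Select the optimal spatial resolution from a sensitivity profile
#'
#' The coarsest resolution whose metric is within `delta` of the best value
#' over the ladder: degrading resolution buys acquisition efficiency, so
#' among statistically similar resolutions the coarsest wins. For an
#' error-type metric (`"rmse"`) "within delta of the best" means at most
#' `min + delta`; otherwise at least `max - delta`.
#'
#' @param profile a [sensitivity_profile()].
#' @param scope scope to select within.
#' @param pixel_type,method,metric further cell selectors (defaulting to the
#'   first present).
#' @param delta tolerance band on the metric.
#' @return object of class `optimal_resolution_report`.
#' @export
select_optimal_resolution <- function(profile, scope, pixel_type = NULL,
                                      method = NULL, metric = NULL,
                                      delta = 0.03) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  d <- profile[profile$scope == scope, ]
  if (is.null(pixel_type)) pixel_type <- d$pixel_type[1]
  d <- d[d$pixel_type == pixel_type, ]
  if (is.null(method)) method <- d$method[1]
  d <- d[d$method == method, ]
  if (is.null(metric)) metric <- d$metric[1]
  d <- d[d$metric == metric & is.finite(d$value), ]
  if (nrow(d) < 2)
    stop("profile covers fewer than 2 resolutions for scope '", scope, "'")
  d <- d[order(d$nominal_mm), ]
  if (metric == "rmse") {
    best <- min(d$value)
    ok <- d$value <= best + delta
  } else {
    best <- max(d$value)
    ok <- d$value >= best - delta
  }
  chosen <- max(d$nominal_mm[ok])
  structure(list(scope = scope, pixel_type = pixel_type, method = method,
                 metric = metric, delta = delta,
                 optimal_mm = chosen,
                 value_at_optimum = d$value[d$nominal_mm == chosen][1],
                 value_at_best = best,
                 base_mm = min(d$nominal_mm),
                 value_at_base = d$value[1]),
            class = "optimal_resolution_report")
}

#' @export
print.optimal_resolution_report <- function(x, ...) {
  cat("<optimal_resolution_report> ", x$scope, " / ", x$pixel_type, " / ",
      x$method, ": optimal ", x$optimal_mm, " mm (", x$metric, " ",
      format(x$value_at_optimum, digits = 3), " vs best ",
      format(x$value_at_best, digits = 3), ", base ",
      format(x$value_at_base, digits = 3), " at ", x$base_mm,
      " mm; delta = ", x$delta, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.sensitivity_profile <- function(x, scope = NULL, method = NULL,
                                     metric = "rho2", ...) {
  d <- as.data.frame(x)
  if (is.null(scope)) scope <- d$scope[1]
  d <- d[d$scope == scope & d$metric == metric, ]
  if (is.null(method)) method <- d$method[1]
  d <- d[d$method == method & is.finite(d$value), ]
  if (!nrow(d)) stop("nothing to plot for this scope/method/metric")
  pts <- sort(unique(d$pixel_type))
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(pts)), "Dark 3")[
    seq_along(pts)], pts)
  graphics::plot(NA, xlim = range(d$nominal_mm), ylim = range(d$value),
                 log = "x", xlab = "resolution (mm)", ylab = metric,
                 main = paste(method, "-", scope), ...)
  for (pt in pts) {
    dd <- d[d$pixel_type == pt, ]
    dd <- dd[order(dd$nominal_mm), ]
    graphics::lines(dd$nominal_mm, dd$value, type = "b", col = cols[pt], pch = 16)
  }
  graphics::legend("bottomleft", legend = pts, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Write a sensitivity profile (and its samples) to CSV
#'
#' @param profile a [sensitivity_profile()].
#' @param path CSV path for the profile table.
#' @param samples_path optional CSV path for the underlying sample table.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, samples_path = NULL) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  if (!is.null(samples_path) && !is.null(attr(profile, "samples")))
    utils::write.csv(as.data.frame(attr(profile, "samples")), samples_path,
                     row.names = FALSE)
  invisible(path)
}
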