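#' Assemble modelling samples from an experiment
#'
#' Runs the image pipeline for every scene at the requested resolutions and
#' returns one sample per scene x resolution x pixel type: the class-mean
#' reflectance spectrum, the 16 registry indices computed from it, and the
#' design metadata (LNC, stage, year, treatment, replicate block).
#'
#' Per stage-date group the pipeline is: crop the middle half; classify at
#' base resolution with the default thresholds; pool the base class
#' proportions as the adaptation reference; then for each coarser ladder
#' entry aggregate, adapt the thresholds so the pooled class proportions
#' match the reference (`threshold_scope = "stage"`; `"plot"` adapts per
#' scene), classify, and average spectra per pixel type. Ladder entries too
#' coarse to leave more than one aggregated pixel fall back to the
#' whole-image rule: all leaf pixel types receive the base-resolution
#' whole-image mean spectrum.
#'
#' @param experiment a [`rice_experiment`][generate_experiment].
#' @param ladder a [build_resolution_ladder()] result, or `NULL` for base
#'   resolution only.
#' @param pixel_types subset of `all_leaf`, `sunlit_leaf`, `shaded_leaf`.
#' @param scenes scene numbers to process (default all).
#' @param threshold_scope `"stage"` pools the adaptation across the plots of
#'   a stage-date; `"plot"` adapts each scene separately.
#' @param vi_names registry indices to compute.
#' @param verbose print per-group progress.
#' @return object of class `lnc_samples`: a data.frame with one row per
#'   sample plus attributes `spectra` (matching matrix of mean spectra) and
#'   `wavelength`.
#' @export
collect_samples <- function(experiment, ladder = NULL,
                            pixel_types = c("all_leaf", "sunlit_leaf", "shaded_leaf"),
                            scenes = NULL,
                            threshold_scope = c("stage", "plot"),
                            vi_names = vi_registry()$name,
                            verbose = FALSE) {
  stopifnot(inherits(experiment, "rice_experiment"))
  threshold_scope <- match.arg(threshold_scope)
  if (is.null(ladder)) {
    ladder <- data.frame(nominal_mm = experiment$pixel_size_mm, factor = 1L,
                         realized_mm = experiment$pixel_size_mm)
  }
  plots <- experiment$plots
  if (!is.null(scenes)) plots <- plots[plots$scene %in% scenes, ]
  groups <- split(plots, list(plots$year, plots$stage), drop = TRUE)
  rows <- list()
  spectra <- list()
  for (g in groups) {
    if (verbose)
      message("stage ", g$stage[1], " year ", g$year[1], ": ", nrow(g), " scenes")
    res <- process_stage_group(experiment, g, ladder, pixel_types,
                               threshold_scope, vi_names)
    rows[[length(rows) + 1L]] <- res$table
    spectra[[length(spectra) + 1L]] <- res$spectra
  }
  tab <- do.call(rbind, rows)
  sp <- do.call(rbind, spectra)
  rownames(tab) <- NULL
  structure(tab, spectra = sp, wavelength = experiment$library$wavelength,
            class = c("lnc_samples", "data.frame"))
}

# pipeline for the scenes of one stage-date group
process_stage_group <- function(experiment, g, ladder, pixel_types,
                                threshold_scope, vi_names) {
  nsc <- nrow(g)
  defaults <- threshold_set()
  base <- vector("list", nsc)       # per-plot base products
  agg <- vector("list", nsc)        # per-plot aggregated cubes by entry
  entries <- ladder[ladder$factor > 1L, , drop = FALSE]
  for (s in seq_len(nsc)) {
    sc <- get_scene(experiment, g$scene[s])
    cube <- crop_middle_half(sc$cube)
    maps <- pixel_index_maps(cube)
    lab <- classify_from_indices(maps$evi, maps$pri, maps$tcari, defaults)
    cm <- class_map(matrix(lab, dim(cube$data)[1], dim(cube$data)[2]),
                    cube$pixel_size_mm, g$stage[s])
    base[[s]] <- list(
      counts = tabulate(lab + 1L, nbins = 5L),
      means = lapply(stats::setNames(pixel_types, pixel_types), function(pt)
        mean_spectrum_by_class(cube, cm, pt)),
      whole = coarsest_level_spectrum(cube))
    keep <- list()
    for (e in seq_len(nrow(entries))) {
      N <- entries$factor[e]
      d <- dim(cube$data)
      if (d[1] %/% N >= 1L && d[2] %/% N >= 1L && (d[1] %/% N) * (d[2] %/% N) > 1L)
        keep[[as.character(N)]] <- aggregate_cube(cube, N)
    }
    agg[[s]] <- keep
  }
  pooled_counts <- Reduce(`+`, lapply(base, `[[`, "counts"))
  reference <- proportions_from_counts(pooled_counts)
  wavelength <- experiment$library$wavelength
  out <- list(); osp <- list()
  add_row <- function(meta, entry, pt, ms) {
    vis <- if (ms$n > 0 || ms$pixel_type == "whole_image")
      compute_vis(ms$values, wavelength, vi_names)
    else stats::setNames(rep(NA_real_, length(vi_names)), vi_names)
    row <- data.frame(scene = meta$scene, year = meta$year, stage = meta$stage,
                      treatment = meta$treatment, n_rate = meta$n_rate,
                      density = meta$density, block = meta$block,
                      lnc = meta$lnc, nominal_mm = entry$nominal_mm,
                      realized_mm = entry$realized_mm,
                      pixel_type = pt, n_pixels = ms$n,
                      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <<- cbind(row, as.data.frame(as.list(vis),
                                                         check.names = FALSE))
    osp[[length(osp) + 1L]] <<- ms$values
  }
  base_entry <- ladder[ladder$factor == 1L, , drop = FALSE]
  if (nrow(base_entry))
    for (s in seq_len(nsc)) for (pt in pixel_types)
      add_row(g[s, ], base_entry[1, ], pt, base[[s]]$means[[pt]])
  for (e in seq_len(nrow(entries))) {
    N <- as.character(entries$factor[e])
    have <- !vapply(agg, function(a) is.null(a[[N]]), logical(1))
    if (!any(have)) {
      # whole-image rule: too coarse to classify, use the base whole-image mean
      for (s in seq_len(nsc)) for (pt in pixel_types)
        add_row(g[s, ], entries[e, ], pt, base[[s]]$whole)
      next
    }
    if (threshold_scope == "stage") {
      pooled <- list(evi = numeric(0), pri = numeric(0), tcari = numeric(0))
      for (s in which(have)) {
        m <- pixel_index_maps(agg[[s]][[N]])
        pooled$evi <- c(pooled$evi, as.numeric(m$evi))
        pooled$pri <- c(pooled$pri, as.numeric(m$pri))
        pooled$tcari <- c(pooled$tcari, as.numeric(m$tcari))
      }
      th <- suppressWarnings(
        adapt_thresholds(pooled, reference, stage = g$stage[1],
                         defaults = defaults))
    }
    for (s in seq_len(nsc)) {
      if (!have[s]) {
        for (pt in pixel_types) add_row(g[s, ], entries[e, ], pt, base[[s]]$whole)
        next
      }
      cube_e <- agg[[s]][[N]]
      if (threshold_scope == "plot")
        th <- suppressWarnings(
          adapt_thresholds(cube_e, proportions_from_counts(base[[s]]$counts),
                           stage = g$stage[s], defaults = defaults))
      cm <- classify_pixels(cube_e, th)
      for (pt in pixel_types)
        add_row(g[s, ], entries[e, ], pt, mean_spectrum_by_class(cube_e, cm, pt))
    }
  }
  list(table = do.call(rbind, out), spectra = do.call(rbind, osp))
}

proportions_from_counts <- function(n) {
  veg <- sum(n[2:5]); leaf <- n[2] + n[3]; pan <- n[4] + n[5]
  list(gf = veg / sum(n),
       leaf_share = if (veg > 0) leaf / veg else NA_real_,
       sunlit_leaf_share = if (leaf > 0) n[2] / leaf else NA_real_,
       sunlit_panicle_share = if (pan > 0) n[4] / pan else NA_real_)
}

#' Filter a sample table to one pixel type and resolution
#'
#' @param samples an `lnc_samples` table.
#' @param pixel_type pixel type to keep.
#' @param nominal_mm nominal resolution to keep (default: the finest present).
#' @return the filtered `lnc_samples`.
#' @export
filter_samples <- function(samples, pixel_type = "all_leaf", nominal_mm = NULL) {
  stopifnot(inherits(samples, "lnc_samples"))
  if (is.null(nominal_mm)) nominal_mm <- min(samples$nominal_mm)
  keep <- samples$pixel_type == pixel_type & samples$nominal_mm == nominal_mm
  subset_samples(samples, keep)
}

subset_samples <- function(samples, keep) {
  sp <- attr(samples, "spectra")
  out <- as.data.frame(samples)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, spectra = sp[keep, , drop = FALSE],
            wavelength = attr(samples, "wavelength"),
            class = c("lnc_samples", "data.frame"))
}

#' Split samples into calibration and validation sets by replicate block
#'
#' Two of the three replicate blocks calibrate, the third validates (2:1 by
#' design). The scope restricts the growth stages: `"global"` keeps all,
#' `"reproductive"` keeps the post-booting group (BT, HD, FL), `"stage"`
#' keeps a single stage-date (`stage` required; `year` optional for a
#' year-specific acquisition).
#'
#' @param samples an `lnc_samples` table (typically already filtered to one
#'   pixel type and resolution).
#' @param scope `"global"`, `"reproductive"` (post-booting stages),
#'   `"vegetative"` (pre-booting stages pooled), or `"stage"`.
#' @param stage,year stage-date selectors for `scope = "stage"`.
#' @param validation_block which replicate block is held out.
#' @return object of class `data_split` with `$calibration` and
#'   `$validation` sample tables.
#' @export
split_by_replicate <- function(samples,
                               scope = c("global", "reproductive",
                                         "vegetative", "stage"),
                               stage = NULL, year = NULL, validation_block = 3L) {
  stopifnot(inherits(samples, "lnc_samples"))
  scope <- match.arg(scope)
  keep <- switch(scope,
    global = rep(TRUE, nrow(samples)),
    reproductive = samples$stage %in% c("BT", "HD", "FL"),
    vegetative = samples$stage %in% c("ET", "LT", "JT"),
    stage = {
      if (is.null(stage)) stop("scope = 'stage' requires `stage`")
      k <- samples$stage == stage
      if (!is.null(year)) k <- k & samples$year == year
      k
    })
  if (!any(keep)) stop("no samples in scope '", scope, "'")
  sub <- subset_samples(samples, keep)
  cal <- subset_samples(sub, sub$block != validation_block)
  val <- subset_samples(sub, sub$block == validation_block)
  if (!nrow(cal) || !nrow(val))
    stop("empty calibration or validation set for scope '", scope, "'")
  structure(list(calibration = cal, validation = val, scope = scope,
                 stage = stage, year = year,
                 validation_block = validation_block),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> scope ", x$scope,
      if (!is.null(x$stage)) paste0(" (", x$stage,
        if (!is.null(x$year)) paste0(", year ", x$year), ")"),
      ": ", nrow(x$calibration), " calibration / ", nrow(x$validation),
      " validation samples (block ", x$validation_block, " held out)\n",
      sep = "")
  invisible(x)
}
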