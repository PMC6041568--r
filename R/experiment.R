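#' Two-year paddy experiment design
#'
#' The factorial layout behind the synthetic experiment: two cultivars
#' crossed with four nitrogen rates (0, 100, 200, 300 kg N/ha) where the two
#' intermediate rates are grown at two row spacings and the extremes at one,
#' giving 12 treatment combinations; three replicate blocks (36 plots per
#' acquisition); six acquisition dates per year spanning early tillering to
#' filling; two years. 6 x 2 x 36 = 432 scenes in total.
#'
#' @param n_blocks replicate blocks.
#' @param years number of years.
#' @param n_effect named additive LNC offsets (% dry mass) per nitrogen rate.
#' @param lnc_sd plot-level LNC noise sd (% dry mass).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(n_blocks = 3L, years = 2L,
                              n_effect = c(N0 = -0.45, N1 = -0.15,
                                           N2 = 0.15, N3 = 0.45),
                              lnc_sd = 0.12) {
  tr <- expand.grid(cultivar = c("V1", "V2"),
                    nd = c("N0.D1", "N1.D1", "N1.D2", "N2.D1", "N2.D2", "N3.D1"),
                    stringsAsFactors = FALSE)
  tr$n_rate <- sub("\\..*", "", tr$nd)
  tr$density <- sub(".*\\.", "", tr$nd)
  tr$nd <- NULL
  tr$treatment <- paste(tr$cultivar, tr$n_rate, tr$density, sep = "_")
  structure(list(treatments = tr, n_blocks = as.integer(n_blocks),
                 years = as.integer(years), stages = stage_defaults()$stage,
                 n_effect = n_effect, lnc_sd = lnc_sd),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", nrow(x$treatments), " treatments x ",
      x$n_blocks, " blocks x ", length(x$stages), " dates x ", x$years,
      " years = ",
      nrow(x$treatments) * x$n_blocks * length(x$stages) * x$years,
      " scenes\n", sep = "")
  invisible(x)
}

# one row per scene: treatment metadata plus simulated ground truth
design_plot_table <- function(design, seed) {
  sd_tab <- stage_defaults()
  g <- expand.grid(block = seq_len(design$n_blocks),
                   trt = seq_len(nrow(design$treatments)),
                   stage = design$stages,
                   year = seq_len(design$years),
                   stringsAsFactors = FALSE)
  tr <- design$treatments[g$trt, ]
  st <- sd_tab[match(g$stage, sd_tab$stage), ]
  n_idx <- as.integer(sub("N", "", tr$n_rate))        # 0..3
  with_seed(seed, {
    n <- nrow(g)
    lnc <- st$base_lnc + design$n_effect[tr$n_rate] +
      stats::rnorm(n, 0, design$lnc_sd)
    lnc <- pmin(4.9, pmax(0.6, lnc))
    gf <- st$green_fraction * (1 + 0.10 * (n_idx - 1.5) / 1.5) *
      ifelse(tr$density == "D2", 0.85, 1) + stats::rnorm(n, 0, 0.03)
    gf <- pmin(0.97, pmax(0.03, gf))
    shade <- pmin(0.6, pmax(0.2, 0.4 + stats::rnorm(n, 0, 0.04)))
    pan <- pmin(0.4, pmax(0, st$panicle_fraction * (1 + stats::rnorm(n, 0, 0.1))))
    pan[st$panicle_fraction == 0] <- 0
    data.frame(scene = seq_len(n), year = g$year, stage = g$stage,
               date_index = match(g$stage, design$stages),
               treatment = tr$treatment, cultivar = tr$cultivar,
               n_rate = tr$n_rate, density = tr$density, block = g$block,
               lnc = as.numeric(lnc), green_fraction = gf,
               shade_fraction = shade, panicle_fraction = pan,
               chl_slope = st$chl_slope, chl_intercept = st$chl_intercept,
               scene_seed = child_seed(seed, seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic experiment
#'
#' Draws the per-plot ground truth for every scene of the design - LNC from a
#' nitrogen-dilution trajectory (monotone stage decline, higher N rate giving
#' higher LNC, plot-level noise), green fraction depending on stage, N rate
#' and row spacing, shade and panicle fractions - and returns a lazy
#' collection: scenes are rendered on demand by [get_scene()] so that a
#' 432-scene experiment never has to reside in memory at once.
#'
#' @param design an [experiment_design()].
#' @param seed integer seed controlling everything (library, ground truth,
#'   per-scene noise).
#' @param rows,cols scene size in pixels.
#' @param noise_sd multiplicative reflectance noise sd.
#' @param clump_scale clump scale in base pixels.
#' @param wavelength_grid wavelength axis for the endmember library.
#' @param pixel_size_mm base resolution, mm.
#' @return object of class `rice_experiment`: the design, the per-scene
#'   ground-truth table `$plots`, the endmember `$library`, and the scene
#'   rendering parameters.
#' @export
generate_experiment <- function(design = experiment_design(), seed = 1L,
                                rows = 128L, cols = 128L, noise_sd = 0.02,
                                clump_scale = 8,
                                wavelength_grid = seq(400, 900, by = 2),
                                pixel_size_mm = 1.3) {
  stopifnot(inherits(design, "experiment_design"))
  library <- generate_endmembers(wavelength_grid, seed = child_seed(seed, 0L))
  plots <- design_plot_table(design, seed = child_seed(seed, 1L))
  structure(list(design = design, plots = plots, library = library,
                 rows = as.integer(rows), cols = as.integer(cols),
                 noise_sd = noise_sd, clump_scale = clump_scale,
                 pixel_size_mm = pixel_size_mm, seed = as.integer(seed)),
            class = "rice_experiment")
}

#' @export
print.rice_experiment <- function(x, ...) {
  cat("<rice_experiment> ", nrow(x$plots), " scenes (",
      length(unique(x$plots$stage)), " stages x ",
      length(unique(x$plots$year)), " years), ", x$rows, " x ", x$cols,
      " px @ ", x$pixel_size_mm, " mm, noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Render one scene of an experiment
#'
#' @param experiment a [`rice_experiment`][generate_experiment].
#' @param i scene number (row of `experiment$plots`).
#' @return list with `cube`, `classmap` and `meta` (the plot-table row).
#' @export
get_scene <- function(experiment, i) {
  stopifnot(inherits(experiment, "rice_experiment"))
  p <- experiment$plots[i, ]
  cfg <- scene_config(stage = p$stage, lnc = p$lnc,
                      green_fraction = p$green_fraction,
                      shade_fraction = p$shade_fraction,
                      panicle_fraction = p$panicle_fraction,
                      chl_slope = p$chl_slope, chl_intercept = p$chl_intercept,
                      noise_sd = experiment$noise_sd,
                      clump_scale = experiment$clump_scale,
                      rows = experiment$rows, cols = experiment$cols,
                      pixel_size_mm = experiment$pixel_size_mm,
                      seed = p$scene_seed)
  sc <- generate_scene(cfg, experiment$library)
  sc$meta <- p
  sc
}

#' Write an experiment to disk as ENVI cubes plus a metadata sidecar
#'
#' Each scene is written as `scene_<i>` (binary + `.hdr`) with its true class
#' map as `scene_<i>_classes`; plot metadata and true LNC go to
#' `plots.csv`.
#'
#' @param experiment a [`rice_experiment`][generate_experiment].
#' @param outdir output directory (created if needed).
#' @param scenes which scene numbers to write (default all).
#' @param interleave ENVI interleave for the cubes.
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(experiment, outdir, scenes = NULL,
                             interleave = "bil") {
  stopifnot(inherits(experiment, "rice_experiment"))
  if (is.null(scenes)) scenes <- experiment$plots$scene
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in scenes) {
    sc <- get_scene(experiment, i)
    write_cube(sc$cube, file.path(outdir, paste0("scene_", i)),
               interleave = interleave)
    write_classmap(sc$classmap, file.path(outdir, paste0("scene_", i, "_classes")))
  }
  utils::write.csv(experiment$plots[experiment$plots$scene %in% scenes, ],
                   file.path(outdir, "plots.csv"), row.names = FALSE)
  invisible(outdir)
}
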