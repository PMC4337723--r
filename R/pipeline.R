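#' Simulate a full gradient-chamber experiment
#'
#' Samples and renders one field per stage position along the chamber,
#' deriving a deterministic per-field seed from the top-level seed.
#'
#' @param config a [chamber_config()].
#' @param model a [response_model()].
#' @param positions_cm stage positions along the chamber; default
#'   `n_positions` evenly spaced fields spanning the channel.
#' @param n_positions number of fields when `positions_cm` is not given.
#' @param n_cells cells per field.
#' @param seed top-level seed.
#' @param ... further arguments passed to [sample_scene()] and, via the
#'   `render_` prefix, none; rendering uses defaults unless `render_args`
#'   is supplied.
#' @param render_args named list of arguments for [render_scene()].
#' @return list with `scenes` and `images` (parallel lists, one per
#'   position), `config`, `model`, `positions_cm`, `seed`.
#' @export
simulate_experiment <- function(config, model, positions_cm = NULL,
                                n_positions = 16, n_cells = 100, seed = 1,
                                ..., render_args = list()) {
  if (is.null(positions_cm)) {
    # keep fields away from the exact ends so bins at both extremes populate
    positions_cm <- seq(0, config$channel_length_cm,
                        length.out = n_positions)
  }
  scenes <- vector("list", length(positions_cm))
  images <- vector("list", length(positions_cm))
  for (i in seq_along(positions_cm)) {
    s <- derive_seed(seed, i)
    scenes[[i]] <- sample_scene(config, model, positions_cm[i], n_cells,
                                seed = s, ...)
    images[[i]] <- do.call(render_scene, c(list(scenes[[i]]), render_args))
  }
  list(scenes = scenes, images = images, config = config, model = model,
       positions_cm = positions_cm, seed = seed)
}

#' Segment and measure a set of chamber fields
#'
#' Runs [segment_nuclei()], [derive_cell_regions()] and [measure_cells()] on
#' each field and row-binds the per-cell measurements, tagging each row with
#' its field index. Fields in which no cell is detected are skipped with a
#' message rather than aborting the run.
#'
#' @param images list of `flow_image` objects (or a single one).
#' @param config optional [chamber_config()] to attach shear values.
#' @param segment_args,region_args named lists of arguments for
#'   [segment_nuclei()] and [derive_cell_regions()].
#' @return tibble of per-cell measurements with an `image` column.
#' @export
analyze_images <- function(images, config = NULL,
                           segment_args = list(), region_args = list()) {
  if (inherits(images, "flow_image")) images <- list(images)
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    masks <- do.call(segment_nuclei, c(list(img), segment_args))
    if (max(masks$nuclei) == 0L) {
      message(sprintf("image %d: no cells detected, skipped", i))
      next
    }
    masks <- do.call(derive_cell_regions,
                     c(list(masks, channel2 = img$ch2), region_args))
    m <- measure_cells(masks, img, config = config)
    m$image <- i
    out[[i]] <- m
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) stop("no cells detected in any image", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Run the full set-point analysis pipeline
#'
#' Composes simulation (or supplied images), segmentation, per-cell
#' morphometry, shear binning, LOWESS smoothing and set-point estimation.
#' Fully deterministic for a given configuration and seed.
#'
#' @param config a [chamber_config()].
#' @param model a [response_model()] used to simulate when no `images` are
#'   supplied.
#' @param images optional list of `flow_image`s to analyse instead of
#'   simulating.
#' @param response response to aggregate (`"orientation_deg"` or `"tf"`).
#' @param direction optimum direction for [estimate_set_point()].
#' @param n_positions,n_cells,seed simulation size and seed.
#' @param n_bins,frac binning and smoothing parameters.
#' @param criterion_fraction,baseline set-point criterion parameters.
#' @param out_dir optional directory; when given, writes
#'   `measurements.csv`, `response_curve.csv` and `set_point.json`.
#' @return list with `measurements`, `curve`, `set_point`, `anova` and the
#'   parameters used.
#' @export
run_pipeline <- function(config, model = NULL, images = NULL,
                         response = "orientation_deg",
                         direction = "min",
                         n_positions = 16, n_cells = 100, seed = 1,
                         n_bins = 15, frac = 0.5,
                         criterion_fraction = 0.8, baseline = NULL,
                         out_dir = NULL) {
  if (is.null(images)) {
    if (is.null(model)) stop("supply either `images` or a `model`",
                             call. = FALSE)
    sim <- simulate_experiment(config, model, n_positions = n_positions,
                               n_cells = n_cells, seed = seed)
    images <- sim$images
  }
  measurements <- analyze_images(images, config = config)
  curve <- bin_by_shear(measurements, response = response, config = config,
                        n_bins = n_bins)
  curve <- smooth_lowess(curve, frac = frac)
  sp <- estimate_set_point(curve, direction = direction,
                           criterion_fraction = criterion_fraction,
                           baseline = baseline)
  bin_f <- cut(measurements$shear_dyn_cm2,
               seq(min(c(config$shear_inlet_dyn_cm2,
                         config$shear_outlet_dyn_cm2)),
                   max(c(config$shear_inlet_dyn_cm2,
                         config$shear_outlet_dyn_cm2)),
                   length.out = n_bins + 1), include.lowest = TRUE)
  aov_res <- anova_shear_effect(measurements[[response]], bin_f)
  result <- list(measurements = measurements, curve = curve,
                 set_point = sp, anova = aov_res,
                 params = list(response = response, direction = direction,
                               n_bins = n_bins, frac = frac,
                               criterion_fraction = criterion_fraction,
                               seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measurements,
                     file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(curve),
                     file.path(out_dir, "response_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(unclass(sp), list(anova = aov_res, params = result$params)),
      file.path(out_dir, "set_point.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
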