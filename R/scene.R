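#' Sample a ground-truthed field of cells at one chamber position
#'
#' Generates the ground truth for one microscope field: cell centroids placed
#' by rejection sampling with a minimum spacing (so nuclei never overlap),
#' per-cell signed nuclear orientation drawn from a wrapped-normal
#' distribution whose population mean folded angle matches the response model
#' at the local shear, and a per-cell true nuclear transcription-factor
#' fraction drawn from a Beta distribution around the model target. The flow
#' direction is the image x-axis by convention.
#'
#' @param config a [chamber_config()]; gives the local shear at `x_cm`.
#' @param model a [response_model()].
#' @param x_cm axial stage position of the field within the chamber (cm).
#' @param n_cells number of cells to place (>= 1).
#' @param seed integer seed; identical arguments give an identical scene.
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um microns per pixel (default 0.65, a typical 20x
#'   confocal scale).
#' @param semi_major_um,semi_minor_um nuclear ellipse semi-axes in microns.
#' @param min_spacing_um minimum centroid spacing; the default (2.2 x the
#'   semi-major axis) guarantees non-overlapping nuclei.
#' @return an object of class `flow_scene`: field geometry plus a tibble
#'   `cells` with columns `id`, `cx_px`, `cy_px`, `a_um`, `b_um`,
#'   `theta_deg` (signed, in (-90, 90]), `tf_true`, `shear_dyn_cm2`.
#' @export
sample_scene <- function(config, model, x_cm, n_cells, seed = 1,
                         width_px = 512, height_px = 512,
                         pixel_size_um = 0.65,
                         semi_major_um = 8, semi_minor_um = 5,
                         min_spacing_um = 2.2 * semi_major_um) {
  stopifnot(inherits(config, "chamber_config"),
            inherits(model, "response_model"),
            n_cells >= 1)
  shear <- position_to_shear(config, x_cm)
  spacing_px <- min_spacing_um / pixel_size_um
  margin_px <- semi_major_um / pixel_size_um + 2
  lo_x <- margin_px; hi_x <- width_px - margin_px
  lo_y <- margin_px; hi_y <- height_px - margin_px
  if (hi_x <= lo_x || hi_y <= lo_y) {
    stop("field too small for the nucleus size", call. = FALSE)
  }
  # generous feasibility bound: disks of radius spacing/2 must fit
  capacity <- floor((hi_x - lo_x) * (hi_y - lo_y) / (0.7 * spacing_px^2))
  if (n_cells > capacity) {
    stop(sprintf(
      "infeasible packing: %d cells requested but at most ~%d fit a %dx%d px field at %.1f um spacing",
      n_cells, capacity, width_px, height_px, min_spacing_um), call. = FALSE)
  }

  with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0)
    attempts <- 0L
    max_attempts <- 400L * n_cells
    while (length(cx) < n_cells && attempts < max_attempts) {
      attempts <- attempts + 1L
      px <- stats::runif(1, lo_x, hi_x)
      py <- stats::runif(1, lo_y, hi_y)
      if (length(cx) == 0 ||
          min((cx - px)^2 + (cy - py)^2) >= spacing_px^2) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
    }
    if (length(cx) < n_cells) {
      stop(sprintf(
        "infeasible packing: placed %d of %d cells after %d attempts",
        length(cx), n_cells, attempts), call. = FALSE)
    }
    theta <- sample_angles(n_cells, target_angle(model, shear),
                           model$angle_concentration)
    tf <- sample_tf(n_cells, target_tf(model, shear),
                    model$tf_concentration)

    structure(
      list(width_px = as.integer(width_px),
           height_px = as.integer(height_px),
           pixel_size_um = pixel_size_um,
           x_cm = x_cm,
           shear_dyn_cm2 = shear,
           seed = seed,
           cells = tibble::tibble(
             id = seq_len(n_cells),
             cx_px = cx, cy_px = cy,
             a_um = semi_major_um, b_um = semi_minor_um,
             theta_deg = theta, tf_true = tf,
             shear_dyn_cm2 = shear)),
      class = "flow_scene")
  })
}

#' @export
print.flow_scene <- function(x, ...) {
  cat(sprintf(
    "flow_scene: %d cells, %dx%d px (%.2f um/px), x = %.2f cm, shear = %.2f dyn/cm^2\n",
    nrow(x$cells), x$width_px, x$height_px, x$pixel_size_um, x$x_cm,
    x$shear_dyn_cm2))
  invisible(x)
}

# Logical pixel mask of a rotated ellipse, returned as (row, col) indices.
# Coordinates: col = image x (flow axis), row = image y; theta in degrees
# from +x toward +y.
ellipse_indices <- function(cx, cy, a_px, b_px, theta_deg, width, height) {
  r <- ceiling(max(a_px, b_px)) + 1
  cols <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
  rows <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
  xg <- matrix(cols, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  yg <- matrix(rows, nrow = length(rows), ncol = length(cols))
  th <- theta_deg * pi / 180
  u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
  v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  cbind(row = yg[inside], col = xg[inside])
}

# True nucleus and cytoplasm-annulus masks of a scene as label matrices.
scene_masks <- function(scene, annulus_um = 6) {
  px <- scene$pixel_size_um
  nuc <- matrix(0L, scene$height_px, scene$width_px)
  ann <- matrix(0L, scene$height_px, scene$width_px)
  t_px <- annulus_um / px
  for (i in seq_len(nrow(scene$cells))) {
    cl <- scene$cells[i, ]
    idx_n <- ellipse_indices(cl$cx_px, cl$cy_px, cl$a_um / px, cl$b_um / px,
                             cl$theta_deg, scene$width_px, scene$height_px)
    idx_o <- ellipse_indices(cl$cx_px, cl$cy_px, cl$a_um / px + t_px,
                             cl$b_um / px + t_px, cl$theta_deg,
                             scene$width_px, scene$height_px)
    ann[idx_o] <- cl$id
    nuc[idx_n] <- cl$id
  }
  ann[nuc > 0L] <- 0L
  list(nucleus = nuc, annulus = ann)
}

#' Render a scene into a two-channel fluorescence image
#'
#' Channel 1 is the nuclear stain: each nucleus is a filled ellipse of
#' constant intensity. Channel 2 is the transcription-factor stain: each
#' cell's total intensity is split between its nucleus and a surrounding
#' cytoplasmic annulus in proportion `tf_true : (1 - tf_true)`, spread
#' uniformly over the respective pixels. Both channels are convolved with a
#' Gaussian point-spread function, offset by a constant background, degraded
#' with additive Gaussian read noise, and quantised to unsigned 16-bit
#' counts. Default intensities leave ample headroom below saturation; if any
#' pixel does saturate a warning is raised and the count recorded in the
#' result.
#'
#' @param scene a [sample_scene()] result.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (0 = no
#'   blur).
#' @param background constant background offset, counts.
#' @param noise_sd additive Gaussian noise standard deviation, counts
#'   (0 = noise-free).
#' @param nucleus_intensity channel-1 intensity of a nucleus pixel above
#'   background, counts.
#' @param tf_total_intensity channel-2 integrated intensity per cell, counts.
#' @param annulus_um cytoplasm annulus thickness in microns (the generated
#'   ground-truth cell boundary).
#' @param seed seed for the noise stream.
#' @return an object of class `flow_image`: integer matrices `ch1`, `ch2`
#'   (rows = image y, cols = image x), `pixel_size_um`, `x_cm`, the true
#'   masks used, a `saturated` pixel count, and the render parameters.
#' @export
render_scene <- function(scene, psf_sigma_px = 1, background = 200,
                         noise_sd = 20, nucleus_intensity = 8000,
                         tf_total_intensity = 150000, annulus_um = 6,
                         seed = scene$seed + 1) {
  stopifnot(inherits(scene, "flow_scene"))
  masks <- scene_masks(scene, annulus_um = annulus_um)
  ch1 <- matrix(0, scene$height_px, scene$width_px)
  ch2 <- matrix(0, scene$height_px, scene$width_px)
  ch1[masks$nucleus > 0L] <- nucleus_intensity
  if (nrow(scene$cells) > 0) {
    n_area <- tabulate(masks$nucleus[masks$nucleus > 0L],
                       nbins = nrow(scene$cells))
    a_area <- tabulate(masks$annulus[masks$annulus > 0L],
                       nbins = nrow(scene$cells))
    tf <- scene$cells$tf_true
    nuc_per_px <- ifelse(n_area > 0, tf_total_intensity * tf / n_area, 0)
    ann_per_px <- ifelse(a_area > 0,
                         tf_total_intensity * (1 - tf) / a_area, 0)
    nz <- masks$nucleus > 0L
    ch2[nz] <- nuc_per_px[masks$nucleus[nz]]
    az <- masks$annulus > 0L
    ch2[az] <- ann_per_px[masks$annulus[az]]
  }
  if (psf_sigma_px > 0) {
    ch1 <- as.matrix(EBImage::gblur(EBImage::Image(ch1),
                                    sigma = psf_sigma_px))
    ch2 <- as.matrix(EBImage::gblur(EBImage::Image(ch2),
                                    sigma = psf_sigma_px))
  }
  ch1 <- ch1 + background
  ch2 <- ch2 + background
  if (noise_sd > 0) {
    with_seed(seed, {
      ch1 <- ch1 + stats::rnorm(length(ch1), 0, noise_sd)
      ch2 <- ch2 + stats::rnorm(length(ch2), 0, noise_sd)
    })
  }
  qmax <- 65535L
  saturated <- sum(ch1 > qmax) + sum(ch2 > qmax)
  if (saturated > 0) {
    warning(sprintf("%d saturated pixels at the requested gains", saturated))
  }
  ch1 <- matrix(as.integer(pmin(pmax(round(ch1), 0), qmax)),
                scene$height_px, scene$width_px)
  ch2 <- matrix(as.integer(pmin(pmax(round(ch2), 0), qmax)),
                scene$height_px, scene$width_px)
  structure(
    list(ch1 = ch1, ch2 = ch2,
         pixel_size_um = scene$pixel_size_um,
         x_cm = scene$x_cm,
         shear_dyn_cm2 = scene$shear_dyn_cm2,
         true_masks = masks,
         saturated = saturated,
         params = list(psf_sigma_px = psf_sigma_px, background = background,
                       noise_sd = noise_sd,
                       nucleus_intensity = nucleus_intensity,
                       tf_total_intensity = tf_total_intensity,
                       annulus_um = annulus_um, seed = seed)),
    class = "flow_image")
}

#' @export
print.flow_image <- function(x, ...) {
  cat(sprintf(
    "flow_image: 2 channels, %dx%d px (%.2f um/px), x = %.2f cm, %d saturated px\n",
    ncol(x$ch1), nrow(x$ch1), x$pixel_size_um, x$x_cm, x$saturated))
  invisible(x)
}
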