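#' Orientation of a binary region relative to the flow axis
#'
#' Fits the region with the ellipse sharing its second central moments and
#' returns the acute angle between the ellipse major axis and the flow
#' direction (the image x-axis), folded into \[0, 90\] degrees. When the
#' moment tensor is degenerate (equal eigenvalues: a circle or a perfectly
#' symmetric cross) the major axis is undefined and `NA` is returned so the
#' cell can be excluded from averages.
#'
#' @param region logical matrix marking the region's pixels, or an integer
#'   label matrix together with `label`.
#' @param label label id when `region` is a label matrix.
#' @return angle in degrees in \[0, 90\], or `NA_real_` if degenerate or the
#'   region has fewer than 5 pixels.
#' @export
orientation <- function(region, label = NULL) {
  if (!is.null(label)) region <- region == label
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) < 5) return(NA_real_)
  x <- idx[, 2]; y <- idx[, 1]  # col = flow axis
  mu20 <- stats::var(x) ; mu02 <- stats::var(y)
  mu11 <- stats::cov(x, y)
  if (abs(mu20 - mu02) < 1e-12 && abs(mu11) < 1e-12) return(NA_real_)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  fold_angle(theta)
}

#' Nuclear translocation factor of a single cell
#'
#' TF = integrated background-subtracted transcription-factor intensity in
#' the nucleus divided by that in the whole cell, so TF = 1 when the entire
#' signal is nuclear and TF = 0 when it is entirely cytoplasmic. Both sums
#' are clipped at zero; if the whole-cell sum is non-positive after
#' background subtraction the ratio is undefined and `NA` is returned.
#'
#' @param nucleus logical matrix marking the nucleus pixels.
#' @param cell logical matrix marking the whole-cell pixels (must contain
#'   the nucleus).
#' @param channel2 transcription-factor channel matrix.
#' @param background scalar background level subtracted from every pixel
#'   (use 0 for literal, background-free quantification).
#' @return TF in \[0, 1\], or `NA_real_` if undefined.
#' @export
translocation_factor <- function(nucleus, cell, channel2, background = 0) {
  if (any(nucleus & !cell)) {
    stop("nucleus region must be contained in the cell region",
         call. = FALSE)
  }
  num <- max(0, sum(channel2[nucleus]) - background * sum(nucleus))
  den <- max(0, sum(channel2[cell]) - background * sum(cell))
  if (den <= 0) return(NA_real_)
  min(1, num / den)
}

#' Estimate the extracellular background level
#'
#' The mode (most frequent rounded value) of the pixels outside every cell
#' region: with no stain outside cells this is the camera offset plus the
#' centre of the noise distribution.
#'
#' @param channel2 intensity matrix.
#' @param cells integer label matrix of cell regions (0 = background).
#' @return scalar background level.
#' @export
estimate_background <- function(channel2, cells) {
  out <- channel2[cells == 0L]
  if (length(out) == 0) return(0)
  tab <- table(round(out))
  as.numeric(names(tab)[which.max(tab)])
}

#' Measure every cell of a segmented field
#'
#' Computes, per labelled cell: nuclear orientation relative to flow
#' ([orientation()]), translocation factor ([translocation_factor()] with a
#' shared background estimate) and nucleus / whole-cell areas. Moment and
#' intensity sums are accumulated in one vectorised pass over the label
#' images, so large fields stay fast.
#'
#' @param masks a `labeled_masks` with cell regions
#'   (see [derive_cell_regions()]).
#' @param channel2 transcription-factor channel matrix or a `flow_image`.
#' @param x_cm chamber stage position of the field (optional).
#' @param config optional [chamber_config()]; if given together with `x_cm`,
#'   a `shear_dyn_cm2` column is added via [position_to_shear()].
#' @param background background level for TF; `NULL` (default) estimates it
#'   with [estimate_background()], 0 disables subtraction.
#' @return a tibble with one row per cell: `label`, `orientation_deg`,
#'   `tf`, `area_nucleus_um2`, `area_cell_um2`, `degenerate` flag, plus
#'   `x_cm` and `shear_dyn_cm2` when available.
#' @export
measure_cells <- function(masks, channel2, x_cm = NULL, config = NULL,
                          background = NULL) {
  stopifnot(inherits(masks, "labeled_masks"))
  if (inherits(channel2, "flow_image")) {
    if (is.null(x_cm)) x_cm <- channel2$x_cm
    channel2 <- channel2$ch2
  }
  if (is.null(masks$cells)) {
    stop("cell regions missing: run derive_cell_regions() first",
         call. = FALSE)
  }
  nuc <- masks$nuclei; cells <- masks$cells
  n <- max(nuc, 0L)
  if (n == 0L) {
    out <- tibble::tibble(label = integer(0), orientation_deg = numeric(0),
                          tf = numeric(0), area_nucleus_um2 = numeric(0),
                          area_cell_um2 = numeric(0), degenerate = logical(0))
    if (!is.null(x_cm)) out$x_cm <- numeric(0)
    if (!is.null(config)) out$shear_dyn_cm2 <- numeric(0)
    return(out)
  }
  if (is.null(background)) background <- estimate_background(channel2, cells)

  # vectorised per-label moments over nucleus pixels
  nz <- which(nuc > 0L)
  lab <- nuc[nz]
  yy <- (nz - 1L) %% nrow(nuc) + 1L
  xx <- (nz - 1L) %/% nrow(nuc) + 1L
  cnt <- tabulate(lab, nbins = n)
  sx <- rowsum(xx, lab)[, 1] ; sy <- rowsum(yy, lab)[, 1]
  mx <- sx / cnt ; my <- sy / cnt
  dx <- xx - mx[lab] ; dy <- yy - my[lab]
  mu20 <- rowsum(dx * dx, lab)[, 1] / cnt
  mu02 <- rowsum(dy * dy, lab)[, 1] / cnt
  mu11 <- rowsum(dx * dy, lab)[, 1] / cnt
  degenerate <- (abs(mu20 - mu02) < 1e-12 & abs(mu11) < 1e-12) | cnt < 5
  theta <- fold_angle(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
  theta[degenerate] <- NA_real_

  # vectorised TF: background-subtracted sums per label, clipped at 0
  nuc_sum <- rowsum(as.numeric(channel2[nz]) - background, lab)[, 1]
  cz <- which(cells > 0L)
  clab <- cells[cz]
  cell_cnt <- tabulate(clab, nbins = n)
  cell_sum <- rowsum(as.numeric(channel2[cz]) - background, clab)[, 1]
  nuc_sum <- pmax(0, nuc_sum)
  cell_sum <- pmax(0, cell_sum)
  tf <- ifelse(cell_sum > 0, pmin(1, nuc_sum / cell_sum), NA_real_)

  px2 <- masks$pixel_size_um^2
  out <- tibble::tibble(label = seq_len(n),
                        cx_px = mx, cy_px = my,
                        orientation_deg = theta,
                        tf = tf,
                        area_nucleus_um2 = cnt * px2,
                        area_cell_um2 = cell_cnt * px2,
                        degenerate = degenerate)
  if (!is.null(x_cm)) out$x_cm <- x_cm
  if (!is.null(config) && !is.null(x_cm)) {
    out$shear_dyn_cm2 <- position_to_shear(config, x_cm)
  }
  out
}

#' Area under a fluorescence line profile
#'
#' Trapezoidal integral of a background-subtracted line-scan fluorescence
#' profile over distance; negative background-subtracted intensities are
#' clipped at zero. Used e.g. to quantify total signal across a vessel wall
#' from a line scan.
#'
#' @param distance_um strictly increasing sample positions in microns.
#' @param intensity fluorescence values at those positions.
#' @param background scalar background level to subtract.
#' @return a list with `auc` (intensity x um) and `auc_per_um` (the same
#'   integral normalised by profile length; reported alongside since the
#'   appropriate normalisation is application-dependent).
#' @export
profile_auc <- function(distance_um, intensity, background = 0) {
  if (length(distance_um) < 2 || length(intensity) != length(distance_um)) {
    stop("need >= 2 samples with matching distance and intensity",
         call. = FALSE)
  }
  if (any(diff(distance_um) <= 0)) {
    stop("profile distances must be strictly increasing", call. = FALSE)
  }
  y <- pmax(0, intensity - background)
  n <- length(y)
  auc <- sum(diff(distance_um) * (y[-1] + y[-n]) / 2)
  span <- distance_um[n] - distance_um[1]
  list(auc = auc, auc_per_um = auc / span)
}

#' Read a two-column line profile from CSV
#'
#' @param path CSV file with columns distance (um) and intensity.
#' @return a tibble with columns `distance_um`, `intensity`.
#' @export
read_line_profile <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected a 2-column CSV", call. = FALSE)
  tibble::tibble(distance_um = df[[1]], intensity = df[[2]])
}
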