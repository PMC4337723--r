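#' Segment nuclei from the nuclear-stain channel
#'
#' Implements the masking recipe used for the chamber micrographs: contrast-
#' limited adaptive histogram equalization (CLAHE), a relative intensity
#' threshold (Otsu by default), connected-component labelling
#' (8-connectivity) and removal of components outside a plausible nuclear
#' area range. The image is rescaled to \[0, 1\] by its own range before
#' equalization, so segmentation is invariant to multiplying the input by a
#' positive constant.
#'
#' @param image single-channel 2-D numeric matrix (rows = image y,
#'   cols = image x) or a `flow_image` (its `ch1` is used).
#' @param pixel_size_um microns per pixel (taken from a `flow_image`
#'   automatically).
#' @param clahe_nx,clahe_limit CLAHE tile grid size and clip limit.
#' @param threshold `"otsu"` or `"quantile"`.
#' @param quantile threshold quantile when `threshold = "quantile"`.
#' @param min_area_um2,max_area_um2 retained component area range in square
#'   microns.
#' @param split_touching if `TRUE`, apply a distance-transform watershed to
#'   split touching nuclei (off by default).
#' @return an object of class `labeled_masks`: integer label matrix
#'   `nuclei` (0 = background, labels contiguous 1..N), `cells` (`NULL`
#'   until [derive_cell_regions()] is run), `pixel_size_um` and the
#'   parameters used (`provenance`).
#' @export
segment_nuclei <- function(image, pixel_size_um = NULL,
                           clahe_nx = 8, clahe_limit = 2,
                           threshold = c("otsu", "quantile"),
                           quantile = 0.99,
                           min_area_um2 = 25, max_area_um2 = 400,
                           split_touching = FALSE) {
  threshold <- match.arg(threshold)
  if (inherits(image, "flow_image")) {
    if (is.null(pixel_size_um)) pixel_size_um <- image$pixel_size_um
    image <- image$ch1
  }
  if (is.null(pixel_size_um)) {
    stop("`pixel_size_um` is required for the area filter", call. = FALSE)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a 2-D numeric matrix", call. = FALSE)
  }
  params <- list(clahe_nx = clahe_nx, clahe_limit = clahe_limit,
                 threshold = threshold, quantile = quantile,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_touching = split_touching,
                 pixel_size_um = pixel_size_um)
  rng <- range(image)
  if (rng[2] <= rng[1]) {
    # blank / constant image: nothing to segment
    return(new_labeled_masks(matrix(0L, nrow(image), ncol(image)),
                             pixel_size_um, params))
  }
  x <- (image - rng[1]) / (rng[2] - rng[1])
  eq <- EBImage::clahe(EBImage::Image(x), nx = clahe_nx, ny = clahe_nx,
                       limit = clahe_limit)
  thr <- if (threshold == "otsu") {
    EBImage::otsu(eq, range = c(0, 1))
  } else {
    stats::quantile(as.numeric(eq), quantile)
  }
  mask <- EBImage::fillHull(eq > thr)
  if (split_touching) {
    lab <- EBImage::watershed(EBImage::distmap(mask))
    lab <- as.matrix(EBImage::imageData(lab))
    storage.mode(lab) <- "integer"
  } else {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
    storage.mode(lab) <- "integer"
    lab <- merge_diagonal_labels(lab)  # bwlabel is 4-connected; want 8
  }
  # area filter in um^2, then relabel contiguously
  px_area <- pixel_size_um^2
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * px_area >= min_area_um2 &
                counts * px_area <= max_area_um2)
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  new_labeled_masks(lab, pixel_size_um, params)
}

# Upgrade a 4-connected labelling to 8-connectivity by union-find merging of
# labels that touch diagonally.
merge_diagonal_labels <- function(lab) {
  n_lab <- max(lab)
  if (n_lab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbours
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right neighbours
  pairs <- rbind(cbind(a1[a1 > 0L & b1 > 0L & a1 != b1],
                       b1[a1 > 0L & b1 > 0L & a1 != b1]),
                 cbind(a2[a2 > 0L & b2 > 0L & a2 != b2],
                       b2[a2 > 0L & b2 > 0L & a2 != b2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n_lab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n_lab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  lab
}

new_labeled_masks <- function(nuclei, pixel_size_um, provenance,
                              cells = NULL) {
  structure(list(nuclei = nuclei, cells = cells,
                 pixel_size_um = pixel_size_um, provenance = provenance),
            class = "labeled_masks")
}

#' @export
print.labeled_masks <- function(x, ...) {
  cat(sprintf("labeled_masks: %d nuclei, %s cell regions, %dx%d px (%.2f um/px)\n",
              max(x$nuclei, 0), if (is.null(x$cells)) "no" else
                as.character(max(x$cells, 0)),
              ncol(x$nuclei), nrow(x$nuclei), x$pixel_size_um))
  invisible(x)
}

#' Extend nucleus labels to whole-cell regions
#'
#' The chamber experiments carry no membrane stain, so the whole-cell region
#' needed for the translocation-factor denominator has to be constructed.
#' Two strategies are provided. `"dilate"` (default) grows each nucleus by a
#' fixed radius and partitions contested pixels between neighbouring cells
#' with a seeded propagation (geodesic nearest-nucleus), so regions are
#' always disjoint and each contains its nucleus. `"channel2"` instead
#' restricts the regions to the Otsu foreground of the transcription-factor
#' channel (union the nuclei), again partitioned by seeded propagation.
#'
#' @param masks a `labeled_masks` from [segment_nuclei()].
#' @param channel2 transcription-factor channel matrix (required for
#'   `strategy = "channel2"`).
#' @param strategy `"dilate"` or `"channel2"`.
#' @param radius_um dilation radius in microns for `"dilate"`.
#' @return `masks` with the `cells` label matrix filled in.
#' @export
derive_cell_regions <- function(masks, channel2 = NULL,
                                strategy = "dilate", radius_um = 6) {
  stopifnot(inherits(masks, "labeled_masks"))
  if (!strategy %in% c("dilate", "channel2")) {
    stop(sprintf("unknown cell-region strategy '%s' (use 'dilate' or 'channel2')",
                 strategy), call. = FALSE)
  }
  nuc <- masks$nuclei
  if (max(nuc) == 0L) {
    masks$cells <- matrix(0L, nrow(nuc), ncol(nuc))
    masks$provenance$cell_strategy <- strategy
    return(masks)
  }
  if (strategy == "dilate") {
    r_px <- max(1L, round(radius_um / masks$pixel_size_um))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    region_mask <- EBImage::dilate(EBImage::Image(nuc > 0L), brush) > 0
  } else {
    if (is.null(channel2)) {
      stop("strategy 'channel2' needs the transcription-factor channel",
           call. = FALSE)
    }
    if (inherits(channel2, "flow_image")) channel2 <- channel2$ch2
    rng <- range(channel2)
    x <- if (rng[2] > rng[1]) (channel2 - rng[1]) / (rng[2] - rng[1]) else
      channel2 * 0
    thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
    region_mask <- (x > thr) | (nuc > 0L)
  }
  seeds <- EBImage::Image(nuc)
  cells <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nuc), ncol(nuc))),
                              seeds = seeds, mask = region_mask)
  cells <- as.matrix(EBImage::imageData(cells))
  storage.mode(cells) <- "integer"
  cells[nuc > 0L] <- nuc[nuc > 0L]  # nucleus always belongs to its own cell
  masks$cells <- cells
  masks$provenance$cell_strategy <- strategy
  masks$provenance$cell_radius_um <- radius_um
  masks
}
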