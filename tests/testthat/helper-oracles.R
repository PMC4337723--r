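# Independent fixture builders used as oracles; deliberately written from
# first principles rather than through the package's rendering path.

# Rasterize a rotated ellipse as a logical mask (row = y, col = x; theta in
# degrees from the +x axis).
ellipse_mask <- function(nrow, ncol, cx, cy, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  xg <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  yg <- matrix(seq_len(nrow), nrow, ncol)
  u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
  v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Single synthetic cell: square-ish nucleus and cell masks plus a channel-2
# image with a prescribed split of integrated intensity.
make_cell_image <- function(nuclear_signal, cyto_signal, background = 0,
                            size = 64) {
  nucleus <- ellipse_mask(size, size, size / 2, size / 2, 8, 8, 0)
  cell <- ellipse_mask(size, size, size / 2, size / 2, 16, 16, 0)
  ch2 <- matrix(background, size, size)
  n_n <- sum(nucleus)
  n_c <- sum(cell & !nucleus)
  ch2[nucleus] <- ch2[nucleus] + nuclear_signal / n_n
  ch2[cell & !nucleus] <- ch2[cell & !nucleus] + cyto_signal / n_c
  list(nucleus = nucleus, cell = cell, ch2 = ch2)
}

# Greedy nearest-centroid matching of measured cells to ground truth.
match_measurements <- function(scene, measurements) {
  truth <- scene$cells
  idx <- vapply(seq_len(nrow(truth)), function(i) {
    which.min((measurements$cx_px - truth$cx_px[i])^2 +
                (measurements$cy_px - truth$cy_px[i])^2)
  }, integer(1))
  list(truth = truth, measured = measurements[idx, ])
}

# Brute-force LOWESS at a single point: tri-cube weighted linear fit over the
# frac-nearest neighbours (no robustness iterations).
tricube_fit_at <- function(x, y, x0, frac) {
  n <- length(x)
  k <- max(2, ceiling(frac * n))
  d <- abs(x - x0)
  h <- sort(d)[k]
  w <- pmax(0, 1 - (d / h)^3)^3
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  sum(fit$coefficients * c(1, x0))
}
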