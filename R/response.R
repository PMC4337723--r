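#' Bin per-cell measurements by shear stress
#'
#' Aggregates per-cell measurements into a shear-binned response curve
#' (mean, SEM, n per bin), mirroring how successive microscope fields along
#' the chamber are averaged at their local shear. By default the response is
#' first averaged within each image and the bin statistics are computed over
#' image means; set `per_image = FALSE` to pool cells directly.
#'
#' @param measurements tibble of per-cell rows with a `shear_dyn_cm2` column
#'   (or `x_cm` plus `config`), the response column, and an `image` column
#'   when `per_image = TRUE`.
#' @param response name of the response column: `"orientation_deg"` or
#'   `"tf"` (any numeric column works).
#' @param config optional [chamber_config()] used to compute shear from
#'   `x_cm` when `shear_dyn_cm2` is absent, and to set default bin limits.
#' @param breaks bin edges in dyn/cm^2; default `n_bins` equal-width bins
#'   spanning the configured (or observed) shear range.
#' @param n_bins number of bins when `breaks` is not given.
#' @param per_image average within images first (default) or pool cells.
#' @return a `response_curve`: tibble with columns `bin_center`, `mean`,
#'   `sem`, `n` (empty bins are dropped with a message), response kind kept
#'   as an attribute.
#' @export
bin_by_shear <- function(measurements, response = "orientation_deg",
                         config = NULL, breaks = NULL, n_bins = 15,
                         per_image = TRUE) {
  m <- measurements
  if (!"shear_dyn_cm2" %in% names(m)) {
    if (is.null(config) || !"x_cm" %in% names(m)) {
      stop("measurements need `shear_dyn_cm2`, or `x_cm` plus a chamber config",
           call. = FALSE)
    }
    m$shear_dyn_cm2 <- position_to_shear(config, m$x_cm)
  }
  if (!response %in% names(m)) {
    stop(sprintf("no `%s` column in measurements", response), call. = FALSE)
  }
  m <- m[is.finite(m[[response]]), ]
  if (nrow(m) == 0) stop("no finite measurements to bin", call. = FALSE)
  if (is.null(breaks)) {
    lim <- if (!is.null(config)) {
      range(c(config$shear_inlet_dyn_cm2, config$shear_outlet_dyn_cm2))
    } else {
      range(m$shear_dyn_cm2)
    }
    breaks <- seq(lim[1], lim[2], length.out = n_bins + 1)
  }
  if (per_image && !"image" %in% names(m)) {
    # one field per distinct position is the natural unit
    m$image <- as.character(m$shear_dyn_cm2)
  }
  bin <- cut(m$shear_dyn_cm2, breaks, include.lowest = TRUE)
  if (all(is.na(bin))) stop("all shear bins are empty", call. = FALSE)
  m$bin <- bin
  m$value <- m[[response]]
  if (per_image) {
    m <- dplyr::summarise(dplyr::group_by(m, .data$bin, .data$image),
                          value = mean(.data$value), .groups = "drop")
  }
  curve <- dplyr::summarise(
    dplyr::group_by(m, .data$bin),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop")
  curve$sem[curve$n == 1] <- 0
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  curve$bin_center <- centers[match(curve$bin, levels(bin))]
  dropped <- sum(!levels(bin) %in% as.character(curve$bin))
  if (dropped > 0) {
    message(sprintf("dropped %d empty shear bin(s)", dropped))
  }
  curve <- curve[order(curve$bin_center),
                 c("bin_center", "mean", "sem", "n")]
  structure(tibble::as_tibble(curve),
            kind = response, class = c("response_curve", class(curve)))
}

#' LOWESS-smooth a response curve
#'
#' Locally weighted linear regression with tri-cube weights and robustness
#' reweighting iterations (the classic LOWESS smoother), evaluated at each
#' bin centre. Used, as in the original analysis, to smooth shear-response
#' curves before reading off the optimum.
#'
#' @param curve a `response_curve` from [bin_by_shear()] with >= 4 bins.
#' @param frac fraction of points in each local window (0 < frac <= 1).
#' @param iter robustness iterations (default 3).
#' @return the curve with a `smoothed` column added.
#' @export
smooth_lowess <- function(curve, frac = 0.5, iter = 3) {
  stopifnot(inherits(curve, "response_curve"))
  if (nrow(curve) < 4) {
    stop("need >= 4 bins to smooth; use the raw curve instead",
         call. = FALSE)
  }
  if (frac <= 0 || frac > 1) stop("`frac` must be in (0, 1]", call. = FALSE)
  # delta = 0: evaluate the local fit at every bin centre (no interpolation)
  fit <- stats::lowess(curve$bin_center, curve$mean, f = frac, iter = iter,
                       delta = 0)
  # bin centers are unique and already sorted, so fit$y aligns positionally
  curve$smoothed <- fit$y
  curve
}

#' Estimate the shear-stress set point from a response curve
#'
#' The set point is read off the (smoothed) response curve as the shear at
#' which the response is extremal: minimal folded angle for orientation,
#' minimal TF for an NF-kB-like readout, maximal TF for a Smad1-like
#' readout. The optimal range is the maximal contiguous run of bins whose
#' response has covered at least `criterion_fraction` of the distance from
#' baseline to the optimum. The baseline defaults to the worst smoothed bin
#' but should be the no-flow measurement when one is available (the dotted
#' reference lines of the original curves). Both the optimum and the range
#' are invariant to affine rescaling of the response values.
#'
#' @param curve a `response_curve`, ideally smoothed
#'   (see [smooth_lowess()]); the `smoothed` column is used when present.
#' @param direction `"min"` if the optimal response is a minimum
#'   (orientation, NF-kB TF) or `"max"` (Smad1 TF).
#' @param criterion_fraction fraction of the baseline-to-optimum span a bin
#'   must reach to count as optimal (default 0.8).
#' @param baseline reference response level (e.g. the no-flow mean);
#'   defaults to the worst smoothed value on the curve.
#' @return an object of class `set_point_estimate`: `optimum_shear`,
#'   `optimum_value`, the contiguous `range_lo`/`range_hi`, the criterion
#'   and baseline used, and `at_boundary` (TRUE when the curve is monotone
#'   so the extremum sits on the first or last bin).
#' @export
estimate_set_point <- function(curve, direction = c("min", "max"),
                               criterion_fraction = 0.8, baseline = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  direction <- match.arg(direction)
  stopifnot(criterion_fraction > 0, criterion_fraction <= 1)
  v <- if ("smoothed" %in% names(curve)) curve$smoothed else curve$mean
  x <- curve$bin_center
  i_opt <- if (direction == "min") which.min(v) else which.max(v)
  if (is.null(baseline)) {
    baseline <- if (direction == "min") max(v) else min(v)
  }
  span <- baseline - v[i_opt]
  progress <- if (abs(span) < .Machine$double.eps) {
    rep(1, length(v))  # flat curve: everything is "optimal"
  } else {
    (baseline - v) / span
  }
  ok <- progress >= criterion_fraction
  lo <- i_opt
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i_opt
  while (hi < length(v) && ok[hi + 1]) hi <- hi + 1
  structure(
    list(optimum_shear = x[i_opt],
         optimum_value = v[i_opt],
         range_lo = x[lo],
         range_hi = x[hi],
         criterion_fraction = criterion_fraction,
         baseline = baseline,
         direction = direction,
         at_boundary = i_opt == 1L || i_opt == length(v)),
    class = "set_point_estimate")
}

#' @export
print.set_point_estimate <- function(x, ...) {
  cat(sprintf(
    "Shear-stress set point: %.2f dyn/cm^2 (optimal range %.2f - %.2f)\n",
    x$optimum_shear, x$range_lo, x$range_hi))
  cat(sprintf("  response %s = %.3f, baseline = %.3f, criterion = %.0f%%%s\n",
              x$direction, x$optimum_value, x$baseline,
              100 * x$criterion_fraction,
              if (x$at_boundary) " [optimum at curve boundary]" else ""))
  invisible(x)
}

#' One-way ANOVA for a shear effect
#'
#' Tests the null hypothesis that shear-stress magnitude has no effect on
#' the response, i.e. a fixed-effects one-way ANOVA of the response grouped
#' by shear bin: F = MS_between / MS_within on (k - 1, N - k) degrees of
#' freedom.
#'
#' @param values numeric response values.
#' @param groups grouping factor (e.g. shear bin), >= 2 levels.
#' @return a list with `F`, `p`, `df1`, `df2`, and `undefined` (TRUE when
#'   the within-group variance is zero so F does not exist).
#' @export
anova_shear_effect <- function(values, groups) {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups); n <- length(values)
  if (k < 2) stop("need >= 2 shear groups", call. = FALSE)
  if (n - k < 1) stop("need more observations than groups", call. = FALSE)
  fit <- suppressWarnings(stats::anova(stats::aov(values ~ groups)))
  msb <- fit[["Mean Sq"]][1]
  msw <- fit[["Mean Sq"]][2]
  scale <- mean(values^2) + .Machine$double.xmin
  if (!is.finite(msw) || msw <= 1e-12 * scale) {
    if (msb <= 1e-12 * scale) {
      # all observations equal within and between groups: F = 0/0
      return(list(F = NA_real_, p = NA_real_,
                  df1 = k - 1L, df2 = n - k, undefined = TRUE))
    }
    # groups separate perfectly: evidence is unbounded
    return(list(F = Inf, p = 0,
                df1 = k - 1L, df2 = n - k, undefined = FALSE))
  }
  list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
       df1 = fit[["Df"]][1], df2 = fit[["Df"]][2], undefined = FALSE)
}
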