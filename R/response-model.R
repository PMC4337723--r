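#' Biphasic shear-response model
#'
#' Parameterises how a population of endothelial cells responds to local wall
#' shear stress. The response is biphasic around a preferred shear magnitude
#' (the set point): within `optimum_halfwidth_dyn_cm2` of
#' `optimum_shear_dyn_cm2` cells express the optimal response (nuclei aligned
#' near `aligned_mean_angle_deg`, nuclear transcription-factor fraction near
#' `tf_nuclear_fraction_at_optimum`); far outside that window they revert to
#' the baseline (random orientation at a mean of 45 degrees and
#' `tf_nuclear_fraction_baseline`). In between, responses interpolate along a
#' Gaussian shoulder: with d = max(0, |tau - optimum| - halfwidth), the
#' response weight is w(tau) = 2^-(d/halfwidth)^2, so the full response
#' plateaus across the optimal window and falls to half a further halfwidth
#' out.
#'
#' @param optimum_shear_dyn_cm2 centre of the optimal shear window
#'   (dyn/cm^2).
#' @param optimum_halfwidth_dyn_cm2 half-width of the full-response plateau
#'   (dyn/cm^2).
#' @param aligned_mean_angle_deg population mean folded angle at the optimum
#'   (degrees in \[0, 90\]; small = aligned with flow).
#' @param misaligned_mean_angle_deg mean folded angle far from the optimum;
#'   the default 45 is the uniform-orientation expectation. Values above 45
#'   model perpendicular alignment (e.g. at very high shear).
#' @param tf_nuclear_fraction_at_optimum nuclear fraction of the
#'   transcription-factor signal at the optimum, in \[0, 1\].
#' @param tf_nuclear_fraction_baseline nuclear fraction far from the optimum,
#'   in \[0, 1\]. Set baseline > optimum for a U-shaped (NF-kB-like) readout,
#'   baseline < optimum for a peaked (Smad1-like) readout.
#' @param angle_concentration dispersion multiplier for per-cell angles.
#'   At the default 1 the per-cell angle spread is solved so that the
#'   population mean folded angle equals the interpolated target exactly;
#'   values below 1 broaden the distribution toward uniform, and 0 gives
#'   fully uniform orientations regardless of shear.
#' @param tf_concentration concentration of the per-cell Beta distribution
#'   around the target nuclear fraction (larger = tighter).
#' @return an object of class `response_model`.
#' @examples
#' response_model_preset("huvec")
#' @export
response_model <- function(optimum_shear_dyn_cm2 = 15,
                           optimum_halfwidth_dyn_cm2 = 5,
                           aligned_mean_angle_deg = 20,
                           misaligned_mean_angle_deg = 45,
                           tf_nuclear_fraction_at_optimum = 0.3,
                           tf_nuclear_fraction_baseline = 0.7,
                           angle_concentration = 1,
                           tf_concentration = 50) {
  stopifnot(optimum_shear_dyn_cm2 > 0, optimum_halfwidth_dyn_cm2 > 0,
            aligned_mean_angle_deg >= 0, aligned_mean_angle_deg <= 90,
            misaligned_mean_angle_deg >= 0, misaligned_mean_angle_deg <= 90,
            tf_nuclear_fraction_at_optimum >= 0,
            tf_nuclear_fraction_at_optimum <= 1,
            tf_nuclear_fraction_baseline >= 0,
            tf_nuclear_fraction_baseline <= 1,
            angle_concentration >= 0, tf_concentration > 0)
  structure(
    list(optimum_shear_dyn_cm2 = optimum_shear_dyn_cm2,
         optimum_halfwidth_dyn_cm2 = optimum_halfwidth_dyn_cm2,
         aligned_mean_angle_deg = aligned_mean_angle_deg,
         misaligned_mean_angle_deg = misaligned_mean_angle_deg,
         tf_nuclear_fraction_at_optimum = tf_nuclear_fraction_at_optimum,
         tf_nuclear_fraction_baseline = tf_nuclear_fraction_baseline,
         angle_concentration = angle_concentration,
         tf_concentration = tf_concentration),
    class = "response_model")
}

#' Preset response models
#'
#' `"huvec"` places the set point at 15 dyn/cm^2 (venous cells respond
#' optimally between roughly 10 and 20 dyn/cm^2); `"hdlec"` places it at
#' 5 dyn/cm^2 (lymphatic cells align maximally around 4-6 dyn/cm^2).
#' Both use a U-shaped nuclear NF-kB-like translocation readout.
#'
#' @param name `"huvec"` or `"hdlec"`.
#' @return a [response_model()].
#' @export
response_model_preset <- function(name = c("huvec", "hdlec")) {
  name <- match.arg(name)
  switch(name,
    huvec = response_model(optimum_shear_dyn_cm2 = 15,
                           optimum_halfwidth_dyn_cm2 = 5),
    hdlec = response_model(optimum_shear_dyn_cm2 = 5,
                           optimum_halfwidth_dyn_cm2 = 2))
}

# Response weight in [0, 1]: 1 across the optimal plateau, Gaussian shoulder
# outside (half response one halfwidth beyond the plateau edge).
response_weight <- function(model, shear) {
  d <- pmax(0, abs(shear - model$optimum_shear_dyn_cm2) -
              model$optimum_halfwidth_dyn_cm2)
  2^(-(d / model$optimum_halfwidth_dyn_cm2)^2)
}

# Population target mean folded angle / nuclear fraction at a given shear.
target_angle <- function(model, shear) {
  w <- response_weight(model, shear)
  w * model$aligned_mean_angle_deg + (1 - w) * model$misaligned_mean_angle_deg
}

target_tf <- function(model, shear) {
  w <- response_weight(model, shear)
  w * model$tf_nuclear_fraction_at_optimum +
    (1 - w) * model$tf_nuclear_fraction_baseline
}

# ---- wrapped-normal angle machinery -------------------------------------

# Mean folded angle E|fold(theta)| for theta ~ wrapped normal with the given
# centre (degrees) and sd (degrees), wrapped on a 180-degree period.
# Computed by quadrature over the wrapped density.
folded_mean_wrapped <- function(center_deg, sd_deg) {
  if (sd_deg <= 0) return(fold_angle(center_deg))
  k <- seq(-max(3L, ceiling(4 * sd_deg / 180)),
           max(3L, ceiling(4 * sd_deg / 180)))
  theta <- seq(-90, 90, length.out = 1441L)
  dens <- rowSums(vapply(
    k, function(kk) stats::dnorm(theta + 180 * kk, center_deg, sd_deg),
    numeric(length(theta))))
  w <- dens / sum(dens)
  sum(fold_angle(theta) * w)
}

# Solve for the wrapped-normal sd whose folded mean equals `target` degrees.
# Centre 0 covers targets in (0, 45); centre 90 covers (45, 90). Targets at
# (numerically) 45 are uniform; returns Inf as the "uniform" sentinel.
sigma_for_folded_mean <- function(target) {
  stopifnot(target >= 0, target <= 90)
  if (abs(target - 45) < 0.05) return(Inf)
  if (target < 0.05 || target > 89.95) return(0)
  center <- if (target < 45) 0 else 90
  f <- function(s) folded_mean_wrapped(center, s) - target
  # folded mean is monotone in sd: from fold(center) at sd=0 toward 45
  stats::uniroot(f, lower = 1e-3, upper = 720, tol = 1e-6)$root
}

# Draw n signed angles in (-90, 90] with the requested mean folded angle.
# concentration scales 1/sd: 1 reproduces the target mean exactly, 0 gives
# uniform orientations.
sample_angles <- function(n, target_mean, concentration) {
  sigma <- if (concentration > 0) {
    sigma_for_folded_mean(target_mean) / concentration
  } else {
    Inf
  }
  if (!is.finite(sigma)) {
    return(stats::runif(n, -90, 90))
  }
  center <- if (target_mean < 45) 0 else 90
  ((center + stats::rnorm(n, 0, sigma) + 90) %% 180) - 90
}

# Draw n nuclear fractions around a target mean in [0, 1] via a Beta
# distribution with the model's concentration; degenerate targets 0/1 are
# returned exactly.
sample_tf <- function(n, target, concentration) {
  if (target <= 0) return(rep(0, n))
  if (target >= 1) return(rep(1, n))
  stats::rbeta(n, concentration * target, concentration * (1 - target))
}
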