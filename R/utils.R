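# internal helpers

stop_domain <- function(name, value) {
  stop(sprintf("`%s` must be strictly positive (got %s)", name,
               paste(format(value), collapse = ", ")), call. = FALSE)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_domain(nm, v)
    }
  }
  invisible(TRUE)
}

# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a top-level seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage) %% 2147483629
}

#' Fold an angle onto the acute range [0, 90] degrees
#'
#' Orientation of a nucleus is axial (the major axis has no head or tail), so
#' angles are equivalent modulo 180 degrees, and the readout used throughout
#' is the acute angle between the major axis and the flow direction:
#' 0 = aligned with flow, 90 = perpendicular, 45 = the expectation for
#' uniformly random orientations.
#'
#' @param theta_deg numeric vector of angles in degrees (any range).
#' @return numeric vector in \[0, 90\].
#' @export
fold_angle <- function(theta_deg) {
  abs(((theta_deg + 90) %% 180) - 90)
}
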