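## Simulated degradation y = D x + eta.

#' Specify an image degradation
#'
#' Bundles the motion-blur parameters, the noise family and level, the RNG
#' seed and the convolution boundary mode that together define how an
#' observation `y = D x + eta` is produced.
#'
#' Noise conventions: for `"gaussian"`, `noise_level` is the noise
#' **variance** on \[0,1\]-scaled intensities (default 0.001); for
#' `"poisson"`, it is a scaling factor `s` (default 0.05) — intensities are
#' multiplied by `1/s`, Poisson counts are drawn with those means, and the
#' counts are scaled back, so smaller factors give less noise.
#'
#' @param psf_length Motion extent in pixels (>= 1); default 30.
#' @param psf_angle Motion angle in degrees; default 60.
#' @param noise_family `"gaussian"`, `"poisson"` or `"none"`.
#' @param noise_level Nonnegative noise level (see Details); defaults to
#'   0.001 for Gaussian, 0.05 for Poisson, 0 for none.
#' @param seed Integer RNG seed used for the noise draw.
#' @param boundary Convolution boundary mode, `"circular"` or `"reflect"`.
#' @return An object of class `"degradation_spec"`.
#' @export
degradation_spec <- function(psf_length = 30, psf_angle = 60,
                             noise_family = c("gaussian", "poisson", "none"),
                             noise_level = NULL, seed = 1L,
                             boundary = "circular") {
  noise_family <- match.arg(noise_family)
  if (is.null(noise_level))
    noise_level <- switch(noise_family, gaussian = 0.001, poisson = 0.05,
                          none = 0)
  if (!is.numeric(noise_level) || noise_level < 0 || !is.finite(noise_level))
    stop("'noise_level' must be a nonnegative finite number", call. = FALSE)
  if (psf_length < 1)
    stop("'psf_length' must be >= 1", call. = FALSE)
  if (noise_family == "poisson" && noise_level == 0)
    stop("Poisson noise requires a positive scaling factor", call. = FALSE)
  structure(list(psf_length = psf_length, psf_angle = psf_angle,
                 noise_family = noise_family, noise_level = noise_level,
                 seed = as.integer(seed),
                 boundary = check_boundary(boundary)),
            class = "degradation_spec")
}

#' @export
print.degradation_spec <- function(x, ...) {
  cat(sprintf(
    "Degradation: motion PSF (length %g, angle %g deg), %s noise (level %g), seed %d, %s boundary\n",
    x$psf_length, x$psf_angle, x$noise_family, x$noise_level, x$seed,
    x$boundary))
  invisible(x)
}

#' Degrade a clean image by motion blur plus noise
#'
#' Produces the observation `y = D x + eta`: the clean image is blurred with
#' the motion PSF of the spec and noise is injected per the spec's family,
#' level and seed. The observation is **not** clipped to \[0,1\] (clipping
#' happens only at image export), and the same seed reproduces the
#' observation bit for bit.
#'
#' @param clean Numeric matrix, intensities in \[0,1\].
#' @param spec A [degradation_spec()].
#' @return An object of class `"degraded_observation"`: list with `observed`,
#'   `psf`, `spec` and `clean`.
#' @export
degrade <- function(clean, spec) {
  check_image(clean)
  if (!inherits(spec, "degradation_spec"))
    stop("'spec' must be a degradation_spec", call. = FALSE)
  psf <- make_motion_psf(spec$psf_length, spec$psf_angle)
  blurred <- apply_blur(clean, psf, spec$boundary)
  observed <- switch(spec$noise_family,
    none = blurred,
    gaussian = with_seed(spec$seed,
      blurred + matrix(stats::rnorm(length(blurred), 0,
                                    sqrt(spec$noise_level)),
                       nrow(blurred), ncol(blurred))),
    poisson = {
      s <- 1 / spec$noise_level
      with_seed(spec$seed,
        matrix(stats::rpois(length(blurred), pmax(blurred, 0) * s),
               nrow(blurred), ncol(blurred)) / s)
    },
    stop("unknown noise family: ", spec$noise_family, call. = FALSE))
  structure(list(observed = observed, psf = psf, spec = spec, clean = clean),
            class = "degraded_observation")
}

#' @export
print.degraded_observation <- function(x, ...) {
  cat(sprintf("Degraded observation: %d x %d image\n",
              nrow(x$observed), ncol(x$observed)))
  print(x$spec)
  invisible(x)
}
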