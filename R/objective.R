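## The restoration problem and its smooth part:
##   F(x) = f(x) + mu g(x),  f(x) = (1/2) ||D x - y||^2,
##   grad f(x) = D^T (D x - y).

#' Pose a restoration problem
#'
#' Pairs an observed image with the blur operator that produced it. When
#' given a [degrade()] result the PSF, boundary mode and clean reference are
#' carried over; a raw observed matrix needs an explicit PSF.
#'
#' @param observation A `"degraded_observation"` or an observed image matrix.
#' @param psf PSF object or kernel matrix (required for a raw matrix;
#'   overrides the stored one otherwise).
#' @param boundary Boundary mode; defaults to the observation's own.
#' @return An object of class `"restoration_problem"` with fields `y`,
#'   `psf`, `boundary` and (optionally) `clean`.
#' @export
restoration_problem <- function(observation, psf = NULL, boundary = NULL) {
  if (inherits(observation, "degraded_observation")) {
    y <- observation$observed
    if (is.null(psf)) psf <- observation$psf
    if (is.null(boundary)) boundary <- observation$spec$boundary
    clean <- observation$clean
  } else {
    y <- observation
    if (is.null(psf))
      stop("'psf' is required when 'observation' is a raw matrix",
           call. = FALSE)
    if (is.null(boundary)) boundary <- "circular"
    clean <- NULL
  }
  check_image(y, "observed image")
  kern <- psf_kernel(psf)
  check_kernel_fits(kern, y)
  boundary <- check_boundary(boundary)
  ## cache the transfer function once per problem; every gradient and
  ## objective evaluation reuses it under circular boundaries
  otf <- if (boundary == "circular") psf_otf(kern, dim(y))
  structure(list(y = y, psf = kern, boundary = boundary, otf = otf,
                 clean = clean),
            class = "restoration_problem")
}

#' Regularised restoration objective
#'
#' Evaluates `F(x) = (1/2) ||D x - y||^2 + mu * g(x)` with `g` either the
#' elementwise l1 norm or the global Euclidean norm, all norms taken over
#' every pixel.
#'
#' @param x Candidate image.
#' @param problem A [restoration_problem()].
#' @param reg_weight Regularisation weight `mu` (>= 0).
#' @param regularizer `"l1"` (default) or `"euclidean_norm"`.
#' @return A single number.
#' @export
objective <- function(x, problem, reg_weight = 0.3, regularizer = "l1") {
  check_image(x)
  check_same_dim(x, problem$y)
  r <- problem_blur(x, problem) - problem$y
  0.5 * sum(r^2) + reg_weight * reg_value(x, regularizer)
}

#' Gradient of the data-fit term
#'
#' `grad_f(x) = D^T (D x - y)`, computed with the exact adjoint of the blur
#' operator.
#'
#' @inheritParams objective
#' @return Image of the same dimensions as `x`.
#' @export
grad_f <- function(x, problem) {
  check_image(x)
  check_same_dim(x, problem$y)
  problem_adjoint(problem_blur(x, problem) - problem$y, problem)
}

## Operator applications through the cached transfer function when possible.
problem_blur <- function(x, problem) {
  if (length(problem$psf) == 1L) x * problem$psf[1L]
  else if (!is.null(problem$otf)) conv_otf(x, problem$otf)
  else apply_blur(x, problem$psf, problem$boundary)
}

problem_adjoint <- function(x, problem) {
  if (length(problem$psf) == 1L) x * problem$psf[1L]
  else if (!is.null(problem$otf)) conv_otf(x, Conj(problem$otf))
  else adjoint_blur(x, problem$psf, problem$boundary)
}
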