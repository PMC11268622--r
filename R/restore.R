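## User-level fitting interface and methods for the restoration object.

#' Restore a motion-blurred image
#'
#' The main fitting function: poses the l1-regularised deconvolution problem
#' for an observed image (or a simulated [degrade()] observation) and solves
#' it with the forward-backward-forward iteration.
#'
#' @param observation A `"degraded_observation"` from [degrade()], or an
#'   observed image matrix (then `psf` is required).
#' @param psf PSF object or kernel matrix; defaults to the one stored in the
#'   observation.
#' @param boundary Convolution boundary mode; defaults to the observation's.
#' @param x0 Optional starting image (default: the observation itself).
#' @param verbose Log solver progress to stderr.
#' @param ... Passed to [solver_config()] (`step_size`, `reg_weight`,
#'   `regularizer`, `max_iters`, `rel_tol`, `trace_metrics`,
#'   `keep_iterates`).
#' @return A `"tseng_restoration"` object; see [tseng_solve()].
#' @examples
#' clean <- generate_phantom(phantom_spec(size = 32, kind = "chest"))
#' obs <- degrade(clean, degradation_spec(psf_length = 5, psf_angle = 0,
#'                                        noise_family = "gaussian",
#'                                        noise_level = 1e-4, seed = 1))
#' fit <- tseng_restore(obs, step_size = 0.9, reg_weight = 0.002,
#'                      max_iters = 50)
#' fit
#' @export
tseng_restore <- function(observation, psf = NULL, boundary = NULL,
                          x0 = NULL, verbose = FALSE, ...) {
  problem <- restoration_problem(observation, psf = psf, boundary = boundary)
  tseng_solve(problem, solver_config(...), x0 = x0, verbose = verbose)
}

#' @export
print.tseng_restoration <- function(x, ...) {
  tr <- x$trace
  cat("Tseng forward-backward-forward restoration\n")
  cat(sprintf("  image: %d x %d, regularizer: %s, lambda = %g, mu = %g\n",
              nrow(x$restored), ncol(x$restored), x$config$regularizer,
              x$config$step_size, x$config$reg_weight))
  cat(sprintf("  iterations: %d (%s), final objective %.6g, final step norm %.3g\n",
              x$iterations,
              if (x$converged) "converged" else "iteration cap reached",
              tr$objective[x$iterations], tr$step_norm[x$iterations]))
  invisible(x)
}

#' @export
summary.tseng_restoration <- function(object, ...) {
  tr <- object$trace
  out <- list(
    dim = dim(object$restored),
    config = object$config,
    iterations = object$iterations,
    converged = object$converged,
    objective_initial = tr$objective[1],
    objective_final = tr$objective[object$iterations],
    step_norm_final = tr$step_norm[object$iterations])
  if (!is.null(object$problem$clean)) {
    clean <- object$problem$clean
    out$metrics <- metrics_report(clean, object$problem$y, object$restored)
  }
  class(out) <- "summary.tseng_restoration"
  out
}

#' @export
print.summary.tseng_restoration <- function(x, ...) {
  cat(sprintf("Tseng restoration of a %d x %d image\n", x$dim[1], x$dim[2]))
  cat(sprintf("  lambda = %g, mu = %g, regularizer = %s\n",
              x$config$step_size, x$config$reg_weight, x$config$regularizer))
  cat(sprintf("  %d iterations, converged: %s\n", x$iterations, x$converged))
  cat(sprintf("  objective: %.6g -> %.6g, final step norm %.3g\n",
              x$objective_initial, x$objective_final, x$step_norm_final))
  if (!is.null(x$metrics)) {
    cat(sprintf("  vs clean reference: SSIM %.4f, ISNR %.3f dB, SNR %.3f dB\n",
                x$metrics$ssim, x$metrics$isnr, x$metrics$snr))
  }
  invisible(x)
}

#' @export
fitted.tseng_restoration <- function(object, ...) object$restored

#' Data-fit residuals of a restoration
#'
#' Returns `D x_hat - y`: the blurred restored image minus the observation.
#'
#' @param object A `"tseng_restoration"`.
#' @param ... Unused.
#' @export
residuals.tseng_restoration <- function(object, ...) {
  apply_blur(object$restored, object$problem$psf, object$problem$boundary) -
    object$problem$y
}

#' Plot convergence diagnostics of a restoration
#'
#' Draws the objective value and the step norm against iteration number
#' (both on a log y-scale).
#'
#' @param x A `"tseng_restoration"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tseng_restoration <- function(x, ...) {
  tr <- x$trace
  it <- seq_len(x$iterations)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(it, tr$objective, type = "l", log = "y",
                 xlab = "iteration", ylab = "objective F(x_k)", ...)
  pos <- tr$step_norm > 0
  graphics::plot(it[pos], tr$step_norm[pos], type = "l", log = "y",
                 xlab = "iteration", ylab = "step norm", ...)
  invisible(x)
}
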