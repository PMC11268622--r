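## Restoration-quality metrics.
##
## SSIM follows the single-window (global-statistics) form
##   SSIM(x,y) = (2 mu_x mu_y + c1)(2 sigma_xy + c2) /
##               ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2)),
## with population moments (divide by N) over the whole image; a sliding
## uniform-window mean-SSIM is available as an option. ISNR and SNR use the
## standard squared-norm decibel forms
##   ISNR = 10 log10(||x - y||^2 / ||x - xn||^2),
##   SNR  = 10 log10(||x||^2    / ||x - xn||^2).

#' SSIM stabilisation constants
#'
#' The conventional choices `c1 = (0.01 R)^2`, `c2 = (0.03 R)^2` for dynamic
#' range `R` (1 for unit-interval images).
#'
#' @param dynamic_range Intensity range `R` > 0; default 1.
#' @param c1,c2 Override the two constants directly.
#' @return List with `c1`, `c2`, `dynamic_range`.
#' @export
ssim_constants <- function(dynamic_range = 1, c1 = (0.01 * dynamic_range)^2,
                           c2 = (0.03 * dynamic_range)^2) {
  if (dynamic_range <= 0) stop("'dynamic_range' must be positive", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("'c1' and 'c2' must be positive", call. = FALSE)
  list(c1 = c1, c2 = c2, dynamic_range = dynamic_range)
}

ssim_from_moments <- function(mx, my, vx, vy, cxy, consts) {
  ((2 * mx * my + consts$c1) * (2 * cxy + consts$c2)) /
    ((mx^2 + my^2 + consts$c1) * (vx + vy + consts$c2))
}

#' Structural similarity index
#'
#' By default the single-window form: means, variances and covariance are
#' taken over the whole image (population convention). `window` switches to a
#' mean of local SSIM values over sliding uniform windows of the given odd
#' size (reflective boundary handling).
#'
#' @param x,y Images of identical dimensions.
#' @param constants [ssim_constants()].
#' @param window `NULL` (global, default) or an odd window side length.
#' @return A number <= 1; 1 exactly iff `x == y`.
#' @export
ssim <- function(x, y, constants = ssim_constants(), window = NULL) {
  check_image(x, "x"); check_image(y, "y")
  check_same_dim(x, y)
  if (is.null(window)) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    return(ssim_from_moments(mx, my, vx, vy, cxy, constants))
  }
  w <- as.integer(window)
  if (w < 1L || w %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  box <- matrix(1 / w^2, w, w)
  mx <- gather_reflect(x, box)
  my <- gather_reflect(y, box)
  vx <- gather_reflect(x * x, box) - mx^2
  vy <- gather_reflect(y * y, box) - my^2
  cxy <- gather_reflect(x * y, box) - mx * my
  mean(ssim_from_moments(mx, my, vx, vy, cxy, constants))
}

#' Improvement in signal-to-noise ratio (dB)
#'
#' `10 log10(||x - y||^2 / ||x - xn||^2)` for clean `x`, observed `y` and
#' estimate `xn`; positive when the estimate is closer to the clean image
#' than the observation is. A perfect estimate yields `Inf`.
#'
#' @param clean,observed,estimate Images of identical dimensions.
#' @return A number in dB (possibly `Inf`).
#' @export
isnr <- function(clean, observed, estimate) {
  check_image(clean, "clean"); check_image(observed, "observed")
  check_image(estimate, "estimate")
  check_same_dim(clean, observed); check_same_dim(clean, estimate)
  num <- sum((clean - observed)^2)
  den <- sum((clean - estimate)^2)
  if (den == 0) return(Inf)
  10 * log10(num / den)
}

#' Signal-to-noise ratio of an estimate (dB)
#'
#' `10 log10(||x||^2 / ||x - xn||^2)`. A perfect estimate yields `Inf`; an
#' all-zero clean image is rejected.
#'
#' @param clean,estimate Images of identical dimensions.
#' @return A number in dB (possibly `Inf`).
#' @export
snr <- function(clean, estimate) {
  check_image(clean, "clean"); check_image(estimate, "estimate")
  check_same_dim(clean, estimate)
  sig <- sum(clean^2)
  if (sig == 0) stop("'clean' must not be all zero", call. = FALSE)
  den <- sum((clean - estimate)^2)
  if (den == 0) return(Inf)
  10 * log10(sig / den)
}

#' Full quality report for a restoration
#'
#' @param clean,observed,estimate Images of identical dimensions.
#' @param constants [ssim_constants()] used for SSIM.
#' @return Object of class `"metrics_report"`: list with `ssim`, `isnr`,
#'   `snr`.
#' @export
metrics_report <- function(clean, observed, estimate,
                           constants = ssim_constants()) {
  structure(list(ssim = ssim(estimate, clean, constants),
                 isnr = isnr(clean, observed, estimate),
                 snr = snr(clean, estimate)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SSIM %.4f, ISNR %.3f dB, SNR %.3f dB\n", x$ssim, x$isnr, x$snr))
  invisible(x)
}

#' Append a metrics row to a CSV table
#'
#' Column layout mirrors the experiment tables: image id, noise family, then
#' the three metrics. A header is written when the file does not exist yet.
#'
#' @param report A [metrics_report()].
#' @param path CSV path.
#' @param image_id Identifier string for the image.
#' @param noise_family Noise family string.
#' @return `path`, invisibly.
#' @export
write_metrics_row <- function(report, path, image_id = "image",
                              noise_family = "none") {
  header <- "image_id,noise_family,ssim,isnr,snr"
  row <- sprintf("%s,%s,%.10g,%.10g,%.10g", image_id, noise_family,
                 report$ssim, report$isnr, report$snr)
  if (!file.exists(path)) writeLines(c(header, row), path)
  else cat(row, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
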