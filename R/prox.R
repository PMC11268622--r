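## Proximal operators (resolvents (I + t dg)^{-1}) of the two regularisers.

#' Elementwise soft thresholding (proximal operator of the l1 norm)
#'
#' `prox_l1(v, t)[i] = sign(v[i]) * max(|v[i]| - t, 0)`, the resolvent of
#' `t * d||.||_1`.
#'
#' @param v Numeric matrix (or vector).
#' @param threshold Nonnegative threshold (the product of step size and
#'   regularisation weight in the solver).
#' @return Object of the same shape as `v`.
#' @export
prox_l1 <- function(v, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0)
    stop("'threshold' must be a single nonnegative number", call. = FALSE)
  sign(v) * pmax(abs(v) - threshold, 0)
}

#' Block soft thresholding (proximal operator of the Euclidean norm)
#'
#' Shrinks the whole array towards zero along its direction:
#' `v * max(1 - t / ||v||_2, 0)`, with the convention that the result is the
#' zero array whenever `||v||_2 <= t`. This is the resolvent of the
#' subdifferential of the (global) Euclidean norm.
#'
#' @inheritParams prox_l1
#' @return Object of the same shape as `v`.
#' @export
prox_euclidean_norm <- function(v, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0)
    stop("'threshold' must be a single nonnegative number", call. = FALSE)
  nv <- sqrt(sum(v^2))
  if (nv <= threshold) return(v * 0)
  v * (1 - threshold / nv)
}

prox_for <- function(regularizer) {
  switch(regularizer,
    l1 = prox_l1,
    euclidean_norm = prox_euclidean_norm,
    stop("unknown regularizer: ", regularizer, call. = FALSE))
}

reg_value <- function(x, regularizer) {
  switch(regularizer,
    l1 = sum(abs(x)),
    euclidean_norm = sqrt(sum(x^2)),
    stop("unknown regularizer: ", regularizer, call. = FALSE))
}
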