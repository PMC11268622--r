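## The blur operator D and its exact adjoint.
##
## Circular (periodic) boundaries diagonalise D by the 2-D DFT: both D and
## D^T are applied through the optical transfer function, so the adjoint is
## exact to machine precision and the operator norm is available analytically
## as max |OTF|. The reflective mode extends the image by half-sample
## symmetry; it is applied as an explicit gather over kernel offsets and its
## adjoint as the corresponding scatter, which keeps <Du, v> = <u, D^T v>
## exact in that mode too.

boundary_modes <- c("circular", "reflect")

check_boundary <- function(boundary) {
  match.arg(boundary, boundary_modes)
}

check_kernel_fits <- function(kern, img) {
  if (nrow(kern) > nrow(img) || ncol(kern) > ncol(img))
    stop(sprintf("psf support (%d x %d) exceeds image size (%d x %d)",
                 nrow(kern), ncol(kern), nrow(img), ncol(img)), call. = FALSE)
  invisible(NULL)
}

## Optical transfer function: kernel zero-padded to the image size and
## circularly shifted so its centre sits at index (1,1), then transformed.
psf_otf <- function(kern, dims) {
  nr <- dims[1]; nc <- dims[2]
  pad <- matrix(0, nr, nc)
  pad[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  sr <- (nrow(kern) - 1L) %/% 2L
  sc <- (ncol(kern) - 1L) %/% 2L
  idx_r <- ((seq_len(nr) - 1L + sr) %% nr) + 1L
  idx_c <- ((seq_len(nc) - 1L + sc) %% nc) + 1L
  stats::fft(pad[idx_r, idx_c, drop = FALSE])
}

conv_otf <- function(img, otf) {
  Re(stats::fft(stats::fft(img) * otf, inverse = TRUE)) / length(img)
}

## Half-sample symmetric ("reflect") index fold: ... 2 1 | 1 2 ... n | n ... 1
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

gather_reflect <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nrow(kern) + 1L) %/% 2L
  cc <- (ncol(kern) + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
    k <- kern[a, b]
    if (k == 0) next
    mr <- reflect_index(seq_len(nr) - (a - cr), nr)
    mc <- reflect_index(seq_len(nc) - (b - cc), nc)
    out <- out + k * img[mr, mc, drop = FALSE]
  }
  out
}

## Adjoint of a row gather: accumulate rows of v onto their source indices.
scatter_rows <- function(v, map, n) {
  acc <- rowsum(v, group = map)
  out <- matrix(0, n, ncol(v))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

scatter_reflect <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nrow(kern) + 1L) %/% 2L
  cc <- (ncol(kern) + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
    k <- kern[a, b]
    if (k == 0) next
    mr <- reflect_index(seq_len(nr) - (a - cr), nr)
    mc <- reflect_index(seq_len(nc) - (b - cc), nc)
    tmp <- scatter_rows(img, mr, nr)
    tmp <- t(scatter_rows(t(tmp), mc, nc))
    out <- out + k * tmp
  }
  out
}

#' Apply the motion-blur operator D
#'
#' Centred 2-D convolution of an image with a PSF kernel; output dimensions
#' equal input dimensions. Circular boundaries are evaluated through the FFT;
#' reflective boundaries extend the image by half-sample symmetry.
#'
#' @param img Numeric matrix.
#' @param psf A [make_motion_psf()] object or a kernel matrix.
#' @param boundary `"circular"` (default) or `"reflect"`.
#' @return Blurred image, same dimensions as `img`.
#' @export
apply_blur <- function(img, psf, boundary = "circular") {
  check_image(img)
  kern <- psf_kernel(psf)
  check_kernel_fits(kern, img)
  boundary <- check_boundary(boundary)
  if (length(kern) == 1L) return(img * kern[1L])   # identity blur, exact
  if (boundary == "circular") conv_otf(img, psf_otf(kern, dim(img)))
  else gather_reflect(img, kern)
}

#' Apply the exact adjoint of the blur operator
#'
#' Transpose of [apply_blur()] with the same kernel and boundary mode:
#' `sum(apply_blur(u) * v) == sum(u * adjoint_blur(v))` to machine precision.
#' Under circular boundaries this is convolution with the conjugate transfer
#' function (equivalently the 180-degree-rotated kernel).
#'
#' @inheritParams apply_blur
#' @return Image of the same dimensions.
#' @export
adjoint_blur <- function(img, psf, boundary = "circular") {
  check_image(img)
  kern <- psf_kernel(psf)
  check_kernel_fits(kern, img)
  boundary <- check_boundary(boundary)
  if (length(kern) == 1L) return(img * kern[1L])
  if (boundary == "circular") conv_otf(img, Conj(psf_otf(kern, dim(img))))
  else scatter_reflect(img, kern)
}

#' Squared operator norm of the blur operator
#'
#' The Lipschitz constant of the data-fit gradient is `L = ||D||^2`. Under
#' circular boundaries this is exactly `max(|OTF|)^2` (at most 1 for a
#' nonnegative unit-sum kernel); under reflective boundaries it is estimated
#' by power iteration on `D^T D` and inflated by a small safety margin.
#'
#' @param psf PSF object or kernel matrix.
#' @param dims Image dimensions `c(rows, cols)`.
#' @param boundary Boundary mode.
#' @return Upper bound on the squared spectral norm of D.
#' @export
operator_norm_sq <- function(psf, dims, boundary = "circular") {
  kern <- psf_kernel(psf)
  boundary <- check_boundary(boundary)
  if (boundary == "circular")
    return(max(Mod(psf_otf(kern, dims)))^2)
  v <- matrix(1, dims[1], dims[2])
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (it in seq_len(50L)) {
    w <- adjoint_blur(apply_blur(v, kern, boundary), kern, boundary)
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam * 1.01
}
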