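## Linear-motion point spread functions.
##
## The kernel is defined intrinsically as the rasterisation of a unit-width
## rectangle of the given length, centred on the kernel centre and rotated to
## the given angle: each cell receives the exact area of its intersection with
## the rectangle (analytic polygon clipping, no sampling), and the kernel is
## normalised to unit mass. The support is the minimal odd-sized bounding box
## of the motion segment, so a length-1 motion is the 1x1 identity kernel.

## Sutherland-Hodgman clip of a convex polygon against an axis-aligned
## half-plane:  sign * coord(v) <= sign * bound.
clip_halfplane <- function(px, py, axis, bound, keep_le) {
  n <- length(px)
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  val <- if (axis == "x") px else py
  inside <- if (keep_le) val <= bound else val >= bound
  outx <- numeric(2L * n); outy <- numeric(2L * n); m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; outx[m] <- px[i]; outy[m] <- py[i]
    }
    if (inside[i] != inside[j]) {
      t <- (bound - val[i]) / (val[j] - val[i])
      m <- m + 1L
      outx[m] <- px[i] + t * (px[j] - px[i])
      outy[m] <- py[i] + t * (py[j] - py[i])
    }
  }
  list(x = outx[seq_len(m)], y = outy[seq_len(m)])
}

## Area of the intersection of a convex polygon with the axis-aligned box
## [xlo,xhi] x [ylo,yhi] (shoelace formula after four half-plane clips).
poly_box_area <- function(px, py, xlo, xhi, ylo, yhi) {
  p <- clip_halfplane(px, py, "x", xlo, keep_le = FALSE)
  p <- clip_halfplane(p$x, p$y, "x", xhi, keep_le = TRUE)
  p <- clip_halfplane(p$x, p$y, "y", ylo, keep_le = FALSE)
  p <- clip_halfplane(p$x, p$y, "y", yhi, keep_le = TRUE)
  n <- length(p$x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(p$x[j] * p$y - p$x * p$y[j])) / 2
}

#' Construct a linear motion-blur point spread function
#'
#' Models uniform straight-line motion of a given extent and direction as a
#' rectangle of that length and unit width; each kernel cell receives the
#' exact overlap area with the rectangle (analytic anti-aliasing) and the
#' kernel is normalised to unit sum. The support is the minimal odd-sized
#' bounding box of the motion segment, so `length = 1` yields the identity
#' kernel for any angle.
#'
#' @param length Motion extent in pixels (>= 1).
#' @param angle Motion direction in degrees, counter-clockwise from
#'   horizontal; reduced modulo 180.
#' @return An object of class `"psf"`: a list with elements `kernel`
#'   (nonnegative matrix summing to 1), `length` and `angle`.
#' @examples
#' make_motion_psf(5, 0)$kernel   # 1 x 5 uniform kernel
#' @export
make_motion_psf <- function(length, angle) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length < 1)
    stop("'length' must be a single finite number >= 1", call. = FALSE)
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle))
    stop("'angle' must be a single finite number", call. = FALSE)
  ang <- angle %% 180
  th <- ang * pi / 180
  ux <- cos(th); uy <- sin(th)
  hx <- (length / 2) * abs(ux)
  hy <- (length / 2) * abs(uy)
  ncb <- 2L * as.integer(ceiling(max(hx - 0.5, 0) - 1e-12)) + 1L
  nrb <- 2L * as.integer(ceiling(max(hy - 0.5, 0) - 1e-12)) + 1L
  cc <- (ncb + 1L) / 2
  cr <- (nrb + 1L) / 2
  ## rectangle corners: +/- (L/2) u +/- (1/2) p, p = unit normal
  hxu <- (length / 2) * ux; hyu <- (length / 2) * uy
  hxp <- -uy / 2; hyp <- ux / 2
  px <- c(hxu + hxp, hxu - hxp, -hxu - hxp, -hxu + hxp)
  py <- c(hyu + hyp, hyu - hyp, -hyu - hyp, -hyu + hyp)
  kern <- matrix(0, nrb, ncb)
  for (i in seq_len(nrb)) {
    yc <- cr - i              # row 1 is the top of the kernel (+y)
    for (j in seq_len(ncb)) {
      xc <- j - cc
      kern[i, j] <- poly_box_area(px, py, xc - 0.5, xc + 0.5,
                                  yc - 0.5, yc + 0.5)
    }
  }
  s <- sum(kern)
  if (s <= 0) stop("degenerate motion kernel (zero mass)", call. = FALSE)
  structure(list(kernel = kern / s, length = length, angle = ang),
            class = "psf")
}

psf_kernel <- function(psf) {
  if (inherits(psf, "psf")) return(psf$kernel)
  if (is.matrix(psf) && is.numeric(psf)) return(psf)
  stop("'psf' must be a \"psf\" object or a numeric kernel matrix",
       call. = FALSE)
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("Motion-blur PSF: length %.6g px, angle %.6g deg, support %d x %d\n",
              x$length, x$angle, nrow(x$kernel), ncol(x$kernel)))
  invisible(x)
}

#' Export a PSF kernel as a plain-text matrix
#'
#' Row-major, whitespace-separated, full double precision.
#'
#' @param psf A `"psf"` object or kernel matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psf <- function(psf, path) {
  k <- psf_kernel(psf)
  lines <- apply(k, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text PSF kernel matrix
#'
#' @param path File written by [write_psf()] (or any whitespace-separated
#'   numeric matrix).
#' @return A numeric kernel matrix.
#' @export
read_psf <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
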