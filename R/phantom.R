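## Procedural grayscale phantoms.
##
## The chest phantom emulates the structural character of a thoracic CT
## slice — dark background, a bright bony ring, two dark lung fields, a
## mid-gray mediastinum, a bright aorta-like disc and a spine — as composited
## anti-aliased ellipses on nominal plateaus (background 0, lung 0.15, soft
## tissue 0.5, bone/vessel 0.9). Edges are anti-aliased by 4x supersampling
## so blur/deblur effects are not confounded by rasterisation artifacts.

#' Specify a synthetic phantom
#'
#' @param size Pixels per side (>= 8).
#' @param kind `"chest"` (default), `"shepp_like"`, `"sparse_spots"` or
#'   `"flat"`.
#' @param seed Integer seed for the stochastic kinds/jitter.
#' @param contrast_jitter Nonnegative relative jitter applied to the chest
#'   plateau levels; 0 (default) gives the nominal levels.
#' @param n_spots Number of discs for the `"sparse_spots"` kind; default 8.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 128L, kind = c("chest", "shepp_like",
                                               "sparse_spots", "flat"),
                         seed = 1L, contrast_jitter = 0, n_spots = 8L) {
  kind <- match.arg(kind)
  if (!is.numeric(size) || size < 8)
    stop("'size' must be at least 8 pixels", call. = FALSE)
  if (contrast_jitter < 0)
    stop("'contrast_jitter' must be nonnegative", call. = FALSE)
  if (n_spots < 1) stop("'n_spots' must be >= 1", call. = FALSE)
  structure(list(size = as.integer(size), kind = kind,
                 seed = as.integer(seed), contrast_jitter = contrast_jitter,
                 n_spots = as.integer(n_spots)),
            class = "phantom_spec")
}

## Average-pool an (S*n) x (S*n) matrix down to n x n.
pool_mean <- function(m, S) {
  n <- nrow(m) %/% S
  a <- matrix(colMeans(matrix(m, nrow = S)), nrow = n)   # pool rows
  t(matrix(colMeans(matrix(t(a), nrow = S)), nrow = ncol(m) %/% S))
}

## Paint ellipse interiors (rotated by phi degrees) onto a value grid.
paint_ellipse <- function(img, X, Y, cx, cy, a, b, value, phi = 0) {
  t <- phi * pi / 180
  xr <- (X - cx) * cos(t) + (Y - cy) * sin(t)
  yr <- -(X - cx) * sin(t) + (Y - cy) * cos(t)
  img[(xr / a)^2 + (yr / b)^2 <= 1] <- value
  img
}

chest_phantom <- function(n, seed, jitter, S = 4L) {
  ## plateau levels, optionally jittered multiplicatively
  lv <- c(bone = 0.9, soft = 0.5, lung = 0.15, vessel = 0.9, spine = 0.9)
  if (jitter > 0)
    lv <- with_seed(seed, pmin(pmax(
      lv * (1 + jitter * stats::runif(length(lv), -1, 1)), 0), 1))
  N <- S * n
  ax <- ((seq_len(N) - 0.5) / N) * 2 - 1
  X <- matrix(ax, N, N, byrow = TRUE)
  Y <- matrix(ax, N, N)
  img <- matrix(0, N, N)
  img <- paint_ellipse(img, X, Y, 0, 0, 0.92, 0.75, lv[["bone"]])
  img <- paint_ellipse(img, X, Y, 0, 0, 0.80, 0.63, lv[["soft"]])
  img <- paint_ellipse(img, X, Y, -0.38, -0.02, 0.30, 0.45, lv[["lung"]])
  img <- paint_ellipse(img, X, Y, 0.38, -0.02, 0.30, 0.45, lv[["lung"]])
  img <- paint_ellipse(img, X, Y, 0.05, 0.10, 0.09, 0.09, lv[["vessel"]])
  img <- paint_ellipse(img, X, Y, 0, 0.52, 0.13, 0.11, lv[["spine"]])
  pool_mean(img, S)
}

## Ellipse table in the style of the classic head phantom (centre x, centre
## y, semi-axis a, semi-axis b, rotation deg, additive value); intensities
## clipped to [0,1] after summation.
shepp_like_phantom <- function(n, S = 4L) {
  e <- rbind(
    c(0,     0,      0.69,   0.92,   0,   1.0),
    c(0,    -0.0184, 0.6624, 0.874,  0,  -0.8),
    c(0.22,  0,      0.11,   0.31, -18,  -0.2),
    c(-0.22, 0,      0.16,   0.41,  18,  -0.2),
    c(0,     0.35,   0.21,   0.25,   0,   0.1),
    c(0,     0.1,    0.046,  0.046,  0,   0.1),
    c(0,    -0.1,    0.046,  0.046,  0,   0.1),
    c(-0.08, -0.605, 0.046,  0.023,  0,   0.1),
    c(0,    -0.605,  0.023,  0.023,  0,   0.1),
    c(0.06, -0.605,  0.023,  0.046,  0,   0.1))
  N <- S * n
  ax <- ((seq_len(N) - 0.5) / N) * 2 - 1
  X <- matrix(ax, N, N, byrow = TRUE)
  Y <- matrix(ax, N, N)
  img <- matrix(0, N, N)
  for (i in seq_len(nrow(e))) {
    t <- e[i, 5] * pi / 180
    xr <- (X - e[i, 1]) * cos(t) + (Y - e[i, 2]) * sin(t)
    yr <- -(X - e[i, 1]) * sin(t) + (Y - e[i, 2]) * cos(t)
    img <- img + e[i, 6] * ((xr / e[i, 3])^2 + (yr / e[i, 4])^2 <= 1)
  }
  pool_mean(pmin(pmax(img, 0), 1), S)
}

sparse_spots_phantom <- function(n, seed, n_spots, S = 4L) {
  r_px <- max(1.5, n / 40)
  min_sep <- 2 * r_px + 3
  pts <- with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0)
    tries <- 0L
    lo <- r_px + 2; hi <- n - r_px - 1
    while (length(cx) < n_spots) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not place ", n_spots,
             " non-touching spots on a ", n, "-pixel grid", call. = FALSE)
      px <- stats::runif(1, lo, hi); py <- stats::runif(1, lo, hi)
      if (length(cx) == 0 ||
          all(sqrt((cx - px)^2 + (cy - py)^2) >= min_sep)) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
    }
    list(x = cx, y = cy, v = stats::runif(n_spots, 0.5, 1))
  })
  N <- S * n
  ax <- (seq_len(N) - 0.5) / S          # pixel coordinates
  X <- matrix(ax, N, N, byrow = TRUE)
  Y <- matrix(ax, N, N)
  img <- matrix(0, N, N)
  for (i in seq_len(n_spots))
    img[(X - pts$x[i])^2 + (Y - pts$y[i])^2 <= r_px^2] <- pts$v[i]
  pool_mean(img, S)
}

#' Generate a synthetic phantom image
#'
#' Deterministic for a fixed spec (seed included); intensities in \[0,1\].
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix of side `spec$size`.
#' @examples
#' img <- generate_phantom(phantom_spec(size = 64, kind = "chest", seed = 7))
#' range(img)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  n <- spec$size
  switch(spec$kind,
    flat = matrix(0.5, n, n),
    chest = chest_phantom(n, spec$seed, spec$contrast_jitter),
    shepp_like = shepp_like_phantom(n),
    sparse_spots = sparse_spots_phantom(n, spec$seed, spec$n_spots),
    stop("unknown phantom kind: ", spec$kind, call. = FALSE))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom: kind %s, %d x %d, seed %d\n", x$kind, x$size, x$size,
              x$seed))
  invisible(x)
}
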