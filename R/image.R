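#' @keywords internal
"_PACKAGE"

## Images are plain numeric matrices with finite entries; intensities are
## expected in [0,1] for clean inputs but intermediate iterates and noisy
## observations are unconstrained reals (no clipping before export).

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

check_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%d x %d vs %d x %d)",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(NULL)
}

#' Rescale an image to the unit intensity interval
#'
#' Linearly maps intensities onto \[0,1\]; a constant image maps to 0.5.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix with values in \[0,1\].
#' @export
normalize_image <- function(img) {
  check_image(img)
  rng <- range(img)
  if (rng[1] == rng[2]) return(array(0.5, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Read a grayscale image from PNG or TIFF
#'
#' Intensities are returned as doubles in \[0,1\] (8- and 16-bit integer data
#' are divided by the full integer range by the underlying readers). Colour
#' images are collapsed to grayscale by averaging the colour channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix in \[0,1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use png or tiff): ", path,
         call. = FALSE))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    else arr <- arr[, , 1]
  }
  check_image(arr, "image file")
}

#' Write a grayscale image to PNG or TIFF
#'
#' Intensities are clipped to \[0,1\] at export only; PNG is written as 8-bit,
#' TIFF as 16-bit.
#'
#' @param img Numeric matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  clipped <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(clipped, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(clipped, where = path, bits.per.sample = 16L),
    stop("unsupported image format '", ext, "' (use png or tiff)", call. = FALSE))
  invisible(path)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's random state afterwards. Keeps all stochastic operations
## reproducible without touching global state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}
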