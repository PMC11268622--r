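## Independent oracles used across the suite. Everything here re-derives the
## quantity it checks from first principles (dense matrices, supersampling,
## grid search, long-run proximal gradient) without calling the package's
## operator code paths.

## Dense matrix of the centred 2-D convolution with wrap-around or
## half-sample-symmetric indexing; pixels are stacked column-major.
dense_blur_matrix <- function(kern, nr, nc, boundary = "circular") {
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    j <- ifelse(j < 0L, j + 2L * n, j)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  fold <- if (boundary == "circular") wrap else refl
  cr <- (nrow(kern) + 1L) %/% 2L
  cc <- (ncol(kern) + 1L) %/% 2L
  D <- matrix(0, nr * nc, nr * nc)
  for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
    k <- kern[a, b]
    if (k == 0) next
    for (jo in seq_len(nc)) for (io in seq_len(nr)) {
      ii <- fold(io - (a - cr), nr)
      jj <- fold(jo - (b - cc), nc)
      p <- (jo - 1L) * nr + io
      q <- (jj - 1L) * nr + ii
      D[p, q] <- D[p, q] + k
    }
  }
  D
}

## Brute-force motion kernel: midpoint supersampling of the unit-width
## rectangle of the given length/angle over each cell, then normalisation.
supersample_motion_psf <- function(length, angle, S = 64L) {
  th <- (angle %% 180) * pi / 180
  ux <- cos(th); uy <- sin(th)
  hx <- (length / 2) * abs(ux)
  hy <- (length / 2) * abs(uy)
  ncb <- 2L * as.integer(ceiling(max(hx - 0.5, 0) - 1e-12)) + 1L
  nrb <- 2L * as.integer(ceiling(max(hy - 0.5, 0) - 1e-12)) + 1L
  cr <- (nrb + 1L) / 2
  cc <- (ncb + 1L) / 2
  off <- ((seq_len(S) - 0.5) / S) - 0.5
  k <- matrix(0, nrb, ncb)
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    xs <- (j - cc) + rep(off, each = S)
    ys <- (cr - i) + rep(off, times = S)
    along <- xs * ux + ys * uy
    perp <- -xs * uy + ys * ux
    k[i, j] <- mean(abs(along) <= length / 2 & abs(perp) <= 0.5)
  }
  k / sum(k)
}

## Long-run proximal-gradient (ISTA) reference minimiser of
## (1/2)||D x - y||^2 + mu ||x||_1 built on the dense operator matrix.
ista_reference <- function(kern, y, mu, iters = 1e5, boundary = "circular",
                           step_frac = 0.99) {
  nr <- nrow(y); nc <- ncol(y)
  D <- dense_blur_matrix(kern, nr, nc, boundary)
  L <- max(svd(D, nu = 0, nv = 0)$d)^2
  lam <- step_frac / L
  DtD <- crossprod(D)
  yv <- as.vector(y)
  Dty <- as.vector(crossprod(D, yv))
  x <- yv
  t <- lam * mu
  for (k in seq_len(iters)) {
    v <- x - lam * (as.vector(DtD %*% x) - Dty)
    x <- sign(v) * pmax(abs(v) - t, 0)
  }
  list(x = matrix(x, nr, nc), D = D, L = L,
       objective = 0.5 * sum((as.vector(D %*% x) - yv)^2) + mu * sum(abs(x)))
}

## Dense 1-D grid-search minimiser of (1/2)(u - v)^2 + t |u|.
grid_prox_l1 <- function(v, t, halfwidth = 3, res = 1e-4) {
  g <- seq(-halfwidth, halfwidth, by = res)
  g[which.min(0.5 * (g - v)^2 + t * abs(g))]
}

## Coarse-to-fine dense 2-D grid-search minimiser of
## (1/2)||u - v||^2 + t ||u||_2; final resolution `res` per axis.
grid_prox_l2 <- function(v, t, halfwidth = 3, res = 1e-4) {
  coarse <- 1e-2
  g <- seq(-halfwidth, halfwidth, by = coarse)
  G1 <- rep(g, times = length(g))
  G2 <- rep(g, each = length(g))
  R <- sqrt(G1^2 + G2^2)
  i <- which.min(0.5 * ((G1 - v[1])^2 + (G2 - v[2])^2) + t * R)
  c1 <- G1[i]; c2 <- G2[i]
  f1 <- seq(c1 - 2 * coarse, c1 + 2 * coarse, by = res)
  f2 <- seq(c2 - 2 * coarse, c2 + 2 * coarse, by = res)
  F1 <- rep(f1, times = length(f2))
  F2 <- rep(f2, each = length(f1))
  j <- which.min(0.5 * ((F1 - v[1])^2 + (F2 - v[2])^2) +
                 t * sqrt(F1^2 + F2^2))
  c(F1[j], F2[j])
}

## 4-connected component labelling by breadth-first search.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in seq_along(mask)) {
    if (!mask[s] || lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      nbrs <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
      for (r in seq_len(4L)) {
        ii <- nbrs[r, 1]; jj <- nbrs[r, 2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

rand_image <- function(nr, nc = nr) matrix(stats::runif(nr * nc), nr, nc)
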