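# Internal helpers shared across modules.

#' Evaluate an expression with a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' generators stay pure functions of (parameters, seed).
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Shift a 3D array by an integer offset, filling exposed planes
#'
#' Element [i,j,k] of the result is a[i-di, j-dj, k-dk] where in-bounds,
#' `fill` otherwise. Used for vectorized dilation and neighbor tests.
#' @noRd
shift3 <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]; off <- d[ax]
    if (abs(off) >= n) return(out)
    if (off >= 0) { dst[[ax]] <- (1 + off):n; src[[ax]] <- 1:(n - off) }
    else          { dst[[ax]] <- 1:(n + off); src[[ax]] <- (1 - off):n }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 26 nonzero offsets of the 3x3x3 neighborhood (vertex adjacency) and
# the 6 face-adjacent offsets, as rows.
offsets26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
offsets6 <- function() {
  rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
}

#' Convert 1-based array indices to a 0-based voxel index matrix
#' @noRd
which_voxels0 <- function(mask) {
  idx <- which(mask)
  arrayInd(idx, dim(mask)) - 1L
}

#' Physical voxel-center coordinates (mm) of 0-based indices
#' @noRd
voxel_centers_mm <- function(index0, spacing) {
  if (is.null(dim(index0))) index0 <- matrix(index0, nrow = 1)
  sweep(index0, 2, spacing, `*`)
}

#' Separable convolution of a 3D array with a sampled Gaussian
#'
#' `sigma_vox` per axis, in voxels; edges handled by replication. A zero
#' sigma on an axis skips that axis.
#' @noRd
gaussian_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# 1D convolution along one axis with replicate padding, via clamped
# plane indexing (out[i] = sum_m k[m] * a[clamp(i - off_m)]).
conv_axis <- function(a, k, ax) {
  r <- (length(k) - 1L) / 2L
  dm <- dim(a)
  n <- dm[ax]
  out <- array(0, dm)
  for (m in seq_along(k)) {
    off <- m - r - 1L
    idx <- pmin(pmax(seq_len(n) - off, 1L), n)
    sh <- switch(ax,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    dim(sh) <- dm
    out <- out + k[m] * sh
  }
  out
}

stop_invalid <- function(...) stop(..., call. = FALSE)
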