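# Separable Gaussian smoothing and scale-normalized LoG filtering on
# anisotropic 3-D grids. Axis convolutions are dense banded-kernel matrix
# products (BLAS) rather than voxel loops; kernels are renormalized at the
# array border (replicate-style edge handling).

# kernel matrix K (n x n) for a 1-D Gaussian with sd `sigma` (in voxels);
# rows renormalized to sum 1 so borders do not lose mass locally.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  i <- seq_len(n)
  K <- matrix(0, n, n)
  offs <- (-half):half
  w <- exp(-0.5 * (offs / sigma)^2)
  for (k in seq_along(offs)) {
    j <- i + offs[k]
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[k]
  }
  K / rowSums(K)
}

# apply matrix M along axis `axis` (1=z, 2=y, 3=x) of 3-D array a
apply_along <- function(a, M, axis) {
  d <- dim(a)
  if (axis == 1L) {
    dim(a) <- c(d[1], d[2] * d[3])
    out <- M %*% a
    dim(out) <- d
    out
  } else if (axis == 2L) {
    ap <- aperm(a, c(2L, 1L, 3L))
    dim(ap) <- c(d[2], d[1] * d[3])
    out <- M %*% ap
    dim(out) <- c(d[2], d[1], d[3])
    aperm(out, c(2L, 1L, 3L))
  } else {
    ap <- aperm(a, c(3L, 1L, 2L))
    dim(ap) <- c(d[3], d[1] * d[2])
    out <- M %*% ap
    dim(out) <- c(d[3], d[1], d[2])
    aperm(out, c(2L, 3L, 1L))
  }
}

#' Separable Gaussian blur of a 3-D volume with per-axis sigmas
#'
#' @param a numeric 3-D array `(nz, ny, nx)`.
#' @param sigma_vox per-axis standard deviations in voxels, `(z, y, x)`;
#'   zero disables smoothing along that axis.
#' @return blurred array of the same dimension.
#' @export
gaussian_blur_3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L)
  d <- dim(a)
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      a <- apply_along(a, gauss_kernel_matrix(d[axis], sigma_vox[axis]), axis)
    }
  }
  a
}

# discrete Laplacian with physical spacings (second central differences,
# replicated edges)
laplacian_3d <- function(a, voxel_size) {
  d <- dim(a)
  out <- array(0, d)
  for (axis in 1:3) {
    h2 <- voxel_size[axis]^2
    n <- d[axis]
    up <- c(2:n, n)        # replicate edge
    dn <- c(1, 1:(n - 1))
    if (axis == 1L) {
      out <- out + (a[up, , , drop = FALSE] + a[dn, , , drop = FALSE] - 2 * a) / h2
    } else if (axis == 2L) {
      out <- out + (a[, up, , drop = FALSE] + a[, dn, , drop = FALSE] - 2 * a) / h2
    } else {
      out <- out + (a[, , up, drop = FALSE] + a[, , dn, drop = FALSE] - 2 * a) / h2
    }
  }
  out
}

#' Multi-scale normalized Laplacian-of-Gaussian blob response
#'
#' Filters one channel of a stack with a scale-adapted LoG: for every
#' scale sigma (um) the channel is Gaussian-smoothed with anisotropy-aware
#' per-axis voxel sigmas, the 3-D Laplacian is taken with physical
#' spacings, and the result is multiplied by `-sigma^2`
#' (scale-normalization, sign flipped so bright blobs give positive
#' response). The returned grid is the per-voxel maximum across scales.
#'
#' @param stack an [image_stack].
#' @param protein_channel channel index or name (default `"protein"`).
#' @param scales blob scales in um; defaults to a 0.1-0.5 um ladder
#'   matching submicron puncta.
#' @return numeric 3-D array of responses; attribute `"scales"` records
#'   the ladder used.
#' @export
log_response <- function(stack, protein_channel = "protein",
                         scales = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(inherits(stack, "image_stack"), length(scales) >= 1)
  a <- stack_channel(stack, protein_channel)
  vs <- stack$voxel_size
  best <- NULL
  for (s in scales) {
    sig_vox <- s / vs
    if (any(sig_vox < 1)) {
      warning(sprintf("scale %.3g um is below one voxel on some axis; clamping", s))
      sig_vox <- pmax(sig_vox, 1)
    }
    sm <- gaussian_blur_3d(a, sig_vox)
    resp <- -s^2 * laplacian_3d(sm, vs)
    best <- if (is.null(best)) resp else pmax(best, resp)
  }
  attr(best, "scales") <- scales
  best
}

# 26-neighbourhood local maxima of a 3-D array restricted to `mask`
# (strict ties broken toward the lexicographically-first voxel by a
# subsequent ordering step in the caller). Returns a logical array.
local_maxima_3d <- function(a, mask) {
  d <- dim(a)
  is_max <- mask
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dz == 0 & shifts$dy == 0 & shifts$dx == 0), ]
  pad <- -Inf
  for (k in seq_len(nrow(shifts))) {
    sz <- shifts$dz[k]; sy <- shifts$dy[k]; sx <- shifts$dx[k]
    shifted <- array(pad, d)
    zi <- seq_len(d[1]); yi <- seq_len(d[2]); xi <- seq_len(d[3])
    src_z <- zi - sz; src_y <- yi - sy; src_x <- xi - sx
    okz <- src_z >= 1 & src_z <= d[1]
    oky <- src_y >= 1 & src_y <= d[2]
    okx <- src_x >= 1 & src_x <= d[3]
    shifted[zi[okz], yi[oky], xi[okx]] <- a[src_z[okz], src_y[oky], src_x[okx]]
    is_max <- is_max & (a >= shifted)
    if (!any(is_max)) break
  }
  is_max
}
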