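#' Parameters of a synthetic two-channel cell scene
#'
#' Describes an ellipsoidal nucleus containing bright submicron puncta in
#' the protein channel over a uniform nucleoplasmic "light phase", plus a
#' smoothed-random DNA-stain texture. Defaults are chosen to emulate the
#' live-cell acquisition the pipeline targets: 0.2 um z-spacing spanning
#' 12.2 um (62 planes), ~0.1 um lateral pixels, hundreds of puncta per
#' nucleus, and dense/light intensity ratios (`kp_true`) spanning the
#' contrast observed between fusion-protein constructs.
#'
#' @param nucleus_semi_axes ellipsoid semi-axes `(z, y, x)` in um.
#' @param puncta_count number of nuclear puncta (>= 0).
#' @param punctum_radius_mean,punctum_radius_sd punctum radius
#'   distribution (um); radii are truncated at 2 lateral voxels.
#' @param lp_intensity mean nucleoplasm ("light phase") intensity, a.u.
#' @param kp_true true dense/light intensity ratio, >= 1.
#' @param dna_intensity mean DNA-channel intensity inside the nucleus.
#' @param cytoplasm_intensity protein intensity outside the nucleus.
#' @param cyto_puncta_count optional cytoplasmic puncta (dense phase at
#'   `kp_true * lp_intensity`), emulating constructs that also condense in
#'   the cytoplasm.
#' @param dna_overlap fraction in `[0, 1]` of nuclear puncta placed on
#'   DNA-dense texture; the remainder is placed on DNA-poor texture.
#' @param psf_sigma per-axis Gaussian blur `(z, y, x)` in um applied to
#'   both channels after painting. The default is a mild sub-voxel blur
#'   that softens sphere edges while keeping scene parameters
#'   identifiable by region-mean estimators; see the methods vignette
#'   for how realistic (larger) confocal PSFs bias partitioning metrics.
#' @param noise_poisson_scale photons per intensity unit for Poisson shot
#'   noise; `0` disables it.
#' @param noise_gaussian_sd additive Gaussian (camera) noise sd, a.u.;
#'   `0` disables it.
#' @param voxel_size `(z, y, x)` voxel spacing in um.
#' @param grid_shape stack shape `(nz, ny, nx)` in voxels.
#' @param seed integer RNG seed; fixed seed gives bit-identical scenes.
#' @return an object of class `scene_params` (a validated list).
#' @export
scene_params <- function(nucleus_semi_axes = c(2.8, 4.5, 4.5),
                         puncta_count = 150L,
                         punctum_radius_mean = 0.35,
                         punctum_radius_sd = 0.05,
                         lp_intensity = 100,
                         kp_true = 10,
                         dna_intensity = 100,
                         cytoplasm_intensity = 0,
                         cyto_puncta_count = 0L,
                         dna_overlap = 0.7,
                         psf_sigma = c(0.05, 0.04, 0.04),
                         noise_poisson_scale = 1,
                         noise_gaussian_sd = 2,
                         voxel_size = c(0.2, 0.1, 0.1),
                         grid_shape = c(62L, 128L, 128L),
                         seed = 1L) {
  p <- list(nucleus_semi_axes = as.numeric(nucleus_semi_axes),
            puncta_count = as.integer(puncta_count),
            punctum_radius_mean = punctum_radius_mean,
            punctum_radius_sd = punctum_radius_sd,
            lp_intensity = lp_intensity, kp_true = kp_true,
            dna_intensity = dna_intensity,
            cytoplasm_intensity = cytoplasm_intensity,
            cyto_puncta_count = as.integer(cyto_puncta_count),
            dna_overlap = dna_overlap,
            psf_sigma = as.numeric(psf_sigma),
            noise_poisson_scale = noise_poisson_scale,
            noise_gaussian_sd = noise_gaussian_sd,
            voxel_size = as.numeric(voxel_size),
            grid_shape = as.integer(grid_shape),
            seed = as.integer(seed))
  stopifnot(length(p$nucleus_semi_axes) == 3, all(p$nucleus_semi_axes > 0),
            p$puncta_count >= 0, p$punctum_radius_mean > 0,
            p$punctum_radius_sd >= 0, p$lp_intensity > 0, p$kp_true >= 1,
            p$dna_overlap >= 0, p$dna_overlap <= 1,
            length(p$psf_sigma) == 3, all(p$psf_sigma >= 0),
            length(p$voxel_size) == 3, all(p$voxel_size > 0),
            length(p$grid_shape) == 3, all(p$grid_shape >= 4))
  structure(p, class = "scene_params")
}

# physical coordinate grids (um) for a given shape/spacing, voxel-centred
coord_grids <- function(shape, voxel_size) {
  list(z = (seq_len(shape[1]) - 1) * voxel_size[1],
       y = (seq_len(shape[2]) - 1) * voxel_size[2],
       x = (seq_len(shape[3]) - 1) * voxel_size[3])
}

# logical 3-D mask of an ellipsoid; center/semi_axes in um (z,y,x)
ellipsoid_mask <- function(shape, voxel_size, center, semi_axes) {
  g <- coord_grids(shape, voxel_size)
  dz2 <- ((g$z - center[1]) / semi_axes[1])^2
  dy2 <- ((g$y - center[2]) / semi_axes[2])^2
  dx2 <- ((g$x - center[3]) / semi_axes[3])^2
  ap <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  ap <= 1
}

# paint a solid sphere of given value into `vol` (adds value on top of
# whatever is present); center/radius in um
paint_sphere <- function(vol, voxel_size, center, radius, value) {
  d <- dim(vol)
  lo <- pmax(1L, as.integer(floor((center - radius) / voxel_size)) + 1L)
  hi <- pmin(d, as.integer(ceiling((center + radius) / voxel_size)) + 1L)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- (zi - 1) * voxel_size[1]; gy <- (yi - 1) * voxel_size[2]
  gx <- (xi - 1) * voxel_size[3]
  d2 <- outer(outer((gz - center[1])^2, (gy - center[2])^2, `+`),
              (gx - center[3])^2, `+`)
  sub <- vol[zi, yi, xi, drop = FALSE]
  sub[d2 <= radius^2] <- sub[d2 <= radius^2] + value
  vol[zi, yi, xi] <- sub
  vol
}

#' Generate a ground-truthed synthetic two-channel cell stack
#'
#' Builds the scene described by a [scene_params] object: an ellipsoidal
#' nucleus with uniform light-phase protein intensity, spherical puncta
#' painted at `kp_true * lp_intensity`, a smoothed random DNA texture with
#' controllable punctum/DNA overlap, optional cytoplasmic puncta, Gaussian
#' PSF-like blur, and Poisson + Gaussian noise. Puncta are placed fully
#' inside the nucleus and pairwise disjoint; placement failure beyond a
#' retry budget is an error.
#'
#' @param params a [scene_params] object.
#' @return list with elements `stack` (an [image_stack], channels
#'   `protein` and `dna`) and `truth` (ground-truth list: per-punctum
#'   table with centres in um, radii and analytic volumes
#'   `(4/3) pi r^3`, the analytic nucleus volume, `kp_true`,
#'   `lp_intensity`, and the input parameters).
#' @export
generate_cell_stack <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, generate_cell_stack_impl(params))
}

generate_cell_stack_impl <- function(p) {
  shape <- p$grid_shape
  vs <- p$voxel_size
  center <- (shape - 1) * vs / 2
  nuc <- ellipsoid_mask(shape, vs, center, p$nucleus_semi_axes)

  # DNA texture: smoothed white noise, rescaled inside the nucleus to
  # mean dna_intensity with ~50% relative contrast
  tex <- array(runif(prod(shape)), dim = shape)
  tex <- gaussian_blur_3d(tex, 0.5 / vs)
  tex <- tex - mean(tex[nuc])
  s <- stats::sd(tex[nuc])
  if (s > 0) tex <- tex / s
  dna <- array(0, shape)
  dna[nuc] <- p$dna_intensity * pmax(0.1, 1 + 0.5 * tex[nuc])

  # punctum radii (truncated below at 2 lateral voxels)
  r_min <- 2 * max(vs[2], vs[3])
  n <- p$puncta_count
  radii <- if (n > 0) pmax(r_min, rnorm(n, p$punctum_radius_mean, p$punctum_radius_sd)) else numeric(0)

  # high/low DNA classification for overlap placement
  thr_hi <- if (any(nuc)) quantile(tex[nuc], 0.6) else Inf
  thr_lo <- if (any(nuc)) quantile(tex[nuc], 0.4) else -Inf
  want_high <- if (n > 0) (runif(n) < p$dna_overlap) else logical(0)

  centers <- matrix(NA_real_, nrow = n, ncol = 3)
  placed_r <- numeric(n)
  budget <- 500L
  for (i in seq_len(n)) {
    ri <- radii[i]
    ax <- pmax(p$nucleus_semi_axes - ri - 0.05, 0.1 * p$nucleus_semi_axes)
    ok <- FALSE
    for (try in seq_len(budget)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      rad <- runif(1)^(1 / 3)
      cand <- center + rad * u * ax
      # texture preference
      vi <- pmin(pmax(round(cand / vs) + 1, 1), shape)
      tv <- tex[vi[1], vi[2], vi[3]]
      if (want_high[i] && tv < thr_hi) next
      if (!want_high[i] && tv > thr_lo) next
      if (i > 1) {
        prev <- seq_len(i - 1)
        dd <- sqrt(colSums((t(centers[prev, , drop = FALSE]) - cand)^2))
        if (any(dd < placed_r[prev] + ri + 0.1)) next
      }
      centers[i, ] <- cand
      placed_r[i] <- ri
      ok <- TRUE
      break
    }
    if (!ok) stop(sprintf("could not place punctum %d without overlap within the retry budget", i))
  }

  protein <- array(0, shape)
  protein[nuc] <- p$lp_intensity
  if (p$cytoplasm_intensity > 0) protein[!nuc] <- p$cytoplasm_intensity
  dense_add <- (p$kp_true - 1) * p$lp_intensity
  for (i in seq_len(n)) {
    protein <- paint_sphere(protein, vs, centers[i, ], placed_r[i], dense_add)
  }

  # optional cytoplasmic puncta, kept off the nucleus and stack borders
  nc <- p$cyto_puncta_count
  cyto_centers <- matrix(NA_real_, nrow = nc, ncol = 3)
  cyto_r <- numeric(nc)
  extent <- (shape - 1) * vs
  for (i in seq_len(nc)) {
    ri <- pmax(r_min, rnorm(1, p$punctum_radius_mean, p$punctum_radius_sd))
    ok <- FALSE
    for (try in seq_len(budget)) {
      cand <- runif(3, min = ri + 0.2, max = extent - ri - 0.2)
      e <- sum(((cand - center) / (p$nucleus_semi_axes + ri + 0.2))^2)
      if (e <= 1) next  # inside or touching nucleus
      if (i > 1) {
        prev <- seq_len(i - 1)
        dd <- sqrt(colSums((t(cyto_centers[prev, , drop = FALSE]) - cand)^2))
        if (any(dd < cyto_r[prev] + ri + 0.1)) next
      }
      cyto_centers[i, ] <- cand
      cyto_r[i] <- ri
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place cytoplasmic punctum within the retry budget")
    protein <- paint_sphere(protein, vs, cyto_centers[i, ], cyto_r[i],
                            p$kp_true * p$lp_intensity - p$cytoplasm_intensity)
  }

  if (any(p$psf_sigma > 0)) {
    sig_vox <- p$psf_sigma / vs
    protein <- gaussian_blur_3d(protein, sig_vox)
    dna <- gaussian_blur_3d(dna, sig_vox)
  }
  if (p$noise_poisson_scale > 0) {
    protein <- rpois(length(protein), pmax(protein, 0) * p$noise_poisson_scale) /
      p$noise_poisson_scale
    dim(protein) <- shape
    dna <- rpois(length(dna), pmax(dna, 0) * p$noise_poisson_scale) /
      p$noise_poisson_scale
    dim(dna) <- shape
  }
  if (p$noise_gaussian_sd > 0) {
    protein <- protein + rnorm(length(protein), 0, p$noise_gaussian_sd)
    dim(protein) <- shape
    dna <- dna + rnorm(length(dna), 0, p$noise_gaussian_sd)
    dim(dna) <- shape
  }
  protein <- pmax(protein, 0)
  dna <- pmax(dna, 0)

  vox <- array(0, dim = c(2L, shape))
  vox[1, , , ] <- protein
  vox[2, , , ] <- dna
  stack <- image_stack(vox, vs, c("protein", "dna"))

  puncta_df <- data.frame(
    id = seq_len(n + nc),
    z = c(centers[, 1], cyto_centers[, 1]),
    y = c(centers[, 2], cyto_centers[, 2]),
    x = c(centers[, 3], cyto_centers[, 3]),
    radius = c(placed_r, cyto_r),
    volume = (4 / 3) * pi * c(placed_r, cyto_r)^3,
    dna_high = c(want_high, rep(NA, nc)),
    compartment = c(rep("nucleus", n), rep("cytoplasm", nc)),
    stringsAsFactors = FALSE
  )
  truth <- list(
    puncta = puncta_df,
    nucleus_center = center,
    nucleus_semi_axes = p$nucleus_semi_axes,
    nucleus_volume = (4 / 3) * pi * prod(p$nucleus_semi_axes),
    kp_true = p$kp_true,
    lp_intensity = p$lp_intensity,
    params = p
  )
  list(stack = stack, truth = truth)
}
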