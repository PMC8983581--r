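# Shared scene builders for the test suite. Scenes are generated at run
# time; "small" is the workhorse validation scene (one nucleus, 50
# puncta), "tiny" favours speed over realism for plumbing tests.

small_scene_params <- function(kp_true = 10, puncta_count = 50L, seed = 11L,
                               noise = FALSE, noise_gaussian_sd = 2, ...) {
  scene_params(
    grid_shape = c(32L, 96L, 96L),
    nucleus_semi_axes = c(2.2, 3.8, 3.8),
    puncta_count = puncta_count,
    kp_true = kp_true,
    noise_poisson_scale = if (noise) 1 else 0,
    noise_gaussian_sd = if (noise) noise_gaussian_sd else 0,
    seed = seed,
    ...
  )
}

tiny_scene_params <- function(puncta_count = 12L, seed = 4L, ...) {
  scene_params(
    grid_shape = c(20L, 64L, 64L),
    nucleus_semi_axes = c(1.6, 2.6, 2.6),
    puncta_count = puncta_count,
    kp_true = 10,
    noise_poisson_scale = 0, noise_gaussian_sd = 0,
    seed = seed,
    ...
  )
}

quantify_quiet <- function(stack, ...) {
  suppressWarnings(suppressMessages(quantify_stack(stack, ...)))
}

# greedy one-to-one matching of detected puncta to ground-truth centres
match_puncta <- function(puncta, truth, tol = 0.3) {
  used <- rep(FALSE, nrow(puncta))
  tp <- 0L
  vol_err <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((puncta$centroid_z - truth$z[i])^2 +
               (puncta$centroid_y - truth$y[i])^2 +
               (puncta$centroid_x - truth$x[i])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && is.finite(dd[j]) && dd[j] < tol) {
      used[j] <- TRUE
      tp <- tp + 1L
      vol_err <- c(vol_err, abs(puncta$volume[j] / truth$volume[i] - 1))
    }
  }
  list(tp = tp, recall = tp / nrow(truth), precision = tp / nrow(puncta),
       vol_err = vol_err)
}

# an image_stack with given 3-D arrays (protein, optionally dna)
manual_stack <- function(protein, dna = NULL, voxel_size = c(0.2, 0.1, 0.1)) {
  if (is.null(dna)) {
    image_stack(array(protein, c(1L, dim(protein))), voxel_size, "protein")
  } else {
    v <- array(0, c(2L, dim(protein)))
    v[1, , , ] <- protein
    v[2, , , ] <- dna
    image_stack(v, voxel_size, c("protein", "dna"))
  }
}

# full-volume nuclei label (for detector tests isolated from nucleus
# segmentation)
full_labels <- function(stack) {
  label_volume(array(1L, dim(stack$voxels)[2:4]), stack$voxel_size, "nuclei")
}
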