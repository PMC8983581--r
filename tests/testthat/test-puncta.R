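# LoG response, seeded-watershed detection, and per-punctum measurement.

# brute-force scale-normalized LoG evaluated at chosen interior voxels:
# direct sum over a dense sampled 3-D Gaussian kernel, then second
# differences, times -sigma^2 (independent of the banded-matrix route)
brute_log_at <- function(vol, voxel_size, sigma_um, pts) {
  d <- dim(vol)
  sig_vox <- pmax(sigma_um / voxel_size, 1)  # same clamping convention
  half <- ceiling(4 * sig_vox)
  w1 <- lapply(1:3, function(a) {
    v <- exp(-0.5 * ((-half[a]:half[a]) / sig_vox[a])^2)
    v
  })
  smooth_at <- function(p) {
    # per-axis kernels truncated to in-bounds offsets and renormalized
    # (the border convention), then contracted directly against the data
    idx <- list(); wgt <- list()
    for (a in 1:3) {
      off <- (-half[a]):half[a]
      jj <- p[a] + off
      ok <- jj >= 1 & jj <= d[a]
      idx[[a]] <- jj[ok]
      wgt[[a]] <- w1[[a]][ok] / sum(w1[[a]][ok])
    }
    sub <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    acc <- 0
    for (iz in seq_along(idx[[1]])) for (iy in seq_along(idx[[2]])) {
      acc <- acc + wgt[[1]][iz] * wgt[[2]][iy] *
        sum(wgt[[3]] * sub[iz, iy, ])
    }
    acc
  }
  apply(pts, 1, function(p) {
    lap <- 0
    s0 <- smooth_at(p)
    for (axis in 1:3) {
      e <- c(0, 0, 0); e[axis] <- 1
      lap <- lap + (smooth_at(p + e) + smooth_at(p - e) - 2 * s0) /
        voxel_size[axis]^2
    }
    -sigma_um^2 * lap
  })
}

test_that("LoG response of a uniform image is numerically zero", {
  stk <- manual_stack(array(500, c(8, 16, 16)))
  resp <- suppressWarnings(log_response(stk, 1, scales = 0.3))
  expect_lt(max(abs(resp)), 1e-6 * 500)
})

test_that("LoG response peaks at the blob centre and matches brute force", {
  d <- c(13L, 21L, 21L)
  vs <- c(0.2, 0.1, 0.1)
  vol <- array(10, d)
  vol <- punctakit:::paint_sphere(vol, vs, c(1.2, 1.0, 1.0), 0.3, 90)
  stk <- manual_stack(vol, voxel_size = vs)
  resp <- suppressWarnings(log_response(stk, 1, scales = 0.3))
  expect_equal(arrayInd(which.max(resp), d), matrix(c(7L, 11L, 11L), 1))
  set.seed(5)
  pts <- cbind(sample(5:9, 12, TRUE), sample(7:15, 12, TRUE),
               sample(7:15, 12, TRUE))
  pts <- rbind(pts, c(7, 11, 11))
  ref <- brute_log_at(vol, vs, 0.3, pts)
  expect_lt(max(abs(resp[pts] - ref)) / max(abs(ref)), 0.02)
})

test_that("sub-voxel scales are clamped with a warning", {
  stk <- manual_stack(array(1, c(6, 12, 12)))
  expect_warning(log_response(stk, 1, scales = 0.1), "clamp")
})

test_that("noiseless scene puncta are each recovered with one matching truth centre", {
  p <- small_scene_params(kp_true = 10, puncta_count = 50L, seed = 11L,
                          dna_overlap = 0.5)
  sc <- generate_cell_stack(p)
  resp <- suppressWarnings(log_response(sc$stack))
  # detector isolated from nucleus segmentation: truth mask as labels
  tl <- label_volume(
    array(as.integer(punctakit:::ellipsoid_mask(p$grid_shape, p$voxel_size,
                                                sc$truth$nucleus_center,
                                                p$nucleus_semi_axes)),
          p$grid_shape),
    p$voxel_size, "nuclei")
  lab <- detect_puncta(resp, sc$stack, tl)
  rec <- suppressMessages(measure_puncta(lab, sc$stack, tl))
  m <- match_puncta(rec, sc$truth$puncta)
  expect_equal(m$tp, 50)
  expect_equal(nrow(rec), 50)
})

test_that("a blank protein channel yields zero puncta", {
  stk <- manual_stack(array(0, c(8, 24, 24)), array(0, c(8, 24, 24)))
  resp <- suppressWarnings(log_response(stk))
  lab <- detect_puncta(resp, stk, full_labels(stk))
  expect_equal(n_labels(lab), 0)
  rec <- measure_puncta(lab, stk, full_labels(stk))
  expect_equal(nrow(rec), 0)
})

test_that("seed separation controls splitting of close blob pairs", {
  d <- c(12L, 40L, 40L)
  vs <- c(0.2, 0.1, 0.1)
  build <- function(sep_um) {
    vol <- array(10, d)
    c1 <- c(1.1, 2.0, 2.0 - sep_um / 2)
    c2 <- c(1.1, 2.0, 2.0 + sep_um / 2)
    vol <- punctakit:::paint_sphere(vol, vs, c1, 0.18, 90)
    vol <- punctakit:::paint_sphere(vol, vs, c2, 0.18, 90)
    manual_stack(gaussian_blur_3d(vol, c(0.3, 0.5, 0.5)), voxel_size = vs)
  }
  far <- build(1.5 * 0.3)
  resp_far <- suppressWarnings(log_response(far, 1, scales = c(0.2, 0.3)))
  expect_equal(n_labels(detect_puncta(resp_far, far, full_labels(far))), 2)
  near <- build(0.5 * 0.3)
  resp_near <- suppressWarnings(log_response(near, 1, scales = c(0.2, 0.3)))
  expect_equal(n_labels(detect_puncta(resp_near, near, full_labels(near))), 1)
})

test_that("detection with a relative threshold is invariant to intensity scaling", {
  sc <- generate_cell_stack(tiny_scene_params(puncta_count = 10L))
  resp1 <- suppressWarnings(log_response(sc$stack))
  lab1 <- detect_puncta(resp1, sc$stack, full_labels(sc$stack))
  scaled <- sc$stack
  scaled$voxels <- scaled$voxels * 4.2
  resp2 <- suppressWarnings(log_response(scaled))
  lab2 <- detect_puncta(resp2, scaled, full_labels(scaled))
  expect_identical(lab1$labels, lab2$labels)
})

test_that("a stricter threshold never increases the puncta count", {
  sc <- generate_cell_stack(small_scene_params(puncta_count = 40L, noise = TRUE,
                                               seed = 6L))
  resp <- suppressWarnings(log_response(sc$stack))
  labs <- full_labels(sc$stack)
  counts <- sapply(c(0.9, 0.99, 0.999, 0.9999), function(prob) {
    n_labels(detect_puncta(resp, sc$stack, labs,
                           threshold_policy = list(method = "quantile", prob = prob)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("per-punctum measurements follow the bookkeeping identities", {
  d <- c(10L, 20L, 20L)
  vs <- c(0.2, 0.1, 0.1)
  plab <- array(0L, d)
  plab[5, 10, 6:15] <- 1L          # 10 voxels
  nlab <- array(1L, d)
  prot <- array(0, d)
  prot[plab == 1L] <- 50
  stk <- manual_stack(prot, voxel_size = vs)
  rec <- measure_puncta(label_volume(plab, vs, "puncta"), stk,
                        label_volume(nlab, vs, "nuclei"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$volume, 10 * 0.002)
  expect_equal(rec$mean_intensity, 50)
  expect_equal(rec$integrated_intensity, 500)
  expect_equal(rec$integrated_intensity, rec$mean_intensity * 10)
})

test_that("boundary distance matches the analytic centre-to-surface minimum", {
  p <- tiny_scene_params(puncta_count = 0L)
  sc <- generate_cell_stack(p)
  d <- p$grid_shape
  vs <- p$voxel_size
  ctr <- sc$truth$nucleus_center
  nmask <- punctakit:::ellipsoid_mask(d, vs, ctr, p$nucleus_semi_axes)
  plab <- array(0L, d)
  cv <- round(ctr / vs) + 1
  plab[cv[1], cv[2], cv[3]] <- 1L
  prot <- array(0, d)
  prot[plab == 1L] <- 10
  stk <- manual_stack(prot, voxel_size = vs)
  rec <- measure_puncta(label_volume(plab, vs, "puncta"), stk,
                        label_volume(array(as.integer(nmask), d), vs, "nuclei"))
  expect_equal(rec$nucleus_id, 1L)
  # centred punctum: nearest surface at the smallest semi-axis
  diag_vox <- sqrt(sum(vs^2))
  expect_lt(abs(rec$boundary_distance - min(p$nucleus_semi_axes)), diag_vox)
})

test_that("record count equals the number of distinct labels", {
  sc <- generate_cell_stack(tiny_scene_params(puncta_count = 8L))
  resp <- suppressWarnings(log_response(sc$stack))
  lab <- detect_puncta(resp, sc$stack, full_labels(sc$stack))
  rec <- measure_puncta(lab, sc$stack, full_labels(sc$stack))
  expect_equal(nrow(rec), n_labels(lab))
})
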