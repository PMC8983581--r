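# Per-cell partitioning metrics, colocalization, and periphery statistics.

test_that("partition coefficient is the dense/light ratio with undefined-metric guards", {
  expect_equal(partition_coefficient(5, 5), 1)
  expect_equal(partition_coefficient(20, 2), 10)
  expect_warning(k <- partition_coefficient(10, 0), "undefined")
  expect_true(is.na(k))
})

test_that("free energy of transfer follows -RT ln K_p with the right sign", {
  th <- thermo_params()   # 310.15 K
  expect_equal(delta_g_transfer(1, th), 0)
  expect_equal(delta_g_transfer(10, th), -1.987e-3 * 310.15 * log(10))
  expect_lt(delta_g_transfer(10, th), 0)    # favourable partitioning
  expect_gt(delta_g_transfer(0.5, th), 0)   # unfavourable
  ks <- c(1.5, 2, 5, 10, 40)
  expect_true(all(diff(delta_g_transfer(ks, th)) < 0))
  expect_error(delta_g_transfer(-1, th), "positive")
})

test_that("phase-exchange antisymmetry holds to machine precision", {
  th <- thermo_params()
  for (k in c(1.7, 3, 12.5, 88)) {
    expect_equal(delta_g_transfer(k, th), -delta_g_transfer(1 / k, th),
                 tolerance = 1e-12)
  }
})

test_that("PCC is exactly +/-1 for identical and inverted channels", {
  sc <- generate_cell_stack(tiny_scene_params(puncta_count = 6L))
  prot <- stack_channel(sc$stack, "protein")
  mask <- punctakit:::ellipsoid_mask(dim(prot), sc$stack$voxel_size,
                                     sc$truth$nucleus_center,
                                     sc$truth$nucleus_semi_axes)
  same <- manual_stack(prot, prot, sc$stack$voxel_size)
  expect_equal(pearson_colocalization(same, mask), 1)
  inv <- manual_stack(prot, max(prot) - prot, sc$stack$voxel_size)
  expect_equal(pearson_colocalization(inv, mask), -1)
  flat <- manual_stack(prot, array(7, dim(prot)), sc$stack$voxel_size)
  expect_warning(p <- pearson_colocalization(flat, mask), "constant")
  expect_true(is.na(p))
})

test_that("PCC is invariant under positive affine rescaling of either channel", {
  p <- tiny_scene_params(puncta_count = 8L)
  sc <- generate_cell_stack(p)
  mask <- punctakit:::ellipsoid_mask(p$grid_shape, sc$stack$voxel_size,
                                     sc$truth$nucleus_center,
                                     sc$truth$nucleus_semi_axes)
  base <- pearson_colocalization(sc$stack, mask)
  resc <- sc$stack
  resc$voxels[1, , , ] <- 3.1 * resc$voxels[1, , , ] + 12
  resc$voxels[2, , , ] <- 0.4 * resc$voxels[2, , , ] + 5
  expect_equal(pearson_colocalization(resc, mask), base, tolerance = 1e-12)
})

test_that("periphery statistics split puncta at the distance cutoff", {
  rec <- data.frame(punctum_id = 1:5, boundary_distance = c(0.1, 0.3, 0.45, 0.8, 2))
  ps <- periphery_stats(rec, cutoff = 0.5)
  expect_equal(ps$periphery_fraction, 3 / 5)
  expect_equal(ps$interior_puncta$punctum_id, c(4L, 5L))
  expect_equal(periphery_stats(rec, cutoff = 0)$periphery_fraction, 0)
  # shell construction: everything within 0.3 um of the boundary
  shell <- data.frame(punctum_id = 1:4, boundary_distance = runif(4, 0, 0.29))
  expect_equal(periphery_stats(shell, cutoff = 0.5)$periphery_fraction, 1)
  # default cutoff is the 0.5 um periphery-exclusion convention
  expect_equal(periphery_stats(rec)$periphery_fraction, 3 / 5)
  expect_true(is.na(periphery_stats(rec[0, ])$periphery_fraction))
})

test_that("cell metrics: density arithmetic and zero-punctum conventions", {
  d <- c(10L, 24L, 24L)
  vs <- c(0.25, 0.2, 0.2)   # voxel volume 0.01
  nlab <- array(0L, d)
  nlab[2:9, 3:22, 3:22] <- 1L
  nvol <- sum(nlab) * 0.01
  prot <- array(0, d); prot[nlab == 1L] <- 100
  stk <- manual_stack(prot, array(40, d) + prot * 0.1, vs)
  nl <- label_volume(nlab, vs, "nuclei")
  nuc <- measure_nuclei(nl, stk)
  # five one-voxel puncta
  plab <- array(0L, d)
  px <- cbind(5, 10, seq(5, 17, by = 3))
  plab[px] <- seq_len(5)
  prot2 <- prot; prot2[px] <- 500
  stk2 <- manual_stack(prot2, array(40, d) + prot2 * 0.1, vs)
  pl <- label_volume(plab, vs, "puncta")
  rec <- measure_puncta(pl, stk2, nl)
  cm <- cell_metrics(nuc, rec, nl, pl, stk2, boundary_margin = 0)
  expect_equal(cm$puncta_density, 1000 * 5 / nvol)
  expect_equal(cm$v_p, 0.01)
  expect_equal(cm$dp, 500)
  expect_equal(cm$k_p, cm$dp / cm$lp)
  # zero-punctum cell: density defined (0), distribution metrics undefined
  cm0 <- suppressWarnings(
    cell_metrics(nuc, rec[0, ], nl, label_volume(array(0L, d), vs, "puncta"),
                 stk, boundary_margin = 0))
  expect_equal(cm0$puncta_density, 0)
  expect_equal(cm0$n_puncta, 0)
  expect_true(is.na(cm0$v_p) && is.na(cm0$dp) && is.na(cm0$k_p) &&
              is.na(cm0$delta_g_tr))
  expect_false(is.na(cm0$lp))
  expect_false(is.na(cm0$total_concentration))
})

test_that("calibration maps intensities linearly and ratios stay calibration-free", {
  sc <- generate_cell_stack(small_scene_params(kp_true = 5, puncta_count = 40L,
                                               seed = 13L))
  q1 <- quantify_quiet(sc$stack)
  q2 <- quantify_quiet(sc$stack, calib = calibration_model(slope = 0.01))
  expect_equal(q2$cells$lp, 0.01 * q1$cells$lp)
  expect_equal(q2$cells$dp, 0.01 * q1$cells$dp)
  expect_equal(q2$cells$k_p, q1$cells$k_p, tolerance = 1e-12)
  # spec example: lp_intensity 100, slope 0.01 -> [LP] ~ 1 umol/L, [DP] ~ 5
  expect_lt(abs(q2$cells$lp - 1), 0.1)
  expect_lt(abs(q2$cells$dp - 5), 0.5)
})

test_that("total nuclear concentration lies between [LP] and [DP]", {
  sc <- generate_cell_stack(small_scene_params(kp_true = 10, puncta_count = 50L,
                                               seed = 11L))
  q <- quantify_quiet(sc$stack)
  expect_gt(q$cells$total_concentration, q$cells$lp)
  expect_lt(q$cells$total_concentration, q$cells$dp)
})
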