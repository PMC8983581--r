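# Ground-truthed scene generation: determinism, geometry, intensity
# conservation, and the auxiliary generators (FRAP, dilution, turbidity,
# construct sequences).

test_that("empty noiseless scene is uniform at lp_intensity inside the nucleus", {
  p <- tiny_scene_params(puncta_count = 0L, psf_sigma = c(0, 0, 0))
  sc <- generate_cell_stack(p)
  prot <- stack_channel(sc$stack, "protein")
  nuc <- punctakit:::ellipsoid_mask(p$grid_shape, p$voxel_size,
                                    sc$truth$nucleus_center, p$nucleus_semi_axes)
  expect_true(all(prot[nuc] == p$lp_intensity))
  expect_true(all(prot[!nuc] == 0))
  expect_equal(nrow(sc$truth$puncta), 0)
})

test_that("default acquisition geometry spans 12.2 um at 0.2 um z-spacing", {
  p <- scene_params()
  expect_equal(p$grid_shape[1], 62L)
  expect_equal(p$voxel_size[1], 0.2)
  expect_equal((p$grid_shape[1] - 1) * p$voxel_size[1], 12.2)
})

test_that("scene generation is bit-identical under a fixed seed", {
  p <- tiny_scene_params(seed = 9L)
  a <- generate_cell_stack(p)
  b <- generate_cell_stack(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$puncta, b$truth$puncta)
  c <- generate_cell_stack(tiny_scene_params(seed = 10L))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("total intensity matches the analytic scene integral within 1%", {
  p <- small_scene_params(kp_true = 10, seed = 21L)
  sc <- generate_cell_stack(p)
  prot <- stack_channel(sc$stack, "protein")
  # independent voxelization of the truth geometry
  nuc <- punctakit:::ellipsoid_mask(p$grid_shape, p$voxel_size,
                                    sc$truth$nucleus_center, p$nucleus_semi_axes)
  n_pun_vox <- 0
  g <- punctakit:::coord_grids(p$grid_shape, p$voxel_size)
  for (i in seq_len(nrow(sc$truth$puncta))) {
    tr <- sc$truth$puncta[i, ]
    d2 <- outer(outer((g$z - tr$z)^2, (g$y - tr$y)^2, `+`), (g$x - tr$x)^2, `+`)
    n_pun_vox <- n_pun_vox + sum(d2 <= tr$radius^2)
  }
  expected <- p$lp_intensity * sum(nuc) +
    (p$kp_true - 1) * p$lp_intensity * n_pun_vox
  expect_lt(abs(sum(prot) / expected - 1), 0.01)
})

test_that("increasing kp_true strictly increases mean punctum-core intensity", {
  means <- sapply(c(2, 5, 10), function(kp) {
    p <- tiny_scene_params(puncta_count = 10L, seed = 3L)
    p$kp_true <- kp
    sc <- generate_cell_stack(p)
    prot <- stack_channel(sc$stack, "protein")
    g <- punctakit:::coord_grids(p$grid_shape, p$voxel_size)
    core <- array(FALSE, p$grid_shape)
    for (i in seq_len(nrow(sc$truth$puncta))) {
      tr <- sc$truth$puncta[i, ]
      d2 <- outer(outer((g$z - tr$z)^2, (g$y - tr$y)^2, `+`), (g$x - tr$x)^2, `+`)
      core <- core | (d2 <= (0.5 * tr$radius)^2)
    }
    mean(prot[core])
  })
  expect_true(all(diff(means) > 0))
})

test_that("ground truth records analytic sphere volumes and placement is disjoint", {
  p <- small_scene_params(puncta_count = 30L, seed = 8L)
  sc <- generate_cell_stack(p)
  tr <- sc$truth$puncta
  expect_equal(tr$volume, (4 / 3) * pi * tr$radius^3)
  expect_equal(sc$truth$nucleus_volume, (4 / 3) * pi * prod(p$nucleus_semi_axes))
  dmat <- as.matrix(dist(tr[, c("z", "y", "x")]))
  diag(dmat) <- Inf
  rsum <- outer(tr$radius, tr$radius, `+`)
  expect_true(all(dmat >= rsum))
  # puncta fully inside the nucleus
  ctr <- sc$truth$nucleus_center
  e <- sqrt(((tr$z - ctr[1]) / p$nucleus_semi_axes[1])^2 +
            ((tr$y - ctr[2]) / p$nucleus_semi_axes[2])^2 +
            ((tr$x - ctr[3]) / p$nucleus_semi_axes[3])^2)
  expect_true(all(e < 1))
})

test_that("impossible placement densities raise a placement error", {
  p <- tiny_scene_params(puncta_count = 120L, punctum_radius_mean = 0.5,
                         punctum_radius_sd = 0.01)
  expect_error(generate_cell_stack(p), "retry budget")
})

test_that("cytoplasmic puncta land outside the nucleus when requested", {
  p <- tiny_scene_params(puncta_count = 5L, cyto_puncta_count = 4L,
                         cytoplasm_intensity = 10)
  sc <- generate_cell_stack(p)
  tr <- sc$truth$puncta
  expect_equal(sum(tr$compartment == "cytoplasm"), 4)
  cy <- tr[tr$compartment == "cytoplasm", ]
  ctr <- sc$truth$nucleus_center
  e <- sqrt(((cy$z - ctr[1]) / p$nucleus_semi_axes[1])^2 +
            ((cy$y - ctr[2]) / p$nucleus_semi_axes[2])^2 +
            ((cy$x - ctr[3]) / p$nucleus_semi_axes[3])^2)
  expect_true(all(e > 1))
})

test_that("FRAP trace generator follows the recovery model exactly", {
  tr <- generate_frap_trace(t_half = 10, m_f = 0.8, noise_sd = 0,
                            n_points = 61, t_max = 30)
  nm <- normalize_trace(tr)
  frac <- (nm$value - 0.5) / 0.5        # recovered fraction (bleach depth 0.5)
  expect_equal(frac[nm$time == 10], 0.8 / 2, tolerance = 1e-12)
  expect_equal(frac[nm$time == 30], 0.8 * (1 - 2^-3), tolerance = 1e-12)
  # full recovery limit
  tr2 <- generate_frap_trace(t_half = 2, m_f = 1, noise_sd = 0,
                             n_points = 50, t_max = 200)
  nm2 <- normalize_trace(tr2)
  expect_equal(tail(nm2$value, 1), 1, tolerance = 1e-6)
  expect_error(generate_frap_trace(t_half = -1, m_f = 0.5), "positive")
  expect_error(generate_frap_trace(t_half = 5, m_f = 1.4), "m_f")
})

test_that("dilution series is condensate-free below csat and grows above", {
  ds <- generate_dilution_series(50, c(10, 20, 40, 80, 160), seed = 2)
  expect_equal(ds$n_spots_true[ds$concentrations < 50], c(0, 0, 0))
  pos <- ds$n_spots_true[ds$concentrations >= 50]
  expect_true(all(pos >= 6))
  expect_true(all(diff(pos) > 0))
  expect_error(generate_dilution_series(50, numeric(0)), "empty")
  expect_error(generate_dilution_series(50, c(20, 10)), "ascending")
})

test_that("construct generator emits exactly the requested motif counts", {
  s <- generate_construct_sequence(17, 21, 3, 6, seed = 1)
  expect_equal(count_fg(s), 38)
  expect_equal(count_glfg(s), 9)
  expect_equal(count_fg(s, "nterm"), 17)
  expect_equal(count_fg(s, "cterm"), 21)
  expect_equal(count_glfg(s, "nterm"), 3)
  expect_equal(count_glfg(s, "cterm"), 6)
  z <- generate_construct_sequence(0, 0, 0, 0, seed = 1)
  expect_equal(count_fg(z), 0)
  expect_error(generate_construct_sequence(2, 2, 3, 0), "exceed")
  expect_error(generate_construct_sequence(-1, 2), "non-negative")
})

test_that("independent regex scan confirms generated counts across random cases", {
  set.seed(77)
  for (rep in 1:15) {
    nf <- sample(0:12, 2, replace = TRUE)
    ng <- c(sample(0:nf[1], 1), sample(0:nf[2], 1))
    s <- generate_construct_sequence(nf[1], nf[2], ng[1], ng[2],
                                     seed = sample.int(1e6, 1))
    res <- s$residues
    cnt <- function(pat) {
      m <- gregexpr(paste0("(?=", pat, ")"), res, perl = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }
    expect_equal(cnt("FG"), nf[1] + nf[2])
    expect_equal(cnt("GLFG"), ng[1] + ng[2])
  }
})
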