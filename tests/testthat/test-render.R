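test_that("an empty cell list renders pure background", {
  stk <- render_stack(empty_truth(), test_optics(), c(10, 40, 40), seed = 1)
  x <- stk$grids$dapi$data
  # per-voxel variance: Poisson shot (bg/gain) + read noise
  o <- test_optics()
  se <- sqrt((o$background_level / o$photon_scale + o$noise_gaussian_sd^2) /
             length(x))
  expect_lt(abs(mean(x) - o$background_level), 3 * se)
})

test_that("the brightest DAPI voxel sits at the nucleus center (noise-free)", {
  cells <- data.frame(id = 1L, x = 1.2, y = -0.7, z = 0.4, radius = 3)
  truth <- assign_phenotypes(cells, phenotype_model(), seed = 1)
  stk <- render_stack(truth, noise_free_optics(), c(10, 40, 40), seed = 1)
  g <- stk$grids$dapi
  idx <- arrayInd(which.max(g$data), dim(g$data))
  tr <- attr(stk, "truth")
  true_idx <- floor(c(tr$z_um, tr$y_um, tr$x_um) / g$voxel_size) + 1
  # the brightest voxel is the centroid voxel or an immediate neighbor
  expect_true(all(abs(idx - true_idx) <= 1))
})

test_that("integrated signal grows with nucleus count and adds linearly", {
  o <- noise_free_optics()
  g <- generate_spheroid_geometry(100, spheroid_radius = 40,
                                  nucleus_radius_cv = 0, seed = 5)
  model <- phenotype_model(beta_fraction = 1, nkx_cv_beta = 0)
  t <- assign_phenotypes(g, model, seed = 5)
  t$dapi_amp <- 1000
  shape <- stack_shape_for(40, o)
  integ <- function(tt) {
    s <- render_stack(tt, o, shape, seed = 1)
    sum(s$grids$dapi$data) - o$background_level * prod(shape)
  }
  v10 <- integ(t[1:10, ]); v50 <- integ(t[1:50, ]); v100 <- integ(t)
  expect_true(v10 < v50 && v50 < v100)
  # linearity in disjoint cell sets
  vA <- integ(t[1:40, ]); vB <- integ(t[41:100, ])
  expect_equal(vA + vB, v100, tolerance = 0.01)
})

test_that("cells outside the stack raise an error naming them", {
  cells <- data.frame(id = c(1L, 99L), x = c(0, 500), y = 0, z = 0, radius = 3)
  truth <- assign_phenotypes(cells, phenotype_model(), seed = 1)
  expect_error(render_stack(truth, test_optics(), c(10, 40, 40), seed = 1),
               "outside stack bounds.*99")
})

test_that("rendering is bit-identical for identical seed and config", {
  g <- generate_spheroid_geometry(30, spheroid_radius = 18, seed = 4)
  t <- assign_phenotypes(g, phenotype_model(), seed = 4)
  a <- render_stack(t, test_optics(), c(14, 84, 84), seed = 11)
  b <- render_stack(t, test_optics(), c(14, 84, 84), seed = 11)
  expect_identical(a$grids$dapi$data, b$grids$dapi$data)
  expect_identical(a$grids$nkx6_1$data, b$grids$nkx6_1$data)
  expect_identical(a$grids$edu$data, b$grids$edu$data)
})
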