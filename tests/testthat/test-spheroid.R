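test_that("the detected spheroid matches the true ball on a noise-free render", {
  pheno <- phenotype_model()
  g <- generate_spheroid_geometry(200, 40, seed = 9)
  t <- assign_phenotypes(g, pheno, seed = 9)
  stk <- render_mt(t, noise_free_optics(), 40, seed = 9)
  sph <- detect_spheroid(stk$grids$dapi)
  ball <- truth_ball(stk, 40)
  jaccard <- sum(sph$mask & ball) / sum(sph$mask | ball)
  expect_gte(jaccard, 0.90)
  # volume invariant: within 15% of the analytic truth
  expect_lt(abs(spheroid_volume(sph) - 4 / 3 * pi * 40^3) / (4 / 3 * pi * 40^3),
            0.15)
  # single connected component
  lab <- isletmt:::cpp_label_components(as.vector(sph$mask), dim(sph$mask), 26L)
  expect_equal(attr(lab, "n_labels"), 1L)
})

test_that("background-only stacks raise 'no spheroid detected'", {
  stk <- render_stack(empty_truth(), test_optics(), c(20, 100, 100), seed = 1)
  expect_error(detect_spheroid(stk$grids$dapi), "no spheroid detected")
})

test_that("with two spheroids in one stack, only the larger is kept", {
  gA <- generate_spheroid_geometry(150, 35, seed = 7); gA$x <- gA$x - 40
  gB <- generate_spheroid_geometry(30, 18, seed = 8); gB$x <- gB$x + 55
  both <- rbind(gA, gB); both$id <- seq_len(nrow(both))
  t <- assign_phenotypes(both, phenotype_model(), seed = 7)
  # diffuse tissue signal of each spheroid, as one dim ball per spheroid
  diff_rows <- t[1:2, ]
  diff_rows$id <- max(t$id) + 1:2
  diff_rows[, c("x", "y", "z")] <- rbind(c(-40, 0, 0), c(55, 0, 0))
  diff_rows$radius <- c(35, 18)
  diff_rows$is_beta <- FALSE; diff_rows$is_proliferating <- FALSE
  diff_rows$dapi_amp <- 150; diff_rows$nkx_amp <- 0; diff_rows$edu_amp <- 0
  stk <- render_stack(rbind(t, diff_rows), test_optics(), c(30, 180, 360),
                      seed = 7)
  sph <- detect_spheroid(stk$grids$dapi)
  xs <- which(apply(sph$mask, 3, any))
  # the large spheroid is centered at x = 50 um (voxel 100), the small at
  # x = 145 um (voxel 290); the mask must not reach the small one
  expect_lt(max(xs), 220)
  expect_gt(length(xs), 100)
})

test_that("spheroid detection is deterministic", {
  stk <- simulate_mt(n_cells = 100, spheroid_radius = 30, seed = 2)
  a <- detect_spheroid(stk$grids$dapi)
  b <- detect_spheroid(stk$grids$dapi)
  expect_identical(a$mask, b$mask)
  expect_identical(a$threshold_used, b$threshold_used)
})
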