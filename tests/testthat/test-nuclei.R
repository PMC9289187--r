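test_that("well-separated nuclei are segmented one-to-one", {
  g <- generate_spheroid_geometry(50, spheroid_radius = 40,
                                  nucleus_radius_cv = 0, seed = 3,
                                  packing_tolerance = 2)
  # spacing >= 4x the 3 um nucleus radius, by construction
  d <- as.matrix(dist(g[, c("x", "y", "z")])); diag(d) <- Inf
  expect_gte(min(d), 12)
  t <- assign_phenotypes(g, phenotype_model(), seed = 3)
  stk <- render_mt(t, hi_snr_optics(), 40, seed = 3)
  a <- suppressWarnings(analyze_stack(stk))
  expect_equal(a$nuclei$n_labels, 50L)
  at <- labels_at_truth(a$nuclei, attr(stk, "truth"))
  expect_true(all(at > 0))
  expect_false(any(duplicated(at)))
})

test_that("an all-background stack yields zero labels, not an error", {
  stk <- render_stack(empty_truth(), test_optics(), c(10, 60, 60), seed = 2)
  nl <- segment_nuclei(stk$grids$dapi, full_mask(stk))
  expect_equal(nl$n_labels, 0L)
  # empty spheroid mask likewise
  m <- full_mask(stk); m$mask[] <- FALSE
  expect_equal(segment_nuclei(stk$grids$dapi, m)$n_labels, 0L)
})

test_that("touching nuclei are split by the watershed", {
  # centers 9 um apart = 1.5x the radius sum; blurred into one blob
  pair <- data.frame(id = 1:2, x = c(-4.5, 4.5), y = 0, z = 0, radius = 3)
  t <- assign_phenotypes(pair, phenotype_model(), seed = 1)
  stk <- render_stack(t, hi_snr_optics(), c(12, 80, 80), seed = 1)
  nl <- segment_nuclei(stk$grids$dapi, full_mask(stk))
  expect_equal(nl$n_labels, 2L)
})

test_that("a local-threshold window under 3 voxels is a config error", {
  stk <- simulate_mt(n_cells = 20, spheroid_radius = 20, seed = 1)
  sph <- detect_spheroid(stk$grids$dapi)
  expect_error(segment_nuclei(stk$grids$dapi, sph,
                              pipeline_config(window_um = 1)),
               "window")
})

test_that("labels live inside the mask with volumes inside the gates", {
  stk <- simulate_mt(n_cells = 100, spheroid_radius = 30, seed = 6)
  cfg <- pipeline_config()
  sph <- detect_spheroid(stk$grids$dapi, cfg)
  nl <- segment_nuclei(stk$grids$dapi, sph, cfg)
  expect_gt(nl$n_labels, 0L)
  expect_true(all(sph$mask[nl$labels > 0]))
  vols <- table(nl$labels[nl$labels > 0]) * prod(nl$voxel_size)
  expect_true(all(vols >= cfg$min_volume_um3 & vols <= cfg$max_volume_um3))
  # consecutive labels
  expect_setequal(sort(unique(as.vector(nl$labels[nl$labels > 0]))),
                  seq_len(nl$n_labels))
  # determinism
  nl2 <- segment_nuclei(stk$grids$dapi, sph, cfg)
  expect_identical(nl$labels, nl2$labels)
})
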