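test_that("null dose reproduces the baseline proliferation rate", {
  pheno <- phenotype_model()
  dm <- dose_effect_model()
  layout <- default_plate_layout(doses = 0, n_mts = 40)
  sim <- simulate_plate(layout, dm, pheno, n_cells = 500,
                        spheroid_radius = 60, seed = 5, render = FALSE)
  frac <- mean(sim$truth$is_proliferating)
  p0 <- expected_prolif_total(pheno)
  se <- sqrt(p0 * (1 - p0) / nrow(sim$truth))
  expect_lt(abs(frac - p0), 4 * se)
})

test_that("expected proliferation is non-decreasing in dose for any Hill model", {
  set.seed(20)
  for (i in 1:25) {
    dm <- dose_effect_model(emax_prolif_beta = runif(1, 0.01, 0.5),
                            emax_prolif_nonbeta = runif(1, 0.01, 0.5),
                            ec50 = runif(1, 0.1, 10), hill = runif(1, 0.2, 5))
    pheno <- phenotype_model(beta_fraction = runif(1))
    doses <- sort(runif(6, 0, 10))
    p <- vapply(doses, function(d)
      prolif_rates_at_dose(dm, pheno, d)$expected_total, numeric(1))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("plate simulation is reproducible and validates its layout", {
  layout <- default_plate_layout(doses = c(0, 5), n_mts = 2)
  a <- simulate_plate(layout, seed = 3, n_cells = 50, render = FALSE)
  b <- simulate_plate(layout, seed = 3, n_cells = 50, render = FALSE)
  expect_identical(a$truth, b$truth)
  expect_identical(a$functional, b$functional)
  expect_equal(length(a$mts), 4L)
  bad <- layout; bad$dose_uM[1] <- -1
  expect_error(simulate_plate(bad, seed = 1), "doses must be >= 0")
  dup <- rbind(layout, layout[1, ])
  expect_error(simulate_plate(dup, seed = 1), "duplicate well")
  expect_error(simulate_plate(layout[, "well", drop = FALSE], seed = 1),
               "layout must contain")
})

test_that("functional endpoints center on their dose-dependent means", {
  dm <- dose_effect_model(endpoint_cv = 0.15)
  layout <- default_plate_layout(doses = c(0, 10), n_mts = 200)
  sim <- simulate_plate(layout, dm, n_cells = 10, seed = 8, render = FALSE)
  f0 <- sim$functional[sim$functional$dose_uM == 0, ]
  expect_equal(mean(f0$basal_secretion), dm$baseline_basal, tolerance = 0.05)
  expect_equal(mean(f0$insulin_content), dm$baseline_content, tolerance = 0.05)
  f10 <- sim$functional[sim$functional$dose_uM == 10, ]
  # basal rises linearly with dose; content is depleted
  expect_gt(mean(f10$basal_secretion), mean(f0$basal_secretion))
  expect_lt(mean(f10$insulin_content), mean(f0$insulin_content))
})

test_that("Hill fits to simulated EdU fractions recover the EC50 within 2x", {
  pheno <- phenotype_model()
  dm <- dose_effect_model()
  doses <- c(0, 1, 3.3, 5, 10)
  n_cells <- 200L
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    d <- rep(doses, each = 12)
    p <- vapply(d, function(x)
      prolif_rates_at_dose(dm, pheno, x)$expected_total, numeric(1))
    y <- rbinom(length(d), n_cells, p) / n_cells
    co <- tryCatch(fit_hill(d, y), error = function(e) NULL)
    !is.null(co) && co[["ec50"]] > dm$ec50 / 2 && co[["ec50"]] < dm$ec50 * 2
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})
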