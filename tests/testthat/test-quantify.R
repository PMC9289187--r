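test_that("label colocalization is exactly the set intersection", {
  expect_equal(colocalize_labels(c(1, 2, 3), c(4, 5)), integer(0))
  expect_equal(colocalize_labels(c(1, 2, 3), c(2, 3, 4)), c(2L, 3L))
  expect_equal(colocalize_labels(integer(0), c(1, 2)), integer(0))
})

test_that("per-MT percentages follow the count definitions", {
  recs <- data.frame(mt_id = "m", label = 1:100,
                     x_um = 0, y_um = 0, z_um = 0, volume_um3 = 100,
                     mean_dapi = 1, mean_nkx = 1, mean_edu = 1,
                     is_beta = rep(c(TRUE, FALSE), c(60, 40)),
                     is_edu = FALSE)
  recs$is_edu[recs$is_beta][1:4] <- TRUE   # 4 EdU+ beta
  recs$is_edu[!recs$is_beta][1:6] <- TRUE  # 6 EdU+ non-beta
  q <- quantify_mt(recs, spheroid_volume = 1e5)
  expect_equal(q$pct_beta, 60)
  expect_equal(q$pct_prolif_total, 10)
  expect_equal(q$pct_prolif_beta, 100 * 4 / 60)
  expect_equal(q$pct_prolif_nonbeta, 15)
  # conservation identities
  expect_equal(q$n_edu_beta + (q$n_edu - q$n_edu_beta), q$n_edu)
  expect_equal(q$n_beta + (q$n_total - q$n_beta), q$n_total)
  # monotonicity: adding one EdU+ beta record increments all four counts
  extra <- recs[1, ]; extra$label <- 101L
  extra$is_beta <- TRUE; extra$is_edu <- TRUE
  q2 <- quantify_mt(rbind(recs, extra), spheroid_volume = 1e5)
  expect_equal(unlist(q2[c("n_total", "n_beta", "n_edu", "n_edu_beta")]),
               unlist(q[c("n_total", "n_beta", "n_edu", "n_edu_beta")]) + 1)
})

test_that("zero denominators yield NA percentages with a warning", {
  recs <- data.frame(mt_id = "m", label = 1:50,
                     x_um = 0, y_um = 0, z_um = 0, volume_um3 = 100,
                     mean_dapi = 1, mean_nkx = 1, mean_edu = 1,
                     is_beta = FALSE, is_edu = rep(c(TRUE, FALSE), c(5, 45)))
  expect_warning(q <- quantify_mt(recs), "pct_prolif_beta")
  expect_true(is.na(q$pct_prolif_beta))
  expect_equal(q$pct_prolif_nonbeta, 10)
  # empty record list: zero counts, NA percentages
  e <- suppressWarnings(quantify_mt(recs[0, ]))
  expect_equal(e$n_total, 0)
  expect_true(is.na(e$pct_beta))
})

test_that("group-mean counts reproduce the control-condition worked example", {
  q <- quantify_mt(list(n_total = 1405, n_beta = NA_real_, n_edu = 2.7,
                        n_edu_beta = NA_real_))
  expect_equal(round(q$pct_prolif_total, 1), 0.2)
})

test_that("spheroid volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 20, 20))
  m[1:10, 1:10, 1:10] <- TRUE           # 1000 voxels
  sph <- structure(list(mask = m, threshold_used = 0,
                        voxel_size = c(3, 0.5, 0.5)), class = "spheroid_mask")
  expect_equal(spheroid_volume(sph), 1000 * 0.75)
  sph$mask[] <- FALSE
  expect_equal(spheroid_volume(sph), 0)
  # rasterized 50 um ball at default resolution vs the analytic volume
  d3 <- c(36, 220, 220); vs <- c(3, 0.5, 0.5)
  ctr <- d3 * vs / 2
  zc <- (seq_len(d3[1]) - 0.5) * vs[1]; yc <- (seq_len(d3[2]) - 0.5) * vs[2]
  xc <- (seq_len(d3[3]) - 0.5) * vs[3]
  ball <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"),
                (xc - ctr[3])^2, "+") <= 50^2
  sphb <- structure(list(mask = ball, threshold_used = 0, voxel_size = vs),
                    class = "spheroid_mask")
  expect_lt(abs(spheroid_volume(sphb) - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3),
            0.03)
})

test_that("relative volume changes match an elementwise loop oracle", {
  expect_equal(volume_change(data.frame(timepoint = c(0, 4),
                                        volume = c(100, 100)))$rel_change, 0)
  expect_equal(volume_change(data.frame(timepoint = c(0, 4),
                                        volume = c(100, 120)))$rel_change, 0.2)
  set.seed(10)
  v <- data.frame(timepoint = 1:8, volume = runif(8, 50, 150))
  got <- volume_change(v)$rel_change
  oracle <- numeric(7)
  for (i in 1:7) oracle[i] <- (v$volume[i + 1] - v$volume[i]) / v$volume[i]
  expect_equal(got, oracle)
  expect_error(volume_change(data.frame(timepoint = 1, volume = 10)),
               "at least 2")
  expect_error(volume_change(data.frame(timepoint = 1:2, volume = c(1, -1))),
               "positive")
})
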