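tiny_config <- function(seed = 1) {
  cfg <- read_run_config(NULL)
  cfg$seed <- seed
  cfg$n_cells <- 20
  cfg$spheroid_radius <- 20
  cfg$n_mts_per_well <- 1
  cfg$doses <- 0
  cfg$pipeline <- pipeline_config(min_spheroid_volume_um3 = 1000)
  cfg
}

test_that("the smallest valid run writes parseable artifacts and a manifest", {
  dir <- withr::local_tempdir()
  run_simulate(tiny_config(), dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(c("plate_layout.csv", "ground_truth.csv",
                    "functional.csv") %in% man$file))
  expect_equal(sum(grepl("\\.tif$", man$file)), 1L)  # 1 well x 1 MT
  stk <- read_stack(file.path(dir, grep("\\.tif$", man$file, value = TRUE)))
  expect_s3_class(stk, "mt_stack")
  truth <- read_ground_truth(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(truth), 20L)
})

test_that("identical configs produce byte-identical manifests", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(tiny_config(), d1)
  run_simulate(tiny_config(), d2)
  m1 <- read.csv(file.path(d1, "manifest.csv"))
  m2 <- read.csv(file.path(d2, "manifest.csv"))
  expect_identical(m1, m2)       # file names and content hashes
})

test_that("analysis covers every simulated MT and is idempotent", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  cfg$n_mts_per_well <- 2
  cfg$doses <- c(0, 10)
  run_simulate(cfg, file.path(dir, "sim"))
  res <- run_analyze(file.path(dir, "sim"),
                     file.path(dir, "sim", "plate_layout.csv"),
                     file.path(dir, "out"), cfg,
                     functional = file.path(dir, "sim", "functional.csv"))
  expect_equal(nrow(res$per_mt), 4L)
  expect_length(res$failures, 0L)
  expect_true(file.exists(file.path(dir, "out", "per_mt.csv")))
  expect_true(file.exists(file.path(dir, "out", "group_summary.csv")))
  per_mt_1 <- read.csv(file.path(dir, "out", "per_mt.csv"))
  res2 <- run_analyze(file.path(dir, "sim"),
                      file.path(dir, "sim", "plate_layout.csv"),
                      file.path(dir, "out2"), cfg,
                      functional = file.path(dir, "sim", "functional.csv"))
  per_mt_2 <- read.csv(file.path(dir, "out2", "per_mt.csv"))
  expect_identical(per_mt_1, per_mt_2)
})

test_that("a corrupted stack is logged and skipped, never fatal", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  cfg$n_mts_per_well <- 3
  run_simulate(cfg, file.path(dir, "sim"))
  tifs <- list.files(file.path(dir, "sim"), pattern = "\\.tif$",
                     full.names = TRUE)
  writeLines("not a tiff", tifs[1])
  res <- suppressMessages(
    run_analyze(file.path(dir, "sim"),
                file.path(dir, "sim", "plate_layout.csv"),
                file.path(dir, "out"), cfg))
  expect_equal(nrow(res$per_mt), 2L)
  expect_length(res$failures, 1L)
  log <- readLines(file.path(dir, "out", "run.log"))
  expect_true(any(grepl("FAILED", log)))
  # no parseable stacks at all is fatal
  for (t in tifs) writeLines("still not a tiff", t)
  expect_error(suppressMessages(
    run_analyze(file.path(dir, "sim"),
                file.path(dir, "sim", "plate_layout.csv"),
                file.path(dir, "out3"), cfg)), "no parseable stacks")
})
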