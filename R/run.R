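#' Read a run configuration from YAML
#'
#' A single YAML file with optional blocks `optics`, `phenotype`,
#' `dose_effect`, `pipeline`, `simulation` (n_cells, spheroid_radius,
#' n_mts_per_well, doses) and a top-level `seed`. Missing fields fall back to
#' the package defaults.
#'
#' @param path YAML path.
#' @return List of class `run_config` with materialized config objects.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, raw[[block]] %||% list())
  seed <- raw$seed %||% 1
  if (!is.numeric(seed) || seed < 0 || seed != round(seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  sim <- raw$simulation %||% list()
  structure(list(seed = as.integer(seed),
                 optics = build(optics_config, "optics"),
                 phenotype = build(phenotype_model, "phenotype"),
                 dose_effect = build(dose_effect_model, "dose_effect"),
                 pipeline = build(pipeline_config, "pipeline"),
                 n_cells = sim$n_cells %||% 200,
                 spheroid_radius = sim$spheroid_radius %||% 40,
                 n_mts_per_well = sim$n_mts_per_well %||% NULL,
                 doses = unlist(sim$doses) %||% c(0, 1, 3.3, 5, 10),
                 raw = raw),
            class = "run_config")
}

# Manifest of written artifacts with content hashes, for reproducibility.
write_manifest <- function(files, out_dir, seed) {
  files <- sort(files)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_files = nrow(manifest)),
                       file.path(out_dir, "run_meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Simulate a plate and write all artifacts
#'
#' Writes per-MT TIFF stacks (+ JSON sidecars), ground-truth CSV, functional
#' CSV, plate-layout CSV, the resolved seed, and a manifest with an MD5
#' content hash per artifact. Deterministic given the seed.
#'
#' @param config A `run_config` from [read_run_config()] (or `NULL` for
#'   defaults).
#' @param out_dir Output directory.
#' @param layout Optional layout data frame; defaults to
#'   [default_plate_layout()] over `config$doses`.
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(config = NULL, out_dir, layout = NULL) {
  if (is.null(config)) config <- read_run_config(NULL)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  layout <- layout %||% default_plate_layout(doses = config$doses,
                                             n_mts = config$n_mts_per_well %||% 6)
  sim <- simulate_plate(layout, config$dose_effect, config$phenotype,
                        config$optics,
                        n_mts_per_well = config$n_mts_per_well,
                        n_cells = config$n_cells,
                        spheroid_radius = config$spheroid_radius,
                        seed = config$seed, out_dir = out_dir)
  write.csv(layout, file.path(out_dir, "plate_layout.csv"), row.names = FALSE)
  write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.csv"))
  write_functional(sim$functional, file.path(out_dir, "functional.csv"))
  files <- c(list.files(out_dir, pattern = "\\.(tif|json)$", full.names = TRUE),
             file.path(out_dir, c("plate_layout.csv", "ground_truth.csv",
                                  "functional.csv")))
  files <- setdiff(files, file.path(out_dir, "run_meta.json"))
  invisible(write_manifest(files, out_dir, config$seed))
}

#' Analyze a directory of microtissue stacks
#'
#' Runs [analyze_stack()] on every TIFF in `stacks_dir`, joins well metadata
#' from the layout, and writes `per_mt.csv` (one row per microtissue),
#' `per_nucleus.csv`, and dose-response summaries for the image-derived
#' endpoints (plus functional endpoints when a functional CSV is supplied).
#' A stack that fails to parse or analyze is logged and skipped; it never
#' aborts the plate.
#'
#' @param stacks_dir Directory of TIFF stacks written by [run_simulate()] /
#'   [write_stack()].
#' @param layout Plate layout data frame or CSV path.
#' @param out_dir Output directory.
#' @param config A `run_config` (or `NULL` for defaults).
#' @param functional Optional functional records data frame or CSV path.
#' @param control_dose Control dose for Dunnett comparisons.
#' @return Invisibly, a list with `per_mt`, `per_nucleus`, `summaries`,
#'   `failures`.
#' @export
run_analyze <- function(stacks_dir, layout, out_dir, config = NULL,
                        functional = NULL, control_dose = 0) {
  if (is.null(config)) config <- read_run_config(NULL)
  if (is.character(layout)) layout <- read_plate_layout(layout)
  if (is.character(functional)) functional <- read_functional(functional)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sort(list.files(stacks_dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(paths)) stop("no stacks found in ", stacks_dir, call. = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  per_mt <- list(); per_nuc <- list(); failures <- character(0)
  for (p in paths) {
    res <- tryCatch({
      stk <- read_stack(p)
      a <- analyze_stack(stk, config$pipeline)
      side <- jsonlite::read_json(sub("\\.tiff?$", ".json", p),
                                  simplifyVector = TRUE)
      q <- a$quant
      q$well <- side$well %||% NA_character_
      q$dose_uM <- side$dose_uM %||% NA_real_
      list(q = q, r = a$records)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, p)
      logf("FAILED %s: %s", basename(p), conditionMessage(res))
      next
    }
    per_mt[[p]] <- res$q
    per_nuc[[p]] <- res$r
    logf("analyzed %s: %d cells", basename(p), res$q$n_total)
  }
  if (!length(per_mt)) stop("no parseable stacks", call. = FALSE)
  per_mt <- do.call(rbind, per_mt)
  rownames(per_mt) <- NULL
  # fill well metadata from the layout where the sidecar lacked it
  if (!is.null(layout) && "well" %in% names(per_mt)) {
    miss <- is.na(per_mt$dose_uM) & per_mt$well %in% layout$well
    per_mt$dose_uM[miss] <- layout$dose_uM[match(per_mt$well[miss], layout$well)]
  }
  per_nuc <- do.call(rbind, per_nuc)
  rownames(per_nuc) <- NULL
  write.csv(format_pct(per_mt), file.path(out_dir, "per_mt.csv"),
            row.names = FALSE, na = "NA")
  write.csv(per_nuc, file.path(out_dir, "per_nucleus.csv"), row.names = FALSE)

  summaries <- list()
  img_endpoints <- c("n_total", "n_beta", "pct_beta", "pct_prolif_total",
                     "pct_prolif_beta", "pct_prolif_nonbeta",
                     "mean_nkx_intensity")
  if (length(unique(per_mt$dose_uM[!is.na(per_mt$dose_uM)])) >= 1L) {
    for (ep in img_endpoints) {
      tab <- tryCatch(dose_response_table(per_mt[!is.na(per_mt$dose_uM), ],
                                          ep, control_dose = control_dose),
                      error = function(e) NULL)
      if (!is.null(tab)) summaries[[ep]] <- tab
    }
  }
  if (!is.null(functional)) {
    for (ep in c("basal_secretion", "stimulated_secretion",
                 "chronic_secretion", "insulin_content", "atp_content",
                 "fold_stimulation")) {
      tab <- tryCatch(dose_response_table(functional, ep,
                                          control_dose = control_dose),
                      error = function(e) NULL)
      if (!is.null(tab)) summaries[[ep]] <- tab
    }
  }
  if (length(summaries)) {
    all_sum <- do.call(rbind, lapply(summaries, as.data.frame))
    rownames(all_sum) <- NULL
    write.csv(all_sum, file.path(out_dir, "group_summary.csv"),
              row.names = FALSE, na = "NA")
  }
  logf("done: %d analyzed, %d failed", nrow(per_mt), length(failures))
  invisible(list(per_mt = per_mt, per_nucleus = per_nuc,
                 summaries = summaries, failures = failures))
}

# Percentages reported to one decimal in CSV outputs; full precision is kept
# in the in-memory objects.
format_pct <- function(per_mt) {
  for (col in grep("^pct_", names(per_mt), value = TRUE))
    per_mt[[col]] <- round(per_mt[[col]], 1)
  per_mt
}

#' Simulate-then-analyze demonstration run
#'
#' Convenience wrapper: simulates a small plate into `out_dir/sim`, analyzes
#' it into `out_dir/analysis`, and returns the analysis results.
#'
#' @param out_dir Output directory.
#' @param config A `run_config` (or `NULL` for defaults).
#' @return The [run_analyze()] result, invisibly.
#' @export
run_demo <- function(out_dir, config = NULL) {
  if (is.null(config)) config <- read_run_config(NULL)
  sim_dir <- file.path(out_dir, "sim")
  run_simulate(config, sim_dir)
  invisible(run_analyze(sim_dir, file.path(sim_dir, "plate_layout.csv"),
                        file.path(out_dir, "analysis"), config,
                        functional = file.path(sim_dir, "functional.csv")))
}
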