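#' Default plate layout
#'
#' One-donor dose-response layout over the compound's dose range
#' (0, 1, 3.3, 5, 10 uM), 4-day treatment, one well per dose.
#'
#' @param doses Doses, uM.
#' @param n_mts Microtissues per well.
#' @param donor Donor label.
#' @param duration_days Treatment duration, days.
#' @param treatment Compound name for treated wells; dose 0 is labeled DMSO.
#' @return Data frame with columns
#'   `well, donor, dose_uM, duration_days, treatment, n_mts`.
#' @export
default_plate_layout <- function(doses = c(0, 1, 3.3, 5, 10), n_mts = 6,
                                 donor = "donor_1", duration_days = 4,
                                 treatment = "harmine") {
  data.frame(well = sprintf("%s%02d", LETTERS[seq_along(doses)], 1L),
             donor = donor, dose_uM = doses, duration_days = duration_days,
             treatment = ifelse(doses == 0, "DMSO", treatment),
             n_mts = as.integer(n_mts))
}

#' Simulate one microtissue
#'
#' Generates geometry, assigns phenotypes at the given dose, and renders the
#' three-channel stack.
#'
#' @param dose Dose, uM.
#' @param phenotype A [phenotype_model()] (baseline, dose-0 rates).
#' @param dose_model A [dose_effect_model()].
#' @param optics An [optics_config()].
#' @param n_cells Number of nuclei.
#' @param spheroid_radius Spheroid radius, um.
#' @param seed RNG seed.
#' @param mt_id Identifier.
#' @return An [mt_stack] with ground truth in `attr(, "truth")`.
#' @export
simulate_mt <- function(dose = 0, phenotype = phenotype_model(),
                        dose_model = dose_effect_model(),
                        optics = optics_config(), n_cells = 200,
                        spheroid_radius = 40, seed = NULL, mt_id = "mt_1") {
  pheno_d <- phenotype_at_dose(phenotype, dose_model, dose)
  with_seed(seed, {
    g <- generate_spheroid_geometry(n_cells, spheroid_radius = spheroid_radius,
                                    seed = NULL)
    truth <- assign_phenotypes(g, pheno_d, seed = NULL)
    render_stack(truth, optics, stack_shape_for(spheroid_radius, optics),
                 seed = NULL,
                 diffuse = diffuse_amplitudes(pheno_d),
                 spheroid_radius = spheroid_radius, mt_id = mt_id)
  })
}

# Per-channel diffuse amplitudes implied by a phenotype model.
diffuse_amplitudes <- function(phenotype) {
  c(dapi = phenotype$dapi_amplitude * phenotype$dapi_diffuse_fraction,
    nkx6_1 = 0, edu = 0)
}

# Draw a lognormal value with given mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# Dose-dependent functional endpoint means.
functional_means_at_dose <- function(dose_model, dose) {
  hstim <- dose^dose_model$stim_hill /
    (dose_model$stim_ec50^dose_model$stim_hill + dose^dose_model$stim_hill)
  list(basal = dose_model$baseline_basal *
         (1 + dose_model$basal_secretion_slope * dose),
       stimulated = dose_model$baseline_stimulated *
         (1 + dose_model$stim_secretion_effect * hstim),
       chronic = dose_model$baseline_chronic *
         (1 + dose_model$chronic_secretion_effect * hstim),
       content = dose_model$baseline_content *
         (1 - dose_model$content_depletion_slope * hstim),
       atp = dose_model$baseline_atp,
       caspase = dose_model$baseline_caspase)
}

# One functional record per MT, lognormal around the dose-dependent means.
simulate_functional_record <- function(mt_id, well, dose, duration_days,
                                       donor, dose_model) {
  mu <- functional_means_at_dose(dose_model, dose)
  cv <- dose_model$endpoint_cv
  data.frame(mt_id = mt_id, well = well, donor = donor, dose_uM = dose,
             duration_days = duration_days,
             basal_secretion = rlnorm_mean_cv(1, mu$basal, cv),
             stimulated_secretion = rlnorm_mean_cv(1, mu$stimulated, cv),
             chronic_secretion = rlnorm_mean_cv(1, mu$chronic, cv),
             insulin_content = rlnorm_mean_cv(1, mu$content, cv),
             atp_content = rlnorm_mean_cv(1, mu$atp, cv),
             caspase_lum = rlnorm_mean_cv(1, mu$caspase, cv))
}

#' Simulate a screening plate
#'
#' For every well in the layout, simulates `n_mts` microtissues at the well's
#' dose: per-MT image stacks with per-nucleus ground truth, plus one
#' functional record per MT (basal/stimulated/chronic insulin secretion,
#' insulin content, ATP, caspase) drawn lognormally around dose-dependent
#' means. The EdU labeling window (final 4 days of treatment) is modeled as a
#' single cumulative Bernoulli proliferation event per cell.
#'
#' @param layout Plate layout data frame (see [default_plate_layout()]); must
#'   contain `well`, `dose_uM` and either `n_mts` or the `n_mts_per_well`
#'   argument.
#' @param dose_model A [dose_effect_model()].
#' @param phenotype A [phenotype_model()].
#' @param optics An [optics_config()].
#' @param n_mts_per_well Overrides the layout's `n_mts` when given.
#' @param n_cells Nuclei per microtissue.
#' @param spheroid_radius Spheroid radius, um.
#' @param seed RNG seed; the whole plate is reproducible given the seed.
#' @param out_dir When given, stacks are written as TIFF (+ JSON sidecar) into
#'   this directory and dropped from memory; the returned `mts` then carry
#'   `path` instead of `stack`.
#' @param render Set `FALSE` to skip image rendering (ground truth and
#'   functional records only; used for statistical calibration work).
#' @return An object of class `plate_sim`: list with `layout`, `mts` (list of
#'   per-MT records: `mt_id`, `well`, `dose_uM`, `truth`, and `stack` or
#'   `path`), `truth` (combined per-nucleus data frame), and `functional`
#'   (one row per MT).
#' @export
simulate_plate <- function(layout = default_plate_layout(),
                           dose_model = dose_effect_model(),
                           phenotype = phenotype_model(),
                           optics = optics_config(),
                           n_mts_per_well = NULL,
                           n_cells = 200, spheroid_radius = 40,
                           seed = 1, out_dir = NULL, render = TRUE) {
  req <- c("well", "dose_uM")
  if (!all(req %in% names(layout)))
    stop("layout must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(layout$dose_uM < 0)) stop("doses must be >= 0", call. = FALSE)
  if (anyDuplicated(layout$well)) stop("duplicate well in layout", call. = FALSE)
  n_mts <- n_mts_per_well %||% layout$n_mts
  if (is.null(n_mts)) stop("n_mts missing from layout and arguments", call. = FALSE)
  n_mts <- rep_len(as.integer(n_mts), nrow(layout))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(seed, {
    mts <- list()
    functional <- list()
    truth_all <- list()
    for (w in seq_len(nrow(layout))) {
      row <- layout[w, ]
      pheno_d <- phenotype_at_dose(phenotype, dose_model, row$dose_uM)
      for (m in seq_len(n_mts[w])) {
        mt_id <- sprintf("%s_mt%02d", row$well, m)
        g <- generate_spheroid_geometry(n_cells,
                                        spheroid_radius = spheroid_radius,
                                        seed = NULL)
        truth <- assign_phenotypes(g, pheno_d, seed = NULL)
        rec <- list(mt_id = mt_id, well = row$well, dose_uM = row$dose_uM,
                    truth = truth)
        if (render) {
          stk <- render_stack(truth, optics,
                              stack_shape_for(spheroid_radius, optics),
                              seed = NULL,
                              diffuse = diffuse_amplitudes(pheno_d),
                              spheroid_radius = spheroid_radius,
                              mt_id = mt_id)
          rec$truth <- attr(stk, "truth")
          if (!is.null(out_dir)) {
            rec$path <- write_stack(stk, out_dir, optics = optics,
                                    meta = list(well = row$well,
                                                dose_uM = row$dose_uM))
          } else rec$stack <- stk
        }
        mts[[mt_id]] <- rec
        truth_df <- rec$truth
        truth_df$mt_id <- mt_id
        truth_df$well <- row$well
        truth_df$dose_uM <- row$dose_uM
        truth_all[[mt_id]] <- truth_df
        functional[[mt_id]] <- simulate_functional_record(
          mt_id, row$well, row$dose_uM,
          row$duration_days %||% NA_real_, row$donor %||% NA_character_,
          dose_model)
      }
    }
    structure(list(layout = layout, mts = mts,
                   truth = do.call(rbind, truth_all),
                   functional = do.call(rbind, functional)),
              class = "plate_sim")
  })
}

#' @export
print.plate_sim <- function(x, ...) {
  cat(sprintf("plate_sim: %d wells, %d microtissues, %d nuclei total\n",
              nrow(x$layout), length(x$mts), nrow(x$truth)))
  invisible(x)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `baseline + (emax - baseline) * d^h / (ec50^h + d^h)`
#' to per-observation responses, via Levenberg-Marquardt with data-driven
#' starting values.
#'
#' @param dose Doses (uM), one per observation.
#' @param response Responses.
#' @return Named numeric vector `baseline, emax, ec50, hill`.
#' @export
fit_hill <- function(dose, response) {
  stopifnot(length(dose) == length(response), length(unique(dose)) >= 3)
  df <- data.frame(d = dose, y = response)
  gm <- aggregate(y ~ d, df, mean)
  start <- list(baseline = max(min(gm$y), 1e-8),
                emax = max(gm$y),
                ec50 = max(stats::median(unique(dose[dose > 0])), 1e-6),
                hill = 1.5)
  fit <- minpack.lm::nlsLM(
    y ~ baseline + (emax - baseline) * d^hill / (ec50^hill + d^hill),
    data = df, start = start,
    lower = c(0, 0, 1e-4, 0.2), upper = c(Inf, Inf, 1e4, 8),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  coef(fit)
}
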