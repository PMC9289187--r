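#' Assign cell phenotypes and channel amplitudes
#'
#' Independently labels each placed nucleus as beta (probability
#' `beta_fraction`) and proliferating (class-specific probability over the EdU
#' labeling window), then draws per-channel amplitudes: DAPI lognormal around
#' `dapi_amplitude` (CV 0.1), NKX6.1 lognormal for beta cells (attenuated by
#' `nkx_prolif_attenuation` when proliferating) and a constant floor for
#' non-beta cells, EdU lognormal (CV 0.15) for proliferating cells and 0
#' otherwise.
#'
#' @param cells Geometry data frame from [generate_spheroid_geometry()].
#' @param model A [phenotype_model()].
#' @param seed RNG seed; deterministic given the seed.
#' @return The input data frame with added columns `is_beta`,
#'   `is_proliferating`, `dapi_amp`, `nkx_amp`, `edu_amp` (ground truth, one
#'   row per nucleus).
#' @export
#' @examples
#' g <- generate_spheroid_geometry(20, spheroid_radius = 30, seed = 1)
#' truth <- assign_phenotypes(g, phenotype_model(), seed = 2)
#' table(truth$is_beta)
assign_phenotypes <- function(cells, model, seed = NULL) {
  stopifnot(inherits(model, "phenotype_model"), is.data.frame(cells))
  n <- nrow(cells)
  out <- cells
  if (n == 0L) {
    out$is_beta <- logical(0); out$is_proliferating <- logical(0)
    out$dapi_amp <- numeric(0); out$nkx_amp <- numeric(0); out$edu_amp <- numeric(0)
    return(out)
  }
  with_seed(seed, {
    is_beta <- runif(n) < model$beta_fraction
    p_prolif <- ifelse(is_beta, model$prolif_rate_beta, model$prolif_rate_nonbeta)
    is_prolif <- runif(n) < p_prolif

    rln <- function(n, mean, cv) {
      if (cv <= 0 || mean <= 0) return(rep(mean, n))
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
    }
    dapi_amp <- rln(n, model$dapi_amplitude, 0.1)
    nkx_amp <- ifelse(is_beta, rln(n, model$nkx_mean_beta, model$nkx_cv_beta),
                      model$nkx_bleedthrough_nonbeta)
    nkx_amp[is_beta & is_prolif] <- nkx_amp[is_beta & is_prolif] *
      model$nkx_prolif_attenuation
    edu_amp <- ifelse(is_prolif, rln(n, model$edu_amplitude, 0.15), 0)

    out$is_beta <- is_beta
    out$is_proliferating <- is_prolif
    out$dapi_amp <- dapi_amp
    out$nkx_amp <- nkx_amp
    out$edu_amp <- edu_amp
    out
  })
}

#' Hill response
#'
#' `baseline + (emax - baseline) * d^h / (ec50^h + d^h)`, the saturating
#' dose-response used throughout the simulator.
#'
#' @param dose Dose(s), uM (>= 0).
#' @param baseline Response at dose 0.
#' @param emax Response at saturating dose.
#' @param ec50 Half-maximal dose, uM.
#' @param hill Hill coefficient (> 0).
#' @return Numeric vector of responses.
#' @export
hill_response <- function(dose, baseline, emax, ec50, hill) {
  stopifnot(all(dose >= 0), ec50 > 0, hill > 0)
  h <- dose^hill / (ec50^hill + dose^hill)
  baseline + (emax - baseline) * h
}

#' Proliferation probabilities at a dose
#'
#' @param dose_model A [dose_effect_model()].
#' @param phenotype A [phenotype_model()] supplying the baseline (dose 0)
#'   proliferation rates.
#' @param dose Dose, uM.
#' @return List with `prolif_rate_beta`, `prolif_rate_nonbeta` and the
#'   population-expected total proliferating fraction `expected_total`.
#' @export
prolif_rates_at_dose <- function(dose_model, phenotype, dose) {
  stopifnot(inherits(dose_model, "dose_effect_model"),
            inherits(phenotype, "phenotype_model"))
  pb <- hill_response(dose, phenotype$prolif_rate_beta,
                      dose_model$emax_prolif_beta, dose_model$ec50,
                      dose_model$hill)
  pn <- hill_response(dose, phenotype$prolif_rate_nonbeta,
                      dose_model$emax_prolif_nonbeta, dose_model$ec50,
                      dose_model$hill)
  fb <- phenotype$beta_fraction
  list(prolif_rate_beta = pb, prolif_rate_nonbeta = pn,
       expected_total = fb * pb + (1 - fb) * pn)
}

#' Expected total proliferating fraction under a phenotype model
#'
#' @param model A [phenotype_model()].
#' @return `beta_fraction * prolif_rate_beta + (1 - beta_fraction) *
#'   prolif_rate_nonbeta`.
#' @export
expected_prolif_total <- function(model) {
  stopifnot(inherits(model, "phenotype_model"))
  model$beta_fraction * model$prolif_rate_beta +
    (1 - model$beta_fraction) * model$prolif_rate_nonbeta
}

# Phenotype model with proliferation rates moved to a given dose.
phenotype_at_dose <- function(phenotype, dose_model, dose) {
  r <- prolif_rates_at_dose(dose_model, phenotype, dose)
  phenotype$prolif_rate_beta <- r$prolif_rate_beta
  phenotype$prolif_rate_nonbeta <- r$prolif_rate_nonbeta
  phenotype
}
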