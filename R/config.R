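#' Imaging (optics) configuration
#'
#' Physical sampling and noise model for simulated confocal stacks. The axial
#' step defaults to 3 um, the step used to image whole microtissues; the
#' lateral pixel size defaults to 0.5 um (a 40x dry objective on a benchtop
#' high-content confocal; configurable). Anisotropy is enforced:
#' `voxel_z >= voxel_xy`.
#'
#' The noise model is Poisson-Gaussian: the expected photon image is scaled by
#' `photon_scale` (counts per intensity unit), Poisson-resampled, rescaled,
#' and read noise of standard deviation `noise_gaussian_sd` is added before
#' clipping to the detector bit depth. `photon_scale = Inf` disables shot
#' noise (useful for noise-free renders).
#'
#' @param voxel_xy Lateral pixel size, um/pixel.
#' @param voxel_z Axial step, um/plane.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um.
#' @param background_level Constant background offset, intensity a.u.
#' @param noise_gaussian_sd Additive read-noise SD, intensity a.u.
#' @param photon_scale Poisson gain (expected counts per intensity unit);
#'   `Inf` for no shot noise.
#' @param bit_depth Detector bit depth, 8 or 16.
#' @return An object of class `optics_config`.
#' @export
#' @examples
#' optics_config()
optics_config <- function(voxel_xy = 0.5, voxel_z = 3,
                          psf_sigma_xy = 0.5, psf_sigma_z = 1.5,
                          background_level = 100, noise_gaussian_sd = 10,
                          photon_scale = 0.2, bit_depth = 16L) {
  assert_number(voxel_xy, "voxel_xy", lower = 1e-9)
  assert_number(voxel_z, "voxel_z", lower = 1e-9)
  if (voxel_z < voxel_xy)
    stop("voxel_z must be >= voxel_xy (axial sampling is the coarse axis)",
         call. = FALSE)
  assert_number(psf_sigma_xy, "psf_sigma_xy", lower = 1e-9)
  assert_number(psf_sigma_z, "psf_sigma_z", lower = 1e-9)
  assert_number(background_level, "background_level", lower = 0)
  assert_number(noise_gaussian_sd, "noise_gaussian_sd", lower = 0)
  if (!(is.numeric(photon_scale) && length(photon_scale) == 1L &&
        (is.infinite(photon_scale) || photon_scale > 0)))
    stop("photon_scale must be a positive number or Inf", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(list(voxel_xy = voxel_xy, voxel_z = voxel_z,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 background_level = background_level,
                 noise_gaussian_sd = noise_gaussian_sd,
                 photon_scale = photon_scale, bit_depth = as.integer(bit_depth)),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf("optics_config: voxel %g x %g x %g um (z,y,x), PSF sigma %g/%g um (xy/z)\n",
              x$voxel_z, x$voxel_xy, x$voxel_xy, x$psf_sigma_xy, x$psf_sigma_z))
  cat(sprintf("  background %g, read noise sd %g, photon gain %g, %d bit\n",
              x$background_level, x$noise_gaussian_sd, x$photon_scale, x$bit_depth))
  invisible(x)
}

#' Cellular phenotype model
#'
#' Per-cell phenotype probabilities and channel amplitudes for the simulator.
#' Defaults reproduce the control condition of a 4-day EdU labeling window in
#' human islet MTs: beta-cell fraction 0.55 (within the 40-65% range detected
#' in human islets), near-zero baseline proliferation (expected total
#' proliferation 0.2% of all cells), and non-beta proliferation 7.5x the
#' beta-cell rate. NKX6.1 nuclear amplitude in beta cells is lognormal with a
#' broad CV; proliferating beta cells have their NKX6.1 amplitude multiplied
#' by `nkx_prolif_attenuation` (< 1), reflecting reduced NKX6.1 expression in
#' EdU+/NKX6.1+ cells. Non-beta nuclei carry a constant low NKX6.1 floor
#' (`nkx_bleedthrough_nonbeta`).
#'
#' @param beta_fraction Probability a cell is a beta cell.
#' @param prolif_rate_beta,prolif_rate_nonbeta Probability of proliferating
#'   during the EdU labeling window, per class.
#' @param nkx_mean_beta Mean NKX6.1 amplitude of beta nuclei, a.u.
#' @param nkx_cv_beta Coefficient of variation of beta NKX6.1 amplitude.
#' @param nkx_prolif_attenuation Multiplier in (0, 1] applied to NKX6.1
#'   amplitude of proliferating beta cells.
#' @param nkx_bleedthrough_nonbeta NKX6.1 amplitude floor of non-beta nuclei.
#' @param edu_amplitude EdU amplitude of proliferating nuclei, a.u.
#' @param dapi_amplitude DAPI amplitude of all nuclei, a.u.
#' @param dapi_diffuse_fraction Fraction of `dapi_amplitude` present as
#'   diffuse signal throughout the spheroid (cytoplasmic staining plus
#'   out-of-focus light in cleared tissue); makes the spheroid a solid object
#'   in the DAPI channel, as in real stacks.
#' @return An object of class `phenotype_model`.
#' @export
#' @examples
#' phenotype_model(beta_fraction = 0.5)
phenotype_model <- function(beta_fraction = 0.55,
                            prolif_rate_beta = 5e-4,
                            prolif_rate_nonbeta = 3.75e-3,
                            nkx_mean_beta = 600, nkx_cv_beta = 0.35,
                            nkx_prolif_attenuation = 0.5,
                            nkx_bleedthrough_nonbeta = 40,
                            edu_amplitude = 800, dapi_amplitude = 1000,
                            dapi_diffuse_fraction = 0.15) {
  assert_number(beta_fraction, "beta_fraction", 0, 1)
  assert_number(prolif_rate_beta, "prolif_rate_beta", 0, 1)
  assert_number(prolif_rate_nonbeta, "prolif_rate_nonbeta", 0, 1)
  assert_number(nkx_mean_beta, "nkx_mean_beta", lower = 0)
  assert_number(nkx_cv_beta, "nkx_cv_beta", lower = 0)
  assert_number(nkx_prolif_attenuation, "nkx_prolif_attenuation", 1e-9, 1)
  assert_number(nkx_bleedthrough_nonbeta, "nkx_bleedthrough_nonbeta", lower = 0)
  assert_number(edu_amplitude, "edu_amplitude", lower = 0)
  assert_number(dapi_amplitude, "dapi_amplitude", lower = 0)
  assert_number(dapi_diffuse_fraction, "dapi_diffuse_fraction", 0, 1)
  structure(list(beta_fraction = beta_fraction,
                 prolif_rate_beta = prolif_rate_beta,
                 prolif_rate_nonbeta = prolif_rate_nonbeta,
                 nkx_mean_beta = nkx_mean_beta, nkx_cv_beta = nkx_cv_beta,
                 nkx_prolif_attenuation = nkx_prolif_attenuation,
                 nkx_bleedthrough_nonbeta = nkx_bleedthrough_nonbeta,
                 edu_amplitude = edu_amplitude, dapi_amplitude = dapi_amplitude,
                 dapi_diffuse_fraction = dapi_diffuse_fraction),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("phenotype_model: beta fraction %.2f, proliferation %.2g (beta) / %.2g (non-beta)\n",
              x$beta_fraction, x$prolif_rate_beta, x$prolif_rate_nonbeta))
  cat(sprintf("  expected total proliferation %.3f%%\n",
              100 * expected_prolif_total(x)))
  invisible(x)
}

#' Dose-effect model for compound treatment
#'
#' Hill-type effects of a proliferative compound (harmine-like DYRK1A
#' inhibitor, dose range 0-10 uM) on per-class proliferation probabilities and
#' on functional endpoints. Proliferation probabilities follow
#' `baseline + (emax - baseline) * d^h / (ec50^h + d^h)`. Default maxima give
#' ~6% total proliferation at saturating dose with the non-beta rate 7.5x the
#' beta rate. Stimulated secretion saturates with its own Hill shape while
#' basal secretion rises linearly with dose, so mean fold-stimulation
#' (stimulated/basal) peaks at an intermediate dose; insulin content is
#' depleted with dose.
#'
#' @param emax_prolif_beta,emax_prolif_nonbeta Proliferation probability at
#'   saturating dose, per class.
#' @param ec50 Half-maximal dose for proliferation, uM.
#' @param hill Hill coefficient for proliferation.
#' @param basal_secretion_slope Linear increase of basal secretion per uM.
#' @param stim_secretion_effect Maximal fractional increase of stimulated
#'   secretion (Hill-shaped with `stim_ec50`, `stim_hill`).
#' @param stim_ec50,stim_hill Hill parameters of the secretion effect.
#' @param content_depletion_slope Maximal fractional depletion of insulin
#'   content (Hill-shaped with `stim_ec50`, `stim_hill`).
#' @param chronic_secretion_effect Maximal fractional increase of chronic
#'   secretion.
#' @param baseline_basal,baseline_stimulated Baseline secretion, ng/MT.
#' @param baseline_chronic Baseline chronic secretion, ng/MT/day.
#' @param baseline_content Baseline insulin content, ng/MT.
#' @param baseline_atp Baseline ATP content, pmol/MT.
#' @param baseline_caspase Baseline caspase 3/7 luminescence, a.u.
#' @param endpoint_cv Lognormal CV of each per-MT functional endpoint.
#' @return An object of class `dose_effect_model`.
#' @export
#' @examples
#' m <- dose_effect_model()
#' prolif_rates_at_dose(m, phenotype_model(), dose = 3.3)
dose_effect_model <- function(emax_prolif_beta = 0.0153,
                              emax_prolif_nonbeta = 0.1146,
                              ec50 = 3, hill = 1.5,
                              basal_secretion_slope = 0.12,
                              stim_secretion_effect = 1.8,
                              stim_ec50 = 1.2, stim_hill = 2,
                              content_depletion_slope = 0.4,
                              chronic_secretion_effect = 1.0,
                              baseline_basal = 0.5,
                              baseline_stimulated = 2.0,
                              baseline_chronic = 1.0,
                              baseline_content = 25,
                              baseline_atp = 50,
                              baseline_caspase = 1000,
                              endpoint_cv = 0.15) {
  assert_number(emax_prolif_beta, "emax_prolif_beta", 0, 1)
  assert_number(emax_prolif_nonbeta, "emax_prolif_nonbeta", 0, 1)
  assert_number(ec50, "ec50", lower = 1e-9)
  assert_number(hill, "hill", lower = 1e-9)
  assert_number(stim_ec50, "stim_ec50", lower = 1e-9)
  assert_number(stim_hill, "stim_hill", lower = 1e-9)
  assert_number(content_depletion_slope, "content_depletion_slope", 0, 1)
  for (nm in c("baseline_basal", "baseline_stimulated", "baseline_chronic",
               "baseline_content", "baseline_atp", "baseline_caspase"))
    assert_number(get(nm), nm, lower = 1e-12)
  assert_number(endpoint_cv, "endpoint_cv", lower = 0)
  structure(list(emax_prolif_beta = emax_prolif_beta,
                 emax_prolif_nonbeta = emax_prolif_nonbeta,
                 ec50 = ec50, hill = hill,
                 basal_secretion_slope = basal_secretion_slope,
                 stim_secretion_effect = stim_secretion_effect,
                 stim_ec50 = stim_ec50, stim_hill = stim_hill,
                 content_depletion_slope = content_depletion_slope,
                 chronic_secretion_effect = chronic_secretion_effect,
                 baseline_basal = baseline_basal,
                 baseline_stimulated = baseline_stimulated,
                 baseline_chronic = baseline_chronic,
                 baseline_content = baseline_content,
                 baseline_atp = baseline_atp,
                 baseline_caspase = baseline_caspase,
                 endpoint_cv = endpoint_cv),
            class = "dose_effect_model")
}

#' @export
print.dose_effect_model <- function(x, ...) {
  cat(sprintf("dose_effect_model: proliferation EC50 %g uM (hill %g), Emax %.3g (beta) / %.3g (non-beta)\n",
              x$ec50, x$hill, x$emax_prolif_beta, x$emax_prolif_nonbeta))
  invisible(x)
}

#' Image-analysis pipeline configuration
#'
#' Parameters of the four-step analysis. `window_um` and `offset_k` define the
#' dynamic (local-mean) threshold: a voxel is foreground when its intensity
#' exceeds the local in-mask mean over a `window_um` box by `offset_k` robust
#' SDs of the in-mask intensities. Nucleus volume gates are in physical um^3.
#'
#' @param channels Named list or vector mapping channel roles
#'   (`dapi`, `nkx6_1`, `edu`) to stack channel names or 1-based indices.
#' @param smooth_sigma_um Gaussian pre-smoothing sigma (um) for segmentation.
#' @param window_um Side length of the local-threshold window, um.
#' @param offset_k Threshold offset in units of the in-mask robust SD.
#' @param min_volume_um3,max_volume_um3 Accepted nucleus volume range, um^3.
#' @param positive_fraction Fraction of a nucleus' voxels that must exceed the
#'   marker threshold for the nucleus to be called positive.
#' @param seed_min_distance_um Minimum separation of watershed seeds, um.
#' @param spheroid_smooth_sigma_um Gaussian smoothing sigma (um) applied to
#'   the DAPI channel before Otsu thresholding in spheroid detection; at the
#'   nucleus-spacing scale this merges the nuclear point cloud into a solid
#'   object.
#' @param min_spheroid_contrast Minimum ratio of foreground to background mean
#'   intensity (on the smoothed image) for a detection to count as a spheroid.
#' @param spheroid_truncation_upper_pct Upper percentile at which the smoothed
#'   DAPI volume is clipped before Otsu thresholding; removes the nuclear
#'   intensity tail so the histogram is two-class (tissue vs background) and
#'   the threshold falls at the object boundary.
#' @param closing_radius_um Morphological closing radius for spheroid
#'   detection, um.
#' @param min_spheroid_volume_um3 Smallest accepted spheroid, um^3.
#' @param truncation_lower_pct,truncation_upper_pct Percentiles for NKX6.1
#'   intensity truncation, computed within the spheroid mask.
#' @param nkx_mean_domain `"beta"` (default) averages NKX6.1 intensity over
#'   beta-classified nuclei; `"all"` over all nuclei.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(channels = list(dapi = "dapi", nkx6_1 = "nkx6_1",
                                            edu = "edu"),
                            smooth_sigma_um = 0.5,
                            window_um = 15, offset_k = 2.0,
                            min_volume_um3 = 30, max_volume_um3 = 1500,
                            positive_fraction = 0.5,
                            seed_min_distance_um = 2.5,
                            spheroid_smooth_sigma_um = 2,
                            min_spheroid_contrast = 1.2,
                            spheroid_truncation_upper_pct = 85,
                            closing_radius_um = 5,
                            min_spheroid_volume_um3 = 1e4,
                            truncation_lower_pct = 1,
                            truncation_upper_pct = 99.5,
                            nkx_mean_domain = c("beta", "all")) {
  assert_number(smooth_sigma_um, "smooth_sigma_um", lower = 0)
  assert_number(window_um, "window_um", lower = 1e-9)
  assert_number(offset_k, "offset_k", lower = 0)
  assert_number(min_volume_um3, "min_volume_um3", lower = 0)
  assert_number(max_volume_um3, "max_volume_um3", lower = min_volume_um3)
  assert_number(positive_fraction, "positive_fraction", 0, 1)
  assert_number(seed_min_distance_um, "seed_min_distance_um", lower = 0)
  assert_number(spheroid_smooth_sigma_um, "spheroid_smooth_sigma_um", lower = 0)
  assert_number(min_spheroid_contrast, "min_spheroid_contrast", lower = 1)
  assert_number(spheroid_truncation_upper_pct, "spheroid_truncation_upper_pct",
                1, 100)
  assert_number(closing_radius_um, "closing_radius_um", lower = 0)
  assert_number(min_spheroid_volume_um3, "min_spheroid_volume_um3", lower = 0)
  assert_number(truncation_lower_pct, "truncation_lower_pct", 0, 100)
  assert_number(truncation_upper_pct, "truncation_upper_pct", 0, 100)
  if (truncation_lower_pct >= truncation_upper_pct)
    stop("truncation_lower_pct must be < truncation_upper_pct", call. = FALSE)
  structure(list(channels = as.list(channels),
                 smooth_sigma_um = smooth_sigma_um,
                 window_um = window_um, offset_k = offset_k,
                 min_volume_um3 = min_volume_um3,
                 max_volume_um3 = max_volume_um3,
                 positive_fraction = positive_fraction,
                 seed_min_distance_um = seed_min_distance_um,
                 spheroid_smooth_sigma_um = spheroid_smooth_sigma_um,
                 min_spheroid_contrast = min_spheroid_contrast,
                 spheroid_truncation_upper_pct = spheroid_truncation_upper_pct,
                 closing_radius_um = closing_radius_um,
                 min_spheroid_volume_um3 = min_spheroid_volume_um3,
                 truncation_lower_pct = truncation_lower_pct,
                 truncation_upper_pct = truncation_upper_pct,
                 nkx_mean_domain = match.arg(nkx_mean_domain)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config: window %g um, offset %g rSD, nucleus volume [%g, %g] um^3\n",
              x$window_um, x$offset_k, x$min_volume_um3, x$max_volume_um3))
  invisible(x)
}
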