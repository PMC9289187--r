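#' Render a multi-channel confocal stack from ground truth
#'
#' Forward imaging model: each channel is the sum of solid-sphere indicator
#' volumes scaled by per-nucleus amplitude, convolved with an anisotropic
#' Gaussian PSF, plus a constant background; the expected image is then
#' Poisson-resampled at the configured photon gain, Gaussian read noise is
#' added, and values are clipped to the detector bit depth and rounded to
#' integer grey levels.
#'
#' The stack's physical origin coincides with the array corner; ground-truth
#' coordinates from [generate_spheroid_geometry()] are centered on the
#' spheroid, so they are shifted to the stack center before rasterization.
#'
#' @param cells Ground-truth data frame from [assign_phenotypes()].
#' @param optics An [optics_config()].
#' @param stack_shape Integer `(nz, ny, nx)`.
#' @param seed RNG seed for the noise; deterministic given the seed.
#' @param channels Channel names to render, a subset of
#'   `c("dapi", "nkx6_1", "edu")`.
#' @param diffuse Named per-channel amplitudes of a diffuse signal filling the
#'   whole spheroid ball (requires `spheroid_radius`); emulates cytoplasmic
#'   staining and out-of-focus light that make the spheroid appear solid.
#'   `NULL` renders nuclei only.
#' @param spheroid_radius Radius (um) of the diffuse ball, centered in the
#'   stack.
#' @param mt_id Identifier stored on the returned stack.
#' @return An [mt_stack] with one [voxel_grid] per channel. The attribute
#'   `"truth"` carries the input ground truth with stack-frame coordinates
#'   (`x_um`, `y_um`, `z_um`).
#' @export
#' @examples
#' g <- generate_spheroid_geometry(10, spheroid_radius = 20, seed = 1)
#' truth <- assign_phenotypes(g, phenotype_model(), seed = 1)
#' stk <- render_stack(truth, optics_config(), c(12, 64, 64), seed = 1)
render_stack <- function(cells, optics, stack_shape, seed = NULL,
                         channels = c("dapi", "nkx6_1", "edu"),
                         diffuse = NULL, spheroid_radius = NULL,
                         mt_id = "mt_1") {
  stopifnot(inherits(optics, "optics_config"), length(stack_shape) == 3L)
  stack_shape <- as.integer(stack_shape)
  spacing <- c(optics$voxel_z, optics$voxel_xy, optics$voxel_xy) # (z,y,x)
  extent <- stack_shape * spacing
  center <- extent / 2

  n <- nrow(cells)
  if (n > 0) {
    # stack-frame centers, (z,y,x) um
    cz <- cells$z + center[1]; cy <- cells$y + center[2]; cx <- cells$x + center[3]
    bad <- which(cz - cells$radius < 0 | cz + cells$radius > extent[1] |
                 cy - cells$radius < 0 | cy + cells$radius > extent[2] |
                 cx - cells$radius < 0 | cx + cells$radius > extent[3])
    if (length(bad))
      stop(sprintf("cells outside stack bounds: id %s",
                   paste(cells$id[bad], collapse = ", ")), call. = FALSE)
    centers <- cbind(cz, cy, cx)
  } else centers <- matrix(numeric(0), 0, 3)

  amp_col <- c(dapi = "dapi_amp", nkx6_1 = "nkx_amp", edu = "edu_amp")
  sigma_vox <- c(optics$psf_sigma_z / optics$voxel_z,
                 optics$psf_sigma_xy / optics$voxel_xy,
                 optics$psf_sigma_xy / optics$voxel_xy)
  maxval <- 2^optics$bit_depth - 1

  with_seed(seed, {
    grids <- lapply(channels, function(ch) {
      amps <- if (n > 0) cells[[amp_col[[ch]]]] else numeric(0)
      vol <- cpp_rasterize_spheres(stack_shape, spacing, centers,
                                   if (n > 0) cells$radius else numeric(0),
                                   amps)
      damp <- if (is.null(diffuse)) 0 else (diffuse[[ch]] %||% 0)
      if (damp > 0) {
        if (is.null(spheroid_radius))
          stop("diffuse signal requires spheroid_radius", call. = FALSE)
        vol <- vol + cpp_rasterize_spheres(stack_shape, spacing,
                                           matrix(center, 1, 3),
                                           spheroid_radius, damp)
      }
      vol <- cpp_gaussian_blur(vol, stack_shape, sigma_vox)
      expected <- vol + optics$background_level
      if (is.finite(optics$photon_scale)) {
        noisy <- rpois(length(expected), as.vector(expected) * optics$photon_scale) /
          optics$photon_scale
      } else noisy <- as.vector(expected)
      if (optics$noise_gaussian_sd > 0)
        noisy <- noisy + rnorm(length(noisy), 0, optics$noise_gaussian_sd)
      noisy <- round(pmin(pmax(noisy, 0), maxval))
      voxel_grid(array(noisy, stack_shape), spacing, ch)
    })
    names(grids) <- channels
    stk <- mt_stack(grids, mt_id = mt_id)
    if (n > 0) {
      truth <- cells
      truth$x_um <- cx; truth$y_um <- cy; truth$z_um <- cz
      attr(stk, "truth") <- truth
    } else attr(stk, "truth") <- cells
    stk
  })
}

#' Default stack shape for a spheroid
#'
#' Smallest stack (with a margin) that contains a centered spheroid of the
#' given radius at the configured sampling.
#'
#' @param spheroid_radius Spheroid radius, um.
#' @param optics An [optics_config()].
#' @param margin_um Extra space on every side, um.
#' @return Integer `(nz, ny, nx)`.
#' @export
stack_shape_for <- function(spheroid_radius, optics, margin_um = 5) {
  side <- 2 * (spheroid_radius + margin_um)
  c(ceiling(side / optics$voxel_z),
    ceiling(side / optics$voxel_xy),
    ceiling(side / optics$voxel_xy))
}
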