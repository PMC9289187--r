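#' Detect the spheroid region on the DAPI channel
#'
#' Step 1 of the analysis: Gaussian smoothing of the DAPI channel at the
#' nucleus-spacing scale, Otsu thresholding, morphological closing with a
#' physical radius (converted per axis to voxels), selection of the largest
#' connected foreground component, and per-Z-plane filling of internal holes.
#' The result is a single connected component. A detection whose foreground
#' mean is not clearly above the background mean (ratio below
#' `min_spheroid_contrast`) or whose volume is below
#' `min_spheroid_volume_um3` raises a "no spheroid detected" error.
#'
#' @param dapi DAPI [voxel_grid].
#' @param config A [pipeline_config()].
#' @return An object of class `spheroid_mask`: list with `mask` (3D logical
#'   array), `threshold_used`, and `voxel_size`.
#' @export
detect_spheroid <- function(dapi, config = pipeline_config()) {
  stopifnot(inherits(dapi, "voxel_grid"))
  dim3 <- dim(dapi$data)
  # smooth at the nucleus-spacing scale so the nuclear point cloud merges
  # into one solid object before thresholding
  work <- dapi$data
  if (config$spheroid_smooth_sigma_um > 0) {
    sig <- config$spheroid_smooth_sigma_um / dapi$voxel_size
    num <- cpp_gaussian_blur(as.numeric(work), dim3, sig)
    den <- cpp_gaussian_blur(rep(1, length(work)), dim3, sig)
    work <- num / den   # edge-normalized: no dark rim at the stack border
    dim(work) <- dim3
  }
  # clip the nuclear intensity tail so Otsu separates tissue from background
  # rather than nuclei from everything else
  if (config$spheroid_truncation_upper_pct < 100)
    work <- pmin(work, quantile(work, config$spheroid_truncation_upper_pct / 100))
  dim(work) <- dim3
  thr <- otsu_threshold(work)
  fg <- work > thr
  mu_fg <- mean(work[fg]); mu_bg <- mean(work[!fg])
  if (!is.finite(mu_fg) || !is.finite(mu_bg) ||
      mu_fg < config$min_spheroid_contrast * mu_bg)
    stop(sprintf("no spheroid detected: foreground/background contrast %.3f below %.2f",
                 mu_fg / mu_bg, config$min_spheroid_contrast), call. = FALSE)

  # closing: dilation then erosion with a per-axis physical half width
  r_um <- config$closing_radius_um
  if (r_um > 0) {
    half <- pmax(0L, as.integer(round(r_um / dapi$voxel_size)))
    if (any(half > 0)) {
      d <- cpp_extreme_filter(as.numeric(fg), dim3, half, TRUE)
      fg <- cpp_extreme_filter(d, dim3, half, FALSE, pad_background = TRUE) > 0.5
    }
  }
  dim(fg) <- dim3

  labels <- cpp_label_components(fg, dim3, 26L)
  n_lab <- attr(labels, "n_labels")
  if (n_lab == 0L)
    stop("no spheroid detected: no foreground after thresholding", call. = FALSE)
  sizes <- tabulate(labels[labels > 0L], nbins = n_lab)
  keep <- which.max(sizes)
  mask <- labels == keep
  dim(mask) <- dim3

  # fill internal holes plane by plane: background components of each Z-plane
  # that do not touch the plane border become foreground
  for (z in seq_len(dim3[1])) {
    sl <- mask[z, , ]
    if (!any(sl)) next
    bg <- !sl
    lab2 <- cpp_label_components(as.vector(bg), c(1L, dim3[2], dim3[3]), 6L)
    dim(lab2) <- dim(sl)
    border <- unique(c(lab2[1, ], lab2[nrow(lab2), ], lab2[, 1],
                       lab2[, ncol(lab2)]))
    border <- border[border > 0L]
    hole <- bg & !(lab2 %in% border)
    dim(hole) <- dim(sl)
    mask[z, , ] <- sl | hole
  }

  vol <- sum(mask) * prod(dapi$voxel_size)
  if (vol < config$min_spheroid_volume_um3)
    stop(sprintf("no spheroid detected: foreground volume %.0f um^3 below minimum %.0f",
                 vol, config$min_spheroid_volume_um3), call. = FALSE)
  structure(list(mask = mask, threshold_used = thr,
                 voxel_size = dapi$voxel_size),
            class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf("spheroid_mask: %d voxels (%.3g um^3), Otsu threshold %.4g\n",
              sum(x$mask), spheroid_volume(x), x$threshold_used))
  invisible(x)
}

#' Spheroid volume
#'
#' Foreground voxel count times the physical voxel volume.
#'
#' @param mask A `spheroid_mask` (from [detect_spheroid()]).
#' @param voxel_size Optional `(z, y, x)` voxel size in um, overriding the
#'   mask's own.
#' @return Volume in um^3 (0 for an empty mask).
#' @export
spheroid_volume <- function(mask, voxel_size = NULL) {
  stopifnot(inherits(mask, "spheroid_mask"))
  vs <- voxel_size %||% mask$voxel_size
  sum(mask$mask) * prod(vs)
}
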