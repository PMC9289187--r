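# Dynamic (local-mean) threshold evaluated inside a mask: a voxel is
# foreground when its intensity exceeds the local in-mask mean over a physical
# window by `offset_k` robust SDs of the in-mask intensities.
dynamic_threshold_mask <- function(grid, region, window_um, offset_k) {
  dim3 <- dim(grid$data)
  half <- integer(3)
  for (ax in 1:3) {
    w <- as.integer(round(window_um / grid$voxel_size[ax]))
    if (w < 3L)
      stop(sprintf("local-threshold window of %g um spans %d voxel(s) on axis %d; 3 required",
                   window_um, w, ax), call. = FALSE)
    if (w %% 2L == 0L) w <- w + 1L
    half[ax] <- (w - 1L) %/% 2L
  }
  m <- as.numeric(region)
  vals <- as.numeric(grid$data) * m
  s_val <- cpp_box_sum(vals, dim3, half)
  s_cnt <- cpp_box_sum(m, dim3, half)
  local_mean <- ifelse(s_cnt > 0, s_val / pmax(s_cnt, 1), 0)
  inside <- grid$data[region]
  rsd <- mad(inside)
  fg <- region & (grid$data > local_mean + offset_k * rsd)
  dim(fg) <- dim3
  fg
}

#' Segment nuclei in the DAPI channel
#'
#' Step 2 of the analysis, restricted to the spheroid mask:
#' anisotropy-aware Gaussian smoothing, dynamic (local-mean) thresholding over
#' a physical window combined with a global in-mask Otsu gate (a voxel must
#' exceed both; the global gate keeps the local offset, which scales with the
#' noise level, from admitting background at high signal-to-noise), then a
#' marker-controlled watershed seeded at maxima of the anisotropic Euclidean
#' distance transform to split touching nuclei.
#' Labels whose physical volume falls outside
#' `[min_volume_um3, max_volume_um3]` are discarded and the survivors are
#' relabeled consecutively.
#'
#' @param dapi DAPI [voxel_grid].
#' @param spheroid A `spheroid_mask` from [detect_spheroid()].
#' @param config A [pipeline_config()].
#' @return An object of class `nucleus_labels`: list with `labels` (3D integer
#'   array, 0 background), `n_labels`, and `voxel_size`.
#' @export
segment_nuclei <- function(dapi, spheroid, config = pipeline_config()) {
  stopifnot(inherits(dapi, "voxel_grid"), inherits(spheroid, "spheroid_mask"))
  dim3 <- dim(dapi$data)
  if (!identical(dim(spheroid$mask), dim3))
    stop("spheroid mask shape does not match the grid", call. = FALSE)
  vs <- dapi$voxel_size
  empty <- structure(list(labels = array(0L, dim3), n_labels = 0L,
                          voxel_size = vs), class = "nucleus_labels")
  if (!any(spheroid$mask)) return(empty)

  work <- dapi
  if (config$smooth_sigma_um > 0) {
    sig_vox <- config$smooth_sigma_um / vs
    sm <- cpp_gaussian_blur(as.numeric(dapi$data), dim3, sig_vox)
    dim(sm) <- dim3
    work <- voxel_grid(sm, vs, dapi$channel_name)
  }
  fg <- dynamic_threshold_mask(work, spheroid$mask, config$window_um,
                               config$offset_k)
  gate <- tryCatch(otsu_threshold(work$data[spheroid$mask]),
                   error = function(e) -Inf)   # constant in-mask: no gate
  fg <- fg & (work$data > gate)
  if (!any(fg)) return(empty)

  edt <- cpp_edt(as.vector(fg), dim3, vs)
  dim(edt) <- dim3

  # seeds: EDT plateaus that survive a running-max filter over the minimum
  # seed separation, then greedy suppression of close seed pairs
  sep <- max(config$seed_min_distance_um, 1e-6)
  half <- pmax(1L, as.integer(round(sep / vs)))
  mx <- cpp_extreme_filter(as.vector(edt), dim3, half, TRUE)
  dim(mx) <- dim3
  is_max <- fg & (edt >= mx) & (edt > 0.5 * min(vs[2:3]))
  plateau <- cpp_label_components(as.vector(is_max), dim3, 26L)
  n_pl <- attr(plateau, "n_labels")
  if (n_pl == 0L) return(empty)
  dim(plateau) <- dim3

  # one representative voxel per plateau (max EDT, then lowest linear index)
  idx <- which(plateau > 0L)
  pl <- plateau[idx]
  ord <- order(pl, -edt[idx], idx)
  first <- !duplicated(pl[ord])
  seed_idx <- idx[ord][first]
  # physical seed coordinates for separation test
  co <- arrayInd(seed_idx, dim3)
  pz <- (co[, 1] - 0.5) * vs[1]; py <- (co[, 2] - 0.5) * vs[2]
  px <- (co[, 3] - 0.5) * vs[3]
  keep_order <- order(-edt[seed_idx], seed_idx)
  accepted <- integer(0)
  for (k in keep_order) {
    if (length(accepted)) {
      d2 <- (pz[accepted] - pz[k])^2 + (py[accepted] - py[k])^2 +
        (px[accepted] - px[k])^2
      if (any(d2 < sep^2)) next
    }
    accepted <- c(accepted, k)
  }
  seeds <- array(0L, dim3)
  seeds[seed_idx[accepted]] <- seq_along(accepted)

  labels <- cpp_watershed(as.vector(edt), as.vector(seeds), as.vector(fg), dim3)
  dim(labels) <- dim3

  # volume gating and consecutive relabeling
  n_lab <- length(accepted)
  counts <- tabulate(labels[labels > 0L], nbins = n_lab)
  vox_vol <- prod(vs)
  ok <- which(counts * vox_vol >= config$min_volume_um3 &
              counts * vox_vol <= config$max_volume_um3)
  remap <- integer(n_lab)
  remap[ok] <- seq_along(ok)
  out <- array(0L, dim3)
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  structure(list(labels = out, n_labels = length(ok), voxel_size = vs),
            class = "nucleus_labels")
}

#' @export
print.nucleus_labels <- function(x, ...) {
  cat(sprintf("nucleus_labels: %d nuclei in a %s volume\n", x$n_labels,
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}
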