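#' Truncate channel intensities to in-mask percentile bounds
#'
#' Clips a channel to the `[lower_pct, upper_pct]` percentiles of its
#' intensities inside a reference region, bringing stacks (or wells) into a
#' similar intensity range before dynamic thresholding. Used on the NKX6.1
#' channel, whose staining intensity varies strongly with treatment. The
#' operation is idempotent and order-preserving on non-clipped values.
#'
#' @param grid A [voxel_grid].
#' @param lower_pct,upper_pct Percentile bounds, `0 <= lower < upper <= 100`.
#' @param reference_region A `spheroid_mask` (or logical array) over which the
#'   percentiles are computed.
#' @return A [voxel_grid] with clipped intensities.
#' @export
truncate_intensities <- function(grid, lower_pct = 1, upper_pct = 99.5,
                                 reference_region) {
  stopifnot(inherits(grid, "voxel_grid"))
  assert_number(lower_pct, "lower_pct", 0, 100)
  assert_number(upper_pct, "upper_pct", 0, 100)
  if (lower_pct >= upper_pct)
    stop("lower_pct must be < upper_pct", call. = FALSE)
  region <- if (inherits(reference_region, "spheroid_mask"))
    reference_region$mask else reference_region
  if (!identical(dim(region), dim(grid$data)))
    stop("reference region shape does not match the grid", call. = FALSE)
  vals <- grid$data[region]
  if (length(vals) == 0L)
    stop("empty reference region", call. = FALSE)
  # type-1 (inverse-CDF) quantiles: interpolating types are not idempotent
  # once the tails have been clipped to the bounds
  bounds <- quantile(vals, c(lower_pct, upper_pct) / 100, names = FALSE,
                     type = 1)
  out <- pmin(pmax(grid$data, bounds[1]), bounds[2])
  dim(out) <- dim(grid$data)
  voxel_grid(out, grid$voxel_size, grid$channel_name)
}
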