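#' Voxel grid: one channel of one 3D stack
#'
#' A 3D scalar intensity volume with physical voxel sizes. Arrays are ordered
#' `(z, y, x)`; voxel sizes are `(z, y, x)` in um. Voxel centers sit at
#' `(i + 0.5) * voxel_size` for 0-based index `i`.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, non-negative.
#' @param voxel_size Numeric length-3 `(z, y, x)` voxel size in um.
#' @param channel_name Channel label, e.g. `"dapi"`.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), c(3, 0.5, 0.5), "dapi")
#' voxel_volume(g)
voxel_grid <- function(data, voxel_size, channel_name = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (anyNA(data) || min(data) < 0)
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (z, y, x)", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel_name = as.character(channel_name)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_grid '%s': %d x %d x %d voxels (z,y,x), %g x %g x %g um, range [%g, %g]\n",
              x$channel_name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname voxel_grid
#' @param x A `voxel_grid`.
#' @export
voxel_volume <- function(x) prod(x$voxel_size)

#' Plot a Z-slice of a voxel grid
#'
#' @param x A `voxel_grid`.
#' @param z 1-based Z-plane (default: middle plane).
#' @param ... Passed to [graphics::image()].
#' @export
plot.voxel_grid <- function(x, z = ceiling(dim(x$data)[1] / 2), ...) {
  sl <- x$data[z, , ]
  graphics::image(t(sl)[, rev(seq_len(nrow(sl))), drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE,
                  main = sprintf("%s, z = %d", x$channel_name, z), ...)
  invisible(x)
}

#' Multi-channel microtissue stack
#'
#' Bundles one [voxel_grid] per channel for a single microtissue.
#'
#' @param grids Named list of `voxel_grid`s with identical shape & voxel size.
#' @param mt_id Microtissue identifier.
#' @return An object of class `mt_stack`.
#' @export
mt_stack <- function(grids, mt_id = "mt_1") {
  stopifnot(is.list(grids), length(grids) >= 1L, !is.null(names(grids)))
  d0 <- dim(grids[[1]]$data)
  for (g in grids) {
    if (!inherits(g, "voxel_grid")) stop("grids must be voxel_grid objects")
    if (!identical(dim(g$data), d0)) stop("all channels must share one shape")
  }
  structure(list(grids = grids, mt_id = mt_id), class = "mt_stack")
}

#' @export
print.mt_stack <- function(x, ...) {
  d <- dim(x$grids[[1]]$data)
  cat(sprintf("mt_stack '%s': channels [%s], %d x %d x %d voxels\n", x$mt_id,
              paste(names(x$grids), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}
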