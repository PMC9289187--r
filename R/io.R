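#' Write a microtissue stack as multi-page TIFF
#'
#' Pages are ordered channel-major (all Z-planes of channel 1, then channel 2,
#' ...). Channel names, stack shape, voxel sizes, bit depth and any extra
#' metadata go to a JSON sidecar `<stem>.json` next to the TIFF, since
#' baseline TIFF has no standard slot for channel names.
#'
#' @param stack An [mt_stack].
#' @param dir Output directory (created if missing).
#' @param optics An [optics_config()] (supplies the bit depth).
#' @param meta Named list of extra metadata stored in the sidecar.
#' @return Invisibly, the TIFF path.
#' @export
write_stack <- function(stack, dir, optics = optics_config(), meta = list()) {
  stopifnot(inherits(stack, "mt_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^optics$bit_depth - 1
  pages <- list()
  for (ch in names(stack$grids)) {
    a <- stack$grids[[ch]]$data
    for (z in seq_len(dim(a)[1]))
      pages[[length(pages) + 1L]] <- pmin(pmax(a[z, , ], 0), maxval) / maxval
  }
  path <- file.path(dir, paste0(stack$mt_id, ".tif"))
  tiff::writeTIFF(pages, path, bits.per.sample = optics$bit_depth,
                  compression = "LZW")
  side <- c(list(mt_id = stack$mt_id,
                 channels = names(stack$grids),
                 shape = dim(stack$grids[[1]]$data),
                 voxel_size_um = stack$grids[[1]]$voxel_size,
                 bit_depth = optics$bit_depth), meta)
  jsonlite::write_json(side, sub("\\.tif$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a microtissue stack written by [write_stack()]
#'
#' @param path Path to the TIFF file (the JSON sidecar must sit next to it).
#' @return An [mt_stack].
#' @export
read_stack <- function(path) {
  side_path <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(side_path))
    stop("metadata sidecar not found: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(side$shape)
  channels <- as.character(side$channels)
  if (length(pages) != shape[1] * length(channels))
    stop("page count does not match sidecar shape in ", path, call. = FALSE)
  maxval <- 2^side$bit_depth - 1
  grids <- list()
  k <- 0L
  for (ch in channels) {
    a <- array(0, shape)
    for (z in seq_len(shape[1])) {
      k <- k + 1L
      a[z, , ] <- round(pages[[k]] * maxval)
    }
    grids[[ch]] <- voxel_grid(a, as.numeric(side$voxel_size_um), ch)
  }
  mt_stack(grids, mt_id = side$mt_id %||% sub("\\.tiff?$", "", basename(path)))
}

#' Write/read per-nucleus ground truth CSV
#'
#' One row per nucleus: `id, x_um, y_um, z_um, radius_um, is_beta,
#' is_proliferating` (stack-frame coordinates, um).
#'
#' @param truth Ground-truth data frame (from `attr(render_stack(...),
#'   "truth")` or `plate_sim$truth`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  cols <- c("id", "x_um", "y_um", "z_um", "radius", "is_beta",
            "is_proliferating")
  extra <- intersect(c("mt_id", "well", "dose_uM"), names(truth))
  df <- truth[, c(extra, cols)]
  names(df)[names(df) == "radius"] <- "radius_um"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write/read functional records CSV
#'
#' Schema: `mt_id, well, donor, dose_uM, duration_days, basal_secretion,
#' stimulated_secretion, chronic_secretion, insulin_content, atp_content,
#' caspase_lum`.
#'
#' @param functional Data frame of functional records.
#' @param path CSV path.
#' @return Invisibly, `path` (writer) / the data frame (reader).
#' @export
write_functional <- function(functional, path) {
  write.csv(functional, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_functional
#' @export
read_functional <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Read a plate layout CSV
#'
#' Required columns: `well, dose_uM`; recognised extras: `donor,
#' duration_days, treatment, n_mts`.
#'
#' @param path CSV path.
#' @return Layout data frame.
#' @export
read_plate_layout <- function(path) {
  layout <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "dose_uM")
  if (!all(req %in% names(layout)))
    stop("layout CSV must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  layout
}
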