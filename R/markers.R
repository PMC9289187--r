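#' Score marker positivity per nucleus
#'
#' Steps 3-4 of the analysis: the marker channel (optionally truncated
#' beforehand) is segmented with the same dynamic (local-mean) threshold used
#' for nuclei, evaluated inside the spheroid mask; a nucleus is called
#' positive when the fraction of its voxels above the threshold exceeds
#' `config$positive_fraction`. Mean marker intensity per nucleus is computed
#' over the nucleus' voxels from the supplied grid.
#'
#' @param marker Marker [voxel_grid] (NKX6.1 or EdU), congruent with the
#'   label map.
#' @param nuclei A `nucleus_labels` from [segment_nuclei()].
#' @param spheroid A `spheroid_mask`.
#' @param config A [pipeline_config()].
#' @return Data frame with one row per nucleus label: `label`,
#'   `mean_intensity`, `positive_fraction`, `positive`.
#' @export
score_markers <- function(marker, nuclei, spheroid,
                          config = pipeline_config()) {
  stopifnot(inherits(marker, "voxel_grid"), inherits(nuclei, "nucleus_labels"),
            inherits(spheroid, "spheroid_mask"))
  dim3 <- dim(marker$data)
  if (!identical(dim(nuclei$labels), dim3) ||
      !identical(dim(spheroid$mask), dim3))
    stop("marker grid, label map and spheroid mask must share one shape",
         call. = FALSE)
  n <- nuclei$n_labels
  if (n == 0L)
    return(data.frame(label = integer(0), mean_intensity = numeric(0),
                      positive_fraction = numeric(0), positive = logical(0)))
  fg <- dynamic_threshold_mask(marker, spheroid$mask, config$window_um,
                               config$offset_k)
  stats <- cpp_label_stats(as.vector(nuclei$labels), as.numeric(marker$data),
                           dim3, n)
  pos_counts <- cpp_label_true_counts(as.vector(nuclei$labels), as.vector(fg), n)
  frac <- pos_counts / pmax(stats$count, 1)
  data.frame(label = seq_len(n),
             mean_intensity = stats$sum_val / pmax(stats$count, 1),
             positive_fraction = frac,
             positive = frac > config$positive_fraction)
}
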