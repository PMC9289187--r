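#' Colocalize marker label sets
#'
#' Proliferating beta cells are the nuclei carrying both the beta (NKX6.1) and
#' the proliferation (EdU) label: the set intersection.
#'
#' @param beta_ids,edu_ids Integer vectors of nucleus labels drawn from the
#'   same label map.
#' @return Sorted integer vector of proliferating-beta labels.
#' @export
#' @examples
#' colocalize_labels(c(1, 2, 3), c(2, 3, 4)) # 2 3
colocalize_labels <- function(beta_ids, edu_ids) {
  sort(intersect(as.integer(beta_ids), as.integer(edu_ids)))
}

#' Build per-nucleus records from a label map and marker scores
#'
#' @param nuclei A `nucleus_labels`.
#' @param dapi DAPI [voxel_grid].
#' @param nkx_scores,edu_scores Data frames from [score_markers()].
#' @param mt_id Microtissue id stored on every row.
#' @return Data frame (one row per nucleus): `mt_id, label, x_um, y_um, z_um,
#'   volume_um3, mean_dapi, mean_nkx, mean_edu, is_beta, is_edu`.
#' @export
nucleus_records <- function(nuclei, dapi, nkx_scores, edu_scores,
                            mt_id = "mt_1") {
  stopifnot(inherits(nuclei, "nucleus_labels"))
  n <- nuclei$n_labels
  if (n == 0L)
    return(data.frame(mt_id = character(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      volume_um3 = numeric(0), mean_dapi = numeric(0),
                      mean_nkx = numeric(0), mean_edu = numeric(0),
                      is_beta = logical(0), is_edu = logical(0)))
  dim3 <- dim(nuclei$labels)
  st <- cpp_label_stats(as.vector(nuclei$labels), as.numeric(dapi$data), dim3, n)
  vs <- nuclei$voxel_size
  # voxel centers at (i + 0.5) * voxel size, 0-based index = sum/count
  data.frame(mt_id = mt_id, label = seq_len(n),
             x_um = (st$sum_x / st$count + 0.5) * vs[3],
             y_um = (st$sum_y / st$count + 0.5) * vs[2],
             z_um = (st$sum_z / st$count + 0.5) * vs[1],
             volume_um3 = st$count * prod(vs),
             mean_dapi = st$sum_val / st$count,
             mean_nkx = nkx_scores$mean_intensity,
             mean_edu = edu_scores$mean_intensity,
             is_beta = nkx_scores$positive,
             is_edu = edu_scores$positive)
}

#' Quantify one microtissue
#'
#' Per-MT metrics from per-nucleus records: total cell number (DAPI), beta
#' cells (NKX6.1+), proliferating cells (EdU+), proliferating beta cells
#' (EdU+NKX6.1+), the derived percentages (beta fraction = 100 n_beta/n_total,
#' total proliferation = 100 n_edu/n_total, beta proliferation =
#' 100 n_edu_beta/n_beta, non-beta proliferation =
#' 100 (n_edu - n_edu_beta)/(n_total - n_beta)), mean NKX6.1 intensity, and
#' the spheroid volume. Zero denominators yield `NA` percentages with a
#' warning, never errors. Counts may be non-integer (e.g. group means).
#'
#' @param records Per-nucleus data frame from [nucleus_records()], or a list
#'   with counts `n_total, n_beta, n_edu, n_edu_beta` (for worked examples on
#'   printed group means).
#' @param spheroid_volume Spheroid volume, um^3.
#' @param mt_id Identifier (taken from records when present).
#' @param nkx_mean_domain `"beta"`: mean NKX6.1 intensity over beta-classified
#'   nuclei (default); `"all"`: over all nuclei.
#' @return One-row data frame of class `mt_quant`.
#' @export
#' @examples
#' # control-group means: 2.7 proliferating of 1405 total cells
#' q <- quantify_mt(list(n_total = 1405, n_beta = NA, n_edu = 2.7,
#'                       n_edu_beta = NA))
#' round(q$pct_prolif_total, 1) # 0.2
quantify_mt <- function(records, spheroid_volume = NA_real_, mt_id = NULL,
                        nkx_mean_domain = c("beta", "all")) {
  nkx_mean_domain <- match.arg(nkx_mean_domain)
  if (is.data.frame(records)) {
    if (nrow(records) > 0 && any(records$volume_um3 <= 0, na.rm = TRUE))
      stop("nucleus volumes must be positive", call. = FALSE)
    n_total <- nrow(records)
    n_beta <- sum(records$is_beta)
    n_edu <- sum(records$is_edu)
    n_edu_beta <- sum(records$is_beta & records$is_edu)
    mean_nkx <- if (n_total == 0) NA_real_
    else if (nkx_mean_domain == "beta") {
      if (n_beta > 0) mean(records$mean_nkx[records$is_beta]) else NA_real_
    } else mean(records$mean_nkx)
    mt_id <- mt_id %||% (if (n_total > 0) records$mt_id[1] else "mt")
  } else {
    n_total <- records$n_total
    n_beta <- records$n_beta
    n_edu <- records$n_edu
    n_edu_beta <- records$n_edu_beta
    mean_nkx <- records$mean_nkx %||% NA_real_
    mt_id <- mt_id %||% "mt"
  }
  pct <- function(num, den, what) {
    if (is.na(den) || is.na(num)) return(NA_real_)
    if (den <= 0) {
      warning(sprintf("zero denominator for %s; reporting NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  out <- data.frame(
    mt_id = mt_id,
    n_total = n_total, n_beta = n_beta, n_edu = n_edu,
    n_edu_beta = n_edu_beta,
    pct_beta = pct(n_beta, n_total, "pct_beta"),
    pct_prolif_total = pct(n_edu, n_total, "pct_prolif_total"),
    pct_prolif_beta = pct(n_edu_beta, n_beta, "pct_prolif_beta"),
    pct_prolif_nonbeta = pct(n_edu - n_edu_beta, n_total - n_beta,
                             "pct_prolif_nonbeta"),
    mean_nkx_intensity = mean_nkx,
    spheroid_volume_um3 = spheroid_volume)
  # conservation identities hold by construction; assert them anyway
  if (!is.na(out$n_edu_beta) && !is.na(out$n_beta) &&
      (out$n_edu_beta > min(out$n_beta, out$n_edu) + 1e-9 ||
       out$n_beta > out$n_total + 1e-9))
    stop("count invariants violated", call. = FALSE)
  class(out) <- c("mt_quant", "data.frame")
  out
}

#' @export
print.mt_quant <- function(x, ...) {
  cat(sprintf("MT '%s': %g cells, %g beta (%.1f%%), %g EdU+ (%.1f%% total proliferation), %g EdU+ beta\n",
              x$mt_id, x$n_total, x$n_beta, x$pct_beta, x$n_edu,
              x$pct_prolif_total, x$n_edu_beta))
  invisible(x)
}

#' Relative volume change between consecutive timepoints
#'
#' @param volumes Data frame with columns `timepoint` and `volume` (um^3), or
#'   a list of `(timepoint, volume)` pairs; must be time-ordered with at least
#'   2 rows and positive volumes.
#' @return Data frame `t_from, t_to, rel_change` with
#'   `rel_change = (V_t2 - V_t1) / V_t1` per consecutive pair.
#' @export
#' @examples
#' volume_change(data.frame(timepoint = c(0, 4), volume = c(100, 120)))
volume_change <- function(volumes) {
  if (is.list(volumes) && !is.data.frame(volumes))
    volumes <- data.frame(timepoint = vapply(volumes, `[[`, 0, 1),
                          volume = vapply(volumes, `[[`, 0, 2))
  stopifnot(is.data.frame(volumes),
            all(c("timepoint", "volume") %in% names(volumes)))
  if (nrow(volumes) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (any(volumes$volume <= 0)) stop("volumes must be positive", call. = FALSE)
  if (is.unsorted(volumes$timepoint, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  n <- nrow(volumes)
  data.frame(t_from = volumes$timepoint[-n], t_to = volumes$timepoint[-1],
             rel_change = diff(volumes$volume) / volumes$volume[-n])
}

#' Analyze one microtissue stack end to end
#'
#' Runs the full four-step algorithm on a three-channel stack: spheroid
#' detection (DAPI) -> NKX6.1 intensity truncation inside the spheroid ->
#' nuclear segmentation (DAPI) -> marker scoring (NKX6.1, EdU) -> label
#' colocalization -> per-MT quantification.
#'
#' @param stack An [mt_stack] with channels named per `config$channels`.
#' @param config A [pipeline_config()].
#' @return List with `quant` ([quantify_mt] row), `records` (per-nucleus data
#'   frame), `spheroid`, `nuclei`, and `prolif_beta_labels`.
#' @export
analyze_stack <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "mt_stack"))
  ch <- config$channels
  pick <- function(role) {
    key <- ch[[role]]
    g <- if (is.numeric(key)) stack$grids[[key]] else stack$grids[[as.character(key)]]
    if (is.null(g)) stop("channel not found in stack: ", role, call. = FALSE)
    g
  }
  dapi <- pick("dapi"); nkx <- pick("nkx6_1"); edu <- pick("edu")
  spheroid <- detect_spheroid(dapi, config)
  nkx_t <- truncate_intensities(nkx, config$truncation_lower_pct,
                                config$truncation_upper_pct, spheroid)
  nuclei <- segment_nuclei(dapi, spheroid, config)
  nkx_scores <- score_markers(nkx_t, nuclei, spheroid, config)
  edu_scores <- score_markers(edu, nuclei, spheroid, config)
  records <- nucleus_records(nuclei, dapi, nkx_scores, edu_scores,
                             mt_id = stack$mt_id)
  coloc <- colocalize_labels(records$label[records$is_beta],
                             records$label[records$is_edu])
  quant <- quantify_mt(records, spheroid_volume = spheroid_volume(spheroid),
                       mt_id = stack$mt_id,
                       nkx_mean_domain = config$nkx_mean_domain)
  list(quant = quant, records = records, spheroid = spheroid,
       nuclei = nuclei, prolif_beta_labels = coloc)
}
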