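#' Place non-overlapping nuclei inside a spheroid
#'
#' Packs `n_cells` spherical nuclei uniformly inside a ball of radius
#' `spheroid_radius` centered at the origin, by rejection sampling with a
#' spatial hash. Nucleus radii are lognormal with the given mean and CV. At
#' the physiological scale a microtissue reaggregated from ~1700 cells forms
#' a spheroid of ~150 um diameter (one islet equivalent); the package's
#' test-scale default elsewhere is 200 nuclei in a 40 um-radius spheroid.
#'
#' @param n_cells Number of nuclei to place (>= 0).
#' @param spheroid_radius Spheroid radius, um.
#' @param nucleus_radius_mean Mean nucleus radius, um.
#' @param nucleus_radius_cv CV of the nucleus radius (lognormal).
#' @param seed RNG seed; placement is deterministic given the seed.
#' @param packing_tolerance Two nuclei must satisfy
#'   `center distance >= packing_tolerance * (r1 + r2)`.
#' @param max_attempts Rejection attempts per nucleus before failing.
#' @return Data frame with columns `id, x, y, z, radius` (um, origin at the
#'   spheroid center).
#' @export
#' @examples
#' g <- generate_spheroid_geometry(50, spheroid_radius = 30, seed = 1)
#' range(sqrt(g$x^2 + g$y^2 + g$z^2) + g$radius) # all inside the ball
generate_spheroid_geometry <- function(n_cells, spheroid_radius = 40,
                                       nucleus_radius_mean = 3,
                                       nucleus_radius_cv = 0.15,
                                       seed = NULL,
                                       packing_tolerance = 1.0,
                                       max_attempts = 10000L) {
  assert_number(n_cells, "n_cells", lower = 0)
  assert_number(spheroid_radius, "spheroid_radius", lower = 1e-9)
  assert_number(nucleus_radius_mean, "nucleus_radius_mean", lower = 1e-9)
  assert_number(nucleus_radius_cv, "nucleus_radius_cv", lower = 0)
  n_cells <- as.integer(n_cells)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0))
  if (n_cells == 0L) return(empty)
  if (spheroid_radius <= 2 * nucleus_radius_mean)
    stop("spheroid_radius must exceed 2 x nucleus_radius_mean", call. = FALSE)
  # feasibility: total expected nuclear volume at most 60% of the spheroid
  vol_ratio <- n_cells * (4 / 3) * pi * nucleus_radius_mean^3 /
    ((4 / 3) * pi * spheroid_radius^3)
  if (vol_ratio > 0.6)
    stop(sprintf("infeasible packing: requested nuclear volume is %.0f%% of the spheroid",
                 100 * vol_ratio), call. = FALSE)

  with_seed(seed, {
    sdlog <- sqrt(log(1 + nucleus_radius_cv^2))
    meanlog <- log(nucleus_radius_mean) - sdlog^2 / 2
    radii <- if (nucleus_radius_cv > 0) rlnorm(n_cells, meanlog, sdlog)
             else rep(nucleus_radius_mean, n_cells)
    # spatial hash with cell size >= max possible pair reach
    hcell <- 2 * max(radii) * max(packing_tolerance, 1)
    hash <- new.env(hash = TRUE, parent = emptyenv())
    hkey <- function(p) paste(floor(p / hcell), collapse = ",")
    xs <- ys <- zs <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      r <- radii[i]
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        # uniform point in the ball of radius (R - r)
        u <- runif(3, -1, 1)
        while (sum(u^2) > 1) u <- runif(3, -1, 1)
        p <- u * (spheroid_radius - r)
        # neighbors from the 27 surrounding hash cells
        ok <- TRUE
        base <- floor(p / hcell)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          key <- paste(base + c(dx, dy, dz), collapse = ",")
          idxs <- hash[[key]]
          if (is.null(idxs)) next
          for (j in idxs) {
            dd <- sqrt((p[1] - xs[j])^2 + (p[2] - ys[j])^2 + (p[3] - zs[j])^2)
            if (dd < packing_tolerance * (r + radii[j])) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) {
          xs[i] <- p[1]; ys[i] <- p[2]; zs[i] <- p[3]
          key <- hkey(p)
          hash[[key]] <- c(hash[[key]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("packing failed: placed %d of %d nuclei after %d attempts each",
                     i - 1L, n_cells, max_attempts), call. = FALSE)
    }
    data.frame(id = seq_len(n_cells), x = xs, y = ys, z = zs, radius = radii)
  })
}
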