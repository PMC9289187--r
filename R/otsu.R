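#' Otsu threshold of a voxel grid
#'
#' Builds an `n_bins` intensity histogram over the grid's range and returns
#' the bin edge that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties are broken by the lowest qualifying
#' threshold. Voxels strictly above the returned value are foreground.
#'
#' @param grid A [voxel_grid] (or bare numeric array/vector).
#' @param n_bins Number of histogram bins.
#' @return The threshold intensity (a bin edge).
#' @export
#' @examples
#' v <- voxel_grid(array(c(rep(10, 900), rep(200, 100)), c(10, 10, 10)),
#'                 c(3, 0.5, 0.5))
#' otsu_threshold(v)
otsu_threshold <- function(grid, n_bins = 256L) {
  x <- if (inherits(grid, "voxel_grid")) as.vector(grid$data) else as.vector(grid)
  assert_number(n_bins, "n_bins", lower = 2)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate histogram: image is constant, no threshold exists",
         call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  n <- length(x)
  w0 <- cumsum(counts) / n                 # weight of class <= edge t
  m0 <- cumsum(counts * mids)              # cumulative intensity mass
  mu_tot <- m0[n_bins] / n
  # candidate thresholds are the upper edges of bins 1..n_bins-1
  w0c <- w0[-n_bins]
  mu0 <- ifelse(w0c > 0, (m0[-n_bins] / n) / w0c, 0)
  w1c <- 1 - w0c
  mu1 <- ifelse(w1c > 0, (mu_tot - w0c * mu0) / w1c, 0)
  bcv <- w0c * w1c * (mu0 - mu1)^2
  best <- which(bcv == max(bcv))[1]        # lowest qualifying threshold
  edges[best + 1L]
}
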