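# Shared fixtures: small synthetic microtissues and truth-matching utilities.

# Default test-scale conditions: 200 nuclei in a 40 um-radius spheroid.
test_optics <- function(...) optics_config(...)
hi_snr_optics <- function() optics_config(photon_scale = 5, noise_gaussian_sd = 2)
noise_free_optics <- function() optics_config(photon_scale = Inf,
                                              noise_gaussian_sd = 0)

# Empty ground-truth table with all phenotype columns.
empty_truth <- function() {
  assign_phenotypes(generate_spheroid_geometry(0), phenotype_model())
}

# Render custom ground truth with the diffuse tissue signal the simulator uses.
render_mt <- function(truth, optics, spheroid_radius, seed,
                      stack_shape = stack_shape_for(spheroid_radius, optics)) {
  render_stack(truth, optics, stack_shape, seed = seed,
               diffuse = c(dapi = 150, nkx6_1 = 0, edu = 0),
               spheroid_radius = spheroid_radius)
}

# Label value of the nucleus label map at each true centroid.
labels_at_truth <- function(labels, truth) {
  dim3 <- dim(labels$labels)
  vs <- labels$voxel_size
  iz <- pmin(pmax(floor(truth$z_um / vs[1]) + 1L, 1L), dim3[1])
  iy <- pmin(pmax(floor(truth$y_um / vs[2]) + 1L, 1L), dim3[2])
  ix <- pmin(pmax(floor(truth$x_um / vs[3]) + 1L, 1L), dim3[3])
  labels$labels[cbind(iz, iy, ix)]
}

# 1-1 greedy matching of true centroids to labels: a label holding several
# centroids matches exactly one of them.
match_truth <- function(analysis, truth) {
  at <- labels_at_truth(analysis$nuclei, truth)
  tt <- table(at[at > 0])
  singles <- as.integer(names(tt)[tt == 1])
  list(label_at_truth = at,
       recall = sum(tt >= 1) / nrow(truth),
       unique_idx = which(at %in% singles))
}

# Rasterized ball congruent with a stack (voxel-center convention).
truth_ball <- function(stack, radius) {
  d3 <- dim(stack$grids[[1]]$data)
  vs <- stack$grids[[1]]$voxel_size
  zc <- (seq_len(d3[1]) - 0.5) * vs[1]
  yc <- (seq_len(d3[2]) - 0.5) * vs[2]
  xc <- (seq_len(d3[3]) - 0.5) * vs[3]
  ctr <- d3 * vs / 2
  outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"), (xc - ctr[3])^2, "+") <=
    radius^2
}

# Whole-volume spheroid mask (for exercising segment_nuclei in isolation).
full_mask <- function(stack) {
  g <- stack$grids[[1]]
  structure(list(mask = array(TRUE, dim(g$data)), threshold_used = 0,
                 voxel_size = g$voxel_size), class = "spheroid_mask")
}
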