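# Shared fixtures built in code: small volumes, hand-made sweep sets, and
# matching utilities used across the suite.

# a sweep_set assembled directly from a current matrix
make_sweeps <- function(current, fs = 20000, stimulus_times_s = 0.05,
                        holding_mv = -60, reversal_mv = 0,
                        filter_cutoff_hz = 4000) {
  acq <- acquisition_spec(sampling_rate_hz = fs,
                          filter_cutoff_hz = filter_cutoff_hz,
                          sweep_duration_s = nrow(current) / fs,
                          holding_mv = holding_mv, reversal_mv = reversal_mv,
                          stimulus_times_s = stimulus_times_s)
  structure(list(current = current, acquisition = acq, truth = NULL,
                 burst_truth = NULL), class = "sweep_set")
}

# match each detected position to the nearest truth row (3-d euclidean, um);
# returns truth row indices
match_boutons <- function(detected, truth, max_dist_um = 0.5) {
  vapply(seq_len(nrow(detected)), function(i) {
    d2 <- (truth$x_um - detected$x_um[i])^2 +
          (truth$y_um - detected$y_um[i])^2 +
          (truth$z_um - detected$z_um[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist_um) j else NA_integer_
  }, 1L)
}

# small standard test volume spec (20 x 20 x 3 um)
small_spec <- function(nxy = 200L) volume_spec(shape_xy = c(nxy, nxy), n_z = 15L)

# build a VOI-shaped channel stack from two vectors recycled over the block;
# the vgat values stay below the edge threshold so no voxel is excluded
voi_stack <- function(vgat_vals, marker_vals, dims = c(15L, 15L, 5L)) {
  n <- prod(dims)
  list(vgat = array(rep_len(vgat_vals, n), dim = dims),
       syp_tdt = array(rep_len(marker_vals, n), dim = dims))
}

# score a full-block VOI with edge exclusion disabled (threshold above any
# intensity), centered in a stack exactly one VOI large
score_full_voi <- function(vgat_vals, marker_vals, dims = c(15L, 15L, 5L)) {
  stk <- voi_stack(vgat_vals, marker_vals, dims)
  cfg <- coloc_config()
  score_bouton(stk, centroid = (dims + 1L) / 2L, marker = "syp_tdt",
               config = cfg, voxel_size_um = c(0.1, 0.1, 0.2),
               background = list(mean = 1e6, sd = 1))
}
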