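# Shared fixtures: small phantoms and a pre-trained storage-tissue
# classifier, built once per test run.

# Mid-size phantom with storage tissue, native (no further downsampling).
small_phantom <- function(seed = 1, n_tubules = 8, noise_sd = 5,
                          size = 256, st_fraction = 0.2,
                          semi_axis_um = c(log(16 * size / 256), 0.1),
                          margin = 4 * size / 256) {
  generate_phantom(phantom_spec(
    height_px = size, width_px = size, microns_per_pixel = 2,
    n_tubules = n_tubules, tubule_semi_axis_um = semi_axis_um,
    aspect_ratio_range = c(1, 1.2), st_fraction = st_fraction,
    tissue_fraction = 0.7, tubule_margin_px = margin,
    noise_sd = noise_sd, seed = seed
  ))
}

# Storage-tissue classifier trained on a phantom disjoint from any used in
# assertions (same palette).
trained_st_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      ph <- small_phantom(seed = 4242)
      tr <- st_training_frame(ph$image, ph$truth$whole_mask,
                              ph$truth$gt_mask, ph$truth$st_mask,
                              max_per_class = 2500, seed = 11)
      model <<- fit_st_classifier(tr, seed = 7)
    }
    model
  }
})

# Config for native-resolution phantom images (2 um/px, no downsampling).
native_config <- function(...) {
  pipeline_config(microns_per_pixel = 2, downsample_factor = 1, ...)
}

expect_jaccard_gte <- function(est, truth, floor) {
  j <- sum(est & truth) / sum(est | truth)
  expect_gte(j, floor)
  invisible(j)
}
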