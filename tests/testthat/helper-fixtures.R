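# Small scene fixtures used across the suite.

# A scene with perfectly flat boundaries at the given 0-based rows.
flat_scene <- function(width = 20L, depth = 80L,
                       rows = c(10, 20, 30, 40, 50, 60),
                       layer_means = c(NFL = 0.1, GCL_IPL = 0.3, INL = 0.5,
                                       OPL = 0.7, ONL = 0.9),
                       vitreous_mean = 0.02, sub_elm_mean = 0.6,
                       band = 20L) {
  scene_config(width = width, depth = depth, layer_means = layer_means,
               vitreous_mean = vitreous_mean, sub_elm_mean = sub_elm_mean,
               band = band,
               boundary_params = list(base_frac = rows / depth,
                                      tilt = 0, bow = 0,
                                      fovea_center = 0.5, fovea_width = 0.1,
                                      dip_frac = rep(0, 6)))
}

# A compact curved scene for study-level tests (keeps runtimes small).
small_scene <- function(width = 96L, depth = 160L) {
  scene_config(width = width, depth = depth)
}

# Noise with only the per-frame uncorrelated component (sqrt-M regime).
uncorrelated_noise <- function(sigma_u = 0.05) {
  noise_config(sigma_u = sigma_u, sigma_c = 0)
}

# Mid-range layer means that keep +-6 sd away from the [0,1] clip
# boundaries at sigma_u = 0.05.
midrange_scene <- function(width = 64L, depth = 96L) {
  flat_scene(width = width, depth = depth,
             rows = round(c(10, 22, 34, 46, 58, 70) * depth / 96),
             layer_means = c(NFL = 0.35, GCL_IPL = 0.45, INL = 0.55,
                             OPL = 0.65, ONL = 0.75),
             vitreous_mean = 0.5, sub_elm_mean = 0.5,
             band = round(20 * depth / 96))
}

# Image-level SNR of an averaged stack generated from a clean scene.
measured_image_snr <- function(clean, mask, M, noise, seed) {
  avg <- average_frames(generate_frames(clean, M, noise, seed = seed))
  image_quality(avg, mask)$snr_image
}
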