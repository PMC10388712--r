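# Shared fixtures: small phantom/hologram pairs and error metrics.

centered_phantom <- function(shape = c(96, 96), radius = 30, peak = 6,
                             label = "viable", profile = "auto",
                             texture_sd = 0, seed = NULL) {
  make_phantom(label, shape = shape, center = (shape - 1) / 2,
               radius = radius, peak_phase = peak, profile = profile,
               texture_sd = texture_sd, seed = seed)
}

erode_mask <- function(mask, by = 2) {
  EBImage::erode(mask * 1, EBImage::makeBrush(2 * by + 1, "disc")) == 1
}

masked_rmse <- function(phase, truth, mask) {
  sqrt(mean((phase[mask] - truth[mask])^2))
}

# Reconstruct a hologram all the way to a flattened phase map.
recover_phase <- function(field, mask = NULL) {
  remove_background(unwrap_tie(wrap_phase(field)), mask = mask)
}
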